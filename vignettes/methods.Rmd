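---
title: "Methods: dimer conformational coordinates, well-tempered metadynamics, and channel kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dimer conformational coordinates, well-tempered metadynamics, and channel kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampartools)
```

`ampartools` analyses the conformational behaviour of two-lobed
receptor-domain dimers — the N-terminal domain (NTD) dimers of
AMPA-type glutamate receptors being the motivating case — together
with the patch-clamp kinetics of the channels those receptors gate.
This vignette records the models implemented, the conventions chosen
where several were defensible, and what the synthetic data used for
validation does and does not capture.

## Conformational coordinates of a clamshell dimer

Each subunit of an NTD dimer is a two-lobed clamshell. The package
reduces a dimer's conformation to two collective variables built from
six centres of mass (C-alpha, unweighted means — identical to mass
weighting when a single atom type is used):

* `com1`/`com2`: upper and lower lobe of subunit 1,
* `com3`/`com4`: upper and lower lobe of subunit 2,
* `com13`/`com24`: joint centroids of both upper and both lower lobes.

The default lobe partition, exposed via `lobe_definition()`, is
residues 117–243 and 354–380 (upper) and 1–116 and 244–353 (lower) in
mature-peptide numbering, i.e. with the signal peptide removed.
Deposited coordinate files frequently use a different numbering; the
per-structure `numbering_offset` maps file numbering onto mature
numbering and is deliberately a user parameter with no hard-coded
per-entry table — the offset should be verified against marker
residues (for instance the interfacial arginine of the GluA3 NTD
dimer) before quantitative use.

**Displacement torsion** is the signed dihedral over the ordered
points (`com2`, `com1`, `com3`, `com4`): the rotation of the two
lower lobes relative to each other about the axis through the two
upper-lobe centroids. It is near 0° for "flat" dimers and moves
towards roughly −25° to −30° for displaced, GluA2-like dimers. We use
the standard atan2 dihedral convention and report degrees in
(−180, 180]. A note on the point order: the torsion is stated in the
underlying simulation setup as running from the lower lobe of subunit
1 through both upper lobes to the *lower* lobe of subunit 2; the
fourth point is therefore `com4`. (A description that reuses the
upper-lobe label for the final point is internally inconsistent with
the quantity's purpose — capturing lower-lobe counter-rotation — and
is treated as a label slip.)

**Projected opening angle**: with `v1 = com2 − com13` and
`v2 = com4 − com13`, both vectors are projected onto the plane
perpendicular to the *ghost axis* and the signed angle from the first
projection to the second about that axis is returned. The ghost point
`g2` sits 0.5 Å from `com24` along the normal of the plane through
`com24`, `com1`, `com3` (normal direction
`(com1 − com24) × (com3 − com24)`); the projection removes the
component of apparent opening that is really lower-lobe displacement.
The angle is reported signed; consumers who only care about magnitude
can take `abs()`. Both coordinates are invariant under rigid motion of
the whole dimer, the torsion is invariant under subunit relabelling
and changes sign under mirror reflection — these are tested as
properties.

`coords_series()` maps either computation over trajectory frames
(multi-model PDB or plain XYZ frame series).

## Interface metrics

`com_separation()`, `residue_pair_distance()` (atom rules `CA`, `CZ`,
or `closest-heavy`), `contact_footprint()` and
`footprint_difference()` implement the distance-type measurements
used to compare receptor architectures: tier expansion as a
centre-of-mass separation, marker-residue approximation distances,
arginine-stack Cζ–Cζ distances, and residue-level interface
footprints whose set difference reports contacts lost or gained in a
mutant. The contact cutoff defaults to 4.0 Å on the minimum
heavy-atom distance; no cutoff is canonical for open-book footprint
figures, so it is configurable and recorded in the `footprint`
object, and footprints at different cutoffs refuse to be compared.

## Well-tempered metadynamics

Metadynamics deposits Gaussian bias hills along a trajectory of
collective variables; well-tempering shrinks the deposit as bias
accumulates. With temperature `T`, bias factor
`gamma = (T + dT)/T = 10`, initial height `h0 = 1.2` kJ/mol and
deposition every 10 ps (the defaults of `wt_params()`), the height of
a hill deposited at CV position `s` is

```
h = h0 * exp(-V(s) / (kB * dT)),        dT = (gamma - 1) * T,
```

with `V` the bias already present and `kB = 0.0083144621` kJ/mol/K.
Hill widths are diffusion-adaptive: per CV, sigma is the
root-mean-square displacement of the CV over the trailing 10 ps
window, clamped to `[0.1, 0.25]` CV units (fallback `sigma0` before
the window fills — the width used before the adaptive window is full
is not a published quantity, so it is an explicit parameter). The
band is deliberately narrow: hill *volume* grows with sigma², and
widths that vary strongly across the landscape distort the
deposition-flux balance on which the histogram free-energy estimator
(below) rests. Torsion-like CVs are treated as periodic with period
360° using minimum-image differences everywhere.

Hills logs are read and written in the PLUMED text dialect
(`#! FIELDS time <cv1> <cv2> sigma_* height biasf` plus optional
`#! SET min_*/max_*` periodicity metadata); multiple walker files
merge into one time-sorted log with the file index as walker id.

Two reconstructions of the free-energy surface are provided and
labelled in `fes$method`:

* `fes_from_hills()`: `F(s) = -(gamma/(gamma-1)) * V(s, t_final)`,
  the standard well-tempered estimator from the summed bias;
* `fes_from_histogram()`: `F(s) = -kB*(T + dT) * log(density)`, using
  the well-tempered stationary distribution
  `P(s) ∝ exp(-F(s)/(kB*(T + dT)))`; the density is a Gaussian-kernel
  estimate (`MASS::kde2d`) of the visited CV values.

Both are min-shifted to zero; histogram nodes with negligible density
are marked unvisited (`NA`). Which route a published landscape used
is often not recoverable; providing both, plus their agreement check,
is the package's answer. A practical caveat worth stating: any error
in the log-density is amplified by `kB*(T + dT)` (about 25 kJ/mol at
the defaults), so the histogram route needs either long sampling or
deliberate kernel smoothing, and its node-level noise makes
basin-*minimum* readouts biased low — `fes_basin_difference()`
therefore offers a disk-mean statistic alongside the minimum.

### The toy Langevin driver

`run_toy_metad()` integrates overdamped (Brownian) dynamics of
multiple walkers directly in the 2D CV space of an analytic potential
(`toy_potential()`), sharing one bias: per CV,
`ds = -grad(U + V) dt/friction + sqrt(2 kB T dt/friction) * N(0,1)`.
The thermostat and all-atom machinery of a molecular-dynamics engine
are out of scope; the driver exists so that every claim about the
well-tempered scheme can be tested against an exactly known surface.
For speed the shared bias *force* is accumulated on a 201×201 grid
(each deposited hill added analytically, read back by bilinear
interpolation); the recorded hills themselves are exact, and all
reconstruction uses exact Gaussian summation over the log. The
integration domain has reflective walls at ±2.5 CV units and a hard
stability guard one unit further out that raises an error naming the
step. All randomness flows through R's RNG, so a seed fixes the run
bit for bit.

The reference validation, `double_well_benchmark()`, uses the tilted
double well

```
U(x, y) = barrier*(x^2-1)^2 - (delta/4)*(3x - x^3) + 0.5*ky*y^2
```

whose tilt term has zero slope at x = ±1, so the minima sit exactly
at (±1, 0) with an *exact* free-energy difference `delta` (default
5 kJ/mol, barrier 12 kJ/mol, ky = 10). Because the CVs are the
coordinates themselves, the true surface is the potential — no
quadrature or reference simulation is needed. The documented problem
size is 8×10⁷ steps per walker (dt = 0.005 ps, friction 50, i.e.
400 ns per walker, four walkers, ~4×10⁴ hills per walker); the
histogram estimate discards the first 35 % of the run as fill-in
transient and smooths with a 0.2-unit kernel. At this length both
routes land within 1 kJ/mol of the analytic difference across seeds;
the acceptance script recomputes this end to end. Equipartition of
the zero-bias driver (`h0 = 0`) on a harmonic well is tested
separately against `var(s) = kB*T/k`.

## Patch-clamp kinetics

`fit_decay()` fits desensitization decays with one or two
exponentials plus a baseline, by bounded Levenberg–Marquardt
(`minpack.lm`) from three deterministic starts. The fit window opens
at the first falling-phase sample at 90 % of the peak — the standard
convention for macroscopic decay fitting — and the reported
amplitudes are referenced to the window start (as any windowed fit's
coefficients are). For two components the amplitude-weighted time
constant

```
tau_w,des = tau_f * Af/(Af+As) + tau_s * As/(Af+As)
```

is reported with components ordered `tau_f <= tau_s`; it always lies
between the two time constants and is invariant to rescaling both
amplitudes.

`fit_recovery()` fits two-pulse recovery-from-desensitization series
with a sum of two Hodgkin–Huxley terms,

```
y = y0 + a1*(1 - exp(-x*k1))^m1 + (ymax - a1 - y0)*(1 - exp(-x*k2))^m2,
```

with slopes fixed (`m1 = 4`, `m2 = 1`) and `ymax = 1`, matching the
protocol in which recovery profiles are steep enough that the slopes
need not float. Time constants are the reciprocal rates
(`tau_i = 1/k_i`) and the weighted recovery tau is
`(tau1*a1 + tau2*(ymax - a1 - y0))/(ymax - y0)`.

`nsfa()` implements non-stationary fluctuation analysis on the
desensitizing phase of repeated responses: per-sample ensemble mean
and variance, ten equal-count amplitude bins (equal-width available),
and a least-squares fit of the parabola
`sigma² = i*I − I²/N + sigma_b²`. Because the model is linear in `i`,
`1/N` and the background term, an exact linear fit is used — no
iterative optimizer, no starting values. One numerically material
choice: the quadratic regressor is the within-bin mean of `I²`, not
the square of the bin mean. Equal-count bins are wide in the sparse
near-peak amplitude range, and ignoring the within-bin variance of
`I` there biases `N` downward by tens of percent; using the bin mean
of `I²` makes the binned relation exact. The background-variance term
is reported under a configurable sign convention: the printed form of
the relation in the experimental literature carries `−sigma_o²`,
while an additive fitted background `+sigma_b²` is the conventional
reading; both describe the same fitted parabola and `background =
"add"` (default) vs `"subtract"` only flips the reported sign. The
single-channel conductance is `gamma = i/Vh` (holding potential
−60 mV by default, uncorrected for junction potential, reported in
pS) and the peak open probability is `Popen = I_peak/(N*i)`. The
fitted-parabola vertex identities (`I = i*N/2`,
`sigma² = i²*N/4 + sigma_b²`) are returned with every fit and checked
in the tests.

`rectification_index()` is the three-point index
`RI = −(I(+40) − I(0))/(I(−60) − I(0))` from a voltage ramp: about
2/3 for an ohmic conductance, near 0 for fully inwardly rectifying
(GluA2-lacking, polyamine-blocked) receptors. `train_ratios()`
normalizes pulse-train peak amplitudes to the first pulse and reports
P5/P1.

## Synthetic data: what it does and does not emulate

The generators in this package define the study conditions under
which every claim is tested:

* `make_two_lobe_dimer()` builds rigid two-lobe subunits as Gaussian
  point clouds (s.d. 5 Å, ~40 residues per lobe) whose centroids
  realize a prescribed torsion and opening *exactly* in closed form;
  isotropic coordinate noise is added afterwards. Real NTD dimers add
  internal lobe deformation, asymmetric subunits and correlated
  motions that this construction deliberately omits: passing the
  round-trip tests shows the coordinate definitions and their
  numerics are exact, not that real structures are rigid.
* `make_channel_sweeps()` draws open-channel counts
  Binomial(N, p(t)) per sample with additive Gaussian baseline noise
  — precisely the ensemble NSFA assumes. Gating correlations between
  samples, rundown between sweeps and filtering artefacts are not
  modelled, so the NSFA recovery bounds certify the estimator, not
  robustness to every experimental pathology.
* `make_recovery_series()` and `make_iv_ramp()` evaluate the fitted
  functional forms themselves (plus noise / a logistic block factor),
  so recovery there validates the fitting machinery and closed-form
  arithmetic.
* The toy double well stands in for the all-atom dimer system; its
  two CVs are sampled directly rather than through molecular
  coordinates, so metadynamics conclusions transfer only at the level
  of the biasing scheme and estimators.

Experimental-scale validation against deposited structures and
trajectories (PDB entries, archived simulation records) requires
downloads and is intentionally outside the default test surface;
`load_structure()` and `coords_series()` accept those files directly
once the numbering offset is established.

## Numerical choices and degenerate inputs

Angles are degrees externally, radians internally. Superposition uses
the Kabsch SVD construction with the determinant sign correction;
collinear point sets are rejected (conditioning), as are point sets
smaller than three. Dihedrals and opening angles raise errors on
zero-length or collinear constructions rather than returning
arbitrary values. Altloc-bearing structures keep the
highest-occupancy conformer (ties broken by label order); hydrogens
are excluded from all geometry by default. Flat traces, zero total
amplitudes, identical sweeps and sub-minimal ensembles (< 20 sweeps
for NSFA, < 6 points for recovery fits) are rejected with specific
errors. Decay and recovery fits mitigate local minima with three
deterministic multi-starts; the NSFA fit is linear and needs none.

## Interfaces

The exported R functions are the package's interface, composed in
scripts or interactively; `scripts/acceptance.R` in the source tree
is a worked example of driving every module end to end. Readers and
writers cover PDB/mmCIF structures, multi-model PDB and XYZ
trajectories, PLUMED-style hills logs, FES grid text/CSV, sweep CSV
tables, and CSV dumps of point sets, coordinate series and
footprints.

## Known limitations

* The histogram FES estimator inherits the `kB*(T+dT)` amplification
  of density errors discussed above; on short runs prefer
  `fes_from_hills()` and treat histogram basin minima with caution.
* Adaptive Gaussians use a windowed RMS-displacement estimator as a
  stand-in for engine-specific diffusion estimators; non-diagonal
  covariance is not implemented.
* `Popen` assumes the fitted `N*i` and the observed peak mean belong
  to the same ensemble; partial rundown across sweeps violates this.
* The mmCIF writer emits a minimal `atom_site` loop sufficient for
  round-tripping atom tables, not a full mmCIF data model.
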