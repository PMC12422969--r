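# Synthetic inputs with the statistical and geometric structure the
# analyses assume: rigid two-lobe dimers with exactly prescribed
# conformational coordinates, binomial channel-noise sweep ensembles,
# two-pulse recovery series, and rectifying I-V ramps. Every generator
# is deterministic given its seed and records its construction ground
# truth as attributes.

#' Build a two-lobe dimer with prescribed coordinates
#'
#' Constructs two rigid two-lobe subunits as Gaussian point clouds
#' whose lobe centroids realize the prescribed displacement torsion and
#' projected opening angle exactly (before noise). The construction
#' places the two upper-lobe centroids on the x axis, symmetric about
#' the origin, and solves for the two lower-lobe centroids in closed
#' form; each lobe cloud is mean-centred and translated onto its
#' centroid, so the centroid values are exact to machine precision.
#'
#' @param residues_per_lobe atoms (C-alpha) per lobe, >= 3.
#' @param lobe_spacing upper-to-lower lobe centroid distance within a
#'   subunit, Angstrom.
#' @param subunit_separation distance between the two upper-lobe
#'   centroids, Angstrom.
#' @param torsion prescribed displacement torsion, degrees in
#'   (-180, 180].
#' @param opening prescribed projected opening angle, degrees in
#'   (-180, 180).
#' @param noise isotropic per-atom Gaussian noise s.d., Angstrom.
#' @param seed RNG seed; identical inputs give identical output.
#' @param cloud_sd s.d. of the per-lobe Gaussian point cloud,
#'   Angstrom.
#' @return a `structure3d` with chains "A" and "B"; lower lobe =
#'   residues 1..n, upper lobe = residues (n+1)..2n. Attributes:
#'   `lobes` (the matching [lobe_definition()]) and `truth` (list of
#'   the prescribed torsion/opening and exact centroid positions).
#' @export
make_two_lobe_dimer <- function(residues_per_lobe = 40L,
                                lobe_spacing = 25,
                                subunit_separation = 30,
                                torsion = 0, opening = 40, noise = 0,
                                seed = 1L, cloud_sd = 5) {
  n <- as.integer(residues_per_lobe)
  stopifnot(n >= 3L, noise >= 0, lobe_spacing > 0,
            subunit_separation > 0)
  if (torsion <= -180 || torsion > 180 || opening <= -180 ||
      opening >= 180)
    stop("torsion/opening outside (-180, 180]", call. = FALSE)
  coms <- dimer_centroid_layout(torsion, opening, lobe_spacing,
                                subunit_separation)
  set.seed(as.integer(seed))
  centred_cloud <- function() {
    m <- matrix(stats::rnorm(3L * n, sd = cloud_sd), ncol = 3L)
    sweep(m, 2L, colMeans(m))
  }
  t_up <- centred_cloud()
  t_low <- centred_cloud()
  place <- function(template, com) sweep(template, 2L, com, `+`)
  xyz <- rbind(place(t_low, coms$com2),  # chain A lower, res 1..n
               place(t_up, coms$com1),   # chain A upper, res n+1..2n
               place(t_low, coms$com4),  # chain B lower
               place(t_up, coms$com3))   # chain B upper
  if (noise > 0)
    xyz <- xyz + matrix(stats::rnorm(length(xyz), sd = noise),
                        ncol = 3L)
  atom <- data.frame(
    chain = rep(c("A", "B"), each = 2L * n),
    resno = rep(seq_len(2L * n), times = 2L),
    resid = "ALA", elety = "CA",
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    stringsAsFactors = FALSE)
  st <- structure3d(atom)
  attr(st, "lobes") <- lobe_definition(
    upper_ranges = list(c(n + 1L, 2L * n)),
    lower_ranges = list(c(1L, n)))
  attr(st, "truth") <- c(list(torsion = torsion, opening = opening,
                              noise = noise, seed = seed), coms)
  st
}

# Closed-form centroid layout realizing (torsion, opening) exactly.
dimer_centroid_layout <- function(torsion, opening, lobe_spacing,
                                  subunit_separation) {
  th <- torsion * pi / 180
  ph <- opening * pi / 180
  a <- subunit_separation / 2
  r <- lobe_spacing
  rc2 <- r * cos(th / 2)
  rs2 <- r * sin(th / 2)
  cc <- -rc2 * tan(ph / 2)
  list(com1 = c(-a, 0, 0), com3 = c(a, 0, 0),
       com2 = c(-cc, -rc2, -rs2), com4 = c(cc, -rc2, rs2))
}

#' Generate a dimer trajectory following a coordinate schedule
#'
#' One [make_two_lobe_dimer()] per frame with common lobe templates
#' (the same template seed for every frame), so the only frame-to-frame
#' changes are the prescribed coordinates and the per-frame noise.
#'
#' @param schedule data frame (or list) with per-frame `torsion` and
#'   `opening` targets, degrees.
#' @param noise per-atom noise s.d., Angstrom.
#' @param seed RNG seed.
#' @param ... passed to [make_two_lobe_dimer()].
#' @return list of `structure3d`, one per schedule row (empty schedule
#'   gives an empty list).
#' @export
make_dimer_trajectory <- function(schedule, noise = 0, seed = 1L, ...) {
  schedule <- as.data.frame(schedule)
  if (!nrow(schedule)) return(list())
  stopifnot(all(c("torsion", "opening") %in% names(schedule)))
  lapply(seq_len(nrow(schedule)), function(i) {
    fr <- make_two_lobe_dimer(torsion = schedule$torsion[i],
                              opening = schedule$opening[i],
                              noise = 0, seed = seed, ...)
    if (noise > 0) {
      # per-frame noise stream independent of the template seed
      set.seed(as.integer(seed) + i)
      fr$atom[, c("x", "y", "z")] <- fr$atom[, c("x", "y", "z")] +
        matrix(stats::rnorm(3L * nrow(fr$atom), sd = noise), ncol = 3L)
    }
    fr$model_index <- i
    fr
  })
}

#' Simulate binomial channel-gating current sweeps
#'
#' Per sample, the number of open channels is Binomial(N, p(t)) and
#' the current is `count * i` plus Gaussian baseline noise: the
#' ensemble model underlying non-stationary fluctuation analysis
#' (sample-to-sample gating correlations are not modelled, matching
#' NSFA's own assumption).
#'
#' @param n_channels N, number of channels.
#' @param i_single single-channel current, pA (negative for inward).
#' @param p_open open-probability time course: a function of time
#'   (ms) or a vector on the time grid, values in \[0, 1\]. The default
#'   is a bi-exponentially desensitizing pulse response,
#'   `0.8 * (1 - exp(-t/0.3)) * (0.7*exp(-t/5) + 0.3*exp(-t/50))`.
#' @param duration_ms sweep length, ms.
#' @param dt_ms sampling interval, ms.
#' @param baseline_sd additive Gaussian baseline noise s.d., pA.
#' @param n_sweeps number of sweeps.
#' @param holding_potential mV.
#' @param seed RNG seed.
#' @return a [sweep_set()] with attribute `truth` (N, i, p trace).
#' @export
make_channel_sweeps <- function(n_channels = 100L, i_single = -1,
                                p_open = NULL, duration_ms = 200,
                                dt_ms = 0.1, baseline_sd = 0.2,
                                n_sweeps = 60L,
                                holding_potential = -60, seed = 1L) {
  stopifnot(n_channels >= 1L, n_sweeps >= 1L)
  t <- seq(0, duration_ms, by = dt_ms)
  p <- if (is.null(p_open)) {
    0.8 * (1 - exp(-t / 0.3)) * (0.7 * exp(-t / 5) + 0.3 * exp(-t / 50))
  } else if (is.function(p_open)) {
    p_open(t)
  } else {
    rep_len(p_open, length(t))
  }
  if (any(p < 0 | p > 1))
    stop("open probabilities must lie in [0, 1]", call. = FALSE)
  set.seed(as.integer(seed))
  cur <- vapply(seq_len(n_sweeps), function(s) {
    counts <- stats::rbinom(length(t), n_channels, p)
    counts * i_single +
      if (baseline_sd > 0) stats::rnorm(length(t), sd = baseline_sd)
      else 0
  }, numeric(length(t)))
  out <- sweep_set(t, cur, holding_potential = holding_potential,
                   protocol = "synthetic binomial gating")
  attr(out, "truth") <- list(N = n_channels, i = i_single, p = p,
                             baseline_sd = baseline_sd, seed = seed)
  out
}

#' Generate a two-pulse recovery series
#'
#' Evaluates the two-term Hodgkin-Huxley recovery expression at each
#' inter-pulse interval and adds Gaussian noise.
#'
#' @param intervals inter-pulse intervals, ms (positive, increasing).
#'   The default follows a paired-pulse protocol with 2 ms spacing up
#'   to 40 ms and 10 ms spacing thereafter.
#' @param y0,a1,k1,k2,m1,m2,ymax curve parameters (rates in 1/ms).
#' @param noise_sd additive noise s.d. on the normalized amplitude.
#' @param seed RNG seed.
#' @return data frame `interval_ms`, `amplitude`, with attribute
#'   `truth` (the generating parameters).
#' @export
make_recovery_series <- function(intervals = c(seq(2, 40, by = 2),
                                               seq(50, 400, by = 10)),
                                 y0 = 0.1, a1 = 0.6, k1 = 0.2,
                                 k2 = 0.02, m1 = 4, m2 = 1, ymax = 1,
                                 noise_sd = 0, seed = 1L) {
  if (any(intervals <= 0) || any(diff(intervals) <= 0))
    stop("intervals must be positive and increasing", call. = FALSE)
  y <- recovery_curve(intervals, y0, a1, k1, k2, m1, m2, ymax)
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    y <- y + stats::rnorm(length(y), sd = noise_sd)
  }
  out <- data.frame(interval_ms = intervals, amplitude = y)
  attr(out, "truth") <- list(y0 = y0, a1 = a1, k1 = k1, k2 = k2,
                             m1 = m1, m2 = m2, ymax = ymax)
  out
}

#' Generate a rectifying current-voltage ramp
#'
#' Ohmic current `I = g * V` scaled by a voltage-dependent block
#' factor in \[0, 1\] emulating intracellular polyamine block of
#' inwardly rectifying channels, evaluated over a voltage ramp, with
#' the three currents used by the rectification index extracted
#' exactly.
#'
#' @param g linear conductance, nS (current in pA for V in mV).
#' @param block `"none"` (factor 1 everywhere), `"full_above_0"`
#'   (factor 0 for V > 0), `"polyamine"` (logistic relief of block,
#'   `1/(1 + exp((V - v_half)/v_slope))`), or a function of voltage.
#' @param v_half,v_slope logistic block parameters, mV.
#' @param voltages ramp voltages, mV; must cover -60, 0 and +40.
#' @return list with `ramp` (data frame `V_mV`, `I_pA`) and `iv`
#'   (named vector `I_plus40`, `I_0`, `I_minus60`).
#' @export
make_iv_ramp <- function(g = 0.5,
                         block = c("polyamine", "none",
                                   "full_above_0"),
                         v_half = 0, v_slope = 15,
                         voltages = seq(-100, 100, by = 1)) {
  if (is.function(block)) {
    bf <- block
  } else {
    block <- match.arg(block)
    bf <- switch(block,
      none = function(v) rep(1, length(v)),
      full_above_0 = function(v) as.numeric(v <= 0),
      polyamine = function(v) 1 / (1 + exp((v - v_half) / v_slope)))
  }
  need <- c(-60, 0, 40)
  if (!all(need %in% voltages))
    stop("voltage ramp must cover -60, 0 and +40 mV", call. = FALSE)
  b <- bf(voltages)
  if (any(b < 0 | b > 1))
    stop("block factor must lie in [0, 1]", call. = FALSE)
  I <- g * voltages * b
  iv <- c(I_plus40 = I[voltages == 40],
          I_0 = I[voltages == 0],
          I_minus60 = I[voltages == -60])
  list(ramp = data.frame(V_mV = voltages, I_pA = I), iv = iv)
}
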