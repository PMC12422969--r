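# Conformational coordinates of a two-lobed clamshell dimer: the
# displacement torsion and the projected (ghost-axis) opening angle,
# computed from six lobe centres of mass.
#
# Point naming follows the collective-variable construction used for
# the NTD dimer simulations: subunit 1 upper/lower lobe centroids
# (com1/com2), subunit 2 upper/lower (com3/com4), joint upper (com13)
# and joint lower (com24) centroids, and a ghost point g2 placed 0.5 A
# from com24 along the normal of the plane through com24, com1, com3.

#' Define the upper/lower lobe partition of a clamshell domain
#'
#' Defaults are the NTD lobe residue ranges used throughout this
#' package: upper lobe residues 117-243 and 354-380, lower lobe
#' residues 1-116 and 244-353 (mature-peptide numbering), C-alpha
#' atoms.
#'
#' @param upper_ranges,lower_ranges lists of inclusive `c(lo, hi)`
#'   residue-number pairs in mature numbering.
#' @param atom_name atom used for centroids (default `"CA"`).
#' @return object of class `lobe_definition`.
#' @export
lobe_definition <- function(upper_ranges = list(c(117L, 243L),
                                                c(354L, 380L)),
                            lower_ranges = list(c(1L, 116L),
                                                c(244L, 353L)),
                            atom_name = "CA") {
  up <- normalize_ranges(upper_ranges)
  lo <- normalize_ranges(lower_ranges)
  up_set <- unlist(apply(up, 1L, function(r) r[1L]:r[2L],
                         simplify = FALSE))
  lo_set <- unlist(apply(lo, 1L, function(r) r[1L]:r[2L],
                         simplify = FALSE))
  if (length(intersect(up_set, lo_set)))
    stop("upper and lower lobe ranges overlap", call. = FALSE)
  structure(list(upper_ranges = up, lower_ranges = lo,
                 atom_name = atom_name),
            class = "lobe_definition")
}

#' Lobe centres of mass of a dimer
#'
#' Computes the six centroids and the ghost point that define the
#' displacement torsion and the projected opening angle. Centroids are
#' unweighted means of the selected atom positions (identical to
#' mass-weighting when a single atom type such as C-alpha is used).
#'
#' @param dimer either a single `structure3d` containing both subunits,
#'   or a list of two `structure3d` (one per subunit).
#' @param chains length-2 character vector naming the two subunit
#'   chains (ignored when `dimer` is a two-structure list with
#'   single-chain members; required otherwise).
#' @param lobes a [lobe_definition()].
#' @return object of class `lobe_centroids`: list of 3-vectors `com1`
#'   (upper, subunit 1), `com2` (lower, subunit 1), `com3` (upper,
#'   subunit 2), `com4` (lower, subunit 2), `com13`, `com24`, and `g2`
#'   with `|g2 - com24| = 0.5` Angstrom.
#' @export
lobe_centroids <- function(dimer, chains = c("A", "B"),
                           lobes = lobe_definition()) {
  stopifnot(inherits(lobes, "lobe_definition"))
  sel <- dimer_selections(dimer, chains, lobes)
  com1 <- colMeans(sel$upper1$xyz)
  com2 <- colMeans(sel$lower1$xyz)
  com3 <- colMeans(sel$upper2$xyz)
  com4 <- colMeans(sel$lower2$xyz)
  com13 <- colMeans(rbind(sel$upper1$xyz, sel$upper2$xyz))
  com24 <- colMeans(rbind(sel$lower1$xyz, sel$lower2$xyz))
  n <- cross3(com1 - com24, com3 - com24)
  nn <- vec_norm(n)
  if (nn < 1e-9)
    stop("ghost point undefined: com1, com3 and com24 are collinear",
         call. = FALSE)
  g2 <- com24 + 0.5 * n / nn
  structure(list(com1 = com1, com2 = com2, com3 = com3, com4 = com4,
                 com13 = com13, com24 = com24, g2 = g2),
            class = "lobe_centroids")
}

# Resolve the four lobe point sets (>= 3 atoms each).
dimer_selections <- function(dimer, chains, lobes) {
  pick <- function(s, chain, ranges) {
    ps <- select_atoms(s, chain, ranges, lobes$atom_name)
    if (nrow(ps$xyz) < 3L)
      stop("lobe selection has fewer than 3 atoms (chain '", chain,
           "')", call. = FALSE)
    ps
  }
  if (inherits(dimer, "structure3d")) {
    s1 <- s2 <- dimer
    ch <- chains
  } else if (is.list(dimer) && length(dimer) == 2L &&
             all(vapply(dimer, inherits, TRUE, "structure3d"))) {
    s1 <- dimer[[1L]]
    s2 <- dimer[[2L]]
    ch <- c(unique(s1$atom$chain)[1L], unique(s2$atom$chain)[1L])
    if (!missing(chains)) ch <- chains
  } else {
    stop("dimer must be a structure3d or a list of two structure3d",
         call. = FALSE)
  }
  list(upper1 = pick(s1, ch[1L], lobes$upper_ranges),
       lower1 = pick(s1, ch[1L], lobes$lower_ranges),
       upper2 = pick(s2, ch[2L], lobes$upper_ranges),
       lower2 = pick(s2, ch[2L], lobes$lower_ranges))
}

#' Displacement torsion of a dimer
#'
#' Signed dihedral over the ordered centroids (com2, com1, com3, com4):
#' the rotation of the two lower lobes relative to each other about the
#' axis through the two upper-lobe centroids. Near 0 degrees for flat
#' dimers; displaced dimers move towards about -25 to -30 degrees.
#'
#' @param centroids a `lobe_centroids` object (or anything accepted by
#'   [lobe_centroids()] when `...` supplies `chains`/`lobes`).
#' @param ... passed on to [lobe_centroids()] when `centroids` is a
#'   structure.
#' @return signed angle in degrees, in (-180, 180].
#' @export
displacement_torsion <- function(centroids, ...) {
  c4 <- as_lobe_centroids(centroids, ...)
  dihedral_angle(c4$com2, c4$com1, c4$com3, c4$com4)
}

#' Projected opening angle of a dimer
#'
#' The angle between `v1 = com2 - com13` and `v2 = com4 - com13` after
#' projecting both onto the plane perpendicular to the ghost axis
#' `g2 - com24`, signed by the atan2 convention about that axis. The
#' projection removes the contribution of lower-lobe displacement to
#' the apparent opening.
#'
#' @inheritParams displacement_torsion
#' @return signed angle in degrees, in (-180, 180].
#' @export
opening_angle <- function(centroids, ...) {
  c4 <- as_lobe_centroids(centroids, ...)
  axis <- c4$g2 - c4$com24
  v1 <- project_onto_plane(c4$com2 - c4$com13, axis)
  v2 <- project_onto_plane(c4$com4 - c4$com13, axis)
  if (vec_norm(v1) < 1e-9 || vec_norm(v2) < 1e-9)
    stop("opening angle undefined: zero-length in-plane projection",
         call. = FALSE)
  signed_angle_about(v1, v2, axis)
}

as_lobe_centroids <- function(x, ...) {
  if (inherits(x, "lobe_centroids")) return(x)
  lobe_centroids(x, ...)
}

#' Conformational coordinates of one dimer
#'
#' @inheritParams displacement_torsion
#' @return named numeric vector `c(torsion_deg, opening_deg)`.
#' @export
conf_coords <- function(centroids, ...) {
  c4 <- as_lobe_centroids(centroids, ...)
  c(torsion_deg = displacement_torsion(c4),
    opening_deg = opening_angle(c4))
}

#' Conformational coordinates along a trajectory
#'
#' @param frames list of `structure3d` (e.g. from [read_trajectory()]).
#' @param chains length-2 character vector of subunit chains.
#' @param lobes a [lobe_definition()].
#' @return data frame with columns `frame`, `torsion_deg`,
#'   `opening_deg`, one row per frame in input order.
#' @export
coords_series <- function(frames, chains = c("A", "B"),
                          lobes = lobe_definition()) {
  out <- data.frame(frame = integer(0), torsion_deg = numeric(0),
                    opening_deg = numeric(0))
  for (i in seq_along(frames)) {
    cc <- tryCatch(
      conf_coords(frames[[i]], chains = chains, lobes = lobes),
      error = function(e)
        stop("frame ", i, ": ", conditionMessage(e), call. = FALSE))
    out[i, ] <- list(i, cc[["torsion_deg"]], cc[["opening_deg"]])
  }
  out
}

#' Write a coordinate series as CSV
#'
#' @param series data frame from [coords_series()].
#' @param path output path.
#' @export
write_coords_csv <- function(series, path) {
  utils::write.csv(series, path, row.names = FALSE)
  invisible(path)
}
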