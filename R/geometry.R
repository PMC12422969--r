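# Rigid-body geometry primitives shared by the structure and
# conformational-coordinate modules.

DEG <- 180 / pi

`%||%` <- function(a, b) if (is.null(a)) b else a

vec_norm <- function(v) sqrt(sum(v * v))

cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Signed dihedral angle over four points
#'
#' Standard atan2 torsion convention used for biomolecular dihedrals:
#' with bond vectors `b1 = p2 - p1`, `b2 = p3 - p2`, `b3 = p4 - p3`,
#' the angle is `atan2((n1 x b2hat) . n2, n1 . n2)` where
#' `n1 = b1 x b2`, `n2 = b2 x b3`.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom).
#' @return signed angle in degrees, in (-180, 180].
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  nb2 <- vec_norm(b2)
  if (vec_norm(b1) < 1e-12 || nb2 < 1e-12 || vec_norm(b3) < 1e-12)
    stop("undefined dihedral: zero-length bond vector", call. = FALSE)
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vec_norm(n1) < 1e-10 || vec_norm(n2) < 1e-10)
    stop("undefined dihedral: collinear points", call. = FALSE)
  m1 <- cross3(n1, b2 / nb2)
  atan2(sum(m1 * n2), sum(n1 * n2)) * DEG
}

# Signed angle from v1 to v2 about unit axis a (right-hand rule), degrees.
signed_angle_about <- function(v1, v2, axis) {
  a <- axis / vec_norm(axis)
  if (vec_norm(v1) < 1e-12 || vec_norm(v2) < 1e-12)
    stop("undefined angle: zero-length vector", call. = FALSE)
  atan2(sum(cross3(v1, v2) * a), sum(v1 * v2)) * DEG
}

# Remove the component of v along unit axis a.
project_onto_plane <- function(v, axis) {
  a <- axis / vec_norm(axis)
  v - sum(v * a) * a
}

#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' two paired point sets, via singular value decomposition of the
#' covariance matrix with the usual determinant sign correction.
#'
#' @param mobile,reference point sets: either `pointset` objects or
#'   n x 3 numeric matrices, with matched rows (n >= 3).
#' @return a list of class `rigid_transform` with elements `rotation`
#'   (3 x 3 proper rotation), `translation` (length-3), and `rmsd`
#'   (Angstrom, after applying the transform to `mobile`). The transform
#'   maps mobile coordinates as `x %*% t(rotation) + translation`.
#' @examples
#' m <- matrix(rnorm(15), ncol = 3)
#' fit <- kabsch_superpose(m, m)
#' fit$rmsd  # 0
#' @export
kabsch_superpose <- function(mobile, reference) {
  X <- as_xyz_matrix(mobile)
  Y <- as_xyz_matrix(reference)
  if (nrow(X) != nrow(Y))
    stop("point sets differ in size (", nrow(X), " vs ", nrow(Y), ")",
         call. = FALSE)
  if (nrow(X) < 3L)
    stop("need at least 3 points for superposition", call. = FALSE)
  cx <- colMeans(X)
  cy <- colMeans(Y)
  Xc <- sweep(X, 2L, cx)
  Yc <- sweep(Y, 2L, cy)
  H <- crossprod(Xc, Yc)
  sv <- svd(H)
  # guard against degenerate (collinear) geometry: two near-zero
  # singular values leave the rotation under-determined
  if (sv$d[2L] < 1e-9 * max(sv$d[1L], 1e-30))
    stop("degenerate geometry: points are (nearly) collinear",
         call. = FALSE)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cy - as.vector(R %*% cx)
  moved <- Xc %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Yc)^2)))
  structure(list(rotation = R, translation = tr, rmsd = rmsd),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param transform a `rigid_transform` from [kabsch_superpose()].
#' @param x an n x 3 coordinate matrix or a `pointset`.
#' @return object of the same kind with transformed coordinates.
#' @export
apply_transform <- function(transform, x) {
  stopifnot(inherits(transform, "rigid_transform"))
  if (inherits(x, "pointset")) {
    x$xyz <- apply_transform(transform, x$xyz)
    return(x)
  }
  X <- as_xyz_matrix(x)
  sweep(X %*% t(transform$rotation), 2L, transform$translation, `+`)
}

#' Rotation magnitude of a rigid transform
#'
#' `acos((trace(R) - 1)/2)` in degrees, i.e. the angle of the
#' axis-angle representation, in \[0, 180\].
#'
#' @param transform a `rigid_transform` or a 3 x 3 rotation matrix.
#' @param tol orthogonality tolerance.
#' @return angle in degrees.
#' @export
rotation_angle <- function(transform, tol = 1e-6) {
  R <- if (inherits(transform, "rigid_transform")) transform$rotation
       else as.matrix(transform)
  if (!all(dim(R) == c(3L, 3L)) ||
      max(abs(crossprod(R) - diag(3))) > tol ||
      abs(det(R) - 1) > tol)
    stop("not a proper rotation matrix", call. = FALSE)
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) * DEG
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform: rotation", sprintf("%.3f", rotation_angle(x)),
      "deg, translation", sprintf("%.3f", vec_norm(x$translation)),
      "A, rmsd", sprintf("%.4f", x$rmsd), "A\n")
  invisible(x)
}

# Coerce pointsets / data frames / matrices to an n x 3 matrix.
as_xyz_matrix <- function(x) {
  if (inherits(x, "pointset")) return(x$xyz)
  m <- as.matrix(x)
  if (ncol(m) != 3L) stop("expected 3 coordinate columns", call. = FALSE)
  storage.mode(m) <- "double"
  m
}
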