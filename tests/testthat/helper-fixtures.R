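# Fixtures built in code: tiny PDB text, toy structures, random
# rotations. No binary data; everything is generated at test time.

# A hand-written three-residue PDB fixture (chain A, CA atoms).
write_tiny_pdb <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       4.000   5.000   6.000  1.00  0.00           C",
    "ATOM      3  CA  SER A   3       7.500   8.250   9.125  1.00  0.00           C",
    "END"), path)
  path
}

# Structure with arbitrary atom content from a compact spec.
make_structure <- function(chain, resno, elety, xyz, resid = "ALA",
                           offset = 0L) {
  structure3d(data.frame(chain = chain, resno = resno, resid = resid,
                         elety = elety, x = xyz[, 1L], y = xyz[, 2L],
                         z = xyz[, 3L], stringsAsFactors = FALSE),
              numbering_offset = offset)
}

# Uniformly random proper rotation matrix.
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# Rotation by a given angle (deg) about a given axis.
axis_rotation <- function(axis, angle_deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

# Apply a rigid motion (R, t) to every atom of a structure3d.
transform_structure <- function(s, R, tvec = c(0, 0, 0)) {
  xyz <- as.matrix(s$atom[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(R), 2L, tvec, `+`)
  s$atom[, c("x", "y", "z")] <- xyz
  s
}

# Cross product (independent of package internals).
xprod <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
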