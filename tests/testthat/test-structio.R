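test_that("PDB fixtures are read back verbatim", {
  path <- write_tiny_pdb()
  s <- load_structure(path)
  expect_s3_class(s, "structure3d")
  expect_equal(nrow(s$atom), 3L)
  expect_equal(s$atom$elety, rep("CA", 3))
  expect_equal(s$atom$resno, 1:3)
  expect_equal(s$atom$x, c(1, 4, 7.5))
  expect_equal(s$atom$z, c(3, 6, 9.125))
  expect_equal(s$numbering_offset, 0L)
})

test_that("PDB -> mmCIF -> read round trip preserves the atom table", {
  path <- write_tiny_pdb()
  s <- load_structure(path)
  cif <- tempfile(fileext = ".cif")
  write_structure(s, cif)
  s2 <- load_structure(cif)
  expect_equal(s2$atom$chain, s$atom$chain)
  expect_equal(s2$atom$resno, s$atom$resno)
  expect_equal(s2$atom$elety, s$atom$elety)
  expect_equal(s2$atom$resid, s$atom$resid)
  expect_equal(as.matrix(s2$atom[, c("x", "y", "z")]),
               as.matrix(s$atom[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("write -> read PDB round trip holds at PDB precision", {
  set.seed(41)
  s <- make_structure("A", 1:25, "CA",
                      matrix(round(rnorm(75, sd = 20), 3), ncol = 3))
  out <- tempfile(fileext = ".pdb")
  write_structure(s, out)
  s2 <- load_structure(out)
  expect_equal(nrow(s2$atom), 25L)
  expect_equal(as.matrix(s2$atom[, c("x", "y", "z")]),
               as.matrix(s$atom[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("missing models and unreadable files raise errors", {
  path <- write_tiny_pdb()
  expect_error(load_structure(path, model = 5), "model 5 not found")
  expect_error(load_structure(tempfile(fileext = ".pdb")),
               "no such file")
  odd <- tempfile(fileext = ".xyz2")
  file.copy(path, odd)
  expect_error(load_structure(odd), "cannot infer format")
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.40  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   9.000   9.000  0.60  0.00           C",
    "ATOM      3  CA AGLY A   2       1.000   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CA BGLY A   2       8.000   8.000   8.000  0.50  0.00           C",
    "END"), path)
  s <- load_structure(path)
  expect_equal(nrow(s$atom), 2L)
  # residue 1: occupancy picks B; residue 2: tie broken by label (A)
  expect_equal(s$atom$x, c(9, 1))
})

test_that("hydrogens are dropped by default", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  HA  ALA A   1       0.500   0.000   0.000  1.00  0.00           H",
    "END"), path)
  expect_equal(nrow(load_structure(path)$atom), 1L)
  expect_equal(nrow(load_structure(path, keep_hydrogens = TRUE)$atom),
               2L)
})

test_that("select_atoms applies ranges, offsets and skip counting", {
  path <- write_tiny_pdb()
  s <- load_structure(path)
  ps <- select_atoms(s, "A", list(c(1, 3)), "CA")
  expect_equal(nrow(ps$xyz), 3L)
  expect_equal(ps$n_skipped, 0L)

  # enumeration oracle: how many residues of 1..380 fall in the two
  # upper-lobe ranges
  n_oracle <- sum(1:380 %in% c(117:243, 354:380))
  big <- make_structure("A", 1:380, "CA",
                        matrix(seq_len(380 * 3), ncol = 3))
  sel <- select_atoms(big, "A", list(c(117, 243), c(354, 380)))
  expect_equal(nrow(sel$xyz), n_oracle)
  expect_equal(nrow(sel$xyz), 154L)

  # numbering offset: file numbering 1..380 with offset +5 means
  # mature residue 117 is file residue 112
  big5 <- make_structure("A", 1:380, "CA",
                         matrix(seq_len(380 * 3), ncol = 3),
                         offset = 5L)
  sel5 <- select_atoms(big5, "A", list(c(117, 243), c(354, 380)))
  expect_equal(sel5$labels$resno[1L], 117)
  expect_equal(sel5$xyz[1L, ],
               as.matrix(big5$atom[big5$atom$resno == 112,
                                   c("x", "y", "z")])[1L, ],
               ignore_attr = TRUE)

  expect_error(select_atoms(s, "Z", list(c(1, 3))), "empty selection")
  expect_error(select_atoms(s, "A", list(c(5, 2))), "low > high")

  # residues lacking the atom are skipped and counted
  mixed <- make_structure("A", c(1, 1, 2), c("CA", "CB", "CB"),
                          matrix(1:9, ncol = 3))
  ps2 <- select_atoms(mixed, "A", list(c(1, 2)), "CA")
  expect_equal(nrow(ps2$xyz), 1L)
  expect_equal(ps2$n_skipped, 1L)
})

test_that("kabsch superposition recovers constructed transforms", {
  set.seed(7)
  ref <- matrix(rnorm(30, sd = 10), ncol = 3)

  # identity case
  fit0 <- kabsch_superpose(ref, ref)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-10)
  expect_lt(fit0$rmsd, 1e-10)

  # constructed rotation + translation is inverted exactly
  R <- axis_rotation(c(0, 0, 1), 30)
  tv <- c(4, -2, 7)
  target <- sweep(ref %*% t(R), 2L, tv, `+`)
  fit <- kabsch_superpose(ref, target)
  expect_lt(fit$rmsd, 1e-8)
  expect_equal(fit$rotation, R, tolerance = 1e-8)
  expect_equal(apply_transform(fit, ref), target, tolerance = 1e-8)
  expect_equal(rotation_angle(fit), 30, tolerance = 1e-6)

  # agreement with an independent reference implementation (bio3d)
  set.seed(8)
  mob <- ref + matrix(rnorm(30, sd = 0.5), ncol = 3)
  fit2 <- kabsch_superpose(mob, ref)
  b3d <- suppressWarnings(
    bio3d::fit.xyz(fixed = as.vector(t(ref)),
                   mobile = as.vector(t(mob)),
                   fixed.inds = 1:30, mobile.inds = 1:30))
  rmsd_b3d <- sqrt(mean(rowSums(
    (matrix(b3d, ncol = 3, byrow = TRUE) - ref)^2)))
  expect_equal(fit2$rmsd, rmsd_b3d, tolerance = 1e-6)

  expect_error(kabsch_superpose(ref[1:2, ], ref[1:2, ]),
               "at least 3 points")
  expect_error(kabsch_superpose(ref[1:4, ], ref[1:3, ]),
               "differ in size")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(kabsch_superpose(line, line), "collinear")
})

test_that("superposition rmsd is invariant under common rigid motion", {
  set.seed(9)
  a <- matrix(rnorm(45, sd = 8), ncol = 3)
  b <- a + matrix(rnorm(45, sd = 1), ncol = 3)
  base <- kabsch_superpose(a, b)$rmsd
  for (k in 1:5) {
    R <- random_rotation()
    tv <- rnorm(3, sd = 20)
    a2 <- sweep(a %*% t(R), 2L, tv, `+`)
    b2 <- sweep(b %*% t(R), 2L, tv, `+`)
    expect_equal(kabsch_superpose(a2, b2)$rmsd, base,
                 tolerance = 1e-8)
  }
})

test_that("rotation_angle follows the trace formula", {
  expect_equal(rotation_angle(diag(3)), 0)
  expect_equal(rotation_angle(axis_rotation(c(1, 0, 0), 180)), 180)
  set.seed(10)
  for (ang in c(5, 30, 90, 150)) {
    axis <- rnorm(3)
    expect_equal(rotation_angle(axis_rotation(axis, ang)), ang,
                 tolerance = 1e-8)
  }
  # R %*% t(R) is the identity: zero angle for random rotations
  for (k in 1:5) {
    R <- random_rotation()
    expect_equal(rotation_angle(R %*% t(R)), 0, tolerance = 1e-5)
  }
  expect_error(rotation_angle(matrix(1:9 * 1.0, 3)), "not a proper")
})

test_that("multi-model PDB and XYZ trajectories read frame by frame", {
  set.seed(11)
  frames <- lapply(1:3, function(i)
    make_structure("A", 1:4, "CA",
                   matrix(round(rnorm(12, sd = 5), 3), ncol = 3)))
  path <- tempfile(fileext = ".pdb")
  write_trajectory(frames, path)
  back <- read_trajectory(path)
  expect_length(back, 3L)
  for (i in 1:3)
    expect_equal(as.matrix(back[[i]]$atom[, c("x", "y", "z")]),
                 as.matrix(frames[[i]]$atom[, c("x", "y", "z")]),
                 tolerance = 1e-3, ignore_attr = TRUE)

  # XYZ frame series
  xyz_path <- tempfile(fileext = ".xyz")
  writeLines(c("2", "frame 1",
               "C 0.0 0.0 0.0", "C 1.0 0.0 0.0",
               "2", "frame 2",
               "C 0.0 0.0 0.5", "C 1.0 0.0 0.5"), xyz_path)
  fr <- read_trajectory(xyz_path)
  expect_length(fr, 2L)
  expect_equal(fr[[2L]]$atom$z, c(0.5, 0.5))
  bad <- tempfile(fileext = ".xyz")
  writeLines(c("2", "frame", "C 0 0 0"), bad)
  expect_error(read_trajectory(bad), "truncated|malformed")
})

test_that("pointset CSV dump has one labelled row per point", {
  s <- load_structure(write_tiny_pdb())
  ps <- select_atoms(s, "A", list(c(1, 3)))
  out <- tempfile(fileext = ".csv")
  write_pointset_csv(ps, out)
  back <- read.csv(out)
  expect_equal(nrow(back), 3L)
  expect_equal(back$x, c(1, 4, 7.5))
})
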