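# Small random hills log used across tests.
random_hills <- function(n = 100, seed = 1, periodic = c(FALSE, FALSE)) {
  set.seed(seed)
  hills_log(data.frame(
    time = sort(runif(n, 0, 1000)),
    s1 = runif(n, -60, 60), s2 = runif(n, -60, 60),
    sigma1 = runif(n, 2, 8), sigma2 = runif(n, 2, 8),
    height = runif(n, 0.1, 1.2), biasf = 10),
    periodic = periodic)
}

# Brute-force Gaussian sum, written independently of bias_at.
brute_bias <- function(log, p, upto = Inf) {
  h <- log$hills[log$hills$time <= upto, ]
  tot <- 0
  for (r in seq_len(nrow(h))) {
    d1 <- p[1] - h$s1[r]
    d2 <- p[2] - h$s2[r]
    if (log$periodic[1]) d1 <- d1 - log$period[1] * round(d1 / log$period[1])
    if (log$periodic[2]) d2 <- d2 - log$period[2] * round(d2 / log$period[2])
    tot <- tot + h$height[r] *
      exp(-(d1^2 / (2 * h$sigma1[r]^2) + d2^2 / (2 * h$sigma2[r]^2)))
  }
  tot
}

test_that("hills files parse, merge and round trip", {
  log <- random_hills(5, seed = 2)
  p1 <- tempfile()
  write_hills(log, p1)
  back <- parse_hills(p1)
  expect_equal(back$hills$s1, log$hills$s1, tolerance = 1e-8)
  expect_equal(back$hills$height, log$hills$height, tolerance = 1e-8)

  # single-row file: fields equal the row
  one <- tempfile()
  writeLines(c("#! FIELDS time s1 s2 sigma_s1 sigma_s2 height biasf",
               " 10.0 0.5 -0.25 0.1 0.2 1.2 10"), one)
  lg1 <- parse_hills(one)
  expect_equal(nrow(lg1$hills), 1L)
  expect_equal(lg1$hills$time, 10)
  expect_equal(lg1$hills$s2, -0.25)
  expect_equal(lg1$hills$sigma2, 0.2)
  expect_equal(lg1$hills$biasf, 10)

  # two walker files merge globally time-sorted with walker ids
  la <- random_hills(5, seed = 3)
  lb <- random_hills(5, seed = 4)
  fa <- tempfile(); fb <- tempfile()
  write_hills(la, fa); write_hills(lb, fb)
  merged <- parse_hills(c(fa, fb))
  expect_equal(nrow(merged$hills), 10L)
  expect_true(!is.unsorted(merged$hills$time))
  expect_setequal(unique(merged$hills$walker), 1:2)

  # malformed rows and missing headers are reported
  bad <- tempfile()
  writeLines(c("#! FIELDS time s1 s2 sigma_s1 sigma_s2 height biasf",
               "1.0 0.1 0.2"), bad)
  expect_error(parse_hills(bad), "line 2")
  nohdr <- tempfile()
  writeLines("1 2 3 4 5 6 7", nohdr)
  expect_error(parse_hills(nohdr), "FIELDS")
})

test_that("periodicity metadata survives the hills round trip", {
  log <- random_hills(8, seed = 5, periodic = c(TRUE, FALSE))
  p <- tempfile()
  write_hills(log, p)
  back <- parse_hills(p)
  expect_equal(back$periodic, c(TRUE, FALSE))
  expect_equal(back$period[1], 360)
})

test_that("bias_at equals brute-force summation and honours time cuts", {
  log <- random_hills(100, seed = 6)
  expect_equal(bias_at(log, c(0, 0)),
               brute_bias(log, c(0, 0)), tolerance = 1e-12)
  # empty log and single-hill centre
  empty <- hills_log(log$hills[0, ])
  expect_equal(bias_at(empty, c(1, 1)), 0)
  single <- hills_log(data.frame(time = 0, s1 = 3, s2 = -2,
                                 sigma1 = 1, sigma2 = 1, height = 1.2,
                                 biasf = 10))
  expect_equal(bias_at(single, c(3, -2)), 1.2)
  # time cut
  tcut <- stats::median(log$hills$time)
  expect_equal(bias_at(log, c(5, 5), upto_time = tcut),
               brute_bias(log, c(5, 5), upto = tcut),
               tolerance = 1e-12)
  # periodic minimum image
  plog <- random_hills(50, seed = 7, periodic = c(TRUE, TRUE))
  expect_equal(bias_at(plog, c(179, -179)),
               brute_bias(plog, c(179, -179)), tolerance = 1e-12)
})

test_that("hill-sum FES follows the well-tempered closed form", {
  params <- wt_params()
  g <- params$bias_factor
  single <- hills_log(data.frame(time = 0, s1 = 0, s2 = 0, sigma1 = 1,
                                 sigma2 = 1, height = 1.2, biasf = g))
  s <- seq(-30, 30, length.out = 61)
  fes <- fes_from_hills(single, params, s, s)
  expect_equal(min(fes$F), 0)
  # basin at the hill centre; far field sits at (g/(g-1))*h above it
  ctr <- which(s == 0)
  expect_equal(fes$F[ctr, ctr], 0)
  expect_equal(fes$F[1L, 1L], g / (g - 1) * 1.2, tolerance = 1e-6)

  # a spatially uniform hill leaves all energy differences unchanged
  wide <- hills_log(rbind(single$hills,
                          data.frame(time = 1, s1 = 0, s2 = 0,
                                     sigma1 = 1e6, sigma2 = 1e6,
                                     height = 0.7, biasf = g,
                                     walker = 1L)))
  fes2 <- fes_from_hills(wide, params, s, s)
  expect_equal(fes2$F, fes$F, tolerance = 1e-6)

  expect_error(fes_from_hills(single, wt_params(bias_factor = 5),
                              s, s), "inconsistent")
})

test_that("histogram FES inverts a known stationary distribution", {
  # samples drawn exactly from exp(-F0/(kB*(T+dT))) for a harmonic F0.
  # Tolerances follow the estimator's Monte-Carlo noise: the log
  # density carries ~1/sqrt(n_eff) noise per node (n_eff = samples per
  # kernel footprint), amplified by kB*(T+dT) ~ 24.9 kJ/mol. With
  # n = 2e5, kernel sd 0.15 and peak density ~0.1 the per-node F noise
  # is ~0.4 kJ/mol; the medians below allow ~3x that.
  params <- wt_params()
  kTeff <- params$kB * params$temperature * params$bias_factor
  k1 <- 8; k2 <- 15
  set.seed(31)
  n <- 200000
  samp <- cbind(rnorm(n, sd = sqrt(kTeff / k1)),
                rnorm(n, sd = sqrt(kTeff / k2)))
  s <- seq(-2, 2, length.out = 81)
  fes <- fes_from_histogram(samp, params, s, s, kernel_width = 0.15)
  F0 <- outer(0.5 * k1 * fes$s1^2, 0.5 * k2 * fes$s2^2, `+`)
  F0 <- F0 - min(F0)
  core <- F0 <= 8  # compare where sampling is adequate
  err <- abs(fes$F - F0)[core]
  expect_lt(stats::median(err, na.rm = TRUE), 1.2)

  # uniform samples give a flat surface (same noise calculus; the
  # uniform density is ~16x lower than the harmonic peak)
  set.seed(32)
  u <- cbind(runif(100000, -2, 2), runif(100000, -2, 2))
  fu <- fes_from_histogram(u, params, s, s, kernel_width = 0.2)
  inner <- abs(fu$s1) < 1.5
  expect_lt(max(fu$F[inner, inner], na.rm = TRUE), 2.5)

  # a single repeated sample peaks at its node
  f1 <- fes_from_histogram(rbind(c(0.5, -0.5)), params, s, s,
                           kernel_width = 0.1)
  i <- which.min(abs(f1$s1 - 0.5)); j <- which.min(abs(f1$s2 + 0.5))
  expect_equal(f1$F[i, j], 0, tolerance = 1e-9)

  expect_error(fes_from_histogram(matrix(numeric(0), ncol = 2),
                                  params, s, s), "no CV samples")
})

test_that("the deposition rule matches its closed forms", {
  params <- wt_params()
  empty <- hills_log(data.frame(time = numeric(0), s1 = numeric(0),
                                s2 = numeric(0), sigma1 = numeric(0),
                                sigma2 = numeric(0),
                                height = numeric(0),
                                biasf = numeric(0)))
  # first hill anywhere has height h0
  h1 <- next_hill(c(0.2, -0.3), empty, params, history = NULL,
                  time = 10)
  expect_equal(h1$height, 1.2)
  expect_equal(h1$sigma1, params$sigma0[1L])  # fallback width

  # second hill at the centre of the first: closed-form height
  log1 <- hills_log(h1)
  h2 <- next_hill(c(0.2, -0.3), log1, params, history = NULL,
                  time = 20)
  expect_equal(h2$height, 1.2 * exp(-1.2 / (0.0083145 * 2700)),
               tolerance = 1e-4)
  expect_equal(h2$height, 1.1375, tolerance = 1e-4)

  # stationary CVs floor the adaptive width
  hist_still <- cbind(time = seq(0, 10, by = 0.5), s1 = 1, s2 = 1)
  h3 <- next_hill(c(1, 1), empty, params, history = hist_still,
                  time = 10)
  expect_equal(h3$sigma1, params$sigma_min)
  expect_equal(h3$sigma2, params$sigma_min)
})

test_that("deposited heights follow the well-tempered rule", {
  pot <- toy_potential("harmonic", kx = 50, ky = 50)
  params <- wt_params()
  r <- run_toy_metad(pot, params, n_steps = 100000, n_walkers = 1,
                     seed = 9)
  h <- r$log$hills
  expect_gt(nrow(h), 20)

  # each hill's height equals h0*exp(-V/(kB*dT)) with V the bias
  # accumulated before it (driver uses a fine grid; allow its
  # interpolation error)
  for (k in c(2, 5, 10, nrow(h))) {
    V <- bias_at(r$log, c(h$s1[k], h$s2[k]),
                 upto_time = h$time[k] - 1e-9)
    expect_equal(h$height[k],
                 params$h0 * exp(-V / (params$kB * params$delta_T)),
                 tolerance = 0.02)
  }

  # the implied height at a fixed point never increases over time
  p0 <- c(0, 0)
  times <- unique(h$time)
  v_seq <- vapply(times, function(tt) bias_at(r$log, p0, tt), 0)
  expect_true(all(diff(v_seq) >= -1e-12))

  # first hill carries the full initial height
  expect_equal(h$height[1L], params$h0, tolerance = 1e-9)
})

test_that("zero-bias Brownian dynamics satisfies equipartition", {
  pot <- toy_potential("harmonic", kx = 10, ky = 20)
  r <- run_toy_metad(pot, wt_params(h0 = 0), n_steps = 400000,
                     n_walkers = 2, seed = 7, sample_stride = 10)
  kT <- KB_KJMOL * 300
  expect_equal(var(r$samples$s1), kT / 10, tolerance = 0.05)
  expect_equal(var(r$samples$s2), kT / 20, tolerance = 0.05)
  expect_equal(nrow(r$log$hills), 0L)
})

test_that("fes text output is a readable three-column grid", {
  log <- random_hills(10, seed = 8)
  s <- seq(-60, 60, length.out = 21)
  fes <- fes_from_hills(log, wt_params(), s, s)
  path <- tempfile()
  write_fes(fes, path)
  back <- read.table(path, header = FALSE)
  expect_equal(nrow(back), 21L * 21L)
  expect_equal(max(abs(back[, 3L])), max(fes$F), tolerance = 1e-6)
})
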