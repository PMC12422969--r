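# Patch-clamp kinetics: desensitization decay fits and the
# amplitude-weighted time constant, two-component Hodgkin-Huxley
# recovery fits, non-stationary fluctuation analysis (NSFA),
# rectification index and pulse-train ratios.

#' Construct a current sweep
#'
#' @param time uniform time grid, ms.
#' @param current current per sample, pA.
#' @param holding_potential holding potential, mV (default -60).
#' @return object of class `sweep`.
#' @export
ephys_sweep <- function(time, current, holding_potential = -60) {
  stopifnot(length(time) == length(current), length(time) >= 2L)
  dt <- diff(time)
  if (max(dt) - min(dt) > 1e-6 * max(abs(dt)))
    stop("time grid is not uniform", call. = FALSE)
  structure(list(time = as.numeric(time), current = as.numeric(current),
                 holding_potential = holding_potential),
            class = "sweep")
}

#' Construct a sweep set
#'
#' @param time shared uniform time grid, ms.
#' @param currents samples x sweeps numeric matrix, pA.
#' @param holding_potential mV.
#' @param protocol free-text protocol tag.
#' @return object of class `sweep_set`.
#' @export
sweep_set <- function(time, currents, holding_potential = -60,
                      protocol = "") {
  currents <- as.matrix(currents)
  stopifnot(nrow(currents) == length(time), ncol(currents) >= 1L)
  structure(list(time = as.numeric(time), currents = currents,
                 holding_potential = holding_potential,
                 protocol = protocol),
            class = "sweep_set")
}

#' Read sweeps from CSV
#'
#' Expects columns `time_ms`, `current_pA` and optionally `sweep_id`;
#' all sweeps must share one time grid.
#'
#' @param path CSV path.
#' @param holding_potential mV.
#' @return a [sweep_set()].
#' @export
read_sweeps_csv <- function(path, holding_potential = -60) {
  df <- utils::read.csv(path)
  if (!all(c("time_ms", "current_pA") %in% names(df)))
    stop("CSV must have columns time_ms, current_pA", call. = FALSE)
  if (is.null(df$sweep_id)) df$sweep_id <- 1L
  ids <- unique(df$sweep_id)
  t0 <- df$time_ms[df$sweep_id == ids[1L]]
  cur <- vapply(ids, function(id) {
    d <- df[df$sweep_id == id, ]
    if (!isTRUE(all.equal(d$time_ms, t0)))
      stop("sweeps do not share a time grid", call. = FALSE)
    d$current_pA
  }, numeric(length(t0)))
  sweep_set(t0, cur, holding_potential = holding_potential)
}

#' Amplitude-weighted time constant
#'
#' `tau_w = tau_f * Af/(Af + As) + tau_s * As/(Af + As)`, the weighted
#' desensitization time constant of a bi-exponential decay.
#'
#' @param tau_f,tau_s fast and slow time constants, ms.
#' @param a_f,a_s corresponding amplitude coefficients.
#' @return weighted tau, ms.
#' @examples
#' weighted_tau(5, 3, 50, 1)  # 16.25
#' @export
weighted_tau <- function(tau_f, a_f, tau_s, a_s) {
  tot <- a_f + a_s
  if (abs(tot) < .Machine$double.eps * 100)
    stop("total amplitude is zero", call. = FALSE)
  if (any(c(tau_f, tau_s) <= 0))
    stop("time constants must be positive", call. = FALSE)
  tau_f * (a_f / tot) + tau_s * (a_s / tot)
}

#' Fit the desensitization decay of a sweep
#'
#' Finds the peak, starts the fit window at the first sample on the
#' falling phase at `window_start_frac` (default 90%) of the peak, and
#' fits `I(t) = baseline + sum_k A_k * exp(-(t - t_start)/tau_k)` by
#' bounded Levenberg-Marquardt least squares with three deterministic
#' multi-starts. With two components, components are ordered
#' `tau_f <= tau_s` and the amplitude-weighted `tau_w_des` is reported.
#'
#' @param sweep a [ephys_sweep()] (or anything with `time`/`current`).
#' @param n_components 1 or 2 exponentials.
#' @param window_start_frac fraction of peak amplitude at which the
#'   fit window starts on the falling phase (default 0.9).
#' @param window_end_ms optional end of the fit window, ms.
#' @return list of class `decay_fit`: `n_components`, `tau_f`,
#'   `tau_s`, `a_f`, `a_s` (pA; `NA` for single-exponential fits),
#'   `baseline`, `tau_w_des` (ms), `residual_norm`, `window` (ms).
#' @export
fit_decay <- function(sweep, n_components = 2L,
                      window_start_frac = 0.9, window_end_ms = NULL) {
  stopifnot(n_components %in% c(1L, 2L))
  t <- sweep$time
  i <- sweep$current
  if (stats::sd(i) < .Machine$double.eps * 100 * (abs(mean(i)) + 1))
    stop("degenerate input: flat trace has no decay to fit",
         call. = FALSE)
  pk <- which.max(abs(i - i[1L]))
  pk_amp <- i[pk] - i[1L]
  # first falling-phase sample at <= window_start_frac of peak
  after <- seq(pk, length(i))
  rel <- (i[after] - i[1L]) / pk_amp
  start_idx <- after[which(rel <= window_start_frac)[1L]]
  if (is.na(start_idx)) start_idx <- pk
  end_idx <- if (is.null(window_end_ms)) length(t)
             else max(which(t <= window_end_ms))
  win <- start_idx:end_idx
  if (length(win) < 10L)
    stop("fit window contains fewer than 10 samples", call. = FALSE)
  tw <- t[win] - t[win][1L]
  iw <- i[win]
  span <- max(tw)
  amp0 <- iw[1L] - iw[length(iw)]
  base0 <- iw[length(iw)]

  if (n_components == 1L) {
    starts <- list(c(tau1 = span / 10), c(tau1 = span / 3),
                   c(tau1 = span))
    fits <- lapply(starts, function(s0) {
      try(minpack.lm::nlsLM(
        iw ~ b + a1 * exp(-tw / tau1),
        start = c(list(b = base0, a1 = amp0), as.list(s0)),
        lower = c(-Inf, -Inf, span * 1e-5),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
        silent = TRUE)
    })
    fit <- best_fit(fits)
    cf <- stats::coef(fit)
    out <- list(n_components = 1L, tau_f = unname(cf["tau1"]),
                tau_s = NA_real_, a_f = unname(cf["a1"]),
                a_s = NA_real_, baseline = unname(cf["b"]),
                tau_w_des = unname(cf["tau1"]))
  } else {
    starts <- list(c(tau1 = span / 50, tau2 = span / 5),
                   c(tau1 = span / 20, tau2 = span / 2),
                   c(tau1 = span / 100, tau2 = span))
    fits <- lapply(starts, function(s0) {
      try(minpack.lm::nlsLM(
        iw ~ b + a1 * exp(-tw / tau1) + a2 * exp(-tw / tau2),
        start = c(list(b = base0, a1 = 0.7 * amp0, a2 = 0.3 * amp0),
                  as.list(s0)),
        lower = c(-Inf, -Inf, -Inf, span * 1e-5, span * 1e-5),
        control = minpack.lm::nls.lm.control(maxiter = 400)),
        silent = TRUE)
    })
    fit <- best_fit(fits)
    cf <- stats::coef(fit)
    taus <- c(cf[["tau1"]], cf[["tau2"]])
    amps <- c(cf[["a1"]], cf[["a2"]])
    ord <- order(taus)
    out <- list(n_components = 2L, tau_f = taus[ord[1L]],
                tau_s = taus[ord[2L]], a_f = amps[ord[1L]],
                a_s = amps[ord[2L]], baseline = unname(cf["b"]),
                tau_w_des = weighted_tau(taus[ord[1L]], amps[ord[1L]],
                                         taus[ord[2L]], amps[ord[2L]]))
  }
  out$residual_norm <- sqrt(sum(stats::resid(fit)^2))
  out$window <- c(t[win][1L], t[end_idx])
  class(out) <- "decay_fit"
  out
}

best_fit <- function(fits) {
  ok <- !vapply(fits, inherits, TRUE, "try-error")
  if (!any(ok))
    stop("decay fit failed to converge from all starts: ",
         attr(fits[[1L]], "condition")$message %||% "", call. = FALSE)
  fits <- fits[ok]
  rss <- vapply(fits, function(f) sum(stats::resid(f)^2), 0)
  fits[[which.min(rss)]]
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$n_components == 2L)
    cat(sprintf(
      "decay_fit: tau_f %.3g ms (A %.3g), tau_s %.3g ms (A %.3g), tau_w,des %.3g ms\n",
      x$tau_f, x$a_f, x$tau_s, x$a_s, x$tau_w_des))
  else
    cat(sprintf("decay_fit: tau %.3g ms (A %.3g)\n", x$tau_f, x$a_f))
  invisible(x)
}

# Two-term Hodgkin-Huxley recovery curve.
recovery_curve <- function(x, y0, a1, k1, k2, m1 = 4, m2 = 1,
                           ymax = 1) {
  y0 + a1 * (1 - exp(-x * k1))^m1 +
    (ymax - a1 - y0) * (1 - exp(-x * k2))^m2
}

#' Fit recovery from desensitization
#'
#' Fits normalized two-pulse recovery amplitudes with a sum of two
#' Hodgkin-Huxley terms, `y = y0 + a1*(1 - exp(-x*k1))^m1 +
#' (ymax - a1 - y0)*(1 - exp(-x*k2))^m2`, with the slopes fixed
#' (`m1 = 4`, `m2 = 1` by default) and `ymax` constrained to 1. The
#' weighted recovery time constant is
#' `tau_w = (tau1*a1 + tau2*(ymax - a1 - y0))/(ymax - y0)` with
#' `tau_i = 1/k_i`.
#'
#' @param intervals inter-pulse intervals, ms (positive, increasing).
#' @param amplitudes normalized recovery amplitudes.
#' @param m1,m2 fixed slopes of the fast and slow terms.
#' @param ymax fixed plateau (default 1).
#' @return list of class `recovery_fit`: `y0`, `a1`, `ymax`, `k1`,
#'   `k2` (1/ms), `tau1`, `tau2`, `tau_w_rec` (ms), `m1`, `m2`,
#'   `residual_norm`, `fitted` (function of interval).
#' @export
fit_recovery <- function(intervals, amplitudes, m1 = 4, m2 = 1,
                         ymax = 1) {
  x <- as.numeric(intervals)
  y <- as.numeric(amplitudes)
  if (length(x) < 6L)
    stop("need at least 6 recovery points", call. = FALSE)
  if (any(x <= 0) || any(diff(x) <= 0))
    stop("intervals must be positive and increasing", call. = FALSE)
  span <- max(x)
  starts <- list(c(k1 = 10 / span, k2 = 1 / span),
                 c(k1 = 30 / span, k2 = 3 / span),
                 c(k1 = 3 / span, k2 = 0.3 / span))
  y0_0 <- max(min(y[1L], 0.9), 0)
  fits <- lapply(starts, function(s0) {
    try(minpack.lm::nlsLM(
      y ~ recovery_curve(x, y0, a1, k1, k2, m1, m2, ymax),
      start = list(y0 = y0_0, a1 = 0.5, k1 = s0[["k1"]],
                   k2 = s0[["k2"]]),
      lower = c(0, 0, 1e-8, 1e-8), upper = c(1, 1, Inf, Inf),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
      silent = TRUE)
  })
  fit <- best_fit(fits)
  cf <- stats::coef(fit)
  # label the m1-term as "fast": enforce k1 >= k2 by construction of
  # starts; if the optimizer swapped them, swap back (slopes equal
  # only when m1 == m2)
  k1 <- cf[["k1"]]; k2 <- cf[["k2"]]; a1 <- cf[["a1"]]
  y0 <- cf[["y0"]]
  tau1 <- 1 / k1
  tau2 <- 1 / k2
  tau_w <- (tau1 * a1 + tau2 * (ymax - a1 - y0)) / (ymax - y0)
  out <- list(y0 = y0, a1 = a1, ymax = ymax, k1 = k1, k2 = k2,
              tau1 = tau1, tau2 = tau2, tau_w_rec = tau_w, m1 = m1,
              m2 = m2, residual_norm = sqrt(sum(stats::resid(fit)^2)),
              fitted = function(xx)
                recovery_curve(xx, y0, a1, k1, k2, m1, m2, ymax))
  class(out) <- "recovery_fit"
  out
}

#' @export
print.recovery_fit <- function(x, ...) {
  cat(sprintf(
    "recovery_fit: y0 %.3g, a1 %.3g, k1 %.3g /ms, k2 %.3g /ms, tau_w %.3g ms\n",
    x$y0, x$a1, x$k1, x$k2, x$tau_w_rec))
  invisible(x)
}

#' Non-stationary fluctuation analysis
#'
#' Computes the ensemble mean and variance across repeated sweeps over
#' the desensitizing (decay) phase, groups samples into amplitude bins
#' of equal count, and fits the parabolic variance-mean relation
#' `sigma^2 = i*I - I^2/N + sigma_b^2` by least squares (the model is
#' linear in `i`, `1/N` and the background term, so an exact linear
#' fit is used). The single-channel conductance is `gamma = i/Vh` and
#' the peak open probability `Popen = I_peak/(N*i)`.
#'
#' The background variance enters with a configurable sign:
#' `background = "add"` (default) fits `+sigma_b^2` as an additive
#' baseline-noise variance; `background = "subtract"` reports the
#' negated intercept, matching the convention that writes the relation
#' as `sigma^2 = i*I - I^2/N - sigma_o^2`. The two conventions fit the
#' same parabola and differ only in the reported sign of the
#' background term.
#'
#' @param sweeps a [sweep_set()] with at least 20 sweeps.
#' @param n_bins number of equal-count amplitude bins (default 10).
#' @param baseline_window `c(t0, t1)` ms defining the background
#'   (pre-stimulus) window; default the first 5% of the sweep.
#' @param decay_window optional `c(t0, t1)` ms restricting the
#'   analysed phase; default peak-to-end of the mean trace.
#' @param background `"add"` or `"subtract"` (sign convention above).
#' @return list of class `nsfa_result`: `i` (pA), `N`, `sigma_b2`
#'   (pA^2, reported under the chosen convention), `gamma_pS`,
#'   `p_open`, `binned` (data frame mean_pA, var_pA2), `vertex`
#'   (mean and variance at the fitted parabola vertex), `warning`
#'   (non-convex data flag).
#' @export
nsfa <- function(sweeps, n_bins = 10L, baseline_window = NULL,
                 decay_window = NULL,
                 background = c("add", "subtract")) {
  stopifnot(inherits(sweeps, "sweep_set"))
  background <- match.arg(background)
  cur <- sweeps$currents
  if (ncol(cur) < 20L)
    stop("NSFA needs at least 20 sweeps (got ", ncol(cur), ")",
         call. = FALSE)
  t <- sweeps$time
  mean_tr <- rowMeans(cur)
  var_tr <- apply(cur, 1L, stats::var)
  if (max(var_tr) < .Machine$double.eps * 100)
    stop("degenerate fit: sweeps are identical (zero variance)",
         call. = FALSE)
  if (is.null(baseline_window))
    baseline_window <- c(t[1L], t[1L] + 0.05 * (t[length(t)] - t[1L]))
  base_idx <- t >= baseline_window[1L] & t <= baseline_window[2L]
  sigma_o2 <- mean(var_tr[base_idx])
  pk <- which.max(abs(mean_tr))
  if (is.null(decay_window)) {
    idx <- seq(pk, length(t))
  } else {
    idx <- which(t >= decay_window[1L] & t <= decay_window[2L])
  }
  m <- mean_tr[idx]
  v <- var_tr[idx]
  # equal-count amplitude bins over the decay phase
  ord <- order(abs(m))
  bins <- cut(seq_along(ord), breaks = n_bins, labels = FALSE)
  bm <- tapply(m[ord], bins, mean)
  bv <- tapply(v[ord], bins, mean)
  # the quadratic regressor is the within-bin mean of I^2, not the
  # squared bin mean: bins spanning a wide amplitude range (the sparse
  # peak region under equal-count binning) otherwise bias N downward
  bm2 <- tapply(m[ord]^2, bins, mean)
  fit <- stats::lm(bv ~ bm + bm2)
  cf <- stats::coef(fit)
  i_hat <- unname(cf["bm"])
  curv <- unname(cf["bm2"])
  warn <- NULL
  if (!is.finite(curv) || curv >= 0) {
    warn <- "variance-mean relation is not concave; N unreliable"
    warning(warn, call. = FALSE)
  }
  N_hat <- -1 / curv
  c0 <- unname(cf["(Intercept)"])
  sigma_b2 <- if (background == "add") c0 else -c0
  vh <- sweeps$holding_potential
  gamma_pS <- 1000 * i_hat / vh
  p_open <- mean_tr[pk] / (N_hat * i_hat)
  out <- list(i = i_hat, N = N_hat, sigma_b2 = sigma_b2,
              sigma_o2_measured = sigma_o2, gamma_pS = gamma_pS,
              p_open = p_open,
              binned = data.frame(mean_pA = as.numeric(bm),
                                  var_pA2 = as.numeric(bv)),
              vertex = c(mean = i_hat * N_hat / 2,
                         var = i_hat^2 * N_hat / 4 + c0),
              background = background, warning = warn)
  class(out) <- "nsfa_result"
  out
}

#' @export
print.nsfa_result <- function(x, ...) {
  cat(sprintf(
    "nsfa: i = %.3g pA, N = %.1f, gamma = %.1f pS, Popen = %.2f\n",
    x$i, x$N, x$gamma_pS, x$p_open))
  invisible(x)
}

#' Rectification index from three I-V points
#'
#' `RI = -(I(+40) - I(0)) / (I(-60) - I(0))`: near 2/3 for a linear
#' (ohmic) conductance and near 0 for fully inwardly rectifying
#' (GluA2-lacking, polyamine-blocked) receptors.
#'
#' @param iv list or named vector with `I_plus40`, `I_0`, `I_minus60`
#'   (pA, sweep-averaged currents at +40, 0 and -60 mV).
#' @return dimensionless RI.
#' @export
rectification_index <- function(iv) {
  ip <- iv[["I_plus40"]]
  i0 <- iv[["I_0"]]
  im <- iv[["I_minus60"]]
  stopifnot(is.finite(ip), is.finite(i0), is.finite(im))
  den <- im - i0
  if (abs(den) < .Machine$double.eps * 100)
    stop("I(-60) equals I(0): rectification index undefined",
         call. = FALSE)
  -(ip - i0) / den
}

#' Pulse-train amplitude ratios
#'
#' Normalizes per-pulse peak amplitudes to the first pulse and reports
#' the fifth-to-first ratio when at least five pulses are present.
#'
#' @param peaks ordered per-pulse peak amplitudes (>= 2).
#' @return list with `normalized` (series divided by P1) and `p5_p1`
#'   (`NA` when fewer than 5 pulses).
#' @export
train_ratios <- function(peaks) {
  stopifnot(length(peaks) >= 2L)
  if (abs(peaks[1L]) < .Machine$double.eps * 100)
    stop("first pulse amplitude is zero", call. = FALSE)
  norm <- peaks / peaks[1L]
  list(normalized = norm,
       p5_p1 = if (length(peaks) >= 5L) norm[5L] else NA_real_)
}
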