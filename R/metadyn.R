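# Well-tempered metadynamics: PLUMED-style hills logs, bias and
# free-energy-surface reconstruction, and the adaptive-Gaussian
# deposition rule. The toy Langevin driver lives in metadyn-sim.R.

#' Boltzmann constant in kJ/mol/K
#' @export
KB_KJMOL <- 0.0083144621

#' Well-tempered metadynamics parameters
#'
#' @param temperature system temperature T in Kelvin (default 300).
#' @param bias_factor gamma = (T + dT)/T, > 1 (default 10). The
#'   well-tempered "boost" temperature is `dT = (gamma - 1) * T`.
#' @param h0 initial Gaussian hill height, kJ/mol (default 1.2).
#' @param deposition_interval hill deposition period, ps (default 10).
#' @param adaptive_window time window over which the CV mean-square
#'   displacement sets the adaptive hill widths, ps (default 10).
#' @param sigma_min,sigma_max floor and cap for adaptive widths, CV
#'   units. The band is kept narrow by default: hill volume scales
#'   with sigma^2, and strongly varying volumes distort the
#'   deposition-flux balance that the histogram free-energy estimator
#'   relies on.
#' @param sigma0 per-CV fallback widths used before the adaptive
#'   window has filled.
#' @param kB Boltzmann constant, kJ/mol/K.
#' @return list of class `wt_params`.
#' @export
wt_params <- function(temperature = 300, bias_factor = 10, h0 = 1.2,
                      deposition_interval = 10, adaptive_window = 10,
                      sigma_min = 0.1, sigma_max = 0.25,
                      sigma0 = c(0.1, 0.1), kB = KB_KJMOL) {
  if (bias_factor <= 1) stop("bias_factor must exceed 1", call. = FALSE)
  if (temperature <= 0) stop("temperature must be positive",
                             call. = FALSE)
  structure(list(temperature = temperature, bias_factor = bias_factor,
                 h0 = h0, deposition_interval = deposition_interval,
                 adaptive_window = adaptive_window,
                 sigma_min = sigma_min, sigma_max = sigma_max,
                 sigma0 = rep_len(sigma0, 2L), kB = kB,
                 delta_T = (bias_factor - 1) * temperature),
            class = "wt_params")
}

#' Construct a hills log
#'
#' @param hills data frame with columns `time` (ps), `s1`, `s2` (CV
#'   units), `sigma1`, `sigma2` (> 0), `height` (kJ/mol, >= 0),
#'   `biasf`, and optionally `walker`.
#' @param cv_names names of the two collective variables.
#' @param periodic logical length-2: is each CV periodic?
#' @param period per-CV period (e.g. 360 for torsions in degrees).
#' @return object of class `hills_log`, hills sorted by time (stable
#'   within walker).
#' @export
hills_log <- function(hills, cv_names = c("s1", "s2"),
                      periodic = c(FALSE, FALSE), period = c(360, 360)) {
  need <- c("time", "s1", "s2", "sigma1", "sigma2", "height", "biasf")
  miss <- setdiff(need, names(hills))
  if (length(miss))
    stop("hills table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(hills) && any(hills$sigma1 <= 0 | hills$sigma2 <= 0))
    stop("hill widths must be positive", call. = FALSE)
  if (nrow(hills) && any(hills$height < 0))
    stop("hill heights must be non-negative", call. = FALSE)
  if (is.null(hills$walker)) hills$walker <- rep(1L, nrow(hills))
  hills <- hills[order(hills$time), , drop = FALSE]
  rownames(hills) <- NULL
  structure(list(hills = hills, cv_names = cv_names,
                 periodic = rep_len(periodic, 2L),
                 period = rep_len(period, 2L)),
            class = "hills_log")
}

#' @export
print.hills_log <- function(x, ...) {
  cat("hills_log:", nrow(x$hills), "hills,",
      length(unique(x$hills$walker)), "walker(s), CVs",
      paste(x$cv_names, collapse = "/"), "\n")
  invisible(x)
}

#' Parse PLUMED-style HILLS files
#'
#' Reads one or more hills files in the PLUMED text dialect: a
#' `#! FIELDS time <cv1> <cv2> sigma_<cv1> sigma_<cv2> height biasf`
#' header, optional `#! SET min_<cv>/max_<cv>` periodicity metadata,
#' then one hill per row. Multiple files (multiple-walker runs) are
#' merged and globally time-sorted, with walker id equal to the file
#' index.
#'
#' @param paths character vector of file paths.
#' @return a [hills_log()].
#' @export
parse_hills <- function(paths) {
  logs <- lapply(seq_along(paths), function(w) {
    parse_hills_one(paths[w], walker = w)
  })
  cv_names <- logs[[1L]]$cv_names
  for (lg in logs)
    if (!identical(lg$cv_names, cv_names))
      stop("hills files declare different CV names", call. = FALSE)
  hills_log(do.call(rbind, lapply(logs, `[[`, "hills")),
            cv_names = cv_names, periodic = logs[[1L]]$periodic,
            period = logs[[1L]]$period)
}

parse_hills_one <- function(path, walker = 1L) {
  if (!file.exists(path))
    stop("cannot read '", path, "': no such file", call. = FALSE)
  lines <- readLines(path)
  fields_line <- grep("^#!\\s*FIELDS", lines, value = TRUE)
  if (!length(fields_line))
    stop("'", path, "': missing '#! FIELDS' header", call. = FALSE)
  cols <- strsplit(trimws(sub("^#!\\s*FIELDS", "", fields_line[1L])),
                   "[[:space:]]+")[[1L]]
  if (cols[1L] != "time" || length(cols) < 7L)
    stop("'", path, "': unsupported FIELDS header", call. = FALSE)
  cv_names <- cols[2:3]
  sigma_cols <- paste0("sigma_", cv_names)
  want <- c("time", cv_names, sigma_cols, "height", "biasf")
  if (!all(want %in% cols))
    stop("'", path, "': FIELDS header lacks ",
         paste(setdiff(want, cols), collapse = ", "), call. = FALSE)
  # periodicity metadata: "#! SET min_<cv> ..." / "#! SET max_<cv> ..."
  periodic <- c(FALSE, FALSE)
  period <- c(360, 360)
  for (j in 1:2) {
    pat_min <- paste0("^#!\\s*SET\\s+min_", cv_names[j], "\\s+(\\S+)")
    pat_max <- paste0("^#!\\s*SET\\s+max_", cv_names[j], "\\s+(\\S+)")
    mn <- regmatches(lines, regexec(pat_min, lines))
    mx <- regmatches(lines, regexec(pat_max, lines))
    mn <- unlist(lapply(mn, function(m) if (length(m)) m[2L]))
    mx <- unlist(lapply(mx, function(m) if (length(m)) m[2L]))
    if (length(mn) && length(mx)) {
      periodic[j] <- TRUE
      period[j] <- plumed_num(mx[1L]) - plumed_num(mn[1L])
    }
  }
  data_idx <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  vals <- lapply(data_idx, function(i) {
    v <- suppressWarnings(as.numeric(
      strsplit(trimws(lines[i]), "[[:space:]]+")[[1L]]))
    if (length(v) != length(cols) || anyNA(v))
      stop("'", path, "' line ", i, ": expected ", length(cols),
           " numeric columns", call. = FALSE)
    v
  })
  m <- if (length(vals)) do.call(rbind, vals)
       else matrix(numeric(0), ncol = length(cols))
  colnames(m) <- cols
  hills <- data.frame(time = m[, "time"],
                      s1 = m[, cv_names[1L]], s2 = m[, cv_names[2L]],
                      sigma1 = m[, sigma_cols[1L]],
                      sigma2 = m[, sigma_cols[2L]],
                      height = m[, "height"], biasf = m[, "biasf"],
                      walker = walker)
  list(hills = hills, cv_names = cv_names, periodic = periodic,
       period = period)
}

plumed_num <- function(x) {
  if (x == "-pi") return(-180)
  if (x == "pi") return(180)
  as.numeric(x)
}

#' Write a hills log in the PLUMED text dialect
#'
#' One file per walker when `split_walkers = TRUE`, else a single
#' merged file. Diagonal (per-CV sigma) Gaussians only.
#'
#' @param log a `hills_log`.
#' @param path output path; with `split_walkers`, walker `w` goes to
#'   `<path>.<w>`.
#' @param split_walkers write one file per walker id.
#' @return the path(s) written, invisibly.
#' @export
write_hills <- function(log, path, split_walkers = FALSE) {
  stopifnot(inherits(log, "hills_log"))
  header <- c(
    paste("#! FIELDS time", log$cv_names[1L], log$cv_names[2L],
          paste0("sigma_", log$cv_names[1L]),
          paste0("sigma_", log$cv_names[2L]), "height biasf"))
  for (j in 1:2) {
    if (log$periodic[j]) {
      header <- c(header,
        paste("#! SET min_", log$cv_names[j], " ",
              format(-log$period[j] / 2), sep = ""),
        paste("#! SET max_", log$cv_names[j], " ",
              format(log$period[j] / 2), sep = ""))
    }
  }
  fmt_rows <- function(h) {
    sprintf("%15.6f %14.9f %14.9f %14.9f %14.9f %14.9f %10.3f",
            h$time, h$s1, h$s2, h$sigma1, h$sigma2, h$height, h$biasf)
  }
  if (split_walkers) {
    ws <- sort(unique(log$hills$walker))
    paths <- paste0(path, ".", ws)
    for (k in seq_along(ws)) {
      h <- log$hills[log$hills$walker == ws[k], , drop = FALSE]
      writeLines(c(header, fmt_rows(h)), paths[k])
    }
    return(invisible(paths))
  }
  writeLines(c(header, fmt_rows(log$hills)), path)
  invisible(path)
}

# Minimum-image CV differences: matrix of point minus hill centres.
cv_delta <- function(x, centers, periodic, period) {
  d <- x - centers
  if (periodic) d <- d - period * round(d / period)
  d
}

#' Metadynamics bias at a point
#'
#' Sum of the deposited Gaussian hills, `V(s) = sum_i h_i *
#' exp(-(d1^2/(2*sigma1^2) + d2^2/(2*sigma2^2)))`, with minimum-image
#' differences for periodic CVs, over hills deposited up to
#' `upto_time`.
#'
#' @param log a `hills_log`.
#' @param point length-2 numeric, CV units.
#' @param upto_time include hills with `time <= upto_time` (default
#'   all).
#' @return bias in kJ/mol.
#' @export
bias_at <- function(log, point, upto_time = Inf) {
  stopifnot(inherits(log, "hills_log"))
  h <- log$hills[log$hills$time <= upto_time, , drop = FALSE]
  if (!nrow(h)) return(0)
  d1 <- cv_delta(point[1L], h$s1, log$periodic[1L], log$period[1L])
  d2 <- cv_delta(point[2L], h$s2, log$periodic[2L], log$period[2L])
  sum(h$height * exp(-(d1^2 / (2 * h$sigma1^2) +
                       d2^2 / (2 * h$sigma2^2))))
}

# Bias on a full grid; exploits separability of diagonal Gaussians.
bias_grid <- function(log, s1, s2, upto_time = Inf) {
  h <- log$hills[log$hills$time <= upto_time, , drop = FALSE]
  V <- matrix(0, nrow = length(s1), ncol = length(s2))
  for (i in seq_len(nrow(h))) {
    e1 <- exp(-cv_delta(s1, h$s1[i], log$periodic[1L],
                        log$period[1L])^2 / (2 * h$sigma1[i]^2))
    e2 <- exp(-cv_delta(s2, h$s2[i], log$periodic[2L],
                        log$period[2L])^2 / (2 * h$sigma2[i]^2))
    V <- V + h$height[i] * tcrossprod(e1, e2)
  }
  V
}

#' Free-energy surface from summed hills
#'
#' The well-tempered estimator `F(s) = -(gamma/(gamma - 1)) * V(s)`
#' evaluated from the final accumulated bias, shifted so that
#' `min(F) = 0`.
#'
#' @param log a `hills_log`.
#' @param params a [wt_params()]; its `bias_factor` must match the
#'   hills' `biasf`.
#' @param s1,s2 grid axis values (CV units).
#' @return object of class `fes` with fields `s1`, `s2`, `F` (matrix,
#'   kJ/mol, `F[i, j]` at `(s1[i], s2[j])`) and `method =
#'   "sum_hills"`.
#' @export
fes_from_hills <- function(log, params, s1, s2) {
  stopifnot(inherits(log, "hills_log"), inherits(params, "wt_params"))
  g <- params$bias_factor
  if (g <= 1) stop("bias factor must exceed 1", call. = FALSE)
  bf <- unique(round(log$hills$biasf, 6))
  if (length(bf) && any(abs(bf - g) > 1e-6))
    stop("params bias_factor (", g, ") inconsistent with hills biasf (",
         paste(bf, collapse = ", "), ")", call. = FALSE)
  V <- bias_grid(log, s1, s2)
  F <- -(g / (g - 1)) * V
  F <- F - min(F)
  structure(list(s1 = s1, s2 = s2, F = F, method = "sum_hills"),
            class = "fes")
}

#' Free-energy surface from the visited-CV histogram
#'
#' Uses the stationary distribution of well-tempered metadynamics: the
#' biased run samples `P(s) ~ exp(-F(s)/(kB*(T + dT)))`, so
#' `F(s) = -kB*(T + dT)*log(density)`, min-shifted to zero. The density
#' is a Gaussian-kernel estimate of the visited CV values
#' (via [MASS::kde2d()]).
#'
#' @param samples two-column matrix or data frame of visited CV pairs.
#' @param params a [wt_params()].
#' @param s1,s2 grid axis values (must be uniform; kde2d requirement).
#' @param kernel_width Gaussian kernel standard deviation, CV units
#'   (scalar or per-CV length 2).
#' @param min_density grid nodes with estimated density below
#'   `min_density * max(density)` are marked unvisited (`NA`).
#' @return an `fes` with `method = "histogram"`; unvisited nodes `NA`.
#' @export
fes_from_histogram <- function(samples, params, s1, s2,
                               kernel_width = 0.1,
                               min_density = 1e-6) {
  stopifnot(inherits(params, "wt_params"))
  samples <- as.matrix(samples)
  if (nrow(samples) < 1L) stop("no CV samples given", call. = FALSE)
  if (any(kernel_width <= 0))
    stop("kernel width must be positive", call. = FALSE)
  kw <- rep_len(kernel_width, 2L)
  # kde2d's bandwidth argument is 4x the Gaussian kernel sd
  kd <- MASS::kde2d(samples[, 1L], samples[, 2L], h = 4 * kw,
                    n = c(length(s1), length(s2)),
                    lims = c(range(s1), range(s2)))
  # kde2d evaluates on its own uniform grid spanning lims; map back
  dens <- kd$z
  Teff <- params$temperature * params$bias_factor
  dens[dens < min_density * max(dens)] <- NA_real_
  F <- -params$kB * Teff * log(dens)
  F <- F - min(F, na.rm = TRUE)
  structure(list(s1 = kd$x, s2 = kd$y, F = F, method = "histogram"),
            class = "fes")
}

#' @export
print.fes <- function(x, ...) {
  cat("fes (", x$method, "): ", length(x$s1), " x ", length(x$s2),
      " grid, F range 0 - ",
      sprintf("%.2f", max(x$F, na.rm = TRUE)), " kJ/mol\n", sep = "")
  invisible(x)
}

#' Plot a free-energy surface
#'
#' @param x an `fes`.
#' @param nlevels contour levels.
#' @param ... passed to [graphics::image()].
#' @export
plot.fes <- function(x, nlevels = 12, ...) {
  graphics::image(x$s1, x$s2, x$F, col = grDevices::hcl.colors(64),
                  xlab = "CV1", ylab = "CV2", ...)
  graphics::contour(x$s1, x$s2, x$F, nlevels = nlevels, add = TRUE)
  invisible(x)
}

#' Free-energy difference between two basins of a surface
#'
#' Summarizes `F` within a disk around each centre and returns
#' `F(basin2) - F(basin1)`. `stat = "min"` reports the basin floor;
#' `stat = "mean"` averages over the disk, which is robust to
#' node-level noise on stochastically reconstructed surfaces (the
#' minimum of a noisy field is biased low) at the cost of a small,
#' largely cancelling curvature offset.
#'
#' @param fes an `fes`.
#' @param basin1,basin2 length-2 CV-space centres.
#' @param radius disk radius, CV units.
#' @param stat `"min"` or `"mean"`.
#' @return kJ/mol.
#' @export
fes_basin_difference <- function(fes, basin1, basin2, radius = 0.4,
                                 stat = c("min", "mean")) {
  stat <- match.arg(stat)
  basin_stat <- function(center) {
    d2 <- outer((fes$s1 - center[1L])^2, (fes$s2 - center[2L])^2, `+`)
    vals <- fes$F[d2 <= radius^2]
    vals <- vals[is.finite(vals)]
    if (!length(vals))
      stop("no sampled grid nodes within basin at (",
           paste(center, collapse = ", "), ")", call. = FALSE)
    if (stat == "min") min(vals) else mean(vals)
  }
  basin_stat(basin2) - basin_stat(basin1)
}

#' Write a free-energy surface as grid text
#'
#' Three columns (s1, s2, F), one grid node per row, s2 fastest.
#'
#' @param fes an `fes`.
#' @param path output path.
#' @param sep column separator; use `","` for CSV.
#' @export
write_fes <- function(fes, path, sep = " ") {
  grid <- expand.grid(s2 = fes$s2, s1 = fes$s1)
  df <- data.frame(s1 = grid$s1, s2 = grid$s2,
                   F = as.vector(t(fes$F)))
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     col.names = (sep == ","), quote = FALSE)
  invisible(path)
}

#' Next hill under the well-tempered adaptive-Gaussian rule
#'
#' Height follows the well-tempered rule `h = h0 * exp(-V(s)/(kB*dT))`
#' with `V` the bias already deposited at the current CV position.
#' Widths are diffusion-adaptive: per CV, sigma is the root-mean-square
#' displacement of the CV over the trailing `adaptive_window`, clamped
#' to `[sigma_min, sigma_max]`; before the window has filled the
#' configured `sigma0` fallback is used.
#'
#' @param state length-2 current CV values.
#' @param log `hills_log` of hills deposited so far (empty allowed:
#'   pass a log with zero rows).
#' @param params a [wt_params()].
#' @param history data frame or matrix with columns (time, s1, s2) of
#'   recent CV samples, or `NULL`.
#' @param time deposition time stamp, ps.
#' @param walker walker id recorded with the hill.
#' @return one-row hills data frame (same columns as
#'   `hills_log$hills`).
#' @export
next_hill <- function(state, log, params, history = NULL, time = 0,
                      walker = 1L) {
  stopifnot(inherits(params, "wt_params"))
  V <- if (is.null(log) || nrow(log$hills) == 0L) 0
       else bias_at(log, state, upto_time = Inf)
  height <- params$h0 * exp(-V / (params$kB * params$delta_T))
  sigma <- adaptive_sigma(state, history, params)
  data.frame(time = time, s1 = state[1L], s2 = state[2L],
             sigma1 = sigma[1L], sigma2 = sigma[2L], height = height,
             biasf = params$bias_factor, walker = walker)
}

# RMS displacement of each CV over the trailing adaptive window,
# clamped to [sigma_min, sigma_max]; sigma0 before the window fills.
adaptive_sigma <- function(state, history, params) {
  if (is.null(history) || nrow(history) < 2L) return(params$sigma0)
  h <- as.matrix(history)
  t_now <- h[nrow(h), 1L]
  keep <- h[, 1L] >= t_now - params$adaptive_window
  h <- h[keep, , drop = FALSE]
  if (nrow(h) < 2L ||
      (t_now - h[1L, 1L]) < 0.5 * params$adaptive_window)
    return(params$sigma0)
  disp2 <- sweep(h[, 2:3, drop = FALSE], 2L, state, `-`)^2
  sigma <- sqrt(colMeans(disp2))
  pmin(pmax(sigma, params$sigma_min), params$sigma_max)
}
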