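# Closed-form assay computations: ACE activity from a fluorogenic kinetic
# slope, and Langendorff coronary-flow responses.

#' Generate a synthetic kinetic trace
#'
#' Linear fluorescence-vs-time trace plus Gaussian noise, with the generating
#' slope recorded as ground truth.
#'
#' @param slope True slope (RFU/min).
#' @param intercept Intercept (RFU).
#' @param duration Duration (min).
#' @param n_points Number of samples (at least 3).
#' @param noise_sd Gaussian noise SD (RFU).
#' @param seed Integer seed.
#' @return A list with `trace` (tibble `time_min`, `rfu`) and `truth`.
#' @export
sim_kinetic_trace <- function(slope, intercept = 100, duration = 30,
                              n_points = 31, noise_sd = 0, seed = 1) {
  if (n_points < 3) abort("`n_points` must be at least 3.")
  check_number(noise_sd, "noise_sd", 0)
  t <- seq(0, duration, length.out = n_points)
  y <- intercept + slope * t
  if (noise_sd > 0) {
    y <- withr::with_seed(substream_seed(seed, "kinetics"),
                          y + rnorm(n_points, 0, noise_sd))
  }
  list(trace = tibble(time_min = t, rfu = y),
       truth = truth_record("kinetic_trace", slope = slope,
                            intercept = intercept, noise_sd = noise_sd,
                            seed = seed))
}

#' Fit the linear slope of a kinetic trace
#'
#' Ordinary least squares of fluorescence on time. Optional linear-range
#' trimming (off by default): the trace is truncated before the first point
#' whose local curvature (second difference, normalised by the fluorescence
#' range) exceeds `curvature_threshold`.
#'
#' @param trace Data frame with `time_min` and `rfu` (at least 3 points,
#'   strictly increasing times).
#' @param trim Enable linear-range trimming.
#' @param curvature_threshold Normalised curvature cut-off for trimming.
#' @return A one-row tibble: `slope` (RFU/min), `se`, `intercept`,
#'   `n_used`.
#' @export
fit_kinetic_slope <- function(trace, trim = FALSE, curvature_threshold = 0.05) {
  stopifnot(all(c("time_min", "rfu") %in% names(trace)))
  t <- trace$time_min; y <- trace$rfu
  if (length(t) < 3) abort("need at least 3 points.")
  if (anyDuplicated(t)) abort("duplicate time points.")
  if (any(diff(t) < 0)) abort("times must be increasing.")
  n_used <- length(t)
  if (trim && length(t) >= 5) {
    rng <- diff(range(y))
    if (rng > 0) {
      curv <- abs(diff(diff(y))) / rng
      bad <- which(curv > curvature_threshold)
      if (length(bad)) n_used <- max(3, bad[1] + 1)
    }
    t <- t[seq_len(n_used)]; y <- y[seq_len(n_used)]
  }
  fit <- lm(y ~ t)
  b <- unname(coef(fit))
  n <- length(t)
  sxx <- sum((t - mean(t))^2)
  se <- sqrt(max(sum(fit$residuals^2), 0) / (n - 2) / sxx)
  tibble(slope = b[2], se = se, intercept = b[1], n_used = n_used)
}

#' ACE activity from a kinetic slope
#'
#' `activity = slope / f_1umol * Y`, where `f_1umol` is the fluorescence
#' intensity of 1 umol of converted substrate (instrument calibration,
#' required input) and `Y` the dilution factor: 33.33 for plasma (result in
#' U/L) or 10 for tissue homogenate (U/g). The dilution factor can be
#' overridden for other protocols.
#'
#' @param slope Kinetic slope (RFU/min).
#' @param f_1umol Fluorescence of 1 umol converted substrate (RFU); > 0.
#' @param matrix_type `"plasma"` or `"tissue"`.
#' @param dilution_y Override for the dilution factor.
#' @return A one-row tibble: `slope`, `f_1umol`, `dilution_y`, `activity`,
#'   `unit`, `matrix_type`.
#' @export
#' @examples
#' ace_activity(0.6, f_1umol = 2, matrix_type = "plasma") # ~10 U/L
ace_activity <- function(slope, f_1umol, matrix_type = c("plasma", "tissue"),
                         dilution_y = NULL) {
  matrix_type <- match.arg(matrix_type)
  check_number(f_1umol, "f_1umol", 0, strict = TRUE)
  y <- dilution_y %||% switch(matrix_type, plasma = 33.33, tissue = 10)
  tibble(slope = slope, f_1umol = f_1umol, dilution_y = y,
         activity = slope / f_1umol * y,
         unit = switch(matrix_type, plasma = "U/L", tissue = "U/g"),
         matrix_type = matrix_type)
}

#' Coronary-flow response to reactive hyperaemia
#'
#' `delta_cf = peak - baseline` (also normalised to ventricle mass) and
#' `reserve = peak / baseline`. A reserve below 1 (peak under baseline) is
#' flagged.
#'
#' @param baseline_cf Baseline coronary flow (ml/min), > 0.
#' @param peak_cf Peak coronary flow during reactive hyperaemia (ml/min).
#' @param ventricle_mass Ventricle mass (g), optional (for the normalised
#'   delta).
#' @return A one-row tibble: `baseline_cf`, `peak_cf`, `delta_cf`,
#'   `delta_cf_per_g`, `reserve`, `warning_low_reserve`.
#' @export
#' @examples
#' flow_response(2, 5, 0.15)
flow_response <- function(baseline_cf, peak_cf, ventricle_mass = NULL) {
  check_number(baseline_cf, "baseline_cf", 0, strict = TRUE)
  check_number(peak_cf, "peak_cf", 0)
  if (!is.null(ventricle_mass)) check_number(ventricle_mass, "ventricle_mass", 0, strict = TRUE)
  delta <- peak_cf - baseline_cf
  low <- peak_cf < baseline_cf
  if (low) warn("peak CF below baseline: reserve < 1.")
  tibble(baseline_cf = baseline_cf, peak_cf = peak_cf, delta_cf = delta,
         delta_cf_per_g = if (is.null(ventricle_mass)) NA_real_ else delta / ventricle_mass,
         reserve = peak_cf / baseline_cf, warning_low_reserve = low)
}
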