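# Synthetic left-ventricular time-volume curves with known phase breakpoints.

#' Configuration for the time-volume-curve generator
#'
#' Describes one cardiac cycle as four linear phases — isovolumetric
#' contraction (IVC), ejection, isovolumetric relaxation (IVR) and filling —
#' with end-diastolic/end-systolic volumes and an optional biphasic filling
#' shape (early E wave, diastasis, atrial A wave) for E/A-ratio work.
#'
#' Defaults mirror a healthy adult mouse heart imaged at high frame rate:
#' EDV 60 ul, ESV 15 ul (EF 75%), R-R 150 ms (400 bpm), 60 reconstructed
#' frames, phase fractions 10/30/20/40% of R-R.
#'
#' @param edv,esv End-diastolic / end-systolic volume (ul); `edv > esv > 0`.
#' @param phase_fractions Fractions of the R-R interval spent in IVC,
#'   ejection, IVR and filling; each positive, summing to 1.
#' @param rr R-R interval (ms). `hr` (bpm) defaults to `60000 / rr` and must
#'   agree with it to 1%.
#' @param hr Heart rate (bpm).
#' @param n_frames Number of frames sampled over the cycle (at least 16).
#' @param noise_sd Gaussian volume noise SD (ul).
#' @param e_peak,a_peak Optional early/atrial peak filling rates (ul/s). When
#'   both are given the filling phase is built from three ramps (E wave,
#'   diastasis, A wave) whose slopes are `e_peak`, a low diastasis rate and
#'   `a_peak`; when `NULL` filling is a single ramp.
#' @param seed Integer seed; all randomness is derived from it.
#' @return A list of class `cycle_sim_config`.
#' @export
cycle_sim_config <- function(edv = 60, esv = 15,
                             phase_fractions = c(ivc = 0.10, ejection = 0.30,
                                                 ivr = 0.20, filling = 0.40),
                             rr = 150, hr = 60000 / rr, n_frames = 60,
                             noise_sd = 0, e_peak = NULL, a_peak = NULL,
                             seed = 1) {
  check_number(edv, "edv", lower = 0, strict = TRUE)
  check_number(esv, "esv", lower = 0, strict = TRUE)
  if (edv <= esv) abort("`edv` must exceed `esv`.")
  if (length(phase_fractions) != 4 || any(phase_fractions <= 0)) {
    abort("`phase_fractions` must be 4 positive fractions (IVC, ejection, IVR, filling).")
  }
  if (abs(sum(phase_fractions) - 1) > 1e-9) {
    abort("`phase_fractions` must sum to 1.")
  }
  check_number(rr, "rr", lower = 0, strict = TRUE)
  if (abs(hr - 60000 / rr) > 0.01 * (60000 / rr)) {
    abort("`hr` and `rr` disagree by more than 1%.")
  }
  if (n_frames < 16) abort("`n_frames` must be at least 16.")
  check_number(noise_sd, "noise_sd", lower = 0)
  if (xor(is.null(e_peak), is.null(a_peak))) {
    abort("supply both `e_peak` and `a_peak`, or neither.")
  }
  structure(list(edv = edv, esv = esv,
                 phase_fractions = unname(phase_fractions), rr = rr, hr = hr,
                 n_frames = as.integer(n_frames), noise_sd = noise_sd,
                 e_peak = e_peak, a_peak = a_peak, seed = seed),
            class = "cycle_sim_config")
}

#' Construct a time-volume curve
#'
#' A tibble of per-frame LV volumes over one R-wave-gated cycle, with the R-R
#' interval and heart rate stored as attributes. The first sample is taken at
#' end-diastole (cycle origin at the R wave).
#'
#' @param time_ms Sample times within the cycle (ms), strictly increasing,
#'   `time_ms[1] >= 0` and `time_ms[n] <= rr`.
#' @param volume_ul LV volumes (ul), positive.
#' @param rr R-R interval (ms).
#' @param hr Heart rate (bpm); defaults to `60000 / rr`.
#' @return A tibble of class `tvc_df` with columns `frame`, `time_ms`,
#'   `volume_ul` and attributes `rr`, `hr`.
#' @export
time_volume_curve <- function(time_ms, volume_ul, rr, hr = 60000 / rr) {
  if (length(time_ms) != length(volume_ul)) abort("time/volume length mismatch.")
  if (length(time_ms) < 16) abort("a time-volume curve needs at least 16 samples.")
  if (any(diff(time_ms) <= 0)) abort("`time_ms` must be strictly increasing.")
  if (time_ms[1] < 0 || time_ms[length(time_ms)] > rr) {
    abort("`time_ms` must lie within [0, rr].")
  }
  if (any(volume_ul <= 0)) abort("volumes must be positive.")
  if (abs(hr - 60000 / rr) > 0.01 * (60000 / rr)) {
    abort("`hr` and `rr` disagree by more than 1%.")
  }
  out <- tibble(frame = seq_along(time_ms) - 1L, time_ms = as.numeric(time_ms),
                volume_ul = as.numeric(volume_ul))
  structure(out, rr = rr, hr = hr, class = c("tvc_df", class(out)))
}

# piecewise-linear cycle model evaluated at times t (ms); knots/values in ms/ul
eval_pl <- function(t, knot_t, knot_v) {
  stats::approx(knot_t, knot_v, xout = t, method = "linear", rule = 2)$y
}

# Solve the three filling sub-ramp durations for a biphasic (E/diastasis/A)
# filling phase. Slopes in ul/ms; ft in ms; rise = sv.
biphasic_knots <- function(t0, ft, esv, sv, e_slope, a_slope, e_share = 0.55) {
  s_d <- 0.1 * min(e_slope, a_slope)
  m <- e_share * e_slope + (1 - e_share) * a_slope
  d_d <- (ft * m - sv) / (m - s_d)
  if (!is.finite(d_d) || d_d < 0 || d_d >= ft) {
    abort(paste0("biphasic filling infeasible: stroke volume ", sv,
                 " ul cannot be reached with the requested E/A peak rates."))
  }
  d_e <- e_share * (ft - d_d)
  d_a <- (1 - e_share) * (ft - d_d)
  t_e <- t0 + d_e
  t_d <- t_e + d_d
  list(t = c(t_e, t_d), v = c(esv + e_slope * d_e, esv + e_slope * d_e + s_d * d_d),
       slopes = c(e = e_slope, diastasis = s_d, a = a_slope),
       durations = c(e = d_e, diastasis = d_d, a = d_a))
}

#' Generate a synthetic time-volume curve with ground truth
#'
#' Builds an exactly piecewise-linear LV volume trace over one cycle — flat
#' IVC at EDV, linear ejection down to ESV, flat IVR, linear (or biphasic)
#' filling back to EDV — samples it at `n_frames` equally spaced times and
#' adds Gaussian noise. Deterministic for a given config (the `seed` field
#' drives a dedicated substream).
#'
#' @param config A [cycle_sim_config()].
#' @return A list with elements `tvc` (a [time_volume_curve()]) and `truth`
#'   (a [truth_record()] holding breakpoints as fractions of R-R, segment
#'   slopes in ul/ms, EDV/ESV/SV/EF and — for biphasic filling — the E/A
#'   ground truth).
#' @export
#' @examples
#' sim <- sim_time_volume_curve(cycle_sim_config(noise_sd = 1, seed = 7))
#' sim$truth$breakpoints
sim_time_volume_curve <- function(config) {
  stopifnot(inherits(config, "cycle_sim_config"))
  pf <- config$phase_fractions
  rr <- config$rr
  b <- cumsum(pf) # ends of IVC, ejection, IVR, filling as fractions of R-R
  t_b <- b * rr
  sv <- config$edv - config$esv

  knot_t <- c(0, t_b[1], t_b[2], t_b[3])
  knot_v <- c(config$edv, config$edv, config$esv, config$esv)
  slopes <- c(ivc = 0,
              ejection = -sv / (t_b[2] - t_b[1]),
              ivr = 0,
              filling = sv / (rr - t_b[3]))
  filling_truth <- NULL
  if (!is.null(config$e_peak)) {
    bi <- biphasic_knots(t_b[3], rr - t_b[3], config$esv, sv,
                         config$e_peak / 1000, config$a_peak / 1000)
    knot_t <- c(knot_t, bi$t)
    knot_v <- c(knot_v, bi$v)
    filling_truth <- list(sub_slopes = bi$slopes, sub_durations = bi$durations,
                          ea_ratio = config$e_peak / config$a_peak)
    slopes[["filling"]] <- max(bi$slopes) # steepest sub-slope convention
  }
  knot_t <- c(knot_t, rr)
  knot_v <- c(knot_v, config$edv)

  times <- (seq_len(config$n_frames) - 1) / config$n_frames * rr
  clean <- eval_pl(times, knot_t, knot_v)
  vols <- if (config$noise_sd > 0) {
    withr::with_seed(substream_seed(config$seed, "tvc"),
                     clean + rnorm(length(clean), 0, config$noise_sd))
  } else clean
  vols <- pmax(vols, 1e-6)

  truth <- truth_record("time_volume_curve",
                        breakpoints = b, slopes = slopes,
                        edv = config$edv, esv = config$esv, sv = sv,
                        ef = 100 * sv / config$edv,
                        er = abs(slopes[["ejection"]]) * rr / sv,
                        fr = slopes[["filling"]] * rr / sv,
                        filling = filling_truth,
                        config = unclass(config))
  list(tvc = time_volume_curve(times, vols, rr = rr, hr = config$hr),
       truth = truth)
}
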