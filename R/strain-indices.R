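# Scalar indices of one segment-averaged strain-time curve.

#' Strain indices of a segment-averaged strain curve
#'
#' Computes the peak-systolic, end-systolic and post-systolic strain family
#' together with strain rates from one strain-time series over a cycle:
#'
#' * `es` — extremal signed strain within systole (`[0, end_systole]`), in
#'   the direction of the dominant deformation (the sign of the whole-cycle
#'   absolute maximum);
#' * `ees` — strain at `end_systole` (linear interpolation);
#' * `epost` — extremal signed strain at or after end-systole;
#' * `emax` — maximum `|strain|` over the cycle;
#' * `psi` — post-systolic strain index `(epost - ees) / emax`;
#' * `tpeak`, `tpeak_si` — time of the absolute strain peak as a fraction of
#'   the R-R interval (already dimensionless);
#' * strain rates (centred finite differences of strain versus cycle
#'   fraction, %/R-R): `srmax` extremal systolic rate in the deformation
#'   direction, `sre` / `sra` the extremal opposite-sign rates in the early
#'   (first half of diastole) and late diastolic windows, `sre_a = sre/sra`;
#' * `ss` — systolic stretch: the maximal opposite-sign strain excursion
#'   during systole (non-negative, %).
#'
#' With fewer than 3 diastolic samples the diastolic rate indices are
#' undefined (`NA`) and `rates_defined` is `FALSE`.
#'
#' @param strain Strain values (%) over one cycle.
#' @param frame_times Cycle fractions in `[0, 1)`, increasing, same length.
#' @param end_systole End-systolic time as a fraction of R-R; default the
#'   time of the whole-curve absolute strain extremum.
#' @return A one-row tibble with the indices above.
#' @export
#' @examples
#' t <- (0:11) / 12
#' e <- c(0, -4, -9, -14, -17, -16, -12, -8, -5, -3, -1.5, -0.5)
#' strain_indices(e, t)
strain_indices <- function(strain, frame_times, end_systole = NULL) {
  n <- length(strain)
  stopifnot(length(frame_times) == n, n >= 4)
  if (any(diff(frame_times) <= 0)) abort("`frame_times` must be increasing.")
  ipeak <- which.max(abs(strain))
  tpeak <- frame_times[ipeak]
  s <- if (strain[ipeak] >= 0) 1 else -1
  if (is.null(end_systole)) end_systole <- tpeak
  check_number(end_systole, "end_systole", 0, 1)

  emax <- max(abs(strain))
  sys <- which(frame_times <= end_systole)
  post <- which(frame_times > end_systole)
  if (length(sys) == 0) abort("no systolic samples before `end_systole`.")
  es <- s * max(s * strain[sys])
  ees <- stats::approx(frame_times, strain, xout = end_systole, rule = 2)$y
  ss <- max(0, max(-s * strain[sys]))

  rate <- numeric(n)
  rate[1] <- (strain[2] - strain[1]) / (frame_times[2] - frame_times[1])
  rate[n] <- (strain[n] - strain[n - 1]) / (frame_times[n] - frame_times[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    rate[i] <- (strain[i + 1] - strain[i - 1]) / (frame_times[i + 1] - frame_times[i - 1])
  }
  srmax <- s * max(s * rate[sys])

  # post-systolic window is closed at end-systole: a curve peaking exactly at
  # end-systole and returning monotonically has epost = ees (and psi = 0)
  epost <- s * max(s * c(ees, strain[post]))
  psi <- (epost - ees) / emax

  rates_defined <- length(post) >= 3
  if (rates_defined) {
    mid <- end_systole + (1 - end_systole) / 2
    early <- post[frame_times[post] <= mid]
    late <- post[frame_times[post] > mid]
    sre <- if (length(early)) -s * max(-s * rate[early]) else NA_real_
    sra <- if (length(late)) -s * max(-s * rate[late]) else NA_real_
    sre_a <- if (!is.na(sre) && !is.na(sra) && sra != 0) sre / sra else NA_real_
  } else {
    sre <- NA_real_; sra <- NA_real_; sre_a <- NA_real_
  }

  tibble(es = es, ees = ees, epost = epost, emax = emax, psi = psi,
         tpeak = tpeak, tpeak_si = tpeak, srmax = srmax,
         sre = sre, sra = sra, sre_a = sre_a, ss = ss,
         rates_defined = rates_defined)
}
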