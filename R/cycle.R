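# Cardiac-cycle phase segmentation of time-volume curves and hemodynamic
# indices. The piecewise linear regression (PLR) splits one R-wave-gated cycle
# into IVC, ejection, IVR and filling; indices follow from the fitted
# breakpoints and slopes.

#' Fit a four-phase piecewise linear model to a time-volume curve
#'
#' Fits a continuous piecewise-linear volume model with three free interior
#' knots (four segments: isovolumetric contraction, ejection, isovolumetric
#' relaxation, filling), anchored at the R wave (first sample = end-diastole).
#' Knots are chosen by exhaustive search over the sample grid — optionally a
#' coarser candidate subset — minimizing the residual sum of squares subject
#' to the cardiac slope-sign constraints (ejection slope negative, filling
#' slope positive, isovolumetric slopes smaller in magnitude than both). Ties
#' are broken toward the earlier breakpoints.
#'
#' Two model variants are available. The default (`isovolumetric = "flat"`)
#' takes the isovolumetric phases as exactly constant-volume plateaus — which
#' is what "isovolumetric" means physiologically — so EDV and ESV are plateau
#' levels estimated from all plateau samples. `isovolumetric = "free"` lets
#' the plateau slopes float within `max_isovol_ratio` times the smaller of
#' the ejection/filling slope magnitudes.
#'
#' @param tvc A [time_volume_curve()] (or data frame with `time_ms`,
#'   `volume_ul` plus an `rr` attribute or explicit `rr`).
#' @param rr R-R interval (ms); taken from `tvc` attributes when absent.
#' @param candidates Integer vector of 0-based sample indices allowed as
#'   knots; default all interior samples. A coarser grid can only increase
#'   the attained SSE.
#' @param min_seg Minimum number of sample intervals per segment (default 2).
#' @param refine Polish the knot positions continuously (Nelder-Mead on the
#'   three knot times with the least-squares solve inside) after the grid
#'   search; removes the grid-quantisation bias of the segment vertices
#'   (default `TRUE`).
#' @param isovolumetric `"flat"` (default: IVC and IVR slopes fixed at 0) or
#'   `"free"` (slopes bounded by `max_isovol_ratio`).
#' @param max_isovol_ratio Flatness bound for `isovolumetric = "free"`:
#'   plateau slope magnitudes must stay below this fraction of the smaller
#'   of the ejection and filling slope magnitudes (default 0.1).
#' @return An object of class `plr_fit`: breakpoints (ends of IVC, ejection,
#'   IVR, filling as fractions of R-R; the last is 1 because filling runs to
#'   the next R wave), per-segment slopes (ul/ms), `sse` (ul^2), fitted
#'   values and knot indices.
#' @export
#' @examples
#' sim <- sim_time_volume_curve(cycle_sim_config(noise_sd = 0))
#' fit <- fit_plr(sim$tvc)
#' fit$breakpoints
fit_plr <- function(tvc, rr = attr(tvc, "rr"), candidates = NULL, min_seg = 2,
                    isovolumetric = c("flat", "free"), max_isovol_ratio = 0.1,
                    refine = TRUE) {
  isovolumetric <- match.arg(isovolumetric)
  if (is.null(rr)) abort("supply `rr` (ms) or use a time_volume_curve().")
  t <- tvc$time_ms
  v <- tvc$volume_ul
  n <- length(t)
  if (n < 16) abort("need at least 16 samples.")
  amp <- max(v) - min(v)
  if (amp <= .Machine$double.eps * max(v)) {
    abort("degenerate curve: volume amplitude is zero.", class = "cardioage_degenerate")
  }
  if (is.null(candidates)) candidates <- seq_len(n - 2)
  candidates <- sort(unique(as.integer(candidates)))
  if (any(candidates < 1 | candidates > n - 2)) {
    abort("`candidates` must be interior 0-based sample indices.")
  }
  res <- if (isovolumetric == "flat") {
    plr_search_flat_cpp(t, v, candidates, as.integer(min_seg))
  } else {
    plr_search_cpp(t, v, candidates, as.integer(min_seg), max_isovol_ratio)
  }
  if (!res$feasible) {
    abort("no knot triple satisfies the cardiac slope-sign constraints.",
          class = "cardioage_plr_infeasible")
  }
  k <- res$knots + 1L # to 1-based
  beta <- res$beta
  knot_t <- t[k]
  sse <- max(res$sse, 0)
  if (refine) {
    pol <- polish_knots(t, v, knot_t, sse, beta, isovolumetric, max_isovol_ratio)
    knot_t <- pol$knot_t
    beta <- pol$beta
    sse <- pol$sse
    k <- vapply(knot_t, function(kt) which.min(abs(t - kt)), integer(1))
  }
  slopes <- plr_slopes(beta, knot_t, isovolumetric)
  fitted <- plr_eval(t, beta, knot_t, isovolumetric)
  resid_sd <- sqrt(sse / max(n - 5, 1))
  if (max(fitted) - min(fitted) < 3 * resid_sd) {
    abort("degenerate curve: fitted amplitude below the noise floor (amplitude < 3 residual SD).",
          class = "cardioage_degenerate")
  }
  structure(list(breakpoints = c(knot_t / rr, 1),
                 knot_idx = k, knot_times = knot_t,
                 slopes = slopes, coef = beta, model = isovolumetric,
                 sse = sse, resid_sd = resid_sd,
                 fitted = fitted, times = t, volumes = v, rr = rr,
                 n_segments = 4L),
            class = "plr_fit")
}

# evaluate the fitted piecewise-linear model at arbitrary times
plr_eval <- function(t, beta, knot_t, model) {
  if (model == "flat") {
    u <- pmin(pmax((t - knot_t[1]) / (knot_t[2] - knot_t[1]), 0), 1)
    beta[1] + beta[2] * u + beta[3] * pmax(t - knot_t[3], 0)
  } else {
    beta[1] + beta[2] * t + beta[3] * pmax(t - knot_t[1], 0) +
      beta[4] * pmax(t - knot_t[2], 0) + beta[5] * pmax(t - knot_t[3], 0)
  }
}

plr_slopes <- function(beta, knot_t, model) {
  s <- if (model == "flat") {
    c(0, beta[2] / (knot_t[2] - knot_t[1]), 0, beta[3])
  } else {
    cumsum(beta[2:5])
  }
  names(s) <- c("ivc", "ejection", "ivr", "filling")
  s
}

# Continuous polish of the three knot times around the grid optimum.
# Infeasible proposals (order violations, slope-sign or flatness violations)
# score +Inf, so the polish can only improve on the feasible grid solution.
polish_knots <- function(t, v, knot_t, sse0, beta0, model, isovol_ratio) {
  n <- length(t)
  lo <- t[2]; hi <- t[n - 1]
  eval_knots <- function(kt) {
    if (any(diff(kt) <= 0) || kt[1] <= lo || kt[3] >= hi) return(NULL)
    X <- if (model == "flat") {
      cbind(1, pmin(pmax((t - kt[1]) / (kt[2] - kt[1]), 0), 1), pmax(t - kt[3], 0))
    } else {
      cbind(1, t, pmax(t - kt[1], 0), pmax(t - kt[2], 0), pmax(t - kt[3], 0))
    }
    f <- tryCatch(.lm.fit(X, v), error = function(e) NULL)
    if (is.null(f)) return(NULL)
    beta <- f$coefficients
    if (model == "flat") {
      if (!(beta[2] < 0 && beta[3] > 0)) return(NULL)
    } else {
      s <- cumsum(beta[2:5])
      if (!(s[2] < 0 && s[4] > 0)) return(NULL)
      cap <- isovol_ratio * min(-s[2], s[4])
      if (abs(s[1]) >= cap || abs(s[3]) >= cap) return(NULL)
    }
    list(sse = sum(f$residuals^2), beta = beta)
  }
  obj <- function(kt) {
    r <- eval_knots(kt)
    if (is.null(r)) Inf else r$sse
  }
  opt <- stats::optim(knot_t, obj, method = "Nelder-Mead",
                      control = list(maxit = 300, reltol = 1e-10))
  r <- eval_knots(opt$par)
  if (!is.null(r) && r$sse <= sse0 + 1e-12) {
    list(knot_t = opt$par, beta = r$beta, sse = r$sse)
  } else {
    list(knot_t = knot_t, beta = beta0, sse = sse0)
  }
}

#' @export
print.plr_fit <- function(x, ...) {
  cat("Piecewise-linear cardiac-cycle fit (4 segments)\n")
  cat(sprintf("  breakpoints (fraction of R-R): %s\n",
              paste(sprintf("%.4f", x$breakpoints), collapse = ", ")))
  cat(sprintf("  slopes (ul/ms): %s\n",
              paste(sprintf("%s=%.4f", names(x$slopes), x$slopes), collapse = ", ")))
  cat(sprintf("  SSE: %.4g ul^2\n", x$sse))
  invisible(x)
}

#' @export
tidy.plr_fit <- function(x, ...) {
  starts <- c(0, x$breakpoints[1:3])
  tibble(segment = names(x$slopes),
         start_frac = starts, end_frac = x$breakpoints,
         duration_pct_rr = 100 * (x$breakpoints - starts),
         slope_ul_ms = unname(x$slopes))
}

#' @export
glance.plr_fit <- function(x, ...) {
  tibble(sse = x$sse, resid_sd = x$resid_sd, n = length(x$times),
         n_segments = x$n_segments, rr = x$rr)
}

#' Subject metadata for index normalisation
#'
#' Body-surface area for the cardiac index uses the Meeh allometry
#' `BSA = k * mass^(2/3)` with `k = 9.8` cm^2/g^(2/3) by default, overridable
#' either through `meeh_k` or by supplying `bsa_override` directly.
#'
#' @param body_mass Body mass (g).
#' @param meeh_k Meeh constant (cm^2/g^(2/3)).
#' @param bsa_override Body-surface area (cm^2), bypassing the allometry.
#' @return A list of class `subject_meta`.
#' @export
subject_meta <- function(body_mass = NULL, meeh_k = 9.8, bsa_override = NULL) {
  if (!is.null(body_mass)) check_number(body_mass, "body_mass", 0, strict = TRUE)
  check_number(meeh_k, "meeh_k", 0, strict = TRUE)
  if (!is.null(bsa_override)) check_number(bsa_override, "bsa_override", 0, strict = TRUE)
  structure(list(body_mass = body_mass, meeh_k = meeh_k,
                 bsa_override = bsa_override), class = "subject_meta")
}

# Refit the filling samples with up to two extra knots (E wave / diastasis /
# A wave). A deeper model is accepted only when it cuts the SSE to below
# `improve` times the shallower one and keeps a positive net filling slope at
# both ends. Returns NULL when the single ramp stands.
split_filling <- function(t, v, min_pts = 7, improve = 0.5) {
  n <- length(t)
  if (n < min_pts) return(NULL)
  fit_knots <- function(ks) {
    X <- cbind(1, t)
    for (k in ks) X <- cbind(X, pmax(t - t[k], 0))
    f <- .lm.fit(X, v)
    list(sse = sum(f$residuals^2), slopes = cumsum(f$coefficients[-1]), ks = ks)
  }
  base <- fit_knots(integer())
  best1 <- NULL
  for (k in 2:(n - 2)) {
    f <- fit_knots(k)
    if (is.null(best1) || f$sse < best1$sse - 1e-12) best1 <- f
  }
  best2 <- NULL
  if (n >= min_pts + 2) {
    for (k1 in 2:(n - 4)) for (k2 in (k1 + 2):(n - 2)) {
      f <- fit_knots(c(k1, k2))
      if (is.null(best2) || f$sse < best2$sse - 1e-12) best2 <- f
    }
  }
  pick <- NULL
  if (!is.null(best1) && best1$sse < improve * base$sse &&
      best1$slopes[1] > 0 && best1$slopes[2] > 0) {
    pick <- best1
    if (!is.null(best2) && best2$sse < improve * best1$sse &&
        best2$slopes[1] > 0 && best2$slopes[3] > 0 && all(best2$slopes > -1e-9)) {
      pick <- best2
    }
  }
  if (is.null(pick)) return(NULL)
  list(slopes = unname(pick$slopes), knot_times = t[pick$ks], sse = pick$sse)
}

#' Derive hemodynamic indices from a fitted cycle
#'
#' Volumes come from the fitted piecewise-linear model (EDV = maximum,
#' ESV = minimum fitted volume); `SV = EDV - ESV`, `EF = 100 SV/EDV`,
#' `CO = SV x HR` (ml/min), `CI = CO / BSA` (ul/min/cm^2) with BSA from the
#' Meeh allometry; ejection and filling rates are the PLR segment slopes
#' normalised to SV and R-R (`ER = |ejection slope| RR / SV`, analogously FR);
#' the four phase durations are the breakpoint gaps as % of R-R and always
#' sum to exactly 100. For visibly biphasic filling (`filling = "auto"`), FR
#' uses the steepest filling sub-slope from a one-knot refit of the filling
#' samples.
#'
#' @param tvc The [time_volume_curve()] that was fitted.
#' @param fit The [fit_plr()] result.
#' @param meta A [subject_meta()]; needed for CI (otherwise CI is `NA`).
#' @param filling `"auto"` (split the filling segment when a two-ramp refit
#'   at least halves its SSE), `"single"`, or `"biphasic"` (force the split).
#' @return A one-row tibble: `edv`, `esv`, `sv` (ul), `ef` (%), `co`
#'   (ml/min), `bsa` (cm^2), `ci` (ul/min/cm^2), `er`, `fr` (LV/R-R),
#'   `ivct`, `et`, `ivrt`, `ft` (% of R-R).
#' @export
derive_indices <- function(tvc, fit, meta = subject_meta(),
                           filling = c("auto", "single", "biphasic")) {
  filling <- match.arg(filling)
  stopifnot(inherits(fit, "plr_fit"))
  rr <- fit$rr
  hr <- attr(tvc, "hr") %||% (60000 / rr)
  ends_t <- c(0, fit$knot_times, fit$times[length(fit$times)])
  ends_v <- plr_eval(ends_t, fit$coef, fit$knot_times, fit$model)
  edv <- max(ends_v)
  esv <- min(ends_v)
  sv <- edv - esv
  if (sv <= 0) abort("stroke volume is non-positive.")
  ef <- 100 * sv / edv
  co_ul_min <- sv * hr
  co <- co_ul_min / 1000
  bsa <- if (!is.null(meta$bsa_override)) {
    meta$bsa_override
  } else if (!is.null(meta$body_mass)) {
    meta$meeh_k * meta$body_mass^(2 / 3)
  } else NA_real_
  ci <- co_ul_min / bsa

  fr_slope <- fit$slopes[["filling"]]
  if (filling != "single") {
    fill_idx <- fit$times >= fit$knot_times[3]
    sp <- split_filling(fit$times[fill_idx], tvc$volume_ul[fill_idx],
                        improve = if (filling == "biphasic") 1 + 1e-9 else 0.5)
    if (!is.null(sp)) {
      fr_slope <- max(sp$slopes)
    } else if (filling == "biphasic") {
      warn("biphasic filling requested but no valid split found; using the single slope.")
    }
  }

  bp <- fit$breakpoints
  durs <- 100 * diff(c(0, bp))
  tibble(edv = edv, esv = esv, sv = sv, ef = ef, co = co, bsa = bsa, ci = ci,
         er = abs(fit$slopes[["ejection"]]) * rr / sv,
         fr = fr_slope * rr / sv,
         ivct = durs[1], et = durs[2], ivrt = durs[3], ft = durs[4])
}

#' Filling-phase dV/dt series
#'
#' Differentiates the raw volume trace over the filling phase (samples at or
#' after the third breakpoint), using wrap-free centered differences with
#' one-sided ends. Units: ul/ms.
#'
#' @param tvc A [time_volume_curve()].
#' @param fit The corresponding [fit_plr()].
#' @return A tibble with `time_ms` and `dvdt`.
#' @export
filling_rate_curve <- function(tvc, fit) {
  idx <- which(tvc$time_ms >= fit$knot_times[3])
  t <- tvc$time_ms[idx]
  v <- tvc$volume_ul[idx]
  n <- length(t)
  if (n < 3) abort("too few filling-phase samples.")
  d <- numeric(n)
  d[1] <- (v[2] - v[1]) / (t[2] - t[1])
  d[n] <- (v[n] - v[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    d[i] <- (v[i + 1] - v[i - 1]) / (t[i + 1] - t[i - 1])
  }
  tibble(time_ms = t, dvdt = d)
}

# plateau-aware local maxima with topographic prominence
find_rate_peaks <- function(v) {
  n <- length(v)
  is_cand <- vapply(seq_len(n), function(i) {
    left_ok <- i == 1 || v[i] >= v[i - 1]
    right_ok <- i == n || v[i] >= v[i + 1]
    left_ok && right_ok
  }, logical(1))
  idx <- which(is_cand)
  if (length(idx) == 0) return(tibble(index = integer(), value = numeric(), prominence = numeric()))
  grp <- cumsum(c(1, diff(idx) > 1))
  peaks <- vapply(split(idx, grp), function(g) g[ceiling(length(g) / 2)], integer(1))
  # prominence with edge dominance: a side whose walk reaches the signal end
  # without meeting a strictly higher value does not constrain the peak
  prom <- vapply(peaks, function(p) {
    pv <- v[p]
    lmin <- pv
    i <- p
    while (i > 1 && v[i - 1] <= pv) { i <- i - 1; lmin <- min(lmin, v[i]) }
    lbase <- if (i == 1) -Inf else lmin
    rmin <- pv
    i <- p
    while (i < n && v[i + 1] <= pv) { i <- i + 1; rmin <- min(rmin, v[i]) }
    rbase <- if (i == n) -Inf else rmin
    base <- max(lbase, rbase)
    if (!is.finite(base)) base <- min(v)
    pv - base
  }, numeric(1))
  tibble(index = unname(peaks), value = v[peaks], prominence = unname(prom))
}

#' Early-to-atrial filling ratio (E/A)
#'
#' Finds the two most prominent local maxima of the filling-rate series in
#' temporal order — the early (E) and atrial (A) filling-rate peaks — and
#' returns their ratio. When only one peak exceeds the prominence threshold
#' the E and A waves are considered fused and the ratio is reported missing,
#' matching the convention of reporting "/" for fused filling.
#'
#' @param rate A data frame with columns `time_ms` and `dvdt` (e.g. from
#'   [filling_rate_curve()]), covering the filling phase with at least 8
#'   samples.
#' @param prominence_frac Minimum peak prominence as a fraction of the dV/dt
#'   range (default 0.05).
#' @return A one-row tibble: `e_peak`, `a_peak` (ul/ms), `ratio`, `fused`.
#' @export
ea_ratio <- function(rate, prominence_frac = 0.05) {
  stopifnot(all(c("time_ms", "dvdt") %in% names(rate)))
  if (nrow(rate) < 8) abort("need at least 8 filling-phase samples.")
  v <- rate$dvdt
  pk <- find_rate_peaks(v)
  thr <- prominence_frac * (max(v) - min(v))
  pk <- pk[pk$prominence > thr, , drop = FALSE]
  if (nrow(pk) < 2) {
    return(tibble(e_peak = if (nrow(pk)) pk$value[1] else NA_real_,
                  a_peak = NA_real_, ratio = NA_real_, fused = TRUE))
  }
  top2 <- pk[order(-pk$prominence)[1:2], ]
  top2 <- top2[order(top2$index), ]
  tibble(e_peak = top2$value[1], a_peak = top2$value[2],
         ratio = top2$value[1] / top2$value[2], fused = FALSE)
}
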