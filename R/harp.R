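# Harmonic-phase (HARP) strain analysis of SPAMM-tagged image stacks.
#
# Pipeline: isolate the first tag harmonic of each tag direction in Fourier
# space (raised-cosine annular band-pass), take the phase of the filtered
# complex image as a material marker, reconstruct the deformation gradient
# from wrap-aware phase gradients, and express Lagrangian strain along the
# radial/circumferential directions as engineering strain. The
# peak-combination refinement averages the phase gradients obtained from the
# +k and -k harmonic peaks, which cancels band-pass asymmetry bias.

# toroidal FFT-bin coordinates (cycles per FOV), 0-based bins
fft_freqs <- function(m) {
  f <- 0:(m - 1)
  f[f > m / 2] <- f[f > m / 2] - m
  f
}

# locate the harmonic peak nearest `nominal` (cycles/FOV, length-2) within
# +/- tol_frac of its magnitude; returns NULL when absent
find_harmonic_peak <- function(Fmag, nominal, tol_frac = 0.2, min_ratio = 5) {
  m <- nrow(Fmag)
  fr <- fft_freqs(m)
  fx <- matrix(fr, m, m, byrow = TRUE) # x-frequency along columns
  fy <- matrix(fr, m, m)
  d2 <- (fx - nominal[1])^2 + (fy - nominal[2])^2
  tol <- tol_frac * sqrt(sum(nominal^2))
  cand <- which(d2 <= tol^2)
  if (length(cand) == 0) return(NULL)
  peak <- cand[which.max(Fmag[cand])]
  # background floor: median spectral magnitude, floored at a tiny fraction
  # of the strongest component so that tag-free images are always rejected
  bg <- max(median(Fmag), 1e-9 * max(Fmag))
  if (Fmag[peak] < min_ratio * bg) return(NULL)
  ij <- arrayInd(peak, dim(Fmag))
  list(index = ij, freq = c(fx[peak], fy[peak]), magnitude = Fmag[peak],
       background = bg)
}

# raised-cosine window of (bin) radius r centred on `freq`, on the torus
bandpass_window <- function(m, freq, radius) {
  fr <- fft_freqs(m)
  fx <- matrix(fr, m, m, byrow = TRUE)
  fy <- matrix(fr, m, m)
  # toroidal distance in bins
  dx <- (fx - freq[1] + m / 2) %% m - m / 2
  dy <- (fy - freq[2] + m / 2) %% m - m / 2
  rho <- sqrt(dx^2 + dy^2)
  w <- 0.5 * (1 + cos(pi * pmin(rho / radius, 1)))
  w[rho >= radius] <- 0
  w
}

#' Extract harmonic-phase maps from a tagged stack
#'
#' For each tag direction: 2-D FFT of each frame, selection of the first
#' harmonic peak nearest the nominal tag wavevector (within 20%), an
#' isotropic raised-cosine band-pass of radius half the DC-to-peak distance,
#' inverse FFT, and the argument of the complex result as the wrapped
#' harmonic phase. Both the +k and the conjugate -k peaks are filtered so
#' that downstream strain can combine their phase gradients.
#'
#' @param stack A `tagged_stack` (see [sim_tagged_stack()]) or compatible
#'   list with `frames`, `pixel_spacing`, `frame_times`, `tag_wavevectors`,
#'   `fov_mm`.
#' @param peak_min_ratio Detection floor: the harmonic peak magnitude must be
#'   at least this multiple of the median spectral magnitude (default 5).
#' @return An object of class `harp_phase_maps`: per direction, arrays of
#'   wrapped phases for the +k and -k peaks (`H x W x n_frames`), the filter
#'   descriptor (centre in cycles/FOV, radius in bins) and the detected peak.
#' @export
harp_phase_maps <- function(stack, peak_min_ratio = 5) {
  frames <- stack$frames
  m <- dim(frames)[1]
  if (dim(frames)[2] != m) abort("frames must be square.")
  n <- dim(frames)[3]
  fov <- stack$fov_mm %||% (m * stack$pixel_spacing)
  dirs <- vector("list", 2)
  for (d in 1:2) {
    nominal <- stack$tag_wavevectors[d, ] * fov # cycles/FOV
    F0 <- fft(frames[, , 1])
    pk <- find_harmonic_peak(Mod(F0), nominal, min_ratio = peak_min_ratio)
    if (is.null(pk)) {
      abort(sprintf(
        "tag harmonic not detected near (%.1f, %.1f) cycles/FOV (direction %d).",
        nominal[1], nominal[2], d), class = "cardioage_tag_detection")
    }
    radius <- 0.5 * sqrt(sum(pk$freq^2))
    phi_p <- array(0, dim = c(m, m, n))
    phi_m <- array(0, dim = c(m, m, n))
    for (f in seq_len(n)) {
      Ff <- fft(frames[, , f])
      pkf <- find_harmonic_peak(Mod(Ff), nominal, min_ratio = peak_min_ratio)
      freq <- if (is.null(pkf)) pk$freq else pkf$freq
      wp <- bandpass_window(m, freq, radius)
      wm <- bandpass_window(m, -freq, radius)
      cp <- fft(Ff * wp, inverse = TRUE) / (m * m)
      cm <- fft(Ff * wm, inverse = TRUE) / (m * m)
      phi_p[, , f] <- Arg(cp)
      phi_m[, , f] <- Arg(cm)
    }
    dirs[[d]] <- list(phi_plus = phi_p, phi_minus = phi_m,
                      peak_cycles_fov = pk$freq, filter_radius = radius,
                      nominal_cycles_fov = nominal)
  }
  structure(list(directions = dirs, pixel_spacing = stack$pixel_spacing,
                 fov_mm = fov, frame_times = stack$frame_times,
                 tag_wavevectors = stack$tag_wavevectors, n_frames = n,
                 matrix = m),
            class = "harp_phase_maps")
}

# wrap-aware phase gradient: average of the two one-pixel wrapped forward /
# backward differences (each must stay below pi), divided by the spacing.
phase_gradient <- function(phi, delta) {
  m <- nrow(phi)
  shift_col <- function(a, by) {
    if (by == 1) cbind(a[, 2:ncol(a)], a[, ncol(a)]) else cbind(a[, 1], a[, 1:(ncol(a) - 1)])
  }
  shift_row <- function(a, by) {
    if (by == 1) rbind(a[2:nrow(a), ], a[nrow(a), ]) else rbind(a[1, ], a[1:(nrow(a) - 1), ])
  }
  fwd_x <- wrap_pi(shift_col(phi, 1) - phi)
  bwd_x <- wrap_pi(phi - shift_col(phi, -1))
  fwd_y <- wrap_pi(shift_row(phi, 1) - phi)
  bwd_y <- wrap_pi(phi - shift_row(phi, -1))
  # replicate interior difference at the borders (one-sided)
  fwd_x[, ncol(phi)] <- bwd_x[, ncol(phi)]
  bwd_x[, 1] <- fwd_x[, 1]
  fwd_y[nrow(phi), ] <- bwd_y[nrow(phi), ]
  bwd_y[1, ] <- fwd_y[1, ]
  list(gx = (fwd_x + bwd_x) / 2 / delta, gy = (fwd_y + bwd_y) / 2 / delta)
}

#' Annular region-of-interest mask
#'
#' @param m Matrix size (pixels).
#' @param center Centre in pixels `(row, col)`; default image centre.
#' @param r_inner,r_outer Annulus radii in pixels.
#' @return A logical `m x m` matrix.
#' @export
annulus_mask <- function(m, center = c((m + 1) / 2, (m + 1) / 2),
                         r_inner = 0.15 * m, r_outer = 0.40 * m) {
  rows <- matrix(seq_len(m), m, m)
  cols <- matrix(seq_len(m), m, m, byrow = TRUE)
  r <- sqrt((rows - center[1])^2 + (cols - center[2])^2)
  r >= r_inner & r <= r_outer
}

#' Radial/circumferential strain maps from harmonic phases
#'
#' Phase gradients from the +k and -k harmonic peaks are averaged (the
#' peak-combination step); stacking the two tag directions gives the phase
#' Jacobian `G` with `G = 2 pi K Finv` (rows of `K` are the material tag
#' wavevectors), from which the deformation gradient `F` follows per pixel.
#' The effective `K` is calibrated on frame 0 (mask-mean gradients), which
#' forces zero strain on the reference frame. Engineering strains along the
#' radial and circumferential unit vectors about `center` are
#' `sqrt(e' (F'F) e) - 1`, in percent.
#'
#' @param phases A [harp_phase_maps()] result.
#' @param center LV centre in pixels `(row, col)`; default image centre.
#' @param mask Logical myocardial mask; default a centred annulus between
#'   15% and 40% of the matrix size.
#' @return An object of class `strain_field`: `err`, `ecc` arrays
#'   (`H x W x n`, percent), `det_f`, `center`, `mask`, `frame_times`.
#'   A warning is raised when `|det F|` leaves `[0.2, 5]` on more than 10%
#'   of mask pixels in any frame.
#' @export
strain_field <- function(phases, center = NULL, mask = NULL) {
  stopifnot(inherits(phases, "harp_phase_maps"))
  m <- phases$matrix
  n <- phases$n_frames
  delta <- phases$pixel_spacing
  if (is.null(center)) center <- c((m + 1) / 2, (m + 1) / 2)
  if (is.null(mask)) mask <- annulus_mask(m, center)
  k1 <- phases$tag_wavevectors[1, ]
  k2 <- phases$tag_wavevectors[2, ]
  if (abs(k1[1] * k2[2] - k1[2] * k2[1]) < 1e-12) {
    abort("tag wavevectors are collinear.")
  }

  grad_dir <- function(d, f) {
    gp <- phase_gradient(phases$directions[[d]]$phi_plus[, , f], delta)
    gm <- phase_gradient(phases$directions[[d]]$phi_minus[, , f], delta)
    list(gx = (gp$gx - gm$gx) / 2, gy = (gp$gy - gm$gy) / 2)
  }

  # calibrate K on the reference frame: rows are mask-mean gradients / 2pi
  g1_0 <- grad_dir(1, 1)
  g2_0 <- grad_dir(2, 1)
  K <- rbind(c(mean(g1_0$gx[mask]), mean(g1_0$gy[mask])),
             c(mean(g2_0$gx[mask]), mean(g2_0$gy[mask]))) / (2 * pi)
  B <- solve(2 * pi * K)

  rows <- matrix(seq_len(m), m, m)
  cols <- matrix(seq_len(m), m, m, byrow = TRUE)
  theta <- atan2(rows - center[1], cols - center[2])
  ct <- cos(theta); st <- sin(theta)

  err <- array(NA_real_, dim = c(m, m, n))
  ecc <- array(NA_real_, dim = c(m, m, n))
  detf <- array(NA_real_, dim = c(m, m, n))
  for (f in seq_len(n)) {
    g1 <- grad_dir(1, f)
    g2 <- grad_dir(2, f)
    # Finv = B %*% G with G rows (g_i_x, g_i_y)
    i11 <- B[1, 1] * g1$gx + B[1, 2] * g2$gx
    i12 <- B[1, 1] * g1$gy + B[1, 2] * g2$gy
    i21 <- B[2, 1] * g1$gx + B[2, 2] * g2$gx
    i22 <- B[2, 1] * g1$gy + B[2, 2] * g2$gy
    di <- i11 * i22 - i12 * i21
    F11 <- i22 / di; F12 <- -i12 / di; F21 <- -i21 / di; F22 <- i11 / di
    detf[, , f] <- F11 * F22 - F12 * F21
    C11 <- F11^2 + F21^2
    C12 <- F11 * F12 + F21 * F22
    C22 <- F12^2 + F22^2
    lr2 <- C11 * ct^2 + 2 * C12 * ct * st + C22 * st^2
    lc2 <- C11 * st^2 - 2 * C12 * ct * st + C22 * ct^2
    err[, , f] <- (sqrt(pmax(lr2, 0)) - 1) * 100
    ecc[, , f] <- (sqrt(pmax(lc2, 0)) - 1) * 100
  }
  bad <- vapply(seq_len(n), function(f) {
    d <- abs(detf[, , f][mask])
    mean(d < 0.2 | d > 5, na.rm = TRUE)
  }, numeric(1))
  if (any(bad > 0.10)) {
    warn(sprintf("unreliable deformation: |det F| outside [0.2, 5] on up to %.0f%% of mask pixels.",
                 100 * max(bad)))
  }
  structure(list(err = err, ecc = ecc, det_f = detf, center = center,
                 mask = mask, frame_times = phases$frame_times,
                 pixel_spacing = delta),
            class = "strain_field")
}

#' Eight-segment strain curves
#'
#' Averages the strain maps over 45-degree angular sectors about the LV
#' centre, per frame. Sector 1 starts at the anterior reference angle
#' (default 90 degrees, measured counterclockwise from the +x axis) and
#' sectors proceed counterclockwise.
#'
#' @param field A [strain_field()] result.
#' @param n_segments Number of sectors (default 8).
#' @param reference_angle Start angle of sector 1 in degrees (default 90).
#' @return A tibble with columns `segment`, `frame`, `time`, `err`, `ecc`;
#'   sectors with no mask pixels yield `NA` rows and a warning. Attribute
#'   `"bounds"` holds the sector angular bounds (radians).
#' @export
segment_strain_curves <- function(field, n_segments = 8, reference_angle = 90) {
  stopifnot(inherits(field, "strain_field"))
  m <- dim(field$err)[1]
  n <- dim(field$err)[3]
  rows <- matrix(seq_len(m), m, m)
  cols <- matrix(seq_len(m), m, m, byrow = TRUE)
  theta <- atan2(rows - field$center[1], cols - field$center[2])
  rel <- (theta - reference_angle * pi / 180) %% (2 * pi)
  sector <- pmin(floor(rel / (2 * pi / n_segments)) + 1L, n_segments)
  sector[!field$mask] <- NA_integer_
  empty <- setdiff(seq_len(n_segments), unique(stats::na.omit(as.vector(sector))))
  if (length(empty)) {
    warn(sprintf("empty sector(s): %s — excluded from averages.",
                 paste(empty, collapse = ", ")))
  }
  out <- tidyr::expand_grid(segment = seq_len(n_segments), frame = seq_len(n) - 1L)
  sec_mean <- function(a, s, f) {
    idx <- which(sector == s)
    if (length(idx) == 0) return(NA_real_)
    mean(a[, , f][idx])
  }
  out$time <- field$frame_times[out$frame + 1L]
  out$err <- purrr::map2_dbl(out$segment, out$frame, ~ sec_mean(field$err, .x, .y + 1L))
  out$ecc <- purrr::map2_dbl(out$segment, out$frame, ~ sec_mean(field$ecc, .x, .y + 1L))
  bounds <- reference_angle * pi / 180 + (0:n_segments) * 2 * pi / n_segments
  structure(out, bounds = bounds, class = c("segment_strain_curves", class(out)))
}

#' Global (mask-mean) strain curves
#'
#' @param field A [strain_field()] result.
#' @return A tibble with `frame`, `time`, `err`, `ecc` (mask means).
#' @export
global_strain_curves <- function(field) {
  n <- dim(field$err)[3]
  tibble(frame = seq_len(n) - 1L, time = field$frame_times,
         err = vapply(seq_len(n), function(f) mean(field$err[, , f][field$mask]), numeric(1)),
         ecc = vapply(seq_len(n), function(f) mean(field$ecc[, , f][field$mask]), numeric(1)))
}
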