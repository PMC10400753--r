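# Synthetic SPAMM-tagged image stacks with analytically known deformation.

#' Deformation models for the tagged phantom
#'
#' Deformations are specified by the spatial-to-material map `X(x)` about the
#' image centre, which is what both image advection (the intensity at spatial
#' position x is the reference pattern evaluated at `X(x)`) and ground-truth
#' strain need. The deformation ramps linearly over the frames: frame `f` of
#' `n` applies amplitude `f / (n - 1)` of the configured deformation, so
#' frame 0 is always the undeformed tag grid.
#'
#' * `deform_identity()` — no motion.
#' * `deform_translation(tx, ty)` — rigid translation by (`tx`, `ty`) mm.
#' * `deform_stretch(lambda_x, lambda_y)` — uniform Cartesian stretch about
#'   the centre; `lambda_x = lambda_y = lambda` is an isotropic stretch with
#'   engineering strain `lambda - 1` everywhere.
#' * `deform_radial(rho_m, lambda_r, lambda_c)` — analytic radial profile:
#'   `rho_m(r, amp)` maps spatial radius (mm) to material radius at ramp
#'   amplitude `amp`; `lambda_r(r, amp)` and `lambda_c(r, amp)` give the true
#'   radial/circumferential stretch for scoring.
#'
#' @param tx,ty Translation components (mm).
#' @param lambda_x,lambda_y Stretch factors (> 0).
#' @param rho_m,lambda_r,lambda_c Functions of (spatial radius mm, amplitude).
#' @return A list of class `tag_deformation`.
#' @name tag_deformation
NULL

new_deformation <- function(type, material_map, params = list(), truth = list()) {
  structure(list(type = type, material_map = material_map, params = params,
                 truth = truth), class = "tag_deformation")
}

#' @rdname tag_deformation
#' @export
deform_identity <- function() {
  new_deformation("identity", function(x, y, amp) list(X = x, Y = y))
}

#' @rdname tag_deformation
#' @export
deform_translation <- function(tx, ty) {
  new_deformation("translation",
                  function(x, y, amp) list(X = x - amp * tx, Y = y - amp * ty),
                  params = list(tx = tx, ty = ty))
}

#' @rdname tag_deformation
#' @export
deform_stretch <- function(lambda_x, lambda_y = lambda_x) {
  if (lambda_x <= 0 || lambda_y <= 0) abort("stretch factors must be positive (folding).")
  new_deformation("stretch",
                  function(x, y, amp) {
                    lx <- 1 + amp * (lambda_x - 1)
                    ly <- 1 + amp * (lambda_y - 1)
                    list(X = x / lx, Y = y / ly)
                  },
                  params = list(lambda_x = lambda_x, lambda_y = lambda_y))
}

#' @rdname tag_deformation
#' @export
deform_radial <- function(rho_m, lambda_r = NULL, lambda_c = NULL) {
  stopifnot(is.function(rho_m))
  new_deformation("radial",
                  function(x, y, amp) {
                    r <- sqrt(x^2 + y^2)
                    R <- rho_m(r, amp)
                    scl <- ifelse(r > 0, R / r, 1)
                    list(X = x * scl, Y = y * scl)
                  },
                  params = list(rho_m = rho_m),
                  truth = list(lambda_r = lambda_r, lambda_c = lambda_c))
}

#' Configuration for the tagged-image generator
#'
#' Defaults follow a murine tagging protocol: 30 x 30 mm field of view on a
#' 192 x 192 matrix, square tags of 0.6 mm span and 0.2 mm line thickness
#' (50 tag periods across the FOV).
#'
#' @param fov_mm Field of view (mm).
#' @param matrix Image matrix size (even).
#' @param tag_span_mm Tag period (mm); `fov_mm / tag_span_mm` must be within
#'   0.01 of an integer so the pattern tiles the FOV.
#' @param tag_line_mm Tag line thickness (mm).
#' @param deformation A [tag_deformation] object.
#' @param n_frames Number of frames.
#' @param noise_sd Intensity noise SD (image baseline is 1).
#' @param tag_depth Tag modulation depth in `[0, 1]`.
#' @param seed Integer seed.
#' @return A list of class `tag_sim_config`.
#' @export
tag_sim_config <- function(fov_mm = 30, matrix = 192, tag_span_mm = 0.6,
                           tag_line_mm = 0.2, deformation = deform_identity(),
                           n_frames = 5, noise_sd = 0, tag_depth = 0.7,
                           seed = 1) {
  check_number(fov_mm, "fov_mm", 0, strict = TRUE)
  if (matrix %% 2 != 0 || matrix < 16) abort("`matrix` must be even and >= 16.")
  check_number(tag_span_mm, "tag_span_mm", 0, strict = TRUE)
  cyc <- fov_mm / tag_span_mm
  if (abs(cyc - round(cyc)) > 0.01) {
    abort("`fov_mm / tag_span_mm` must be an integer number of tag periods.")
  }
  if (tag_line_mm <= 0 || tag_line_mm >= tag_span_mm) {
    abort("`tag_line_mm` must lie in (0, tag_span_mm).")
  }
  stopifnot(inherits(deformation, "tag_deformation"))
  if (n_frames < 1) abort("`n_frames` must be at least 1.")
  check_number(noise_sd, "noise_sd", 0)
  structure(list(fov_mm = fov_mm, matrix = as.integer(matrix),
                 tag_span_mm = tag_span_mm, tag_line_mm = tag_line_mm,
                 deformation = deformation, n_frames = as.integer(n_frames),
                 noise_sd = noise_sd, tag_depth = tag_depth, seed = seed),
            class = "tag_sim_config")
}

# Band-limited tag line profile: the raised-cosine-squared pulse (width
# `line`, period `span`) truncated to its first `n_harmonics` Fourier terms.
# At the default geometry (~3.8 pixels per tag period) an MR acquisition
# resolves only the fundamental — higher pulse harmonics lie beyond the
# sampling band and, if evaluated analytically at pixel centres, would fold
# back into the first-harmonic band-pass and contaminate the phase. The
# default therefore keeps the fundamental only; raise `n_harmonics` for
# coarser tags.
tag_profile <- function(u, span, line, depth, n_harmonics = 1) {
  # Fourier coefficients of g(w) = cos^2(pi w / line) on |w| <= line/2
  nq <- 2048
  w <- (seq_len(nq) - 0.5) / nq * span - span / 2
  g <- ifelse(abs(w) <= line / 2, cos(pi * w / line)^2, 0)
  a0 <- mean(g)
  out <- a0
  for (k in seq_len(n_harmonics)) {
    ak <- 2 * mean(g * cos(2 * pi * k * w / span))
    out <- out + ak * cos(2 * pi * k * u / span)
  }
  1 - depth * out
}

#' Generate a SPAMM-tagged frame stack with ground truth
#'
#' Frame 0 is an undeformed square tag grid (the product of two orthogonal
#' periodic line profiles); later frames evaluate the same reference pattern
#' at the material coordinates of the ramped deformation (periodic
#' continuation at the edges is automatic because the pattern tiles the FOV).
#' Gaussian intensity noise is added last.
#'
#' @param config A [tag_sim_config()].
#' @return A list with `stack` (class `tagged_stack`: `frames` array
#'   `H x W x n`, `pixel_spacing` mm, `frame_times` in `[0, 1)`,
#'   `tag_wavevectors` rows in cycles/mm, `fov_mm`) and `truth` (a
#'   [truth_record()] with the deformation and per-frame ramp amplitudes).
#' @export
#' @examples
#' sim <- sim_tagged_stack(tag_sim_config(matrix = 64, tag_span_mm = 30 / 10,
#'                                        n_frames = 2))
#' dim(sim$stack$frames)
sim_tagged_stack <- function(config) {
  stopifnot(inherits(config, "tag_sim_config"))
  m <- config$matrix
  delta <- config$fov_mm / m
  coord <- (seq_len(m) - 0.5) * delta - config$fov_mm / 2
  xg <- matrix(coord, m, m, byrow = TRUE) # x along columns
  yg <- matrix(coord, m, m)               # y along rows
  amps <- if (config$n_frames == 1) 0 else
    (seq_len(config$n_frames) - 1) / (config$n_frames - 1)

  frames <- array(0, dim = c(m, m, config$n_frames))
  for (f in seq_len(config$n_frames)) {
    mc <- config$deformation$material_map(xg, yg, amps[f])
    if (f > 1 && config$deformation$type != "identity") {
      jac_ok <- check_jacobian(config$deformation, amps[f], config$fov_mm)
      if (!jac_ok) abort("deformation folds (non-positive Jacobian).")
    }
    frames[, , f] <-
      tag_profile(mc$X, config$tag_span_mm, config$tag_line_mm, config$tag_depth) *
      tag_profile(mc$Y, config$tag_span_mm, config$tag_line_mm, config$tag_depth)
  }
  if (config$noise_sd > 0) {
    frames <- withr::with_seed(substream_seed(config$seed, "tags"),
                               frames + rnorm(length(frames), 0, config$noise_sd))
  }
  k <- 1 / config$tag_span_mm
  stack <- structure(list(frames = frames, pixel_spacing = delta,
                          frame_times = (seq_len(config$n_frames) - 1) / config$n_frames,
                          tag_wavevectors = rbind(c(k, 0), c(0, k)),
                          fov_mm = config$fov_mm),
                     class = "tagged_stack")
  truth <- truth_record("tagged_stack",
                        deformation_type = config$deformation$type,
                        deformation_params = config$deformation$params[
                          !vapply(config$deformation$params, is.function, logical(1))],
                        amplitudes = amps, tag_cycles_per_fov = config$fov_mm / config$tag_span_mm,
                        config = list(fov_mm = config$fov_mm, matrix = m,
                                      tag_span_mm = config$tag_span_mm,
                                      tag_line_mm = config$tag_line_mm,
                                      n_frames = config$n_frames,
                                      noise_sd = config$noise_sd,
                                      seed = config$seed))
  list(stack = stack, truth = truth)
}

# numeric folding check on a coarse radius/coordinate grid
check_jacobian <- function(deformation, amp, fov) {
  if (deformation$type == "radial") {
    # a radial map folds when the material radius stops being a positive,
    # strictly increasing function of the spatial radius (det J alone misses
    # reflections, which have positive determinant in 2-D)
    r <- seq(fov / 200, fov / 2, length.out = 100)
    R <- deformation$params$rho_m(r, amp)
    if (any(R <= 0) || any(diff(R) <= 0)) return(FALSE)
  }
  g <- seq(-fov / 2 + fov / 50, fov / 2 - fov / 50, length.out = 25)
  h <- fov / 500
  xg <- matrix(g, 25, 25, byrow = TRUE)
  yg <- matrix(g, 25, 25)
  mm <- deformation$material_map
  px <- mm(xg + h, yg, amp); mx <- mm(xg - h, yg, amp)
  py <- mm(xg, yg + h, amp); my <- mm(xg, yg - h, amp)
  j11 <- (px$X - mx$X) / (2 * h); j12 <- (py$X - my$X) / (2 * h)
  j21 <- (px$Y - mx$Y) / (2 * h); j22 <- (py$Y - my$Y) / (2 * h)
  all(j11 * j22 - j12 * j21 > 0)
}
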