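# Synthetic histology masks: capillary wall annuli in three orientation
# classes, lumens, and a collagen field painted to an exact target fraction.

#' Configuration for the histology-mask generator
#'
#' Capillary cross-sections are ellipses whose aspect ratio encodes the
#' sectioning orientation: transverse cuts are near-circular, oblique cuts
#' moderately elongated, longitudinal cuts strongly elongated. A fraction of
#' capillaries has an open lumen (a concentric inner ellipse). Collagen is a
#' smooth random blob field thresholded — then pixel-flipped — to hit the
#' target collagen fraction of the tissue exactly.
#'
#' @param size Image side (pixels).
#' @param pixel_size Pixel size (micrometres).
#' @param n_capillaries Number of capillaries to place without overlap.
#' @param orientation_mix Fractions (longitudinal, oblique, transverse)
#'   summing to 1.
#' @param radius_range Minor semi-axis range (pixels).
#' @param aspect_ranges Named list of aspect-ratio ranges per class; defaults
#'   transverse `[1, 1.4]`, oblique `[1.7, 2.8]`, longitudinal `[3.2, 5]`.
#' @param lumen_fraction Fraction of capillaries with a visible lumen.
#' @param lumen_scale Lumen semi-axes as a fraction of the outer ones.
#' @param collagen_fraction Target collagen share of tissue (0-1).
#' @param min_gap Minimum edge gap between placed capillaries (pixels).
#' @param max_tries Placement retries per capillary before failing.
#' @param seed Integer seed.
#' @return A list of class `mask_sim_config`.
#' @export
mask_sim_config <- function(size = 360, pixel_size = 0.5, n_capillaries = 25,
                            orientation_mix = c(longitudinal = 0.2,
                                                oblique = 0.35,
                                                transverse = 0.45),
                            radius_range = c(4, 7),
                            aspect_ranges = list(transverse = c(1, 1.4),
                                                 oblique = c(1.7, 2.8),
                                                 longitudinal = c(3.2, 5)),
                            lumen_fraction = 0.6, lumen_scale = 0.55,
                            collagen_fraction = 0.196, min_gap = 4,
                            max_tries = 300, seed = 1) {
  if (length(orientation_mix) != 3 || any(orientation_mix < 0) ||
      abs(sum(orientation_mix) - 1) > 1e-9) {
    abort("`orientation_mix` must be 3 non-negative fractions summing to 1.")
  }
  check_number(collagen_fraction, "collagen_fraction", 0, 1)
  check_number(lumen_fraction, "lumen_fraction", 0, 1)
  check_number(pixel_size, "pixel_size", 0, strict = TRUE)
  structure(list(size = as.integer(size), pixel_size = pixel_size,
                 n_capillaries = as.integer(n_capillaries),
                 orientation_mix = orientation_mix,
                 radius_range = radius_range, aspect_ranges = aspect_ranges,
                 lumen_fraction = lumen_fraction, lumen_scale = lumen_scale,
                 collagen_fraction = collagen_fraction, min_gap = min_gap,
                 max_tries = as.integer(max_tries), seed = seed),
            class = "mask_sim_config")
}

# pixel set of a rotated ellipse (centre cx,cy; semi-axes a >= b; angle rad)
ellipse_pixels <- function(size, cx, cy, a, b, angle) {
  r0 <- max(1, floor(cy - a)); r1 <- min(size, ceiling(cy + a))
  c0 <- max(1, floor(cx - a)); c1 <- min(size, ceiling(cx + a))
  rows <- r0:r1; cols <- c0:c1
  rg <- matrix(rows, length(rows), length(cols))
  cg <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  dx <- cg - cx; dy <- rg - cy
  u <- dx * cos(angle) + dy * sin(angle)
  v <- -dx * sin(angle) + dy * cos(angle)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  cbind(row = rg[inside], col = cg[inside])
}

# smooth value-noise field: coarse Gaussian grid, bilinear upsample
value_noise <- function(size, cell = 24) {
  ng <- ceiling(size / cell) + 2
  g <- matrix(rnorm(ng * ng), ng, ng)
  pos <- (seq_len(size) - 0.5) / cell + 1
  i0 <- pmin(floor(pos), ng - 1)
  fr <- pos - i0
  # separable bilinear interpolation
  a <- g[i0, i0] * ((1 - fr) %o% (1 - fr)) + g[i0 + 1, i0] * (fr %o% (1 - fr)) +
    g[i0, i0 + 1] * ((1 - fr) %o% fr) + g[i0 + 1, i0 + 1] * (fr %o% fr)
  a
}

#' Generate labelled histology masks with ground truth
#'
#' Places non-overlapping elliptical capillary walls (with optional lumens)
#' by rejection sampling, then paints a collagen mask over the remaining
#' tissue to the exact target fraction (threshold on a smooth noise field,
#' final pixel flips).
#'
#' @param config A [mask_sim_config()].
#' @return A list with `capillary` (integer label matrix, 0 = background),
#'   `lumen` (logical matrix), `collagen` and `myocardium` (disjoint logical
#'   matrices covering all non-capillary tissue) and `truth` (a
#'   [truth_record()] with the component table — id, class, centre, semi-axes,
#'   angle, wall/lumen pixel areas — the painted collagen fraction and the
#'   nearest edge-to-edge distance table for oblique/transverse components).
#' @export
sim_histology_masks <- function(config) {
  stopifnot(inherits(config, "mask_sim_config"))
  withr::with_seed(substream_seed(config$seed, "histology"), {
    size <- config$size
    classes <- sample(names(config$orientation_mix), config$n_capillaries,
                      replace = TRUE, prob = config$orientation_mix)
    placed <- list()
    cap <- matrix(0L, size, size)
    lum <- matrix(FALSE, size, size)
    margin <- max(config$radius_range) * max(unlist(config$aspect_ranges)) + 2
    if (2 * margin >= size) {
      abort("image too small for the configured capillary sizes.")
    }
    for (i in seq_len(config$n_capillaries)) {
      cls <- classes[i]
      ok <- FALSE
      for (try in seq_len(config$max_tries)) {
        b <- runif(1, config$radius_range[1], config$radius_range[2])
        ar <- runif(1, config$aspect_ranges[[cls]][1], config$aspect_ranges[[cls]][2])
        a <- b * ar
        ang <- runif(1, 0, pi)
        cx <- runif(1, margin, size - margin)
        cy <- runif(1, margin, size - margin)
        # conservative overlap check on bounding circles
        clash <- any(vapply(placed, function(p) {
          sqrt((p$cx - cx)^2 + (p$cy - cy)^2) < p$a + a + config$min_gap
        }, logical(1)))
        if (!clash) { ok <- TRUE; break }
      }
      if (!ok) {
        abort(sprintf("could not place capillary %d without overlap after %d tries.",
                      i, config$max_tries))
      }
      px <- ellipse_pixels(size, cx, cy, a, b, ang)
      has_lumen <- runif(1) < config$lumen_fraction
      lpx <- NULL
      if (has_lumen) {
        lpx <- ellipse_pixels(size, cx, cy, a * config$lumen_scale,
                              b * config$lumen_scale, ang)
        lum[lpx] <- TRUE
      }
      wall <- px[!(paste(px[, 1], px[, 2]) %in%
                     if (is.null(lpx)) character() else paste(lpx[, 1], lpx[, 2])), ,
                 drop = FALSE]
      cap[wall] <- i
      placed[[i]] <- list(id = i, class = cls, cx = cx, cy = cy, a = a, b = b,
                          angle = ang, wall_px = nrow(wall),
                          lumen_px = if (is.null(lpx)) 0L else nrow(lpx),
                          lumen_present = has_lumen)
    }
    comp <- dplyr::bind_rows(lapply(placed, as_tibble))

    tissue <- cap == 0 & !lum
    n_tissue <- sum(tissue)
    n_col <- round(config$collagen_fraction * n_tissue)
    noise <- value_noise(size)
    vals <- noise[tissue]
    thr <- sort(vals, decreasing = TRUE)[max(n_col, 1)]
    collagen <- tissue & noise >= thr
    # exact fraction by flipping surplus/deficit pixels
    excess <- sum(collagen) - n_col
    if (excess > 0) {
      idx <- which(collagen)
      collagen[sample(idx, excess)] <- FALSE
    } else if (excess < 0) {
      idx <- which(tissue & !collagen)
      collagen[sample(idx, -excess)] <- TRUE
    }
    myocardium <- tissue & !collagen

    # ground-truth nearest edge-to-edge distances among oblique + transverse
    ot <- comp$id[comp$class != "longitudinal"]
    dist_tbl <- NULL
    if (length(ot) >= 2) {
      bnd <- lapply(ot, function(id) boundary_pixels(cap == id))
      names(bnd) <- as.character(ot)
      dist_tbl <- dplyr::bind_rows(lapply(seq_along(ot), function(i) {
        dmins <- vapply(seq_along(ot)[-i], function(j) {
          min_set_distance(bnd[[i]], bnd[[j]])
        }, numeric(1))
        tibble(id = ot[i], nearest_px = min(dmins))
      }))
    }
    truth <- truth_record("histology_masks", components = comp,
                          collagen_fraction = sum(collagen) /
                            (sum(collagen) + sum(myocardium)),
                          nearest_distances = dist_tbl,
                          pixel_size = config$pixel_size, seed = config$seed)
    list(capillary = cap, lumen = lum, collagen = collagen,
         myocardium = myocardium, truth = truth)
  })
}

# pixels of a binary mask with at least one 4-neighbour outside it
boundary_pixels <- function(mask) {
  m <- nrow(mask)
  pad <- matrix(FALSE, m + 2, m + 2)
  pad[2:(m + 1), 2:(m + 1)] <- mask
  core <- pad[2:(m + 1), 2:(m + 1)]
  nb <- pad[1:m, 2:(m + 1)] & pad[3:(m + 2), 2:(m + 1)] &
    pad[2:(m + 1), 1:m] & pad[2:(m + 1), 3:(m + 2)]
  which(core & !nb, arr.ind = TRUE)
}

# minimum Euclidean distance between two pixel coordinate sets
min_set_distance <- function(p1, p2) {
  d2 <- outer(p1[, 1], p2[, 1], "-")^2 + outer(p1[, 2], p2[, 2], "-")^2
  sqrt(min(d2))
}
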