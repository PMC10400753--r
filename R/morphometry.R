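# Capillary morphometry and fibrosis quantification from segmentation masks.

# 8-connected labelling: EBImage::bwlabel (4-connected) plus a union-find
# merge of labels that touch diagonally.
label_components_8 <- function(mask) {
  lab <- EBImage::bwlabel(mask > 0)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nmax <- max(lab)
  if (nmax < 2) return(lab)
  parent <- seq_len(nmax)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  m <- nrow(lab); n <- ncol(lab)
  a <- lab[1:(m - 1), 1:(n - 1)]; b <- lab[2:m, 2:n]
  idx <- which(a > 0 & b > 0 & a != b)
  for (k in idx) union_(a[k], b[k])
  a <- lab[2:m, 1:(n - 1)]; b <- lab[1:(m - 1), 2:n]
  idx <- which(a > 0 & b > 0 & a != b)
  for (k in idx) union_(a[k], b[k])
  roots <- vapply(seq_len(nmax), find, integer(1))
  relabel <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relabel[lab[lab > 0]]
  out
}

#' Extract capillary components from a wall mask
#'
#' Labels 8-connected components, computes ellipse-equivalent axes from the
#' second central moments (major/minor axis length = 4 sqrt(eigenvalue)),
#' classifies the sectioning orientation from the aspect ratio and detects
#' lumens — either from an explicit lumen mask (a lumen blob belongs to the
#' single component fully enclosing it) or as enclosed background holes.
#'
#' Orientation classes (configurable thresholds; the defaults operationalise
#' the usual visual classes): aspect ratio `< 1.5` transverse, `[1.5, 3)`
#' oblique, `>= 3` longitudinal.
#'
#' @param walls Binary or integer-labelled wall mask (matrix).
#' @param lumen Optional logical lumen mask.
#' @param pixel_size Pixel size (micrometres).
#' @param ar_thresholds Length-2 thresholds separating
#'   transverse/oblique/longitudinal (default `c(1.5, 3)`).
#' @return A tibble of class `capillary_components`: `id`, `area_px`,
#'   `area_um2`, `centroid_row`, `centroid_col`, `major_axis`, `minor_axis`
#'   (pixels), `aspect_ratio`, `orientation_class`, `lumen_present`,
#'   `lumen_area_um2`. Empty masks yield an empty table.
#' @export
extract_components <- function(walls, lumen = NULL, pixel_size = 1,
                               ar_thresholds = c(1.5, 3)) {
  if (!is.matrix(walls)) abort("`walls` must be a matrix.")
  if (is.logical(walls)) walls <- walls * 1L
  if (!is.numeric(walls) || any(walls < 0) || any(walls != round(walls))) {
    abort("`walls` must be a binary or integer-labelled mask.")
  }
  check_number(pixel_size, "pixel_size", 0, strict = TRUE)
  lab <- if (max(walls) > 1) matrix(as.integer(walls), nrow(walls)) else
    label_components_8(walls)
  n <- max(lab)
  empty <- tibble(id = integer(), area_px = integer(), area_um2 = numeric(),
                  centroid_row = numeric(), centroid_col = numeric(),
                  major_axis = numeric(), minor_axis = numeric(),
                  aspect_ratio = numeric(), orientation_class = character(),
                  lumen_present = logical(), lumen_area_um2 = numeric())
  if (n == 0) return(structure(empty, class = c("capillary_components", class(empty))))

  lumen_area <- rep(0, n)
  if (!is.null(lumen)) {
    lum_lab <- label_components_8(lumen)
    if (max(lum_lab) > 0) {
      for (l in seq_len(max(lum_lab))) {
        px <- which(lum_lab == l, arr.ind = TRUE)
        ring <- unique(unlist(lapply(c(-1, 0, 1), function(dr)
          lapply(c(-1, 0, 1), function(dc) {
            r <- pmin(pmax(px[, 1] + dr, 1), nrow(lab))
            c <- pmin(pmax(px[, 2] + dc, 1), ncol(lab))
            lab[cbind(r, c)]
          }))))
        owners <- setdiff(ring, 0)
        touches_border <- any(px[, 1] %in% c(1, nrow(lab)) | px[, 2] %in% c(1, ncol(lab)))
        if (length(owners) == 1 && !touches_border) {
          lumen_area[owners] <- lumen_area[owners] + nrow(px)
        }
      }
    }
  } else {
    filled <- EBImage::fillHull(lab > 0)
    holes <- label_components_8(filled & !(lab > 0))
    if (max(holes) > 0) {
      for (l in seq_len(max(holes))) {
        px <- which(holes == l, arr.ind = TRUE)
        ring <- unique(unlist(lapply(c(-1, 0, 1), function(dr)
          lapply(c(-1, 0, 1), function(dc) {
            r <- pmin(pmax(px[, 1] + dr, 1), nrow(lab))
            c <- pmin(pmax(px[, 2] + dc, 1), ncol(lab))
            lab[cbind(r, c)]
          }))))
        owners <- setdiff(ring, 0)
        if (length(owners) == 1) lumen_area[owners] <- lumen_area[owners] + nrow(px)
      }
    }
  }

  rows <- lapply(seq_len(n), function(i) {
    px <- which(lab == i, arr.ind = TRUE)
    cr <- mean(px[, 1]); cc <- mean(px[, 2])
    mrr <- mean((px[, 1] - cr)^2); mcc <- mean((px[, 2] - cc)^2)
    mrc <- mean((px[, 1] - cr) * (px[, 2] - cc))
    tr <- (mrr + mcc) / 2
    d <- sqrt(((mrr - mcc) / 2)^2 + mrc^2)
    l1 <- tr + d; l2 <- max(tr - d, 0)
    major <- 4 * sqrt(l1)
    minor <- 4 * sqrt(max(l2, 1e-12))
    ar <- major / minor
    tibble(id = i, area_px = nrow(px), area_um2 = nrow(px) * pixel_size^2,
           centroid_row = cr, centroid_col = cc,
           major_axis = major, minor_axis = minor, aspect_ratio = ar,
           orientation_class = if (ar < ar_thresholds[1]) "transverse"
                               else if (ar < ar_thresholds[2]) "oblique"
                               else "longitudinal",
           lumen_present = lumen_area[i] > 0,
           lumen_area_um2 = lumen_area[i] * pixel_size^2)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "label_matrix") <- lab
  attr(out, "pixel_size") <- pixel_size
  class(out) <- c("capillary_components", class(out))
  out
}

#' Summarise capillary architecture
#'
#' Wall-area fraction of the tissue, wall-area share per orientation class,
#' mean lumen area of lumen-bearing oblique/transverse capillaries, and the
#' mean nearest edge-to-edge (boundary-pixel) distance among oblique and
#' transverse capillaries.
#'
#' @param components An [extract_components()] result (its label matrix and
#'   pixel size travel along as attributes).
#' @param tissue_area_um2 Reference tissue area (square micrometres).
#' @return A one-row tibble: `n_components`, `wall_area_fraction` (%),
#'   `pct_longitudinal`, `pct_oblique`, `pct_transverse` (% of total wall
#'   area, summing to 100), `mean_lumen_area_um2`, `mean_nearest_distance_um`
#'   (`NA` with a warning when fewer than 2 oblique/transverse components
#'   exist).
#' @export
summarize_architecture <- function(components, tissue_area_um2) {
  stopifnot(inherits(components, "capillary_components"))
  check_number(tissue_area_um2, "tissue_area_um2", 0, strict = TRUE)
  pixel_size <- attr(components, "pixel_size") %||% 1
  n <- nrow(components)
  if (n == 0) {
    return(tibble(n_components = 0L, wall_area_fraction = 0,
                  pct_longitudinal = NA_real_, pct_oblique = NA_real_,
                  pct_transverse = NA_real_, mean_lumen_area_um2 = NA_real_,
                  mean_nearest_distance_um = NA_real_))
  }
  total <- sum(components$area_um2)
  cls_pct <- vapply(c("longitudinal", "oblique", "transverse"), function(cl) {
    100 * sum(components$area_um2[components$orientation_class == cl]) / total
  }, numeric(1))
  ot <- components$orientation_class %in% c("oblique", "transverse")
  lum <- ot & components$lumen_present
  mean_lumen <- if (any(lum)) mean(components$lumen_area_um2[lum]) else NA_real_

  mean_dist <- NA_real_
  lab <- attr(components, "label_matrix")
  ids <- components$id[ot]
  if (length(ids) < 2) {
    warn("fewer than 2 oblique/transverse components: nearest distance undefined.")
  } else if (!is.null(lab)) {
    bnd <- lapply(ids, function(id) boundary_pixels(lab == id))
    nearest <- vapply(seq_along(ids), function(i) {
      min(vapply(seq_along(ids)[-i], function(j)
        min_set_distance(bnd[[i]], bnd[[j]]), numeric(1)))
    }, numeric(1))
    mean_dist <- mean(nearest) * pixel_size
  }
  tibble(n_components = n,
         wall_area_fraction = 100 * total / tissue_area_um2,
         pct_longitudinal = cls_pct[["longitudinal"]],
         pct_oblique = cls_pct[["oblique"]],
         pct_transverse = cls_pct[["transverse"]],
         mean_lumen_area_um2 = mean_lumen,
         mean_nearest_distance_um = mean_dist)
}

#' Collagen (fibrosis) fraction
#'
#' Percent collagen of the whole cardiac tissue section, i.e.
#' `100 * collagen / (collagen + myocardium)` by pixel counts.
#'
#' @param collagen,myocardium Disjoint logical masks of equal shape.
#' @return A one-row tibble: `collagen_percent`, `collagen_area_px`,
#'   `myocardium_area_px`. Both masks empty yields `NA` with a warning.
#' @export
collagen_fraction <- function(collagen, myocardium) {
  if (!identical(dim(collagen), dim(myocardium))) abort("mask shapes differ.")
  collagen <- collagen > 0; myocardium <- myocardium > 0
  if (any(collagen & myocardium)) abort("collagen and myocardium masks overlap.")
  nc <- sum(collagen); nm <- sum(myocardium)
  if (nc + nm == 0) {
    warn("both masks empty: collagen fraction undefined.")
    return(tibble(collagen_percent = NA_real_, collagen_area_px = 0L,
                  myocardium_area_px = 0L))
  }
  tibble(collagen_percent = 100 * nc / (nc + nm),
         collagen_area_px = nc, myocardium_area_px = nm)
}
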