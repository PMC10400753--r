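# Readers and writers for the plain-text / TIFF interchange formats.

#' Read a time-volume curve from TSV
#'
#' Expects columns `frame_index`, `time_ms`, `volume_ul`; the R-R interval
#' and heart rate come from a metadata list or JSON file with `rr_ms` (and
#' optionally `hr_bpm`).
#'
#' @param path TSV file path.
#' @param meta A list with `rr_ms` (and optionally `hr_bpm`), or a path to a
#'   JSON file with those fields.
#' @return A [time_volume_curve()].
#' @export
read_tvc_tsv <- function(path, meta) {
  if (is.character(meta)) meta <- jsonlite::read_json(meta, simplifyVector = TRUE)
  df <- readr::read_tsv(path, show_col_types = FALSE)
  time_volume_curve(df$time_ms, df$volume_ul, rr = meta$rr_ms,
                    hr = meta$hr_bpm %||% (60000 / meta$rr_ms))
}

#' Write a time-volume curve to TSV
#'
#' @param tvc A [time_volume_curve()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_tvc_tsv <- function(tvc, path) {
  readr::write_tsv(tibble(frame_index = tvc$frame, time_ms = tvc$time_ms,
                          volume_ul = tvc$volume_ul), path)
  invisible(path)
}

#' Write / read a tagged frame stack as multi-frame TIFF
#'
#' Intensities are min-max rescaled to `[0, 1]` on write (32-bit float TIFF);
#' the affine scale travels in the sidecar JSON together with the geometry
#' (`pixel_spacing_mm`, `fov_mm`, `frame_times`, `tag_span_mm`), so the round
#' trip is lossless up to float precision.
#'
#' @param stack A `tagged_stack`.
#' @param path Output TIFF path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  lo <- min(stack$frames)
  hi <- max(stack$frames)
  scale <- if (hi > lo) hi - lo else 1
  frames <- lapply(seq_len(dim(stack$frames)[3]),
                   function(f) (stack$frames[, , f] - lo) / scale)
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  jsonlite::write_json(list(pixel_spacing_mm = stack$pixel_spacing,
                            fov_mm = stack$fov_mm,
                            frame_times = stack$frame_times,
                            tag_span_mm = 1 / stack$tag_wavevectors[1, 1],
                            intensity_offset = lo, intensity_scale = scale),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  geom <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  arr <- array(0, dim = c(nrow(frames[[1]]), ncol(frames[[1]]), length(frames)))
  off <- geom$intensity_offset %||% 0
  scl <- geom$intensity_scale %||% 1
  for (f in seq_along(frames)) arr[, , f] <- frames[[f]] * scl + off
  k <- 1 / geom$tag_span_mm
  structure(list(frames = arr, pixel_spacing = geom$pixel_spacing_mm,
                 frame_times = geom$frame_times,
                 tag_wavevectors = rbind(c(k, 0), c(0, k)),
                 fov_mm = geom$fov_mm),
            class = "tagged_stack")
}

#' Read a count matrix (TSV or MatrixMarket)
#'
#' TSV: first column gene ids, remaining columns samples. MatrixMarket:
#' `<path>` plus sidecars `<path>.genes.tsv` / `<path>.samples.tsv` (one id
#' per line, no header).
#'
#' @param path Counts file (`.tsv` or `.mtx`).
#' @return Integer matrix, genes x samples.
#' @export
read_counts <- function(path) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readr::read_lines(paste0(path, ".genes.tsv"))
    colnames(m) <- readr::read_lines(paste0(path, ".samples.tsv"))
    return(m)
  }
  df <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}

#' Write a count matrix as MatrixMarket with sidecars
#'
#' @param counts Integer matrix with dimnames.
#' @param path Output `.mtx` path.
#' @return `path`, invisibly.
#' @export
write_counts_mtx <- function(counts, path) {
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), path)
  readr::write_lines(rownames(counts), paste0(path, ".genes.tsv"))
  readr::write_lines(colnames(counts), paste0(path, ".samples.tsv"))
  invisible(path)
}

#' Read a GMT annotation file
#'
#' Standard gene-set format: one term per line, tab-separated
#' `term <tab> description <tab> gene1 <tab> gene2 ...`.
#'
#' @param path GMT file path.
#' @return Named list: term -> character vector of genes.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  out
}

#' Write / read a 16-bit mask TIFF
#'
#' Integer labels up to 65535; logical masks are written as 0/1.
#'
#' @param mask Integer or logical matrix.
#' @param path TIFF path.
#' @return `path` (write) or an integer matrix (read).
#' @export
write_mask_tiff <- function(mask, path) {
  tiff::writeTIFF(matrix(as.numeric(mask) / 65535, nrow(mask)), path,
                  bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow(m))
}

#' Write a truth record as JSON
#'
#' @param truth A [truth_record()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", null = "null")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "truth_record")
}
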