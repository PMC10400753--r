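# Shared helpers: seed substreams, angle wrapping, argument checks.

#' Derive a reproducible substream seed
#'
#' All generators draw their randomness from a single user seed. Each generator
#' (and each independent draw inside one) works on its own substream, obtained
#' by hashing the user seed together with a stream label. The hash is plain
#' integer arithmetic on doubles below 2^53, reduced modulo 2^31 - 1, so the
#' same (seed, label) pair maps to the same substream on every platform.
#'
#' @param seed Integer user seed.
#' @param stream Character label of the consuming generator.
#' @return A single integer in `[1, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(1, "tvc")
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(stream))
  m <- 2147483647 # 2^31 - 1, prime
  h <- (abs(seed) %% m) + 1
  for (code in utf8ToInt(stream)) {
    h <- (h * 131 + code) %% m
  }
  h <- (h * 48271) %% m # Lehmer step decorrelates nearby seeds
  as.integer(max(1, h))
}

# wrap angles / phase differences into (-pi, pi]
wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

check_number <- function(x, name, lower = -Inf, upper = Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (strict) x > lower else x >= lower
  hi_ok <- if (strict) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf("`%s` = %g is outside its valid range.", name, x))
  }
  invisible(x)
}

#' Ground-truth record attached to synthetic data
#'
#' Every generator returns, alongside its data, a `truth_record`: a plain list
#' that echoes the generating parameters and all derived ground truth
#' (breakpoints, deformation, planted gene memberships, component geometry,
#' slope). It serializes losslessly through JSON via [write_truth_json()].
#'
#' @param generator Name of the generator that produced the record.
#' @param ... Named ground-truth fields.
#' @return A list of class `truth_record`.
#' @export
truth_record <- function(generator, ...) {
  structure(c(list(generator = generator), list(...)), class = "truth_record")
}

#' @export
print.truth_record <- function(x, ...) {
  cat("<truth_record:", x$generator, "> fields:",
      paste(setdiff(names(x), "generator"), collapse = ", "), "\n")
  invisible(x)
}

#' Percentage helper used for retention/annotation summaries
#'
#' @param k Numerator count.
#' @param n Denominator count.
#' @param digits Number of decimal places (default 2).
#' @return `100 * k / n`, rounded.
#' @export
percent_of <- function(k, n, digits = 2) {
  check_number(n, "n", lower = 0, strict = TRUE)
  round(100 * k / n, digits)
}
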