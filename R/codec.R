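#' Fit a linear quantizer
#'
#' The memory operates on discrete functions: real-valued feature vectors
#' (e.g. encoder outputs) are sampled into \code{m} discrete levels, one
#' level range per argument. This quantizer is a per-argument equal-width
#' binning between the minimum and maximum observed values, the minimal
#' faithful stand-in for the sampling step of a learned coder/decoder
#' pair.
#'
#' @param x Numeric matrix (rows = objects, columns = arguments) or a
#'   single numeric vector.
#' @param m Number of levels (rows of the target register).
#' @return An object of class \code{"quantizer"}: \code{n}, \code{m},
#'   \code{lo}, \code{hi} (per-argument bounds, \code{hi > lo}).
#' @seealso [quantize()], [dequantize()], [write_quantizer()]
#' @export
fit_quantizer <- function(x, m) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  m <- as.integer(m)
  if (length(m) != 1L || is.na(m) || m < 1L)
    stop("'m' must be a positive integer", call. = FALSE)
  if (nrow(x) < 1L) stop("empty input", call. = FALSE)
  if (!all(is.finite(x))) stop("non-finite values in input", call. = FALSE)
  lo <- apply(x, 2L, min)
  hi <- apply(x, 2L, max)
  # widen degenerate (constant) arguments so every value maps to level 0
  eps <- pmax(abs(lo), 1) * 1e-8
  deg <- hi <= lo
  hi[deg] <- lo[deg] + eps[deg]
  structure(list(n = ncol(x), m = m, lo = lo, hi = hi), class = "quantizer")
}

#' @export
print.quantizer <- function(x, ...) {
  cat(sprintf("Linear quantizer: %d arguments, %d levels\n", x$n, x$m))
  cat(sprintf("  bounds: lo in [%.4g, %.4g], hi in [%.4g, %.4g]\n",
              min(x$lo), max(x$lo), min(x$hi), max(x$hi)))
  invisible(x)
}

#' Quantize real vectors into discrete levels
#'
#' Maps each value to \code{floor(m * (x - lo) / (hi - lo))}, clipped to
#' \code{[0, m - 1]}; out-of-range values clip to the boundary level, so
#' unseen objects always quantize. \code{NA} values pass through as
#' undefined arguments.
#'
#' @param model A [fit_quantizer()] result.
#' @param x Numeric vector of length \code{n}, or a matrix with \code{n}
#'   columns (quantized row-wise).
#' @return Integer levels (0-based), same shape as \code{x}.
#' @export
quantize <- function(model, x) {
  stopifnot(inherits(model, "quantizer"))
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.matrix(x)) {
    if (ncol(x) != model$n) stop("arity mismatch", call. = FALSE)
    lo <- matrix(model$lo, nrow(x), model$n, byrow = TRUE)
    hi <- matrix(model$hi, nrow(x), model$n, byrow = TRUE)
    lev <- floor(model$m * (x - lo) / (hi - lo))
    lev <- pmin(pmax(lev, 0), model$m - 1L)
    storage.mode(lev) <- "integer"
    return(lev)
  }
  if (length(x) != model$n) stop("arity mismatch", call. = FALSE)
  lev <- floor(model$m * (x - model$lo) / (model$hi - model$lo))
  as.integer(pmin(pmax(lev, 0), model$m - 1L))
}

#' Map discrete levels back to real values
#'
#' The inverse sampling step: each level is mapped to the midpoint of its
#' bin, \code{lo + (level + 0.5) * (hi - lo) / m}. Undefined arguments
#' (\code{NA}) stay undefined. Quantizing a dequantized function returns
#' the same levels (round-trip level stability).
#'
#' @inheritParams quantize
#' @param f Integer levels (0-based) of length \code{n}, or a matrix with
#'   \code{n} columns.
#' @return Numeric values, same shape as \code{f}.
#' @export
dequantize <- function(model, f) {
  stopifnot(inherits(model, "quantizer"))
  if (is.matrix(f)) {
    if (ncol(f) != model$n) stop("arity mismatch", call. = FALSE)
    lo <- matrix(model$lo, nrow(f), model$n, byrow = TRUE)
    hi <- matrix(model$hi, nrow(f), model$n, byrow = TRUE)
    return(lo + (f + 0.5) * (hi - lo) / model$m)
  }
  if (length(f) != model$n) stop("arity mismatch", call. = FALSE)
  model$lo + (f + 0.5) * (model$hi - model$lo) / model$m
}

#' Persist a quantizer as JSON
#'
#' @param model A [fit_quantizer()] result.
#' @param path File path to write.
#' @return \code{path}, invisibly.
#' @export
write_quantizer <- function(model, path) {
  stopifnot(inherits(model, "quantizer"))
  jsonlite::write_json(
    list(n = model$n, m = model$m, lo = model$lo, hi = model$hi),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_quantizer
#' @export
read_quantizer <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(n = as.integer(obj$n), m = as.integer(obj$m),
                 lo = as.numeric(obj$lo), hi = as.numeric(obj$hi)),
            class = "quantizer")
}
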