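#' Shannon entropy of one column
#'
#' The weights of a column, normalized, define a probability distribution
#' over its levels; the column entropy is its Shannon entropy in bits. An
#' all-zero column carries a single (trivial) possibility and has entropy
#' 0.
#'
#' @param object An [amr()].
#' @param i Column index (1-based).
#' @return Entropy in bits, in \code{[0, log2(m)]}.
#' @export
column_entropy <- function(object, i) {
  stopifnot(inherits(object, "amr"))
  i <- as.integer(i)
  if (length(i) != 1L || is.na(i) || i < 1L || i > object$n)
    stop("column index out of range", call. = FALSE)
  p <- object$weights[, i]
  s <- sum(p)
  if (s == 0) return(0)
  p <- p[p > 0] / s
  -sum(p * log2(p))
}

#' Entropy of the memory
#'
#' The entropy of the register is the arithmetic mean of its column
#' entropies. It measures the indeterminacy of the stored content: low
#' entropy means precise but sparse memory (high precision, low recall),
#' high entropy a dense memory where most cues find support but selections
#' are often wrong.
#'
#' @param object An [amr()].
#' @return Mean column entropy in bits.
#' @export
amr_entropy <- function(object) {
  stopifnot(inherits(object, "amr"))
  mean(vapply(seq_len(object$n), function(i) column_entropy(object, i),
              numeric(1)))
}

#' Log2 capacity of the memory
#'
#' The number of functions held by the register at a given state — overt
#' and emerging — is \code{2^(e * n)} where \code{e} is the memory entropy
#' and \code{n} the number of columns. The count is astronomically large
#' even at modest entropy, so this function returns its base-2 logarithm
#' \code{e * n}; use [capacity_count()] for the exact integer when
#' \code{e * n} is integral.
#'
#' @param object An [amr()].
#' @return \code{e * n}, the log2 of the number of representable functions.
#' @export
capacity_log2 <- function(object) {
  stopifnot(inherits(object, "amr"))
  amr_entropy(object) * object$n
}

#' Exact capacity and productivity counts
#'
#' `capacity_count(k)` returns the exact integer `2^k` as a decimal string
#' (arbitrary precision), for integral `k = e * n`. `productivity_count()`
#' returns `2^k - registered`, the number of emerging objects: functions
#' representable by the memory state that were never explicitly
#' registered.
#'
#' @param k Non-negative log2 capacity; must be integral (within 1e-9).
#' @return A decimal digit string.
#' @export
capacity_count <- function(k) {
  if (length(k) != 1L || is.na(k) || k < 0)
    stop("'k' must be a non-negative number", call. = FALSE)
  if (abs(k - round(k)) > 1e-9)
    stop("exact capacity requires integral e * n; use capacity_log2()",
         call. = FALSE)
  big_to_string(big_pow2(as.integer(round(k))))
}

#' @rdname capacity_count
#' @param registered Number of explicitly registered objects (non-negative,
#'   less than `2^k`).
#' @export
productivity_count <- function(k, registered) {
  registered <- as.numeric(registered)
  if (length(registered) != 1L || is.na(registered) || registered < 0 ||
      registered != round(registered))
    stop("'registered' must be a non-negative integer", call. = FALSE)
  big_to_string(big_sub_small(big_pow2(as.integer(round(k))), registered))
}

# -- minimal arbitrary-precision decimal arithmetic ---------------------------
# Numbers are integer vectors of base-10 digits, little-endian. Only the two
# operations the capacity accounting needs are provided: powers of two and
# subtraction of an ordinary (double-representable) non-negative integer.

big_pow2 <- function(k) {
  stopifnot(k >= 0)
  x <- 1L
  for (j in seq_len(k)) {
    x <- x * 2L
    carry <- 0L
    for (d in seq_along(x)) {
      v <- x[d] + carry
      x[d] <- v %% 10L
      carry <- v %/% 10L
    }
    while (carry > 0L) {
      x <- c(x, carry %% 10L)
      carry <- carry %/% 10L
    }
  }
  x
}

big_sub_small <- function(x, s) {
  # subtract the non-negative integer s (as a double) from digit vector x
  sd <- integer(0)
  while (s > 0) {
    sd <- c(sd, as.integer(s %% 10))
    s <- floor(s / 10)
  }
  if (length(sd) > length(x)) stop("negative result", call. = FALSE)
  borrow <- 0L
  for (d in seq_along(x)) {
    sub <- if (d <= length(sd)) sd[d] else 0L
    v <- x[d] - sub - borrow
    if (v < 0L) { v <- v + 10L; borrow <- 1L } else borrow <- 0L
    x[d] <- v
  }
  if (borrow > 0L) stop("negative result", call. = FALSE)
  x
}

big_to_string <- function(x) {
  while (length(x) > 1L && x[length(x)] == 0L) x <- x[-length(x)]
  paste(rev(x), collapse = "")
}
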