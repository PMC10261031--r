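#' Create an associative memory register
#'
#' An associative memory register (AMR) is an \code{n}-column by \code{m}-row
#' table of non-negative integer weights. Columns stand for the arguments of
#' the stored discrete functions and rows for their quantized values
#' (levels). Every stored object marks one cell per column, so distinct
#' objects overlap on the medium and the representation is indeterminate;
#' the degree of indeterminacy is measured by [amr_entropy()].
#'
#' Levels are 0-based throughout: a cue is an integer vector of length
#' \code{n} with values in \code{0:(m - 1)}, with \code{NA} marking an
#' undefined argument (a partial cue).
#'
#' @param n Number of columns (arguments). Positive integer.
#' @param m Number of rows (levels per argument). Positive integer.
#' @param l Maximum cell weight; registration saturates here. The default
#'   65535 corresponds to two-byte cells.
#' @return An object of class \code{"amr"} with fields \code{weights}
#'   (an \code{m} x \code{n} integer matrix, row \code{j} = level
#'   \code{j - 1}), \code{n}, \code{m} and \code{l}.
#' @seealso [amr_register()], [amr_recognize()], [amr_retrieve()],
#'   [amr_entropy()], [write_amr()]
#' @examples
#' a <- amr(n = 4, m = 8)
#' a <- amr_register(a, c(3, 1, 6, 7))
#' amr_recognize(a, c(3, 1, 6, 7))$accepted
#' @export
amr <- function(n, m, l = 65535L) {
  n <- as.integer(n)
  m <- as.integer(m)
  l <- as.integer(l)
  if (length(n) != 1L || is.na(n) || n < 1L)
    stop("'n' must be a positive integer", call. = FALSE)
  if (length(m) != 1L || is.na(m) || m < 1L)
    stop("'m' must be a positive integer", call. = FALSE)
  if (length(l) != 1L || is.na(l) || l < 1L)
    stop("'l' must be a positive integer", call. = FALSE)
  structure(
    list(weights = matrix(0L, nrow = m, ncol = n), n = n, m = m, l = l),
    class = "amr"
  )
}

#' @export
print.amr <- function(x, ...) {
  cat(sprintf("Associative memory register: %d columns x %d rows (max weight %d)\n",
              x$n, x$m, x$l))
  cat(sprintf("  total weight: %.0f   non-zero cells: %d / %d\n",
              sum(as.numeric(x$weights)), sum(x$weights > 0L), x$n * x$m))
  cat(sprintf("  entropy: %.4f bits   capacity: 2^%.1f functions\n",
              amr_entropy(x), capacity_log2(x)))
  invisible(x)
}

#' @export
summary.amr <- function(object, ...) {
  e <- vapply(seq_len(object$n), function(i) column_entropy(object, i),
              numeric(1))
  out <- list(
    n = object$n, m = object$m, l = object$l,
    total_weight = sum(as.numeric(object$weights)),
    nonzero_cells = sum(object$weights > 0L),
    column_entropy = e,
    entropy = mean(e),
    capacity_log2 = mean(e) * object$n
  )
  class(out) <- "summary.amr"
  out
}

#' @export
print.summary.amr <- function(x, ...) {
  cat(sprintf("AMR %d x %d, max weight %d\n", x$n, x$m, x$l))
  cat(sprintf("  total weight %.0f, %d non-zero cells\n",
              x$total_weight, x$nonzero_cells))
  cat("  column entropy (bits):\n")
  print(summary(x$column_entropy))
  cat(sprintf("  memory entropy: %.4f bits; capacity 2^%.2f\n",
              x$entropy, x$capacity_log2))
  invisible(x)
}

#' @export
plot.amr <- function(x, ...) {
  graphics::image(seq_len(x$n), seq_len(x$m), t(x$weights),
                  xlab = "column (argument)", ylab = "row (level, 1-based)",
                  main = sprintf("AMR %d x %d weights", x$n, x$m), ...)
  invisible(x)
}

# Validate a cue against a register; returns an integer vector with NAs for
# undefined arguments.
check_cue <- function(object, cue) {
  if (is.list(cue)) cue <- unlist(cue)
  if (length(cue) != object$n)
    stop(sprintf("cue arity %d does not match register with %d columns",
                 length(cue), object$n), call. = FALSE)
  cue <- as.integer(round(cue))
  def <- !is.na(cue)
  if (!any(def))
    stop("cue has no defined arguments", call. = FALSE)
  if (any(cue[def] < 0L | cue[def] >= object$m))
    stop(sprintf("cue levels must lie in [0, %d]", object$m - 1L),
         call. = FALSE)
  cue
}

#' Register a cue (or batch of cues) into the memory
#'
#' The register operation adds the cue into the memory by incrementing the
#' weight of the cell at (column i, level cue\[i\]) for every defined
#' argument, saturating at the maximum weight \code{l}. Registering
#' reinforces cells in proportion to their frequency of use, a Hebbian-style
#' learning rule; nothing is ever searched or relocated.
#'
#' @param object An [amr()].
#' @param cue An integer vector of length \code{n} (levels, 0-based, `NA`
#'   allowed for undefined arguments), or a matrix with \code{n} columns
#'   whose rows are cues to be registered in order.
#' @return The updated register.
#' @export
amr_register <- function(object, cue) {
  stopifnot(inherits(object, "amr"))
  if (is.matrix(cue) || is.data.frame(cue)) {
    cues <- as.matrix(cue)
    if (ncol(cues) != object$n)
      stop(sprintf("cue arity %d does not match register with %d columns",
                   ncol(cues), object$n), call. = FALSE)
    storage.mode(cues) <- "integer"
    ok <- is.na(cues) | (cues >= 0L & cues < object$m)
    if (!all(ok))
      stop(sprintf("cue levels must lie in [0, %d]", object$m - 1L),
           call. = FALSE)
    w <- object$weights
    for (i in seq_len(object$n)) {
      v <- cues[, i]
      v <- v[!is.na(v)]
      if (length(v))
        w[, i] <- pmin(w[, i] + tabulate(v + 1L, nbins = object$m), object$l)
    }
    object$weights <- w
    return(object)
  }
  cue <- check_cue(object, cue)
  def <- which(!is.na(cue))
  idx <- cbind(cue[def] + 1L, def)
  object$weights[idx] <- pmin(object$weights[idx] + 1L, object$l)
  object
}

#' Recognition test for a cue
#'
#' Recognition is a declarative test, not a search: a cue is accepted iff
#' the relaxed material implication holds column-wise and the cue's mean
#' weight clears a threshold. Column \code{i} fails when the cell hit by
#' the cue has zero weight, or weight below \code{iota * omega_i}, where
#' \code{omega_i} is the mean weight of the non-zero cells of the column.
#' The cue is accepted when at most \code{xi} columns fail and
#' \code{rho >= kappa * Omega}, where \code{rho} is the mean weight of the
#' cells hit by the cue (over its defined arguments) and \code{Omega} the
#' mean of the \code{omega_i}. The defaults \code{iota = kappa = xi = 0}
#' impose no constraint beyond the zero-weight test, under which a cue
#' touching any unsupported cell is rejected directly.
#'
#' @param object An [amr()].
#' @param cue Integer vector of levels (0-based; `NA` = undefined argument).
#' @param iota Minimum weight factor for a cell to count as on; >= 0.
#' @param kappa Cue-weight threshold factor; >= 0.
#' @param xi Number of columns allowed to fail; integer in \code{0:n}.
#' @return A list of class \code{"amr_recognition"}: \code{accepted},
#'   \code{failing_columns} (1-based column indices), \code{omega} (per
#'   column), \code{Omega}, \code{rho}.
#' @export
amr_recognize <- function(object, cue, iota = 0, kappa = 0, xi = 0L) {
  stopifnot(inherits(object, "amr"))
  if (iota < 0 || kappa < 0)
    stop("'iota' and 'kappa' must be non-negative", call. = FALSE)
  xi <- as.integer(xi)
  if (xi < 0L || xi > object$n)
    stop("'xi' must be an integer in [0, n]", call. = FALSE)
  cue <- check_cue(object, cue)
  w <- object$weights
  k <- colSums(w > 0L)
  omega <- ifelse(k > 0L, colSums(w) / pmax(k, 1L), 0)
  Omega <- mean(omega)
  def <- which(!is.na(cue))
  wcue <- w[cbind(cue[def] + 1L, def)]
  rho <- mean(wcue)
  # zero-weight cells are always off, even when iota = 0
  failing <- def[wcue == 0L | wcue < iota * omega[def]]
  accepted <- (length(failing) <= xi) && (rho >= kappa * Omega)
  structure(
    list(accepted = accepted, failing_columns = failing,
         omega = omega, Omega = Omega, rho = rho),
    class = "amr_recognition"
  )
}

#' @export
print.amr_recognition <- function(x, ...) {
  cat(sprintf("Cue %s: %d failing column(s); rho = %.4f, Omega = %.4f\n",
              if (x$accepted) "ACCEPTED" else "REJECTED",
              length(x$failing_columns), x$rho, x$Omega))
  invisible(x)
}

#' Constructive retrieval of an object from the memory
#'
#' If the cue is rejected by [amr_recognize()] the result is undefined and
#' \code{NULL} is returned (rejection is a result, not an error). Otherwise
#' each column \code{i} is treated as a probability distribution
#' \code{Psi_i} proportional to its weights (the prior), the cue as a
#' normal kernel \code{zeta_i} centered at its level with standard
#' deviation \code{sigma * m} evaluated at the integer levels (the
#' likelihood), and one level is sampled from their normalized product
#' \code{Phi_i}. With \code{sigma = 0} the kernel is a point mass and the
#' memory is reproductive: a stored cue retrieves itself exactly. Larger
#' \code{sigma} admits more indeterminacy, yielding associated and
#' eventually imaged objects.
#'
#' Undefined cue arguments are sampled from \code{Psi_i} alone; a column
#' with no support for an undefined argument yields \code{NA} at that
#' position.
#'
#' @inheritParams amr_recognize
#' @param sigma Non-negative spread of the cue kernel, in units of the
#'   full row range (the kernel standard deviation is \code{sigma * m}).
#' @param seed Optional integer; when supplied the random draws are made
#'   under this seed and the caller's RNG state is restored on exit.
#' @return An integer vector of levels (possibly with \code{NA} where no
#'   support existed), or \code{NULL} when the cue is rejected.
#' @export
amr_retrieve <- function(object, cue, sigma = 0.1, iota = 0, kappa = 0,
                         xi = 0L, seed = NULL) {
  stopifnot(inherits(object, "amr"))
  if (length(sigma) != 1L || is.na(sigma) || sigma < 0)
    stop("'sigma' must be a non-negative number", call. = FALSE)
  rec <- amr_recognize(object, cue, iota = iota, kappa = kappa, xi = xi)
  if (!rec$accepted) return(NULL)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
  }
  cue <- check_cue(object, cue)
  w <- object$weights
  m <- object$m
  out <- rep(NA_integer_, object$n)
  levels0 <- seq.int(0L, m - 1L)
  for (i in seq_len(object$n)) {
    psi <- w[, i]
    s <- sum(psi)
    if (is.na(cue[i])) {
      if (s > 0) out[i] <- sample.int(m, 1L, prob = psi) - 1L
      next
    }
    if (s == 0) next  # only reachable in xi-relaxed columns
    if (sigma == 0) {
      # point-mass kernel; fall back to the prior if the cue cell is empty
      # (possible only in xi-relaxed columns), so retrieval stays defined
      if (psi[cue[i] + 1L] > 0) out[i] <- cue[i]
      else out[i] <- sample.int(m, 1L, prob = psi) - 1L
      next
    }
    zeta <- stats::dnorm(levels0, mean = cue[i], sd = sigma * m)
    phi <- psi * zeta
    if (sum(phi) <= 0) phi <- psi  # kernel underflow guard
    out[i] <- sample.int(m, 1L, prob = phi) - 1L
  }
  out
}

#' Analytic retrieval distribution of one column
#'
#' Returns the normalized product \code{Phi_i} of the column weight
#' distribution \code{Psi_i} and the discretized normal cue kernel
#' \code{zeta_i} that [amr_retrieve()] samples from, for inspection and
#' testing.
#'
#' @inheritParams amr_retrieve
#' @param i Column index (1-based).
#' @param level Cue level at that column (0-based), or \code{NA} for an
#'   undefined argument (the prior alone).
#' @return Numeric vector of length \code{m} summing to 1, or a vector of
#'   zeros when the column has no support.
#' @export
column_distribution <- function(object, i, level, sigma = 0.1) {
  stopifnot(inherits(object, "amr"))
  i <- as.integer(i)
  if (i < 1L || i > object$n) stop("column index out of range", call. = FALSE)
  psi <- object$weights[, i]
  s <- sum(psi)
  if (s == 0) return(rep(0, object$m))
  if (is.na(level)) return(psi / s)
  if (sigma == 0) {
    p <- rep(0, object$m)
    if (psi[level + 1L] > 0) p[level + 1L] <- 1 else p <- psi / s
    return(p)
  }
  zeta <- stats::dnorm(seq.int(0L, object$m - 1L), mean = level,
                       sd = sigma * object$m)
  phi <- psi * zeta
  if (sum(phi) <= 0) phi <- psi
  phi / sum(phi)
}
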