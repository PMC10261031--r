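#' Specification of a synthetic feature-vector domain
#'
#' Describes a labelled corpus of class-conditional Gaussian clusters that
#' emulates the geometry of encoder outputs for a balanced multi-class
#' image corpus: each class has an isotropic Gaussian cluster around its
#' own centroid in feature space. The corpus is split into three disjoint
#' balanced partitions — a training corpus (for fitting the quantizer and
#' the stand-in classifier), a remembered corpus (for filling the memory)
#' and a test corpus (for cueing it) — with the conventional 70/20/10
#' fractions by default.
#'
#' @param n Feature arity (number of memory columns).
#' @param classes Number of classes (default 10).
#' @param separation Standard deviation of the centroid coordinates;
#'   centroids are drawn once per domain from an isotropic Gaussian with
#'   this scale, so larger values separate the classes further.
#' @param noise_sd Within-class standard deviation around the centroid.
#' @param size Total corpus size; must be divisible by \code{classes}
#'   (the corpus is balanced).
#' @param fractions Named numeric vector \code{c(train, remember, test)}
#'   summing to 1; each fraction of the per-class count must be integral.
#' @return An object of class \code{"domain_spec"}.
#' @seealso [generate_domain()]
#' @export
domain_spec <- function(n = 64L, classes = 10L, separation = 3,
                        noise_sd = 1, size = 7000L,
                        fractions = c(train = 0.70, remember = 0.20,
                                      test = 0.10)) {
  n <- as.integer(n); classes <- as.integer(classes); size <- as.integer(size)
  if (classes < 2L) stop("'classes' must be at least 2", call. = FALSE)
  if (n < 1L || size < classes)
    stop("invalid 'n' or 'size'", call. = FALSE)
  if (size %% classes != 0L)
    stop("'size' must be divisible by 'classes' (balanced corpus)",
         call. = FALSE)
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-9 ||
      any(fractions < 0))
    stop("'fractions' must be three non-negative numbers summing to 1",
         call. = FALSE)
  per_class <- size %/% classes
  counts <- fractions * per_class
  if (any(abs(counts - round(counts)) > 1e-9))
    stop("each fraction of the per-class count must be integral",
         call. = FALSE)
  if (separation <= 0 || noise_sd <= 0)
    stop("'separation' and 'noise_sd' must be positive", call. = FALSE)
  structure(list(n = n, classes = classes, separation = separation,
                 noise_sd = noise_sd, size = size,
                 fractions = fractions, per_class = per_class),
            class = "domain_spec")
}

#' @export
print.domain_spec <- function(x, ...) {
  cat(sprintf(
    "Synthetic domain: %d classes x %d objects, %d features\n",
    x$classes, x$per_class, x$n))
  cat(sprintf("  centroid scale %.3g, within-class sd %.3g, split %s\n",
              x$separation, x$noise_sd,
              paste(sprintf("%.0f%%", 100 * x$fractions), collapse = "/")))
  invisible(x)
}

#' Generate a synthetic labelled corpus
#'
#' Draws class centroids and class-conditional Gaussian samples per the
#' spec, and partitions them into disjoint, balanced train / remember /
#' test corpora. Fully reproducible from \code{seed}.
#'
#' @param spec A [domain_spec()].
#' @param seed Integer seed.
#' @return A list of class \code{"domain"}: data frames \code{train},
#'   \code{remember}, \code{test} (feature columns \code{f1..fn} plus
#'   \code{label}, labels \code{0:(classes-1)}), the \code{centroids}
#'   matrix (classes x n) and the \code{spec}.
#' @export
generate_domain <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "domain_spec"))
  set.seed(seed)
  cents <- matrix(stats::rnorm(spec$classes * spec$n, 0, spec$separation),
                  nrow = spec$classes)
  counts <- round(spec$fractions * spec$per_class)
  parts <- list(train = NULL, remember = NULL, test = NULL)
  for (part in names(parts)) parts[[part]] <- vector("list", spec$classes)
  for (k in seq_len(spec$classes)) {
    xk <- matrix(stats::rnorm(spec$per_class * spec$n, 0, spec$noise_sd),
                 ncol = spec$n)
    xk <- sweep(xk, 2L, cents[k, ], "+")
    idx <- sample.int(spec$per_class)
    bounds <- cumsum(c(0, counts))
    for (p in 1:3) {
      rows <- idx[seq.int(bounds[p] + 1L, length.out = counts[p])]
      df <- as.data.frame(xk[rows, , drop = FALSE])
      names(df) <- paste0("f", seq_len(spec$n))
      df$label <- k - 1L
      parts[[p]][[k]] <- df
    }
  }
  out <- lapply(parts, function(p) do.call(rbind, p))
  rownames(out$train) <- rownames(out$remember) <- rownames(out$test) <- NULL
  structure(c(out, list(centroids = cents, spec = spec)), class = "domain")
}

#' @export
print.domain <- function(x, ...) {
  cat(sprintf("Synthetic domain: train %d / remember %d / test %d objects\n",
              nrow(x$train), nrow(x$remember), nrow(x$test)))
  print(x$spec)
  invisible(x)
}

# feature matrix / label helpers
domain_features <- function(df) as.matrix(df[, setdiff(names(df), "label")])
domain_labels <- function(df) df$label

#' Corrupt a feature vector with random noise
#'
#' Replaces an exact number of positions — \code{round(fraction * n)},
#' chosen uniformly without replacement — with uniform draws from the given
#' per-position range, emulating cues in which a fraction of the input has
#' been overwritten by noise. Other positions are untouched.
#'
#' @param x Numeric vector.
#' @param fraction Fraction of positions to corrupt, in \code{[0, 1]}.
#' @param lo,hi Replacement range, scalars or per-position vectors.
#' @return The corrupted vector.
#' @export
corrupt <- function(x, fraction, lo, hi) {
  if (fraction < 0 || fraction > 1)
    stop("'fraction' must be in [0, 1]", call. = FALSE)
  n <- length(x)
  lo <- rep_len(lo, n); hi <- rep_len(hi, n)
  k <- round(fraction * n)
  if (k == 0) return(x)
  pos <- sample.int(n, k)
  x[pos] <- stats::runif(k, lo[pos], hi[pos])
  x
}

#' Nearest-centroid classification
#'
#' The stand-in for a trained classifier: assigns each vector to the class
#' of the nearest centroid in Euclidean distance, breaking ties towards
#' the lowest class id. \code{NA} feature values are ignored in the
#' distance (partial objects are classified on their defined arguments).
#'
#' @param centroids Matrix, one row per class (class ids \code{0:(c-1)} in
#'   row order).
#' @param x Numeric vector, or matrix classified row-wise.
#' @return Integer class id(s).
#' @export
nearest_centroid <- function(centroids, x) {
  centroids <- as.matrix(centroids)
  if (is.matrix(x)) {
    return(vapply(seq_len(nrow(x)),
                  function(r) nearest_centroid(centroids, x[r, ]),
                  integer(1)))
  }
  def <- !is.na(x)
  if (!any(def)) stop("vector has no defined values", call. = FALSE)
  d2 <- colSums((t(centroids[, def, drop = FALSE]) - x[def])^2)
  as.integer(which.min(d2) - 1L)  # which.min takes the first (lowest id) tie
}
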