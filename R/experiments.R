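# Evaluate a filled register against a set of cues: quantize each cue,
# retrieve with the given sigma, classify the dequantized retrieval with the
# nearest-centroid stand-in, and tally right / wrong / none outcomes.
evaluate_cues <- function(object, model, x, labels, centroids, sigma = 0.1,
                          iota = 0, kappa = 0, xi = 0L) {
  lev <- quantize(model, x)
  right <- wrong <- none <- 0L
  for (r in seq_len(nrow(lev))) {
    out <- amr_retrieve(object, lev[r, ], sigma = sigma,
                        iota = iota, kappa = kappa, xi = xi)
    if (is.null(out)) {
      none <- none + 1L
    } else {
      cls <- nearest_centroid(centroids, dequantize(model, out))
      if (cls == labels[r]) right <- right + 1L else wrong <- wrong + 1L
    }
  }
  c(right = right, wrong = wrong, none = none)
}

# Balanced subsample: indices of round(fraction * n_k) objects per class,
# drawn from a per-class permutation fixed by the caller's RNG state.
balanced_subset <- function(labels, fraction) {
  idx <- integer(0)
  for (k in sort(unique(labels))) {
    rows <- which(labels == k)
    take <- round(fraction * length(rows))
    if (take > 0) idx <- c(idx, sample(rows, take))
  }
  if (length(idx) == 0L)
    stop("fraction yields zero objects", call. = FALSE)
  idx
}

#' Fill sweep: performance and entropy versus memory content
#'
#' For each number of rows and each fill fraction, fits a quantizer on the
#' training corpus, fills a fresh register with a balanced fraction of the
#' remembered corpus, cues it with every test object (retrieval at
#' \code{sigma}), classifies the retrievals with the nearest-centroid
#' stand-in trained on the training corpus, and records the entropy and
#' the precision/recall/accuracy scores. This traces the entropy
#' trade-off: at low fill the memory rejects most cues (high precision,
#' low recall); past a moderate fill level recall rises and performance is
#' sustained to full fill.
#'
#' @param domain A [generate_domain()] result.
#' @param rows Integer vector of row counts \code{m} to evaluate.
#' @param fractions Fill fractions in \code{(0, 1]}; default the doubling
#'   sequence 1%, 2%, 4%, 8%, 16%, 32%, 64%, 100%.
#' @param sigma Retrieval spread (default 0.1).
#' @param iota,kappa,xi Recognition parameters.
#' @param seed Integer seed governing subsampling and retrieval.
#' @return A data frame of class \code{"fill_sweep"}: one row per
#'   (\code{m}, \code{fraction}) with \code{n_registered},
#'   \code{entropy}, outcome counts and percentage scores.
#' @export
run_fill_sweep <- function(domain, rows = c(4L, 8L, 16L),
                           fractions = c(0.01, 0.02, 0.04, 0.08,
                                         0.16, 0.32, 0.64, 1.00),
                           sigma = 0.1, iota = 0, kappa = 0, xi = 0L,
                           seed = 1L) {
  stopifnot(inherits(domain, "domain"))
  if (any(fractions <= 0 | fractions > 1))
    stop("'fractions' must lie in (0, 1]", call. = FALSE)
  train_x <- domain_features(domain$train)
  rem_x <- domain_features(domain$remember)
  rem_y <- domain_labels(domain$remember)
  test_x <- domain_features(domain$test)
  test_y <- domain_labels(domain$test)
  centroids <- class_centroids(train_x, domain_labels(domain$train))
  res <- list()
  for (m in rows) {
    model <- fit_quantizer(train_x, m)
    for (f in fractions) {
      set.seed(seed + round(1e4 * f) + 131L * m)
      idx <- balanced_subset(rem_y, f)
      a <- amr(ncol(rem_x), m)
      a <- amr_register(a, quantize(model, rem_x[idx, , drop = FALSE]))
      counts <- evaluate_cues(a, model, test_x, test_y, centroids,
                              sigma = sigma, iota = iota, kappa = kappa,
                              xi = xi)
      sc <- score_outcomes(counts["right"], counts["wrong"], counts["none"])
      res[[length(res) + 1L]] <- data.frame(
        m = m, fraction = f, n_registered = length(idx),
        entropy = amr_entropy(a),
        right = counts[["right"]], wrong = counts[["wrong"]],
        none = counts[["none"]],
        precision = sc[["precision"]], recall = sc[["recall"]],
        accuracy = sc[["accuracy"]]
      )
    }
  }
  structure(do.call(rbind, res), class = c("fill_sweep", "data.frame"))
}

#' @export
plot.fill_sweep <- function(x, ...) {
  graphics::matplot(
    log2(100 * x$fraction[x$m == x$m[1]]),
    cbind(sapply(unique(x$m), function(m) x$precision[x$m == m]),
          sapply(unique(x$m), function(m) x$recall[x$m == m])),
    type = "b", pch = 1, xlab = "log2(fill %)", ylab = "percent",
    main = "Precision (upper) and recall vs fill", ...)
  invisible(x)
}

# Per-class mean feature vectors (rows ordered by class id 0..c-1).
class_centroids <- function(x, labels) {
  cls <- sort(unique(labels))
  t(vapply(cls, function(k) colMeans(x[labels == k, , drop = FALSE]),
           numeric(ncol(x))))
}

#' Sigma sweep: class preservation versus retrieval spread
#'
#' Retrieves every cue at each value of \code{sigma} (optionally after
#' corrupting a fraction of its features with uniform noise over the
#' quantizer range) and tabulates the fraction of retrievals keeping the
#' cue's class, assigned another class, or rejected. Small \code{sigma}
#' remembers, moderate \code{sigma} associates, large \code{sigma} images.
#'
#' @param object A filled [amr()].
#' @param model The [fit_quantizer()] used to fill it.
#' @param x,labels Cue feature matrix and class labels.
#' @param centroids Classifier centroids (rows = class ids 0..c-1).
#' @param sigmas Values of sigma to sweep (defaults 0.05–0.5).
#' @param corrupt_fraction Fraction of features replaced by noise before
#'   cueing (0 = clean cues).
#' @param iota,kappa,xi Recognition parameters.
#' @param seed Integer seed.
#' @return Data frame: one row per sigma with fractions \code{preserved},
#'   \code{reassigned}, \code{rejected} (percent) and raw counts.
#' @export
run_sigma_sweep <- function(object, model, x, labels, centroids,
                            sigmas = c(0.05, 0.1, 0.2, 0.3, 0.4, 0.5),
                            corrupt_fraction = 0, iota = 0, kappa = 0,
                            xi = 0L, seed = 1L) {
  stopifnot(inherits(object, "amr"), inherits(model, "quantizer"))
  res <- list()
  for (s in sigmas) {
    set.seed(seed + round(1e4 * s))
    right <- wrong <- none <- 0L
    for (r in seq_len(nrow(x))) {
      xi_r <- x[r, ]
      if (corrupt_fraction > 0)
        xi_r <- corrupt(xi_r, corrupt_fraction, model$lo, model$hi)
      out <- amr_retrieve(object, quantize(model, xi_r), sigma = s,
                          iota = iota, kappa = kappa, xi = xi)
      if (is.null(out)) none <- none + 1L
      else if (nearest_centroid(centroids, dequantize(model, out)) ==
               labels[r]) right <- right + 1L
      else wrong <- wrong + 1L
    }
    total <- right + wrong + none
    res[[length(res) + 1L]] <- data.frame(
      sigma = s, right = right, wrong = wrong, none = none,
      preserved = 100 * right / total, reassigned = 100 * wrong / total,
      rejected = 100 * none / total
    )
  }
  do.call(rbind, res)
}

#' Association chain: recurrent retrieval
#'
#' Starting from a cue, retrieves an object, classifies it, and feeds the
#' retrieved function back as the cue to the next retrieval, repeating up
#' to \code{steps} times. The chain stops at the first rejection. The
#' defaults (\code{sigma = 0.15}, register of 16 rows) are the setting
#' under which chains drift gradually through related classes rather than
#' either reproducing the cue or collapsing into noise.
#'
#' @param object A filled [amr()].
#' @param model The matching [fit_quantizer()].
#' @param cue_x Real-valued feature vector of the initial cue.
#' @param centroids Classifier centroids.
#' @param sigma Retrieval spread (default 0.15).
#' @param steps Maximum chain length (default 6).
#' @param iota,kappa,xi Recognition parameters.
#' @param seed Integer seed.
#' @return An object of class \code{"amr_chain"}: \code{steps} data frame
#'   (\code{step}, \code{class}, \code{rejected}), the list of
#'   \code{retrieved} level vectors, \code{cue_class}, \code{sigma},
#'   \code{length} (number of successful retrievals).
#' @export
run_chain <- function(object, model, cue_x, centroids, sigma = 0.15,
                      steps = 6L, iota = 0, kappa = 0, xi = 0L, seed = 1L) {
  stopifnot(inherits(object, "amr"), inherits(model, "quantizer"))
  set.seed(seed)
  cue_class <- nearest_centroid(centroids, cue_x)
  lev <- quantize(model, cue_x)
  retrieved <- list()
  cls <- integer(0)
  rejected_at <- NA_integer_
  for (s in seq_len(steps)) {
    out <- amr_retrieve(object, lev, sigma = sigma, iota = iota,
                        kappa = kappa, xi = xi)
    if (is.null(out)) {
      rejected_at <- s
      break
    }
    retrieved[[s]] <- out
    cls[s] <- nearest_centroid(centroids, dequantize(model, out))
    lev <- out
  }
  k <- length(retrieved)
  steps_df <- data.frame(
    step = seq_len(if (is.na(rejected_at)) k else k + 1L),
    class = c(cls, if (!is.na(rejected_at)) NA_integer_),
    rejected = c(rep(FALSE, k), if (!is.na(rejected_at)) TRUE)
  )
  structure(list(steps = steps_df, retrieved = retrieved,
                 cue_class = cue_class, sigma = sigma, length = k),
            class = "amr_chain")
}

#' @export
print.amr_chain <- function(x, ...) {
  cat(sprintf("Association chain (sigma = %.3g): cue class %d -> %s%s\n",
              x$sigma, x$cue_class,
              paste(x$steps$class[!x$steps$rejected], collapse = " -> "),
              if (any(x$steps$rejected)) " -> [rejected]" else ""))
  invisible(x)
}

#' K-fold cross-validation of the fill protocol
#'
#' Splits a labelled corpus into \code{k} balanced folds; each fold in
#' turn serves as the test corpus while the remaining folds fill the
#' memory. The quantizer and the classifier centroids are fit on the
#' filling folds. Per-fold seeds are derived deterministically from the
#' master seed.
#'
#' @param x Feature matrix.
#' @param labels Class labels (0-based).
#' @param k Number of folds (default 10).
#' @param m Register rows (default 4).
#' @param sigma Retrieval spread (default 0.1).
#' @param iota,kappa,xi Recognition parameters.
#' @param seed Master seed.
#' @return A list of class \code{"amr_kfold"}: \code{folds} data frame
#'   (per-fold scores and entropy) and \code{summary} (mean and sd of
#'   precision, recall, accuracy).
#' @export
run_kfold <- function(x, labels, k = 10L, m = 4L, sigma = 0.1,
                      iota = 0, kappa = 0, xi = 0L, seed = 1L) {
  if (is.data.frame(x)) x <- as.matrix(x)
  k <- as.integer(k)
  if (k < 2L) stop("'k' must be at least 2", call. = FALSE)
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in sort(unique(labels))) {
    rows <- which(labels == cl)
    fold[rows] <- sample(rep_len(seq_len(k), length(rows)))
  }
  res <- list()
  for (j in seq_len(k)) {
    test_idx <- which(fold == j)
    fill_idx <- which(fold != j)
    model <- fit_quantizer(x[fill_idx, , drop = FALSE], m)
    centroids <- class_centroids(x[fill_idx, , drop = FALSE],
                                 labels[fill_idx])
    a <- amr(ncol(x), m)
    a <- amr_register(a, quantize(model, x[fill_idx, , drop = FALSE]))
    set.seed(seed * 1000L + j)
    counts <- evaluate_cues(a, model, x[test_idx, , drop = FALSE],
                            labels[test_idx], centroids, sigma = sigma,
                            iota = iota, kappa = kappa, xi = xi)
    sc <- score_outcomes(counts["right"], counts["wrong"], counts["none"])
    res[[j]] <- data.frame(fold = j, n_test = length(test_idx),
                           entropy = amr_entropy(a),
                           right = counts[["right"]],
                           wrong = counts[["wrong"]],
                           none = counts[["none"]],
                           precision = sc[["precision"]],
                           recall = sc[["recall"]],
                           accuracy = sc[["accuracy"]])
  }
  folds <- do.call(rbind, res)
  summ <- data.frame(
    metric = c("precision", "recall", "accuracy"),
    mean = c(mean(folds$precision), mean(folds$recall),
             mean(folds$accuracy)),
    sd = c(stats::sd(folds$precision), stats::sd(folds$recall),
           stats::sd(folds$accuracy))
  )
  structure(list(folds = folds, summary = summ), class = "amr_kfold")
}

#' @export
print.amr_kfold <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation\n", nrow(x$folds)))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
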