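#' Persist an associative memory register
#'
#' Writes the register as a directory holding \code{meta.json} (\code{n},
#' \code{m}, \code{l}, \code{format_version}) and \code{weights.csv}
#' (\code{m} rows by \code{n} columns of integers, first row = level 0, no
#' header). The round trip \code{read_amr(write_amr(a, d))} reproduces the
#' register bit-exactly.
#'
#' @param object An [amr()].
#' @param dir Directory path (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_amr <- function(object, dir) {
  stopifnot(inherits(object, "amr"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(n = object$n, m = object$m, l = object$l, format_version = 1L),
    file.path(dir, "meta.json"), auto_unbox = TRUE
  )
  utils::write.table(object$weights, file.path(dir, "weights.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' @rdname write_amr
#' @export
read_amr <- function(dir) {
  meta_path <- file.path(dir, "meta.json")
  w_path <- file.path(dir, "weights.csv")
  if (!file.exists(meta_path) || !file.exists(w_path))
    stop(sprintf("'%s' is not an AMR directory", dir), call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  w <- as.matrix(utils::read.table(w_path, sep = ",", header = FALSE,
                                   colClasses = "integer"))
  dimnames(w) <- NULL
  if (nrow(w) != meta$m || ncol(w) != meta$n)
    stop("weights.csv shape does not match meta.json", call. = FALSE)
  a <- amr(meta$n, meta$m, meta$l)
  a$weights <- w
  a
}

#' Read and write labelled feature corpora
#'
#' The corpus interchange format is a plain CSV with one row per object:
#' \code{n} feature columns followed by a \code{label} column. Any
#' external encoder may produce this file; the pipeline is agnostic to
#' where the features came from.
#'
#' @param df Data frame of features plus a \code{label} column.
#' @param path CSV file path.
#' @return \code{path} invisibly (write); the data frame (read).
#' @export
write_corpus <- function(df, path) {
  stopifnot(is.data.frame(df), "label" %in% names(df))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_corpus
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path)
  if (!"label" %in% names(df))
    stop("corpus file must have a 'label' column", call. = FALSE)
  df
}
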