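#' Score memory responses with a rejection option
#'
#' Every cue belongs to one of the domain classes, so there are no true
#' negatives: a retrieval classified as the cue's class is a right
#' response (true positive); a retrieval classified otherwise is a wrong
#' response (a false positive of the selected class and a false negative
#' of the right one); and a rejection is no response. Consequently
#' precision, recall and accuracy coincide when every cue gets a response,
#' while recall and accuracy fall below precision as cues are rejected:
#' precision = right / (right + wrong), recall = accuracy = right / total.
#' All three are reported as percentages; precision of an all-rejecting
#' memory is defined as 0.
#'
#' @param right Number of responses assigned the cue's class.
#' @param wrong Number of responses assigned another class.
#' @param none Number of rejections.
#' @return Named numeric vector: \code{precision}, \code{recall},
#'   \code{accuracy} (percent), plus the counts.
#' @export
score_outcomes <- function(right, wrong, none) {
  right <- unname(right); wrong <- unname(wrong); none <- unname(none)
  counts <- c(right = right, wrong = wrong, none = none)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers", call. = FALSE)
  total <- sum(counts)
  if (total == 0) stop("no cues evaluated", call. = FALSE)
  responded <- right + wrong
  precision <- if (responded == 0) 0 else 100 * right / responded
  recall <- 100 * right / total
  c(precision = precision, recall = recall, accuracy = recall, counts,
    total = total)
}
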