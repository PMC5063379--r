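# System Usability Scale scoring.
#
# The SUS questionnaire has ten 5-point Likert items. Odd-numbered items are
# positively worded and contribute (rating - 1); even-numbered items are
# negatively worded and contribute (5 - rating); the sum of contributions
# (0..40) is multiplied by 2.5, giving a score between 0 (worst) and 100
# (best imaginable usability), always a multiple of 2.5.

check_sus <- function(r) {
  r <- as.matrix(r)
  if (ncol(r) == 1L && nrow(r) == 10L) r <- t(r)
  if (ncol(r) != 10L)
    stop("SUS responses must have ten ratings per respondent")
  if (!is.numeric(r) || anyNA(r) || any(r != round(r)) ||
      any(r < 1) || any(r > 5))
    stop("SUS ratings must be integers in 1..5")
  r
}

#' SUS score of one or more respondents
#'
#' @param responses a numeric vector of length 10 (one respondent) or a
#'   matrix / data frame with ten columns, one row per respondent; ratings
#'   are integers in 1..5.
#' @return numeric vector of scores in \[0, 100\].
#' @examples
#' sus_score(c(4, 2, 4, 1, 5, 1, 5, 1, 4, 2))  # 87.5
#' @export
sus_score <- function(responses) {
  r <- check_sus(responses)
  odd <- c(1, 3, 5, 7, 9); even <- c(2, 4, 6, 8, 10)
  2.5 * (rowSums(r[, odd, drop = FALSE] - 1) +
         rowSums(5 - r[, even, drop = FALSE]))
}

round_half_up <- function(x, digits) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Summary of a set of SUS responses
#'
#' @param responses matrix or data frame, ten columns, one respondent per
#'   row.
#' @return a `sus_summary`: list with `scores` (per respondent), `mean`
#'   (half-up rounded to 1 decimal), `mean_raw`, `min`, `max`, `n`.
#' @export
sus_summary <- function(responses) {
  r <- check_sus(responses)
  if (nrow(r) == 0L) stop("sus_summary() needs at least one response")
  scores <- sus_score(r)
  structure(list(scores = scores,
                 mean = round_half_up(mean(scores), 1),
                 mean_raw = mean(scores),
                 min = min(scores), max = max(scores), n = length(scores)),
            class = "sus_summary")
}

#' @export
print.sus_summary <- function(x, ...) {
  cat(sprintf("SUS summary of %d response(s): mean %.1f, min %.1f, max %.1f\n",
              x$n, x$mean, x$min, x$max))
  cat("per-respondent scores:", paste(format(x$scores), collapse = ", "),
      "\n")
  invisible(x)
}

#' Read SUS responses from a CSV file
#'
#' The file must contain ten rating columns (any further columns are
#' ignored); a header row is expected.
#'
#' @param path CSV file path.
#' @return integer matrix with ten columns.
#' @export
read_sus <- function(path) {
  df <- utils::read.csv(path)
  num <- df[vapply(df, is.numeric, logical(1))]
  if (ncol(num) < 10L)
    stop(sprintf("%s: expected at least ten numeric rating columns, found %d",
                 basename(path), ncol(num)))
  as.matrix(num[, 1:10])
}

#' Bundled usability-evaluation responses
#'
#' The ten-item SUS ratings of the twelve participants of the final
#' usability-evaluation round of the form-comparison tool, as published.
#'
#' @return integer matrix, 12 x 10.
#' @export
sus_evaluation_data <- function() {
  read_sus(system.file("extdata", "sus_evaluation.csv", package = "odmsim",
                       mustWork = TRUE))
}
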