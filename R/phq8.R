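# PHQ-8 scoring: eight symptom-frequency items reported as day counts over
# the past two weeks (0-14 days), each converted to a 0-3 category, summed
# to a 0-24 total; totals >= 10 indicate probable major depression.

#' Day-count to item-score mapping
#'
#' Builds the threshold table that converts a number of symptom days in the
#' past two weeks (0-14) into a PHQ item score 0-3 ("not at all" to "nearly
#' every day"). `breaks` gives the smallest day count scoring 1, 2 and 3;
#' the default (2, 7, 12) is the BRFSS convention: 0-1 days -> 0, 2-6 -> 1,
#' 7-11 -> 2, 12-14 -> 3. The mapping is configurable because the source
#' survey documentation of the conversion is not always available.
#'
#' @param breaks Increasing integer vector of length 3 within \[1, 14\].
#' @return An object of class `phq8_day_mapping`.
#' @export
phq8_day_mapping <- function(breaks = c(2L, 7L, 12L)) {
  if (!(is.numeric(breaks) && length(breaks) == 3L &&
        all(breaks == round(breaks)) && all(diff(breaks) > 0) &&
        breaks[1] >= 1 && breaks[3] <= 14)) {
    stop_validation("`breaks` must be 3 strictly increasing integers in [1, 14]")
  }
  structure(list(breaks = as.integer(breaks)), class = "phq8_day_mapping")
}

#' @export
print.phq8_day_mapping <- function(x, ...) {
  b <- x$breaks
  cat("PHQ-8 day-count mapping:\n")
  cat(sprintf("  0-%d days -> 0 | %d-%d -> 1 | %d-%d -> 2 | %d-14 -> 3\n",
              b[1] - 1L, b[1], b[2] - 1L, b[2], b[3] - 1L, b[3]))
  invisible(x)
}

#' Score one PHQ-8 item from a day count
#'
#' @param days Integer day counts in \[0, 14\] (vectorised).
#' @param mapping A [phq8_day_mapping()].
#' @return Integer item scores in \[0, 3\].
#' @export
phq8_score_item <- function(days, mapping = phq8_day_mapping()) {
  if (!inherits(mapping, "phq8_day_mapping")) {
    stop_validation("`mapping` must be a phq8_day_mapping")
  }
  if (!is.numeric(days) || anyNA(days) ||
      any(days < 0 | days > 14 | days != round(days))) {
    stop_validation("day counts must be integers in [0, 14]")
  }
  b <- mapping$breaks
  as.integer((days >= b[1]) + (days >= b[2]) + (days >= b[3]))
}

#' Score the PHQ-8 from eight item day counts
#'
#' Converts each item's day count to a 0-3 score, sums to the 0-24 total,
#' and flags probable major depression at total >= `cutoff`. Rows with any
#' missing item are not scored: they come back with `NA` scores and
#' `complete = FALSE`, matching a complete-case analysis in which such
#' respondents are excluded.
#'
#' @param days A data.frame or matrix with eight columns of day counts
#'   (0-14), one row per respondent.
#' @param mapping A [phq8_day_mapping()].
#' @param cutoff Caseness threshold on the total score; default 10.
#' @return A data.frame with the eight item scores (`item1`..`item8`),
#'   `total`, `probable_major_depression` and `complete`.
#' @export
phq8_score <- function(days, mapping = phq8_day_mapping(), cutoff = 10L) {
  days <- as.matrix(days)
  if (ncol(days) != 8L) {
    stop_validation("PHQ-8 responses must have exactly 8 item columns")
  }
  if (nrow(days) == 0L) {
    out <- as.data.frame(matrix(integer(0), 0L, 8L,
                                dimnames = list(NULL, paste0("item", 1:8))))
    out$total <- integer(0)
    out$probable_major_depression <- logical(0)
    out$complete <- logical(0)
    return(out)
  }
  if (!is.numeric(days)) stop_validation("day counts must be numeric")
  ok <- !is.na(days)
  if (any(days[ok] < 0 | days[ok] > 14 | days[ok] != round(days[ok]))) {
    stop_validation("day counts must be integers in [0, 14]")
  }
  complete <- rowSums(ok) == 8L
  scores <- matrix(NA_integer_, nrow(days), 8L,
                   dimnames = list(NULL, paste0("item", 1:8)))
  if (any(complete)) {
    scores[complete, ] <- phq8_score_item(days[complete, , drop = FALSE],
                                          mapping)
  }
  total <- as.integer(rowSums(scores))
  out <- as.data.frame(scores)
  out$total <- total
  out$probable_major_depression <- total >= cutoff
  out$complete <- complete
  out
}
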