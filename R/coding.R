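# Treatment coding: the survey reports lost teeth in four brackets
# ("None", "1 to 5", "6 or more but not all", "All"). The continuous
# treatment assigns one value per bracket (default: the bracket mid-points
# 0, 3, 16.5, 28 of a 28-tooth mouth, wisdom teeth excluded). Dichotomised
# contrasts and user-supplied sensitivity value sets are also supported.

#' Canonical tooth-loss bracket labels
#' @export
tooth_brackets <- function() c("none", "one_to_five", "six_plus_not_all", "all")

#' Construct a treatment coding for the tooth-loss brackets
#'
#' @param values Numeric length-4 vector: the value assigned to each bracket
#'   (none, 1-5, 6+ not all, all). Must be strictly increasing and within
#'   \[0, 28\].
#' @param name Label used for this coding in reports.
#' @return An object of class `tooth_coding`.
#' @export
tooth_coding <- function(values, name = "custom") {
  if (!(is.numeric(values) && length(values) == 4L && all(is.finite(values)))) {
    stop_validation("`values` must be 4 finite numbers")
  }
  if (any(diff(values) <= 0)) {
    stop_validation("coding values must be strictly increasing across brackets")
  }
  if (values[1] < 0 || values[4] > 28) {
    stop_validation("coding values must lie within [0, 28]")
  }
  structure(list(values = as.numeric(values),
                 name = as.character(name)[1]),
            class = "tooth_coding")
}

#' Mid-point coding (0, 3, 16.5, 28)
#'
#' The main-analysis coding: bracket mid-points for a 28-tooth dentition
#' (wisdom teeth not counted, so the "6 or more but not all" bracket spans
#' 6-27 and has mid-point 16.5).
#' @export
midpoint_coding <- function() tooth_coding(c(0, 3, 16.5, 28), name = "midpoint")

#' @export
print.tooth_coding <- function(x, ...) {
  cat(sprintf("Tooth-loss coding '%s': %s\n", x$name,
              paste(sprintf("%s=%g", tooth_brackets(), x$values),
                    collapse = ", ")))
  invisible(x)
}

check_brackets <- function(bracket) {
  bracket <- as.character(bracket)
  bad <- setdiff(unique(bracket[!is.na(bracket)]), tooth_brackets())
  if (length(bad)) {
    stop_validation(sprintf("unknown tooth-loss bracket label(s): %s",
                            paste(bad, collapse = ", ")))
  }
  bracket
}

#' Code brackets to the continuous treatment
#'
#' @param bracket Character vector of bracket labels (see
#'   [tooth_brackets()]).
#' @param coding A [tooth_coding()]; default mid-points.
#' @return Numeric vector of coded numbers of lost teeth.
#' @export
code_continuous <- function(bracket, coding = midpoint_coding()) {
  if (!inherits(coding, "tooth_coding")) {
    stop_validation("`coding` must be a tooth_coding")
  }
  bracket <- check_brackets(bracket)
  coding$values[match(bracket, tooth_brackets())]
}

#' Code brackets to a dichotomised treatment
#'
#' Two contrasts: `"any_loss"` compares >= 1 lost tooth against full
#' dentition (1 for every bracket except "none"); `"edentulous"` compares
#' having lost all teeth against having >= 1 tooth remaining, a comparison
#' defined only among respondents with at least one lost tooth, so the
#' "none" bracket returns `NA` (an exclusion marker, not a value).
#'
#' @param bracket Character vector of bracket labels.
#' @param contrast `"any_loss"` or `"edentulous"`.
#' @return Numeric 0/1 vector, with `NA` marking rows excluded from the
#'   contrast's analysis set.
#' @export
code_binary <- function(bracket, contrast = c("any_loss", "edentulous")) {
  contrast <- match.arg(contrast)
  bracket <- check_brackets(bracket)
  if (contrast == "any_loss") {
    as.numeric(bracket != "none")
  } else {
    out <- as.numeric(bracket == "all")
    out[bracket == "none"] <- NA_real_
    out
  }
}

#' Build named sensitivity codings
#'
#' Re-analysis codings that replace the bracket mid-points with
#' user-supplied value sets (e.g. the mean, median and mode of clinically
#' examined tooth-loss counts from an external validation study; those
#' values are configuration inputs, not package constants).
#'
#' @param value_sets Named list of numeric length-4 vectors, each strictly
#'   increasing within \[0, 28\].
#' @return A list of [tooth_coding()] objects.
#' @export
#' @examples
#' sensitivity_codings(list(mean = c(0, 2, 12, 28)))
sensitivity_codings <- function(value_sets) {
  if (!is.list(value_sets) || is.null(names(value_sets)) ||
      any(!nzchar(names(value_sets)))) {
    stop_validation("`value_sets` must be a named list of length-4 numeric vectors")
  }
  mapply(tooth_coding, value_sets, names(value_sets), SIMPLIFY = FALSE)
}
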