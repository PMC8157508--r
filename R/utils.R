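#' @keywords internal
"_PACKAGE"

# Typed condition helpers -------------------------------------------------

dentiv_stop <- function(class, message, ..., call = sys.call(-1)) {
  cond <- structure(
    class = c(class, "dentiv_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cond)
}

dentiv_warn <- function(class, message, ...) {
  cond <- structure(
    class = c(class, "dentiv_warning", "warning", "condition"),
    list(message = message, call = NULL, ...)
  )
  warning(cond)
}

stop_config     <- function(msg, ...) dentiv_stop("dentiv_config_error", msg, ...)
stop_validation <- function(msg, ...) dentiv_stop("dentiv_validation_error", msg, ...)
stop_lookup     <- function(msg, ...) dentiv_stop("dentiv_lookup_error", msg, ...)
stop_integrity  <- function(msg, ...) dentiv_stop("dentiv_integrity_error", msg, ...)

# Scalar checks -----------------------------------------------------------

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

is_prob <- function(x) is_scalar_num(x) && x >= 0 && x <= 1

check_year_pair <- function(x, what) {
  if (!(is.numeric(x) && length(x) == 2L && all(is.finite(x)) &&
        all(x == round(x)) && x[1] <= x[2])) {
    stop_config(sprintf("`%s` must be an ordered pair of integer years", what))
  }
  as.integer(x)
}
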