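#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats quantile rnorm rbinom plogis qlogis lm glm binomial coef
#'   predict setNames complete.cases sd var weighted.mean pt
#' @importFrom utils head
NULL

# internal: stop with a classed condition so tests can target failures
stop_mrf <- function(msg, class, ...) {
  abort(msg, class = c(class, "mrfalsify_error"), ...)
}

warn_mrf <- function(msg, class) {
  warn(msg, class = c(class, "mrfalsify_warning"))
}

# quote a vector of names for messages
fmt_names <- function(x, max = 5) {
  x <- as.character(x)
  if (length(x) > max) x <- c(head(x, max), "...")
  paste0("'", x, "'", collapse = ", ")
}
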