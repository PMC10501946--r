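#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an instrumental-inequality result
#'
#' @param x An `mr_ineq`.
#' @param ... Unused.
#' @return One row per result: `instrument`, `value`, `violated`,
#'   `argmax_x`, `n_strata`, `min_stratum_weight`.
#' @method tidy mr_ineq
#' @export
tidy.mr_ineq <- function(x, ...) {
  tibble(instrument = x$instrument_label, value = x$value,
         violated = x$violated, argmax_x = x$argmax_x,
         n_strata = x$n_strata, min_stratum_weight = x$min_stratum_weight)
}

#' @rdname tidy.mr_ineq
#' @method glance mr_ineq
#' @export
glance.mr_ineq <- function(x, ...) {
  tibble(value = x$value, violated = x$violated, n_strata = x$n_strata,
         total_weight = x$total_weight)
}

#' Tidy MR-Egger results
#'
#' @param x An `mr_egger`.
#' @param ... Unused.
#' @return `tidy()`: one row per regression term with `estimate`,
#'   `std.error`, `p.value`; `glance()`: one row with the intercept test.
#' @method tidy mr_egger
#' @export
tidy.mr_egger <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope),
         std.error = c(x$intercept_se, x$slope_se),
         p.value = c(x$intercept_p, NA_real_))
}

#' @rdname tidy.mr_egger
#' @method glance mr_egger
#' @export
glance.mr_egger <- function(x, ...) {
  tibble(intercept = x$intercept, intercept_se = x$intercept_se,
         intercept_p = x$intercept_p, slope = x$slope, n_snps = x$n_snps)
}

#' Tidy MR-PRESSO global-test results
#'
#' @param x An `mr_presso`.
#' @param ... Unused.
#' @method tidy mr_presso
#' @export
tidy.mr_presso <- function(x, ...) {
  tibble(rss_observed = x$rss_observed, global_p = x$global_p,
         n_sim = x$n_sim, n_snps = x$n_snps, seed = x$seed)
}

#' @rdname tidy.mr_presso
#' @method glance mr_presso
#' @export
glance.mr_presso <- function(x, ...) tidy(x)

#' Tidy an instrument weight model
#'
#' @param x An `mr_weight_model`.
#' @param ... Unused.
#' @return One row per instrument level with its marginal probability.
#' @method tidy mr_weight_model
#' @export
tidy.mr_weight_model <- function(x, ...) {
  tibble(level = x$instrument_levels, marginal_prob = x$marginal_probs)
}
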