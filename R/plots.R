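#' Plot per-SNP inequality values
#'
#' Dot plot of the marginal instrumental-inequality value for each SNP, with
#' the falsification threshold at 1 marked; values above the line falsify
#' the corresponding single-SNP instrument model.
#'
#' @param marginal A tibble from [evaluate_all_marginal()].
#' @return A ggplot object.
#' @export
plot_marginal_values <- function(marginal) {
  stopifnot(all(c("instrument", "value") %in% names(marginal)))
  marginal <- dplyr::arrange(marginal, .data$value)
  marginal$instrument <- factor(marginal$instrument,
                                levels = marginal$instrument)
  ggplot2::ggplot(marginal,
                  ggplot2::aes(x = .data$value, y = .data$instrument,
                               colour = .data$violated)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "instrumental inequality value", y = NULL,
                  title = "Per-SNP instrumental inequalities",
                  subtitle = "values > 1 falsify the IV model") +
    ggplot2::theme_minimal()
}

#' @method autoplot mr_ineq
#' @export
autoplot.mr_ineq <- function(object, ...) {
  ct <- object$cell_terms
  ct$y <- factor(ct$y)
  ggplot2::ggplot(ct, ggplot2::aes(x = .data$y, y = .data$prob,
                                   fill = .data$z)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "outcome value", y = "max over strata of P(x*, y | z)",
                  fill = "maximizing\nstratum",
                  title = sprintf("%s: value %.3f at exposure category %s",
                                  object$instrument_label, object$value,
                                  object$argmax_x)) +
    ggplot2::theme_minimal()
}

#' Funnel-style scatter of per-SNP associations with the Egger fit
#'
#' @param object An `mr_assoc` tibble.
#' @param egger Optional `mr_egger` fit whose line is overlaid.
#' @param ... Unused.
#' @method autoplot mr_assoc
#' @export
autoplot.mr_assoc <- function(object, egger = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$beta_exp,
                                            y = .data$beta_out)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$beta_out - .data$se_out,
                                        ymax = .data$beta_out + .data$se_out),
                           linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "per-allele exposure association",
                  y = "per-allele outcome association (log-odds)") +
    ggplot2::theme_minimal()
  if (!is.null(egger)) {
    p <- p + ggplot2::geom_abline(intercept = egger$intercept,
                                  slope = egger$slope, colour = "firebrick")
  }
  p
}
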