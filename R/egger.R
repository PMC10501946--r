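#' MR-Egger intercept test
#'
#' Inverse-variance-weighted linear regression (weights `1 / se_out^2`) of
#' the per-SNP instrument–outcome associations on the instrument–exposure
#' associations, with an intercept. Under the instrumental conditions plus
#' the InSIDE, linearity and homogeneity assumptions the intercept is zero;
#' a nonzero intercept indicates directional pleiotropy, so rejecting
#' `intercept = 0` (two-sided t test on `n_snps - 2` degrees of freedom)
#' falsifies the MR model. Applied here in the one-sample setting, where the
#' test is known to be potentially biased; the comparison reproduces that
#' setting rather than correcting it.
#'
#' @param assoc An `mr_assoc` tibble (at least 3 SNPs).
#' @return An `mr_egger`: `intercept`, `intercept_se`, `intercept_p`,
#'   `slope`, `slope_se`, `n_snps`, plus the underlying `lm` fit.
#' @export
egger_intercept_test <- function(assoc) {
  assoc <- new_mr_assoc(assoc)
  if (nrow(assoc) < 3) {
    stop_mrf("MR-Egger needs at least 3 SNPs.", "mrf_validation_error")
  }
  if (var(assoc$beta_exp) == 0) {
    stop_mrf("Degenerate design: no variation in the instrument-exposure associations.",
             "mrf_validation_error")
  }
  w <- 1 / assoc$se_out^2
  fit <- lm(beta_out ~ beta_exp, data = assoc, weights = w)
  cf <- summary(fit)$coefficients
  structure(list(intercept = cf["(Intercept)", "Estimate"],
                 intercept_se = cf["(Intercept)", "Std. Error"],
                 intercept_p = cf["(Intercept)", "Pr(>|t|)"],
                 slope = cf["beta_exp", "Estimate"],
                 slope_se = cf["beta_exp", "Std. Error"],
                 n_snps = nrow(assoc),
                 fit = fit),
            class = "mr_egger")
}

#' @export
print.mr_egger <- function(x, ...) {
  cat(sprintf("<mr_egger> intercept %.4g (SE %.3g, p = %.3g), slope %.4g, %d SNPs\n",
              x$intercept, x$intercept_se, x$intercept_p, x$slope, x$n_snps))
  invisible(x)
}
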