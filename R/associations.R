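#' One-sample per-SNP association estimates
#'
#' Estimates, in the same individuals (the one-sample setting), each SNP's
#' association with the exposure by simple linear regression of the exposure
#' on the allele count, and with the binary outcome by logistic regression
#' of the outcome on the allele count (log-odds per allele). These per-SNP
#' summary statistics are the inputs of the MR-Egger intercept test and the
#' MR-PRESSO global test.
#'
#' @param cohort An `mr_cohort` with complete cases, a numeric exposure and
#'   a binary outcome.
#' @param snps SNP names (default: all declared genotype columns); each SNP
#'   must be polymorphic.
#' @return An `mr_assoc` tibble: `snp`, `beta_exp`, `se_exp`, `beta_out`,
#'   `se_out`.
#' @export
estimate_snp_associations <- function(cohort, snps = NULL) {
  roles <- cohort_roles(cohort)
  if (is.null(snps)) snps <- roles$genotypes
  x <- cohort[[roles$exposure]]
  y <- cohort[[roles$outcome]]
  if (!is.numeric(x)) {
    stop_mrf("Per-SNP association estimation requires a numeric exposure.",
             "mrf_validation_error")
  }
  if (anyNA(x) || anyNA(y)) {
    stop_mrf("Missing exposure or outcome values; apply complete_case_filter() first.",
             "mrf_validation_error")
  }
  rows <- purrr::map_dfr(snps, function(s) {
    g <- cohort[[s]]
    if (anyNA(g)) {
      stop_mrf(sprintf("SNP '%s' has missing genotypes; apply complete_case_filter() first.", s),
               "mrf_validation_error")
    }
    if (var(g) == 0) {
      stop_mrf(sprintf("SNP '%s' is monomorphic; no association estimable.", s),
               "mrf_validation_error")
    }
    lf <- lm(x ~ g)
    ls <- summary(lf)$coefficients
    gf <- suppressWarnings(glm(y ~ g, family = binomial()))
    if (!gf$converged) {
      stop_mrf(sprintf("Logistic fit did not converge for SNP '%s' (possible outcome separation).", s),
               "mrf_convergence_error")
    }
    gs <- summary(gf)$coefficients
    tibble(snp = s,
           beta_exp = ls["g", "Estimate"], se_exp = ls["g", "Std. Error"],
           beta_out = gs["g", "Estimate"], se_out = gs["g", "Std. Error"])
  })
  new_mr_assoc(rows)
}

new_mr_assoc <- function(x) {
  x <- as_tibble(x)
  need <- c("snp", "beta_exp", "se_exp", "beta_out", "se_out")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop_mrf(paste0("Summary statistics need columns: ", fmt_names(missing_cols)),
             "mrf_schema_error")
  }
  if (anyDuplicated(x$snp)) {
    stop_mrf("SNP identifiers must be unique.", "mrf_validation_error")
  }
  if (any(x$se_exp <= 0) || any(x$se_out <= 0)) {
    stop_mrf("Standard errors must be positive.", "mrf_validation_error")
  }
  structure(x, class = c("mr_assoc", class(as_tibble(x))))
}

#' Read / write per-SNP summary statistics
#'
#' Tab-delimited with header columns `snp`, `beta_exp`, `se_exp`,
#' `beta_out`, `se_out`, so the comparator tests can also run on externally
#' supplied summary statistics.
#'
#' @param path File path.
#' @return `read_snp_associations()` returns an `mr_assoc` tibble.
#' @export
read_snp_associations <- function(path) {
  new_mr_assoc(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
}

#' @rdname read_snp_associations
#' @param assoc An `mr_assoc` tibble.
#' @export
write_snp_associations <- function(assoc, path) {
  readr::write_tsv(as_tibble(assoc), path)
  invisible(path)
}
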