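#' Pearl's instrumental inequality statistic
#'
#' For a categorical proposed instrument Z, categorical exposure X and
#' outcome Y, the instrumental conditions imply
#' \deqn{\max_x \sum_y \max_z P(x, y \mid z) \le 1.}
#' This function evaluates the left-hand side on an empirical (or analytic)
#' conditional joint distribution. A value above 1 falsifies the
#' instrumental-variable model — at least one of relevance, exclusion
#' restriction or exchangeability must fail in the dataset; a value at or
#' below 1 is not evidence that the conditions hold. The statistic is always
#' at least \eqn{\max_x P(x)} of the z-marginalized distribution (with
#' equality when Z is independent of (X, Y)) and at most the number of
#' outcome levels. Maxima run over observed strata only; argmax ties break
#' to the lowest category index.
#'
#' @param dist An `mr_joint` from [empirical_conditional_joint()] or
#'   [as_mr_joint()].
#' @param instrument_label Label recorded in the result.
#' @return An `mr_ineq` with fields `value`, `violated` (`value > 1`),
#'   `argmax_x`, `cell_terms` (per outcome value, the maximizing stratum and
#'   its probability at the argmax exposure category), `n_strata`,
#'   `min_stratum_weight` and `instrument_label`.
#' @examples
#' # perfect z-to-(x, y) switching: value 2, violated
#' p <- array(0, c(2, 2, 2))
#' p[1, 1, 1] <- 1  # P(x0, y0 | z0) = 1
#' p[2, 1, 2] <- 1  # P(x0, y1 | z1) = 1
#' pearl_inequality(as_mr_joint(p))$value
#' @export
pearl_inequality <- function(dist, instrument_label = "instrument") {
  stopifnot(inherits(dist, "mr_joint"))
  probs <- dist$probs
  # inner max over z for each (x, y); then sum over y; then max over x
  inner <- apply(probs, c(2, 3), max)
  if (is.null(dim(inner))) inner <- matrix(inner, nrow = length(dist$x_levels))
  x_sums <- rowSums(inner)
  argmax_i <- which.max(x_sums)  # first maximum = lowest category index
  value <- x_sums[[argmax_i]]

  cell_terms <- purrr::map_dfr(seq_along(dist$y_levels), function(j) {
    col <- probs[, argmax_i, j]
    zi <- which.max(col)
    tibble(y = dist$y_levels[[j]], z = dist$z_levels[[zi]],
           prob = col[[zi]])
  })

  structure(list(value = as.numeric(value),
                 violated = value > 1,
                 argmax_x = dist$x_levels[[argmax_i]],
                 cell_terms = cell_terms,
                 n_strata = length(dist$z_levels),
                 min_stratum_weight = min(dist$stratum_weights),
                 total_weight = sum(dist$stratum_weights),
                 instrument_label = instrument_label),
            class = "mr_ineq")
}

#' @export
print.mr_ineq <- function(x, ...) {
  cat(sprintf("<mr_ineq> %s: value %.4f (%s), %d strata, argmax exposure category %s\n",
              x$instrument_label, x$value,
              if (x$violated) "VIOLATED: > 1" else "no violation", x$n_strata,
              x$argmax_x))
  invisible(x)
}

# shared plumbing for the evaluate_* wrappers
eval_inequality <- function(cohort, z, label, weights = NULL) {
  roles <- cohort_roles(cohort)
  if (!("exposure_cat" %in% names(cohort))) {
    stop_mrf("Cohort has no `exposure_cat` column; run prepare_exposure() first.",
             "mrf_schema_error")
  }
  if (is.null(weights)) weights <- cohort[[roles$weight]]
  dist <- empirical_conditional_joint(z = z,
                                      x = cohort$exposure_cat,
                                      y = cohort[[roles$outcome]],
                                      weights = weights)
  pearl_inequality(dist, instrument_label = label)
}

#' Instrumental inequality for a single SNP proposed as instrument
#'
#' The instrument strata are the three genotypes (effect-allele counts 0, 1,
#' 2) of one SNP. A monomorphic SNP yields a single stratum, in which case
#' the statistic reduces to `max_x P(x)` and cannot be violated; a warning is
#' emitted.
#'
#' @param cohort An `mr_cohort` with `exposure_cat` (see
#'   [prepare_exposure()]) and complete cases on the SNP, exposure and
#'   outcome.
#' @param snp Genotype column name.
#' @param weights Optional per-individual weights overriding the cohort
#'   `weight` column (e.g. stabilized IP weights).
#' @return An `mr_ineq`.
#' @export
evaluate_snp_marginal <- function(cohort, snp, weights = NULL) {
  if (!(snp %in% names(cohort))) {
    stop_mrf(paste0("SNP column not in cohort: '", snp, "'"), "mrf_schema_error")
  }
  g <- cohort[[snp]]
  if (anyNA(g)) {
    stop_mrf("Missing genotypes; apply complete_case_filter() first.",
             "mrf_validation_error")
  }
  if (length(unique(g)) == 1) {
    warn_mrf(sprintf("SNP '%s' is monomorphic: single stratum, the inequality reduces to max_x P(x).",
                     snp), "mrf_degenerate_warning")
  }
  eval_inequality(cohort, z = g, label = snp, weights = weights)
}

#' Instrumental inequality for every SNP marginally
#'
#' @inheritParams evaluate_snp_marginal
#' @param snps SNP names; defaults to all declared genotype columns.
#' @return A tibble with one row per SNP: `snp`, `value`, `violated`,
#'   `argmax_x`, `n_strata`, `min_stratum_weight`.
#' @export
evaluate_all_marginal <- function(cohort, snps = NULL, weights = NULL) {
  roles <- cohort_roles(cohort)
  if (is.null(snps)) snps <- roles$genotypes
  purrr::map_dfr(snps, function(s) {
    r <- evaluate_snp_marginal(cohort, s, weights = weights)
    tidy(r)
  })
}

#' Instrumental inequality for a cross-classified SNP set
#'
#' The instrument strata are the observed joint genotype configurations of
#' the SNP set (up to `3^length(snps)`, in practice the configurations seen
#' in the data). Refining the instrument partition can only increase the
#' statistic, and with many SNPs the strata become sparse: near the regime
#' where each individual occupies its own stratum the statistic is trivially
#' inflated and a sparsity warning is raised. `min_stratum` optionally drops
#' strata whose total weight is below the threshold (default 1 = keep all),
#' so sensitivity to sparse strata can be probed explicitly.
#'
#' @inheritParams evaluate_all_marginal
#' @param min_stratum Minimum stratum weight retained (default 1: no
#'   filtering).
#' @return An `mr_ineq`.
#' @export
evaluate_joint_set <- function(cohort, snps = NULL, weights = NULL,
                               min_stratum = 1) {
  roles <- cohort_roles(cohort)
  if (is.null(snps)) snps <- roles$genotypes
  missing_cols <- setdiff(snps, names(cohort))
  if (length(missing_cols) > 0) {
    stop_mrf(paste0("SNP column(s) not in cohort: ", fmt_names(missing_cols)),
             "mrf_schema_error")
  }
  gmat <- as.matrix(as_tibble(cohort)[snps])
  if (anyNA(gmat)) {
    stop_mrf("Missing genotypes; apply complete_case_filter() first.",
             "mrf_validation_error")
  }
  z <- apply(gmat, 1, paste, collapse = "")
  n_strata <- length(unique(z))
  if (n_strata > 0.5 * nrow(gmat)) {
    warn_mrf(sprintf(
      "Joint instrument has %d strata for %d individuals: the statistic is trivially inflated in this sparse regime.",
      n_strata, nrow(gmat)), "mrf_sparsity_warning")
  }
  if (!is.null(weights)) {
    w <- weights
  } else {
    w <- cohort[[roles$weight]]
  }
  if (min_stratum > 1) {
    tot <- tapply(w, z, sum)
    keep <- z %in% names(tot)[tot >= min_stratum]
    cohort <- reattach_roles(as_tibble(cohort)[keep, , drop = FALSE], cohort)
    z <- z[keep]
    w <- w[keep]
  }
  eval_inequality(cohort, z = z,
                  label = paste0("joint(", length(snps), " SNPs)"),
                  weights = w)
}

#' Instrumental inequality for unweighted allele-score categories
#'
#' The instrument strata are the quantile categories (deciles by default) of
#' the unweighted allele score over the SNP set; see [build_allele_score()].
#'
#' @inheritParams evaluate_all_marginal
#' @param k Requested number of score categories.
#' @return An `mr_ineq`; the achieved score category map is attached as the
#'   `score_map` attribute.
#' @export
evaluate_allele_score <- function(cohort, snps = NULL, k = 10, weights = NULL) {
  sc <- build_allele_score(cohort, snps = snps, k = k)
  res <- eval_inequality(cohort, z = sc$category, label = "allele_score",
                         weights = weights)
  attr(res, "score_map") <- sc$map
  res
}

#' Nonparametric bootstrap percentile interval for an inequality value
#'
#' Resamples individuals with replacement and recomputes the statistic.
#' Exploratory only: no consensus exists on formal statistical inference for
#' the instrumental inequalities, so this interval describes sampling
#' variability of the plug-in statistic, not a calibrated test.
#'
#' @param z,x,y,weights As in [empirical_conditional_joint()].
#' @param n_boot Number of bootstrap resamples.
#' @param level Interval coverage (default 0.95).
#' @param seed Integer seed (required, for reproducibility).
#' @return A tibble with `value`, `lower`, `upper`, `n_boot`, `level`.
#' @export
inequality_bootstrap <- function(z, x, y, weights = NULL, n_boot = 200,
                                 level = 0.95, seed) {
  if (missing(seed)) stop_mrf("`seed` is required.", "mrf_validation_error")
  n <- length(z)
  if (is.null(weights)) weights <- rep(1, n)
  obs <- pearl_inequality(empirical_conditional_joint(z, x, y, weights))$value
  set.seed(seed)
  vals <- vapply(seq_len(n_boot), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    pearl_inequality(empirical_conditional_joint(z[i], x[i], y[i], weights[i]))$value
  }, numeric(1))
  alpha <- (1 - level) / 2
  tibble(value = obs,
         lower = unname(quantile(vals, alpha, type = 1)),
         upper = unname(quantile(vals, 1 - alpha, type = 1)),
         n_boot = n_boot, level = level)
}
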