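#' Restrict a cohort to complete cases
#'
#' Drops every individual with a missing value in any required column,
#' mirroring the usual eligibility restriction of one-sample MR analyses to
#' individuals with complete data on the exposure, the outcome and the
#' proposed genetic instruments. Row order is preserved and nothing is
#' imputed.
#'
#' @param cohort An `mr_cohort`.
#' @param required Character vector of required columns. Defaults to the
#'   genotype, exposure and outcome columns declared in the cohort roles.
#' @param quiet Suppress the retained/dropped message.
#' @return The filtered `mr_cohort`; errors if no complete case remains.
#' @export
complete_case_filter <- function(cohort, required = NULL, quiet = FALSE) {
  roles <- cohort_roles(cohort)
  if (is.null(required)) {
    required <- c(roles$genotypes, roles$exposure, roles$outcome)
  }
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols) > 0) {
    stop_mrf(paste0("Required column(s) not in cohort: ", fmt_names(missing_cols)),
             "mrf_schema_error")
  }
  keep <- complete.cases(as_tibble(cohort)[required])
  if (!any(keep)) {
    stop_mrf("No complete cases remain after filtering on the required columns.",
             "mrf_validation_error")
  }
  if (!quiet) {
    inform(sprintf("complete_case_filter: retained %d of %d individuals (%d dropped)",
                   sum(keep), length(keep), sum(!keep)))
  }
  reattach_roles(as_tibble(cohort)[keep, , drop = FALSE], cohort)
}

#' Coarsen a continuous variable into empirical quantile categories
#'
#' Cut points are placed at the (weighted) empirical quantiles i/k,
#' i = 1..k-1, taken as the smallest observed value whose cumulative weight
#' reaches i/k. Intervals are closed on the right, so observations tied at a
#' cut point all fall in the lower category. When cut points coincide (heavy
#' ties, e.g. integer allele scores) the affected categories merge and the
#' achieved number of categories is below `k`; indices are re-labelled
#' contiguously from 1 and every achieved category is non-empty. Because cut
#' points are order statistics, the categorization is invariant under any
#' strictly increasing transform of the values.
#'
#' @param values Numeric vector without missing values.
#' @param k Requested number of categories (default 10, i.e. deciles).
#' @param weights Optional nonnegative weights for the empirical CDF.
#' @return A list with `category` (integer vector in 1..n_categories) and
#'   `map` (an `mr_category_map`: cut points, requested and achieved k).
#' @examples
#' categorize_quantiles(1:100, k = 10)$map$n_categories  # 10
#' @export
categorize_quantiles <- function(values, k = 10, weights = NULL) {
  if (anyNA(values)) {
    stop_mrf("`values` must not contain missing values; complete-case filter first.",
             "mrf_validation_error")
  }
  if (!is.numeric(values) || length(values) == 0) {
    stop_mrf("`values` must be a non-empty numeric vector.", "mrf_validation_error")
  }
  if (k < 2) stop_mrf("`k` must be at least 2.", "mrf_validation_error")
  if (is.null(weights)) weights <- rep(1, length(values))
  if (length(weights) != length(values) || any(weights < 0)) {
    stop_mrf("`weights` must be nonnegative and match `values` in length.",
             "mrf_validation_error")
  }

  if (length(unique(values)) == 1) {
    warn_mrf("Constant vector: a single category is returned.", "mrf_degenerate_warning")
    map <- new_category_map(boundaries = numeric(0), k_requested = k,
                            n_categories = 1L, type = "quantile")
    return(list(category = rep(1L, length(values)), map = map))
  }

  o <- order(values)
  cw <- cumsum(weights[o]) / sum(weights)
  probs <- seq_len(k - 1) / k
  cuts <- vapply(probs, function(p) values[o][which(cw >= p - 1e-12)[1]],
                 numeric(1))
  cuts <- unique(cuts)
  # right-closed intervals: category = 1 + #{cuts < value}
  idx <- findInterval(values, cuts, left.open = TRUE) + 1L
  # collapse any empty trailing/internal categories to contiguous indices
  lev <- sort(unique(idx))
  category <- match(idx, lev)
  map <- new_category_map(boundaries = cuts, k_requested = k,
                          n_categories = length(lev), type = "quantile")
  list(category = as.integer(category), map = map)
}

new_category_map <- function(boundaries, k_requested, n_categories,
                             type = c("quantile", "levels"), levels = NULL) {
  structure(list(boundaries = boundaries, k_requested = as.integer(k_requested),
                 n_categories = as.integer(n_categories),
                 type = match.arg(type), levels = levels),
            class = "mr_category_map")
}

#' @export
print.mr_category_map <- function(x, ...) {
  cat(sprintf("<mr_category_map> %s, %d achieved categories (requested %d)\n",
              x$type, x$n_categories, x$k_requested))
  if (x$type == "quantile") {
    cat("  cut points:", paste(signif(x$boundaries, 6), collapse = ", "), "\n")
  } else {
    cat("  levels:", paste(x$levels, collapse = " < "), "\n")
  }
  invisible(x)
}

#' Serialize a category map to JSON (for reproducibility of cut points)
#' @param map An `mr_category_map`.
#' @param path Optional file to write; otherwise the JSON string is returned.
#' @export
category_map_json <- function(map, path = NULL) {
  js <- jsonlite::toJSON(unclass(map), auto_unbox = TRUE, digits = NA,
                         null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(path))
  }
  js
}

#' Attach a categorical exposure column to a cohort
#'
#' Continuous exposures are coarsened into `k` empirical quantile categories
#' (deciles by default) because the instrumental inequalities apply only to
#' categorical exposures. Factor exposures (e.g. an ordered questionnaire
#' scale such as alcohol-consumption frequency) are passed through verbatim,
#' one category per level in level order.
#'
#' @param cohort An `mr_cohort` (complete cases on the exposure).
#' @param k Number of quantile categories for a continuous exposure.
#' @return The cohort with an integer `exposure_cat` column and the category
#'   map stored in the `exposure_map` attribute.
#' @export
prepare_exposure <- function(cohort, k = 10) {
  roles <- cohort_roles(cohort)
  x <- cohort[[roles$exposure]]
  if (anyNA(x)) {
    stop_mrf("Exposure has missing values; apply complete_case_filter() first.",
             "mrf_validation_error")
  }
  if (is.factor(x)) {
    lev <- levels(droplevels(x))
    category <- match(as.character(x), lev)
    map <- new_category_map(boundaries = numeric(0), k_requested = length(lev),
                            n_categories = length(lev), type = "levels",
                            levels = lev)
  } else if (is.character(x)) {
    stop_mrf("Character exposure: convert to a factor with levels in the intended order first.",
             "mrf_validation_error")
  } else {
    cq <- categorize_quantiles(x, k = k)
    category <- cq$category
    map <- cq$map
  }
  out <- dplyr::mutate(as_tibble(cohort), exposure_cat = as.integer(category))
  out <- reattach_roles(out, cohort)
  attr(out, "exposure_map") <- map
  out
}

#' Unweighted allele score and its quantile categories
#'
#' The unweighted allele score of an individual is the plain sum of
#' effect-allele counts over the SNP set, an integer in `[0, 2 * n_snps]`,
#' and is invariant to the order of the SNPs. Score categories ("deciles"
#' when `k = 10`) come from [categorize_quantiles()]; integer scores tie
#' heavily, so the achieved number of categories is often below `k`.
#'
#' @param cohort An `mr_cohort` with no missing genotypes among `snps`
#'   (apply [complete_case_filter()] first).
#' @param snps SNP (genotype column) names; defaults to all declared
#'   genotype columns.
#' @param k Requested number of score categories.
#' @return A list with `score` (integer), `category` (integer) and `map`.
#' @export
build_allele_score <- function(cohort, snps = NULL, k = 10) {
  roles <- cohort_roles(cohort)
  if (is.null(snps)) snps <- roles$genotypes
  missing_cols <- setdiff(snps, names(cohort))
  if (length(missing_cols) > 0) {
    stop_mrf(paste0("SNP column(s) not in cohort: ", fmt_names(missing_cols)),
             "mrf_schema_error")
  }
  gmat <- as.matrix(as_tibble(cohort)[snps])
  if (anyNA(gmat)) {
    stop_mrf("Missing genotypes in the score SNP set; apply complete_case_filter() first.",
             "mrf_validation_error")
  }
  score <- as.integer(rowSums(gmat))
  if (length(unique(score)) == 1) {
    map <- new_category_map(boundaries = numeric(0), k_requested = k,
                            n_categories = 1L, type = "quantile")
    return(list(score = score, category = rep(1L, length(score)), map = map))
  }
  cq <- categorize_quantiles(as.numeric(score), k = k)
  list(score = score, category = cq$category, map = cq$map)
}
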