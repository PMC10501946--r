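#' End-to-end falsification analysis
#'
#' Runs the selected stages in fixed order on one exposure–outcome model:
#' complete-case restriction, exposure coarsening, per-SNP marginal
#' inequalities, the joint cross-classified SNP set, allele-score
#' categories, an IP-weighted allele-score sensitivity analysis, and the
#' MR-Egger and MR-PRESSO comparators. Returns a one-row summary report in
#' the layout of a falsification table (instrument counts, marginal
#' violation counts, maximum marginal value, allele-score value and flag),
#' with the full per-instrument results attached as attributes.
#'
#' @param cohort An `mr_cohort` (e.g. from [load_cohort()] or
#'   [simulate_cohort()]).
#' @param exposure_name Label for the report row.
#' @param k Number of exposure quantile categories (ignored for factor
#'   exposures) and of allele-score categories.
#' @param snps SNP set (default: all declared genotype columns).
#' @param analyses Subset of `c("marginal", "joint", "allele_score", "ipw",
#'   "egger", "presso")`.
#' @param presso_n_sim,seed MR-PRESSO simulation count and seed; the seed is
#'   required whenever `"presso"` is selected.
#' @param quiet Suppress progress messages.
#' @return An `mr_report` tibble (one row) with attributes `marginal`
#'   (per-SNP tibble), `allele_score`, `allele_score_weighted`, `joint`,
#'   `egger`, `presso` and `log` (character vector of stage messages).
#' @export
run_analysis <- function(cohort, exposure_name = "exposure", k = 10,
                         snps = NULL,
                         analyses = c("marginal", "allele_score"),
                         presso_n_sim = 1000, seed = NULL, quiet = FALSE) {
  known <- c("marginal", "joint", "allele_score", "ipw", "egger", "presso")
  bad <- setdiff(analyses, known)
  if (length(bad) > 0) {
    stop_mrf(paste0("Unknown analysis selection: ", fmt_names(bad)),
             "mrf_schema_error")
  }
  if (length(analyses) == 0) {
    stop_mrf("Select at least one analysis.", "mrf_schema_error")
  }
  if ("presso" %in% analyses && is.null(seed)) {
    stop_mrf("`seed` is required when the MR-PRESSO stage is selected.",
             "mrf_validation_error")
  }
  roles <- cohort_roles(cohort)
  if (is.null(snps)) snps <- roles$genotypes
  log <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log <<- c(log, msg)
    if (!quiet) inform(msg)
  }

  n0 <- nrow(cohort)
  cohort <- complete_case_filter(cohort, quiet = TRUE)
  say("complete cases: %d of %d individuals", nrow(cohort), n0)
  cohort <- prepare_exposure(cohort, k = k)
  emap <- attr(cohort, "exposure_map")
  say("exposure categories achieved: %d (requested %d)", emap$n_categories,
      emap$k_requested)

  marginal <- NULL
  joint <- NULL
  score_res <- NULL
  score_res_w <- NULL
  egger <- NULL
  presso <- NULL

  if ("marginal" %in% analyses) {
    marginal <- evaluate_all_marginal(cohort, snps = snps)
    say("marginal inequalities: %d SNPs, %d violation(s), max value %.4f",
        nrow(marginal), sum(marginal$violated), max(marginal$value))
  }
  if ("joint" %in% analyses) {
    joint <- evaluate_joint_set(cohort, snps = snps)
    say("joint set: value %.4f over %d strata (min stratum weight %.3g)",
        joint$value, joint$n_strata, joint$min_stratum_weight)
  }
  if ("allele_score" %in% analyses || "ipw" %in% analyses) {
    score_res <- evaluate_allele_score(cohort, snps = snps, k = k)
    say("allele score: value %.4f over %d categories", score_res$value,
        score_res$n_strata)
  }
  if ("ipw" %in% analyses) {
    wcohort <- add_ipw_weights(cohort, snps = snps, k = k)
    ws <- attr(wcohort, "weight_summary")
    say("stabilized weights: mean %.3f, range [%.3f, %.3f]", ws$mean, ws$min,
        ws$max)
    score_res_w <- evaluate_allele_score(wcohort, snps = snps, k = k)
    say("weighted allele score: value %.4f", score_res_w$value)
  }
  if (any(c("egger", "presso") %in% analyses)) {
    assoc <- estimate_snp_associations(cohort, snps = snps)
    if ("egger" %in% analyses) {
      egger <- egger_intercept_test(assoc)
      say("MR-Egger intercept %.4g (p = %.3g)", egger$intercept,
          egger$intercept_p)
    }
    if ("presso" %in% analyses) {
      presso <- presso_global_test(assoc, n_sim = presso_n_sim, seed = seed)
      say("MR-PRESSO global p = %.4g (%d simulations, seed %d)",
          presso$global_p, presso$n_sim, presso$seed)
    }
  }

  report <- tibble(
    exposure = exposure_name,
    n_proposed_instruments = length(snps),
    n_marginal_violations = if (is.null(marginal)) NA_integer_ else sum(marginal$violated),
    max_marginal_value = if (is.null(marginal)) NA_real_ else max(marginal$value),
    allele_score_violated = if (is.null(score_res)) NA else score_res$violated,
    allele_score_value = if (is.null(score_res)) NA_real_ else score_res$value,
    joint_value = if (is.null(joint)) NA_real_ else joint$value,
    allele_score_value_weighted = if (is.null(score_res_w)) NA_real_ else score_res_w$value,
    allele_score_violated_weighted = if (is.null(score_res_w)) NA else score_res_w$violated
  )
  structure(report,
            class = c("mr_report", class(report)),
            marginal = marginal, joint = joint, allele_score = score_res,
            allele_score_weighted = score_res_w, egger = egger,
            presso = presso, log = log)
}

#' Write a falsification report
#'
#' Writes the per-exposure falsification summary as delimited text with a
#' fixed column order and values printed to 2 decimal places, plus a JSON
#' companion (same stem, `.json` extension) retaining full precision.
#'
#' @param report An `mr_report` (rows from one or more [run_analysis()]
#'   calls bound together).
#' @param path Output path for the delimited file (`.tsv` for tabs,
#'   otherwise comma-delimited).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (is.null(report) || nrow(report) == 0) {
    stop_mrf("Report is empty.", "mrf_validation_error")
  }
  cols <- c("exposure", "n_proposed_instruments", "n_marginal_violations",
            "max_marginal_value", "allele_score_violated",
            "allele_score_value", "joint_value",
            "allele_score_value_weighted", "allele_score_violated_weighted")
  report <- as_tibble(report)
  missing_cols <- setdiff(cols[1:6], names(report))
  if (length(missing_cols) > 0) {
    stop_mrf(paste0("Report lacks column(s): ", fmt_names(missing_cols)),
             "mrf_schema_error")
  }
  out <- report[intersect(cols, names(report))]
  disp <- dplyr::mutate(out, dplyr::across(dplyr::where(is.numeric),
                                           ~ round(.x, 2)))
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(disp, path, delim = delim, na = "")
  json_path <- paste0(sub("\\.[[:alnum:]]+$", "", path), ".json")
  jsonlite::write_json(out, json_path, auto_unbox = FALSE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Read back the full-precision JSON companion of a report
#' @param path Path to the delimited report written by [write_report()]
#'   (or directly to its `.json` companion).
#' @export
read_report_json <- function(path) {
  if (!grepl("\\.json$", path)) {
    path <- paste0(sub("\\.[[:alnum:]]+$", "", path), ".json")
  }
  as_tibble(jsonlite::fromJSON(path))
}
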