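#' Cohort tables: the tabular currency of the falsification pipeline
#'
#' An `mr_cohort` is a tibble of per-individual records carrying column-role
#' metadata: which columns hold biallelic genotypes (effect-allele counts in
#' 0/1/2), which holds the exposure, which the binary outcome, and which are
#' covariates (e.g. principal components). A `weight` column (default 1) is
#' used by the inverse-probability-weighted analyses. All downstream verbs
#' (`complete_case_filter()`, `prepare_exposure()`, `evaluate_snp_marginal()`,
#' ...) take an `mr_cohort` first and return tibbles, so calls chain with the
#' pipe.
#'
#' @param data A data frame of per-individual records.
#' @param genotypes Character vector of genotype column names. Values must be
#'   0, 1, 2 or missing (count of the designated effect allele).
#' @param exposure Name of the exposure column (numeric, or a factor for an
#'   ordered categorical exposure such as a questionnaire frequency scale).
#' @param outcome Name of the binary outcome column (0/1).
#' @param covariates Optional character vector of covariate column names
#'   (numeric, e.g. principal components).
#' @param id Optional name of an identifier column; if absent a sequential
#'   `id` column is added.
#' @param weight Optional name of a nonnegative per-individual weight column;
#'   if absent a unit `weight` column is added.
#'
#' @return A tibble with class `mr_cohort` and a `roles` attribute naming the
#'   genotype, exposure, outcome, covariate, id and weight columns.
#' @examples
#' df <- tibble::tibble(g1 = c(0, 1, 2), g2 = c(1, 1, 0),
#'                      bmi = c(21.2, 25.7, 30.1), chd = c(0, 0, 1))
#' ch <- as_mr_cohort(df, genotypes = c("g1", "g2"),
#'                    exposure = "bmi", outcome = "chd")
#' cohort_roles(ch)$genotypes
#' @export
as_mr_cohort <- function(data, genotypes, exposure, outcome,
                         covariates = character(), id = NULL, weight = NULL) {
  data <- as_tibble(data)
  declared <- c(genotypes, exposure, outcome, covariates, id, weight)
  missing_cols <- setdiff(declared, names(data))
  if (length(missing_cols) > 0) {
    stop_mrf(paste0("Unknown column(s) in schema: ", fmt_names(missing_cols)),
             "mrf_schema_error")
  }
  if (length(exposure) != 1 || length(outcome) != 1) {
    stop_mrf("Schema must name exactly one exposure and one outcome column.",
             "mrf_schema_error")
  }
  if (length(genotypes) < 1) {
    stop_mrf("Schema must name at least one genotype column.",
             "mrf_schema_error")
  }

  for (g in genotypes) {
    v <- data[[g]]
    bad <- which(!is.na(v) & !(v %in% c(0, 1, 2)))
    if (length(bad) > 0) {
      stop_mrf(sprintf(
        "Genotype column '%s' has value outside {0, 1, 2} at row %d (value %s).",
        g, bad[1], format(v[bad[1]])), "mrf_validation_error")
    }
    data[[g]] <- as.integer(v)
  }
  y <- data[[outcome]]
  if (!all(is.na(y) | y %in% c(0, 1))) {
    bad <- which(!is.na(y) & !(y %in% c(0, 1)))
    stop_mrf(sprintf(
      "Outcome column '%s' must be binary 0/1; row %d has value %s.",
      outcome, bad[1], format(y[bad[1]])), "mrf_validation_error")
  }
  data[[outcome]] <- as.integer(y)

  if (is.null(id)) {
    if ("id" %in% names(data)) {
      id <- "id"
    } else {
      data <- dplyr::mutate(data, id = as.character(dplyr::row_number()),
                            .before = 1)
      id <- "id"
    }
  }
  if (is.null(weight)) {
    if (!("weight" %in% names(data))) data$weight <- 1
    weight <- "weight"
  }
  w <- data[[weight]]
  if (any(!is.na(w) & w < 0)) {
    stop_mrf("Weights must be nonnegative.", "mrf_validation_error")
  }
  data[[id]] <- as.character(data[[id]])

  structure(data,
            class = c("mr_cohort", class(as_tibble(data))),
            roles = list(genotypes = genotypes, exposure = exposure,
                         outcome = outcome, covariates = covariates,
                         id = id, weight = weight))
}

#' @rdname as_mr_cohort
#' @param x An `mr_cohort`.
#' @export
cohort_roles <- function(x) {
  roles <- attr(x, "roles", exact = TRUE)
  if (is.null(roles)) {
    stop_mrf("Not an mr_cohort: no column roles attached. Use as_mr_cohort() or load_cohort().",
             "mrf_schema_error")
  }
  roles
}

#' @export
print.mr_cohort <- function(x, ...) {
  roles <- cohort_roles(x)
  cat(sprintf("<mr_cohort> %d individuals, %d SNP(s), exposure '%s', outcome '%s'\n",
              nrow(x), length(roles$genotypes), roles$exposure, roles$outcome))
  if (length(roles$covariates) > 0) {
    cat(sprintf("  covariates: %s\n", fmt_names(roles$covariates)))
  }
  NextMethod()
}

# keep roles across dplyr verbs that preserve attributes poorly
reattach_roles <- function(new, old) {
  structure(as_tibble(new),
            class = c("mr_cohort", class(as_tibble(new))),
            roles = cohort_roles(old))
}

#' Read a genotype/phenotype table into a cohort
#'
#' Reads a delimited table (comma or tab, sniffed from the first line, with
#' header) or a VCF file, and attaches the column roles. Missing genotype or
#' phenotype values are preserved as missing; nothing is imputed — apply
#' [complete_case_filter()] before analysis. For VCF input only biallelic
#' sites are accepted and genotypes are coded as ALT-allele counts; phenotype
#' columns must then be supplied via `phenotypes`.
#'
#' @param path Path to a delimited text file or a VCF (`.vcf`).
#' @param genotypes,exposure,outcome,covariates,id,weight Column roles, as in
#'   [as_mr_cohort()]. For delimited input `genotypes` defaults to every
#'   column not otherwise assigned. For VCF input `genotypes` defaults to all
#'   sites in the file.
#' @param phenotypes For VCF input: a data frame with one row per sample in
#'   VCF sample order (or with an id column matching the VCF sample names)
#'   holding exposure/outcome/covariate columns.
#' @return An [as_mr_cohort()] tibble.
#' @export
load_cohort <- function(path, genotypes = NULL, exposure, outcome,
                        covariates = character(), id = NULL, weight = NULL,
                        phenotypes = NULL) {
  if (!file.exists(path)) {
    stop_mrf(paste0("File not found: ", path), "mrf_io_error")
  }
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    geno <- read_vcf_genotypes(path)
    if (is.null(phenotypes)) {
      stop_mrf("VCF input carries genotypes only; supply `phenotypes` with exposure/outcome columns.",
               "mrf_schema_error")
    }
    phenotypes <- as_tibble(phenotypes)
    if (!is.null(id) && id %in% names(phenotypes)) {
      m <- match(geno$sample, phenotypes[[id]])
      if (anyNA(m)) {
        stop_mrf("Some VCF samples are absent from `phenotypes`.", "mrf_schema_error")
      }
      phenotypes <- phenotypes[m, ]
    } else if (nrow(phenotypes) != nrow(geno)) {
      stop_mrf("`phenotypes` must have one row per VCF sample.", "mrf_schema_error")
    }
    df <- dplyr::bind_cols(geno, phenotypes[setdiff(names(phenotypes), names(geno))])
    if (is.null(genotypes)) genotypes <- setdiff(names(geno), "sample")
    if (is.null(id)) id <- "sample"
  } else {
    first <- readLines(path, n = 1)
    delim <- if (grepl("\t", first)) "\t" else ","
    df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
    if (is.null(genotypes)) {
      genotypes <- setdiff(names(df), c(exposure, outcome, covariates, id,
                                        weight, "id", "weight"))
    }
  }
  as_mr_cohort(df, genotypes = genotypes, exposure = exposure,
               outcome = outcome, covariates = covariates, id = id,
               weight = weight)
}

#' Write a cohort back to delimited text
#'
#' Round-trips with [load_cohort()]: column roles are not stored in the file,
#' so pass the same schema when re-reading.
#'
#' @param cohort An `mr_cohort`.
#' @param path Output path; `.tsv` extension writes tab-delimited, anything
#'   else comma-delimited.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  delim <- if (grepl("\\.tsv$", path)) "\t" else ","
  readr::write_delim(as_tibble(cohort), path, delim = delim, na = "")
  invisible(path)
}
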