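#' Specify a synthetic MR cohort
#'
#' The generator emulates the structure of a biobank-style one-sample MR
#' dataset: independent biallelic SNPs in Hardy–Weinberg proportions within
#' each of up to two subpopulations, a continuous exposure with per-allele
#' genetic effects and an unmeasured standard-normal confounder, and a
#' binary (coronary-artery-disease-like) outcome from a logistic model.
#' Controllable departures from the instrumental conditions: per-SNP direct
#' (pleiotropic) genotype-to-outcome log-odds effects `pi`; population
#' stratification (subpopulation-specific allele frequencies plus a
#' subpopulation outcome shift, with the subpopulation label leaked only
#' through noisy principal-component-like covariates); and selection on
#' exposure, outcome and genotypes.
#'
#' Model: `exposure = intercept + sum_j alpha_j G_j + gamma_u U + N(0, sd)`;
#' `outcome ~ Bernoulli(plogis(beta0 + beta_x exposure + delta_u U +
#' sum_j pi_j G_j + shift[subpop]))`.
#'
#' @param n Number of individuals (before selection).
#' @param snps A data frame with one row per SNP: `maf` (allele frequency in
#'   subpopulation A), optional `maf_b` (subpopulation B; defaults to
#'   `maf`), `alpha` (per-allele exposure effect) and `pi` (per-allele
#'   direct outcome log-odds effect).
#' @param exposure_intercept,gamma_u,exposure_sd Exposure model: intercept,
#'   confounder effect and residual SD.
#' @param exposure_digits Optional number of decimal places the recorded
#'   exposure is rounded to, emulating heaped or coarsely measured
#'   phenotypes (questionnaire scales, low-precision assays). `NULL` (the
#'   default) records the exposure exactly; heaping makes quantile
#'   categories tie and collapse, as coarse real phenotypes do.
#' @param beta0,beta_x,delta_u Outcome model: intercept, exposure log-odds
#'   effect and confounder log-odds effect.
#' @param strat_prop Probability of membership in subpopulation B (0 = one
#'   population).
#' @param strat_shift Subpopulation-B outcome log-odds shift.
#' @param n_pcs Number of emitted principal-component-like covariates (each
#'   is the subpopulation indicator plus `N(0, pc_sd)` noise).
#' @param pc_sd Noise SD of the PC-like covariates.
#' @param selection Optional named list `list(intercept =, on_exposure =,
#'   on_outcome =, on_genotypes =)` giving a logistic inclusion model;
#'   individuals are dropped with probability `1 - plogis(...)`.
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @return An `mr_sim_config`.
#' @export
sim_config <- function(n,
                       snps,
                       exposure_intercept = 0, gamma_u = 0, exposure_sd = 1,
                       exposure_digits = NULL,
                       beta0 = 0, beta_x = 0, delta_u = 0,
                       strat_prop = 0, strat_shift = 0,
                       n_pcs = 0, pc_sd = 1,
                       selection = NULL,
                       seed) {
  if (missing(seed)) stop_mrf("`seed` is required.", "mrf_validation_error")
  snps <- as_tibble(snps)
  if (!("maf" %in% names(snps))) {
    stop_mrf("`snps` needs a `maf` column.", "mrf_schema_error")
  }
  if (!("maf_b" %in% names(snps))) snps$maf_b <- snps$maf
  if (!("alpha" %in% names(snps))) snps$alpha <- 0
  if (!("pi" %in% names(snps))) snps$pi <- 0
  if (any(snps$maf <= 0 | snps$maf >= 1 | snps$maf_b <= 0 | snps$maf_b >= 1)) {
    stop_mrf("Allele frequencies must lie strictly in (0, 1).", "mrf_validation_error")
  }
  if (n < 1) stop_mrf("`n` must be at least 1.", "mrf_validation_error")
  structure(list(n = as.integer(n), snps = snps,
                 exposure_intercept = exposure_intercept, gamma_u = gamma_u,
                 exposure_sd = exposure_sd, exposure_digits = exposure_digits,
                 beta0 = beta0, beta_x = beta_x, delta_u = delta_u,
                 strat_prop = strat_prop, strat_shift = strat_shift,
                 n_pcs = as.integer(n_pcs), pc_sd = pc_sd,
                 selection = selection, seed = as.integer(seed)),
            class = "mr_sim_config")
}

#' Read a simulation configuration from YAML or JSON
#' @param path Path to a `.yaml`/`.yml` or `.json` file whose keys mirror
#'   the arguments of [sim_config()] (`snps` as a list of records).
#' @return An `mr_sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop_mrf(paste0("File not found: ", path), "mrf_io_error")
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  }
  # YAML 1.1 implicitly types an unquoted `n` key as a boolean
  names(cfg)[names(cfg) %in% c("FALSE", "no")] <- "n"
  cfg$snps <- as_tibble(as.data.frame(cfg$snps))
  do.call(sim_config, cfg)
}

#' Generate a synthetic cohort
#'
#' Draws a cohort from an [sim_config()] specification. All draws follow a
#' fixed order (subpopulation, genotypes SNP by SNP, confounder, exposure
#' noise, outcome, PC noise, selection), so a given seed reproduces the
#' cohort exactly.
#'
#' @param config An `mr_sim_config`.
#' @return An `mr_cohort` with genotype columns `g1..gJ`, `exposure`,
#'   `outcome` and, when `n_pcs > 0`, covariates `pc1..pcM`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "mr_sim_config"))
  set.seed(config$seed)
  n <- config$n
  J <- nrow(config$snps)

  s <- if (config$strat_prop > 0) rbinom(n, 1, config$strat_prop) else integer(n)

  G <- matrix(0L, n, J)
  for (j in seq_len(J)) {
    p <- ifelse(s == 1, config$snps$maf_b[j], config$snps$maf[j])
    G[, j] <- rbinom(n, 2, p)
  }
  colnames(G) <- paste0("g", seq_len(J))

  U <- rnorm(n)
  exposure <- config$exposure_intercept +
    as.numeric(G %*% config$snps$alpha) +
    config$gamma_u * U +
    rnorm(n, 0, config$exposure_sd)
  if (!is.null(config$exposure_digits)) {
    exposure <- round(exposure, config$exposure_digits)
  }

  eta <- config$beta0 + config$beta_x * exposure + config$delta_u * U +
    as.numeric(G %*% config$snps$pi) + config$strat_shift * s
  y <- rbinom(n, 1, plogis(eta))
  if (all(y == 0) || all(y == 1)) {
    stop_mrf("Logistic model saturated: all outcomes identical. Use smaller effects or intercept.",
             "mrf_validation_error")
  }

  df <- dplyr::bind_cols(tibble(id = as.character(seq_len(n))),
                         as_tibble(G),
                         tibble(exposure = exposure, outcome = y))
  covs <- character(0)
  if (config$n_pcs > 0) {
    PC <- matrix(rnorm(n * config$n_pcs, sd = config$pc_sd), n, config$n_pcs) + s
    colnames(PC) <- paste0("pc", seq_len(config$n_pcs))
    df <- dplyr::bind_cols(df, as_tibble(PC))
    covs <- colnames(PC)
  }

  if (!is.null(config$selection)) {
    sel <- config$selection
    lin <- (sel$intercept %||% 0) +
      (sel$on_exposure %||% 0) * exposure +
      (sel$on_outcome %||% 0) * y
    if (!is.null(sel$on_genotypes)) {
      lin <- lin + as.numeric(G %*% rep_len(sel$on_genotypes, J))
    }
    keep <- rbinom(n, 1, plogis(lin)) == 1
    if (!any(keep)) {
      stop_mrf("Selection removed every individual.", "mrf_validation_error")
    }
    df <- df[keep, , drop = FALSE]
  }

  as_mr_cohort(df, genotypes = colnames(G), exposure = "exposure",
               outcome = "outcome", covariates = covs, id = "id")
}

#' Exact joint distributions realizing known inequality values
#'
#' Small analytic fixtures for testing the inequality engine against known
#' population values: `"switching"` is the deterministic law where the
#' instrument flips (exposure, outcome) jointly (binary everything,
#' statistic exactly 2); `"null"` is a z-independent uniform law over binary
#' (x, y) (statistic `max_x P(x) = 0.5`); `"confounded"` is a 2x2x2 law with
#' strong z-linked dependence between x and y whose statistic exceeds 1
#' (1.6, verifiable by exhaustive evaluation).
#'
#' @param kind One of `"switching"`, `"null"`, `"confounded"`.
#' @return An `mr_joint`.
#' @export
make_violation_distribution <- function(kind = c("switching", "null", "confounded")) {
  kind <- match.arg(kind)
  p <- array(0, c(2, 2, 2),
             dimnames = list(z = c("0", "1"), x = c("0", "1"), y = c("0", "1")))
  if (kind == "switching") {
    p["0", "0", "0"] <- 1
    p["1", "0", "1"] <- 1
  } else if (kind == "null") {
    p[] <- 0.25
  } else {
    p["0", "0", "0"] <- 0.8
    p["0", "1", "1"] <- 0.2
    p["1", "0", "1"] <- 0.8
    p["1", "1", "0"] <- 0.2
  }
  as_mr_joint(p)
}
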