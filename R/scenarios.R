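#' Canonical simulation scenarios
#'
#' Three fixed generative settings used throughout the package's tests and
#' examples. Each returns an [sim_config()]; pass it to
#' [simulate_cohort()].
#'
#' `config_valid_iv()` is the benchmark null: 15 independent SNPs (MAF 0.3)
#' acting on a continuous exposure (0.5 units/allele, residual SD 1) that is
#' confounded with a roughly 10%-prevalence binary outcome by an unmeasured
#' standard-normal confounder. The genotypes satisfy the instrumental
#' conditions exactly, so the population inequality value is
#' `max_x P(x) <= 1` for every proposed instrument.
#'
#' `config_pleiotropy()` is the detection-power setting: a coarsely measured
#' (integer-heaped) exposure driven by 15 SNPs of modest effect (0.25
#' units/allele); 5 of them — the commoner ones (MAF 0.5, against MAF 0.1
#' for the remaining 10) — carry a direct per-allele log-odds effect
#' `pleiotropy_pi` on the outcome. Heaping makes the achieved exposure
#' categories unequal in mass, which is what lets the allele-score
#' inequality respond to pleiotropy: outcome risk then switches between
#' score categories nested inside one exposure category. The outcome
#' intercept is offset by `-5 * pleiotropy_pi` so that disease prevalence
#' stays comparable across a pleiotropy grid.
#'
#' `config_stratification()` is the population-structure setting with no
#' pleiotropy: two equally mixed subpopulations whose allele-frequency gap
#' (0.2 vs 0.4) is concentrated on the seven weak-effect SNPs (0.05
#' units/allele, against 0.4 for the eight strong ones), plus a
#' subpopulation outcome log-odds shift of 5. Members of the shifted
#' subpopulation thus reach high allele scores without high exposure, so
#' score strata within one exposure category mix the subpopulations in
#' different proportions — a genuine confounding violation that
#' inverse-probability weighting on the 10 emitted PC-like covariates
#' removes.
#'
#' @param n Cohort size.
#' @param seed Integer seed.
#' @param pleiotropy_pi Per-allele direct outcome log-odds effect on the 5
#'   pleiotropic SNPs (`config_pleiotropy()` only).
#' @return An `mr_sim_config`.
#' @export
config_valid_iv <- function(n = 50000, seed) {
  snps <- tibble(maf = rep(0.3, 15), alpha = 0.5, pi = 0)
  mean_expo <- sum(2 * snps$maf * snps$alpha)
  sim_config(n = n, snps = snps,
             gamma_u = 0.4, exposure_sd = 1,
             beta0 = -0.3 * mean_expo - 2.2, beta_x = 0.3, delta_u = 0.6,
             seed = seed)
}

#' @rdname config_valid_iv
#' @export
config_pleiotropy <- function(n = 50000, pleiotropy_pi = 0, seed) {
  snps <- tibble(maf = c(rep(0.5, 5), rep(0.1, 10)),
                 alpha = 0.25,
                 pi = c(rep(pleiotropy_pi, 5), rep(0, 10)))
  mean_expo <- sum(2 * snps$maf * snps$alpha)
  sim_config(n = n, snps = snps,
             gamma_u = 0.2, exposure_sd = 0.3, exposure_digits = 0,
             beta0 = -0.3 * mean_expo - 5 * pleiotropy_pi + 1,
             beta_x = 0.3, delta_u = 0.4,
             seed = seed)
}

#' @rdname config_valid_iv
#' @export
config_stratification <- function(n = 50000, seed) {
  prop <- 0.5
  shift <- 5
  snps <- tibble(maf = rep(0.2, 15),
                 maf_b = c(rep(0.2, 8), rep(0.4, 7)),
                 alpha = c(rep(0.4, 8), rep(0.05, 7)),
                 pi = 0)
  mean_expo <- sum(2 * snps$alpha * ((1 - prop) * snps$maf + prop * snps$maf_b))
  sim_config(n = n, snps = snps,
             gamma_u = 0.2, exposure_sd = 0.3, exposure_digits = 0,
             beta0 = -0.3 * mean_expo - shift * prop + 0.5,
             beta_x = 0.3, delta_u = 0.4,
             strat_prop = prop, strat_shift = shift, n_pcs = 10, pc_sd = 1,
             seed = seed)
}

#' Simulate per-SNP summary statistics directly
#'
#' Generates the two-regression summary statistics that the MR-Egger and
#' MR-PRESSO tests consume, without an individual-level cohort: per-SNP
#' exposure associations are drawn once around `beta_exp_mean`, the true
#' outcome association of SNP j is `theta * beta_exp_j + pleiotropy_j`, and
#' the observed estimates add the sampling noise implied by the standard
#' errors. Pleiotropy with nonzero mean is directional (shifts the Egger
#' intercept); zero-mean ("balanced") pleiotropy inflates heterogeneity
#' without moving the intercept.
#'
#' @param n_snps Number of SNPs.
#' @param theta True exposure-to-outcome effect (log-odds per exposure
#'   unit).
#' @param beta_exp_mean,beta_exp_sd Distribution of true per-allele
#'   exposure effects.
#' @param se_exp,se_out Standard errors of the per-SNP estimates.
#' @param pleiotropy_mean,pleiotropy_sd Distribution of per-SNP direct
#'   outcome effects.
#' @param seed Integer seed.
#' @return An `mr_assoc` tibble.
#' @export
sim_snp_associations <- function(n_snps = 50, theta = 0.2,
                                 beta_exp_mean = 0.15, beta_exp_sd = 0.05,
                                 se_exp = 0.01, se_out = 0.02,
                                 pleiotropy_mean = 0, pleiotropy_sd = 0,
                                 seed) {
  if (missing(seed)) stop_mrf("`seed` is required.", "mrf_validation_error")
  set.seed(seed)
  bx_true <- rnorm(n_snps, beta_exp_mean, beta_exp_sd)
  pleio <- rnorm(n_snps, pleiotropy_mean, pleiotropy_sd)
  by_true <- theta * bx_true + pleio
  new_mr_assoc(tibble(
    snp = sprintf("rs%04d", seq_len(n_snps)),
    beta_exp = rnorm(n_snps, bx_true, se_exp),
    se_exp = se_exp,
    beta_out = rnorm(n_snps, by_true, se_out),
    se_out = se_out))
}
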