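test_that("null-effect cohorts follow Hardy-Weinberg proportions", {
  cfg <- sim_config(n = 100000, snps = tibble::tibble(maf = rep(0.3, 3)),
                    beta0 = -1, seed = 101)
  ch <- simulate_cohort(cfg)
  freq <- table(ch$g1) / nrow(ch)
  hwe <- c(0.49, 0.42, 0.09)
  se <- sqrt(hwe * (1 - hwe) / nrow(ch))
  expect_true(all(abs(as.numeric(freq) - hwe) < 4 * se))
  expect_lt(abs(cor(ch$exposure, ch$g1)), 0.015)
})

test_that("per-allele exposure effects are recovered by regression", {
  cfg <- sim_config(n = 100000,
                    snps = tibble::tibble(maf = 0.3, alpha = 0.5),
                    exposure_sd = 1, beta0 = -1, seed = 103)
  ch <- simulate_cohort(cfg)
  fit <- summary(lm(exposure ~ g1, data = ch))$coefficients
  expect_lt(abs(fit["g1", "Estimate"] - 0.5), 3 * fit["g1", "Std. Error"])
})

test_that("cohorts are bit-identical under a fixed seed", {
  cfg <- config_stratification(n = 2000, seed = 107)
  ch1 <- simulate_cohort(cfg)
  ch2 <- simulate_cohort(cfg)
  expect_identical(tibble::as_tibble(ch1), tibble::as_tibble(ch2))
})

test_that("saturated outcome models and bad configs are rejected", {
  expect_error(simulate_cohort(
    sim_config(n = 200, snps = tibble::tibble(maf = 0.3), beta0 = 50,
               seed = 1)),
    class = "mrf_validation_error")
  expect_error(sim_config(n = 10, snps = tibble::tibble(maf = 1.2), seed = 1),
               class = "mrf_validation_error")
  expect_error(sim_config(n = 10, snps = tibble::tibble(alpha = 1), seed = 1),
               class = "mrf_schema_error")
})

test_that("selection drops rows according to its logistic model", {
  snps <- tibble::tibble(maf = rep(0.3, 2))
  cfg <- sim_config(n = 20000, snps = snps, beta0 = -1,
                    selection = list(intercept = 0, on_exposure = 1),
                    seed = 109)
  ch <- simulate_cohort(cfg)
  expect_lt(nrow(ch), 20000)
  # inclusion increases with exposure, so the kept sample is shifted up
  cfg0 <- sim_config(n = 20000, snps = snps, beta0 = -1, seed = 109)
  ch0 <- simulate_cohort(cfg0)
  expect_gt(mean(ch$exposure), mean(ch0$exposure) + 0.1)
})

test_that("stratified cohorts leak the subpopulation only through PCs", {
  cfg <- config_stratification(n = 5000, seed = 113)
  ch <- simulate_cohort(cfg)
  roles <- cohort_roles(ch)
  expect_equal(roles$covariates, paste0("pc", 1:10))
  expect_false("subpop" %in% names(ch))
  # the PC mixture is bimodal around 0 and 1: overall mean near strat_prop
  expect_equal(mean(ch$pc1), 0.5, tolerance = 0.1)
})

test_that("violation fixtures carry their stated population values", {
  expect_equal(pearl_inequality(make_violation_distribution("switching"))$value, 2)
  expect_equal(pearl_inequality(make_violation_distribution("null"))$value, 0.5)
  conf <- make_violation_distribution("confounded")
  v <- pearl_inequality(conf)$value
  expect_equal(v, pearl_oracle(conf$probs), tolerance = 1e-12)
  expect_gt(v, 1)
  expect_error(make_violation_distribution("nope"))
})

test_that("simulation configs round-trip through YAML and JSON", {
  cfg <- config_pleiotropy(n = 500, pleiotropy_pi = 0.3, seed = 127)
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n = cfg$n, snps = as.data.frame(cfg$snps),
                        gamma_u = cfg$gamma_u, exposure_sd = cfg$exposure_sd,
                        exposure_digits = cfg$exposure_digits,
                        beta0 = cfg$beta0, beta_x = cfg$beta_x,
                        delta_u = cfg$delta_u, seed = cfg$seed), yml)
  back <- read_sim_config(yml)
  expect_identical(tibble::as_tibble(simulate_cohort(back)),
                   tibble::as_tibble(simulate_cohort(cfg)))

  # hand-written YAML with unquoted keys (`n` is implicitly boolean in
  # YAML 1.1) still parses
  yml2 <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n: 50", "seed: 3", "beta0: -1", "snps:",
               "  maf: [0.3, 0.4]", "  alpha: [0.2, 0.2]"), yml2)
  cfg2 <- read_sim_config(yml2)
  expect_equal(cfg2$n, 50L)
  expect_equal(nrow(simulate_cohort(cfg2)), 50)

  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(n = cfg$n, snps = as.data.frame(cfg$snps),
                            gamma_u = cfg$gamma_u,
                            exposure_sd = cfg$exposure_sd,
                            exposure_digits = cfg$exposure_digits,
                            beta0 = cfg$beta0, beta_x = cfg$beta_x,
                            delta_u = cfg$delta_u, seed = cfg$seed),
                       js, auto_unbox = TRUE, digits = NA)
  back2 <- read_sim_config(js)
  expect_identical(tibble::as_tibble(simulate_cohort(back2)),
                   tibble::as_tibble(simulate_cohort(cfg)))
})

test_that("generated cohorts round-trip through the cohort file format", {
  cfg <- config_valid_iv(n = 300, seed = 131)
  ch <- simulate_cohort(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(ch, path)
  back <- load_cohort(path, genotypes = cohort_roles(ch)$genotypes,
                      exposure = "exposure", outcome = "outcome", id = "id")
  expect_equal(tibble::as_tibble(back)[names(ch)], tibble::as_tibble(ch))
})
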