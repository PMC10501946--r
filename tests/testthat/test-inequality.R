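test_that("empirical conditional joint matches hand counts and scales", {
  z <- rep(0:1, each = 4)
  x <- rep(c(0, 0, 1, 1), 2)
  y <- c(0, 1, 0, 1, 0, 0, 1, 1)
  d <- empirical_conditional_joint(z, x, y)
  expect_equal(d$probs["0", "0", "0"], 0.25)
  expect_equal(d$probs["1", "0", "0"], 0.5)
  expect_equal(unname(apply(d$probs, 1, sum)), c(1, 1), tolerance = 1e-12)

  # constant weights leave the distribution unchanged
  d7 <- empirical_conditional_joint(z, x, y, weights = rep(7, 8))
  expect_equal(d7$probs, d$probs, tolerance = 1e-12)

  expect_error(empirical_conditional_joint(z, x, y[-1]),
               class = "mrf_validation_error")
  expect_error(empirical_conditional_joint(z, x, y, weights = rep(0, 8)),
               class = "mrf_validation_error")
})

test_that("weighted tallies agree with a brute-force loop on random data", {
  set.seed(13)
  n <- 1000
  z <- sample(1:4, n, replace = TRUE)
  x <- sample(1:5, n, replace = TRUE)
  y <- rbinom(n, 1, 0.4)
  w <- rexp(n)
  d <- empirical_conditional_joint(z, x, y, weights = w)
  expect_equal(unname(d$probs), unname(tally_oracle(z, x, y, w)),
               tolerance = 1e-12)
})

test_that("the inequality statistic reproduces analytic fixtures", {
  # z-invariant uniform table: independence, value = max_x P(x) = 0.5
  unif <- as_mr_joint(array(0.25, c(2, 2, 2)))
  r <- pearl_inequality(unif)
  expect_equal(r$value, 0.5)
  expect_false(r$violated)

  # deterministic switching: both outer terms reach 1
  sw <- make_violation_distribution("switching")
  rs <- pearl_inequality(sw)
  expect_equal(rs$value, 2)
  expect_true(rs$violated)

  # argmax ties break to the lowest exposure category
  expect_equal(r$argmax_x, "0")

  # z-invariant non-uniform: value = max_x P(x) from the pooled margin
  p <- array(rep(c(0.4, 0.1, 0.3, 0.2), each = 2), c(2, 2, 2))
  rp <- pearl_inequality(as_mr_joint(p))
  expect_equal(rp$value, 0.4 + 0.3)
})

test_that("vectorized evaluation equals the exhaustive oracle on random tables", {
  set.seed(17)
  for (i in 1:200) {
    nz <- sample(1:6, 1)
    nx <- sample(1:10, 1)
    tab <- random_joint_table(nz, nx)
    r <- pearl_inequality(as_mr_joint(tab))
    expect_equal(r$value, pearl_oracle(tab), tolerance = 1e-12)
    # bounds: pooled max_x P(x) <= value <= |y|
    pooled <- apply(sweep(tab, 1, 1 / nz, "*"), 2, sum)
    expect_gte(r$value, max(pooled) - 1e-12)
    expect_lte(r$value, 2 + 1e-12)
  }
})

test_that("single-SNP evaluation handles monomorphic and switching cases", {
  set.seed(19)
  n <- 500
  g <- matrix(c(rbinom(n, 2, 0.4), rep(1L, n)), n, 2)
  ch <- prepare_exposure(toy_cohort(g, rnorm(n), rbinom(n, 1, 0.3)), k = 4)

  # constant SNP: single stratum, value = max_x P(x)
  expect_warning(r1 <- evaluate_snp_marginal(ch, "g2"),
                 class = "mrf_degenerate_warning")
  expect_equal(r1$n_strata, 1L)
  expect_equal(r1$value, max(table(ch$exposure_cat) / n), tolerance = 1e-12)

  # genotype that deterministically flips (x, y): value 2
  g2 <- matrix(rep(0:1, each = 10), 20, 1)
  xf <- rep(0, 20)
  yf <- rep(0:1, each = 10)
  chf <- toy_cohort(g2, xf, yf)
  chf$exposure_cat <- 1L
  r2 <- evaluate_snp_marginal(chf, "g1")
  expect_equal(r2$value, 2)
  expect_true(r2$violated)
})

test_that("joint sets refine marginals and warn when strata are sparse", {
  set.seed(23)
  ch <- random_cohort(n = 300, J = 3)
  joint <- evaluate_joint_set(ch)
  for (s in cohort_roles(ch)$genotypes) {
    expect_gte(joint$value + 1e-12, evaluate_snp_marginal(ch, s)$value)
  }

  # both SNPs constant: single stratum
  chc <- toy_cohort(matrix(1L, 50, 2), rnorm(50), rbinom(50, 1, 0.5))
  chc <- prepare_exposure(chc, k = 2)
  rc <- suppressWarnings(evaluate_joint_set(chc))
  expect_equal(rc$n_strata, 1L)
  expect_equal(rc$value, max(table(chc$exposure_cat)) / 50, tolerance = 1e-12)

  # many SNPs on few rows: strata approach one-per-individual
  set.seed(29)
  gns <- matrix(rbinom(30 * 12, 2, 0.5), 30, 12)
  chs <- prepare_exposure(toy_cohort(gns, rnorm(30), rbinom(30, 1, 0.5)),
                          k = 2)
  expect_warning(evaluate_joint_set(chs), class = "mrf_sparsity_warning")

  # min_stratum filtering drops light strata and records the floor
  rj <- evaluate_joint_set(ch, min_stratum = 5)
  expect_gte(rj$min_stratum_weight, 5)
})

test_that("joint evaluation matches the oracle on a 27-stratum table", {
  set.seed(31)
  n <- 5000
  g <- matrix(rbinom(n * 3, 2, 0.4), n, 3)
  expo <- rnorm(n, 0.4 * rowSums(g), 1)
  yy <- rbinom(n, 1, plogis(-1 + 0.2 * expo))
  ch <- prepare_exposure(toy_cohort(g, expo, yy), k = 5)
  z <- apply(g, 1, paste, collapse = "")
  tab <- tally_oracle(z, ch$exposure_cat, yy, rep(1, n))
  expect_equal(evaluate_joint_set(ch)$value, pearl_oracle(tab),
               tolerance = 1e-12)
})

test_that("weights rescale without changing the statistic, and refinement holds under weights", {
  set.seed(37)
  ch <- random_cohort(n = 500, J = 2)
  w <- rexp(nrow(ch)) + 0.1
  v1 <- evaluate_allele_score(ch, weights = w)$value
  v2 <- evaluate_allele_score(ch, weights = 13.7 * w)$value
  expect_equal(v1, v2, tolerance = 1e-12)

  joint <- evaluate_joint_set(ch, weights = w)
  for (s in cohort_roles(ch)$genotypes) {
    expect_gte(joint$value + 1e-12,
               evaluate_snp_marginal(ch, s, weights = w)$value)
  }
})

test_that("allele-score instrument reduces to a single stratum when constant", {
  ch0 <- toy_cohort(matrix(2L, 40, 2), rnorm(40), rbinom(40, 1, 0.4))
  ch0 <- prepare_exposure(ch0, k = 4)
  r <- evaluate_allele_score(ch0)
  expect_equal(r$n_strata, 1L)
  expect_equal(r$value, max(table(ch0$exposure_cat)) / 40, tolerance = 1e-12)
  expect_equal(r$instrument_label, "allele_score")
})

test_that("bootstrap intervals bracket the observed value deterministically", {
  set.seed(43)
  n <- 300
  z <- sample(0:2, n, TRUE)
  x <- sample(1:4, n, TRUE)
  y <- rbinom(n, 1, 0.4)
  b1 <- inequality_bootstrap(z, x, y, n_boot = 50, seed = 99)
  b2 <- inequality_bootstrap(z, x, y, n_boot = 50, seed = 99)
  expect_equal(b1, b2)
  expect_lte(b1$lower, b1$upper)
  expect_error(inequality_bootstrap(z, x, y, n_boot = 10),
               class = "mrf_validation_error")
})
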