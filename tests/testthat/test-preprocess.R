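test_that("complete-case filter matches a row-wise any-missing scan", {
  g <- matrix(0L, 5, 2)
  g[3, 1] <- NA
  ch <- toy_cohort(g, exposure = 1:5, outcome = c(0, 1, 0, 1, 0))
  kept <- suppressMessages(complete_case_filter(ch))
  expect_equal(nrow(kept), 4)
  expect_equal(kept$exposure, c(1, 2, 4, 5))

  # no missing values: identical table
  ch2 <- toy_cohort(matrix(1L, 3, 1), exposure = 1:3, outcome = c(0, 1, 0))
  expect_equal(tibble::as_tibble(suppressMessages(complete_case_filter(ch2))),
               tibble::as_tibble(ch2))

  # independent 20%-missingness mask on 1,000 rows vs brute-force scan
  set.seed(41)
  n <- 1000
  gm <- matrix(rbinom(n * 4, 2, 0.4), n, 4)
  gm[matrix(runif(n * 4) < 0.2, n, 4)] <- NA
  expo <- rnorm(n); expo[runif(n) < 0.2] <- NA
  y <- rbinom(n, 1, 0.3)
  ch3 <- toy_cohort(gm, expo, y)
  oracle <- 0
  for (i in seq_len(n)) {
    if (!any(is.na(gm[i, ])) && !is.na(expo[i])) oracle <- oracle + 1
  }
  expect_equal(nrow(suppressMessages(complete_case_filter(ch3))), oracle)

  # everything missing in a required column errors
  ch4 <- toy_cohort(matrix(NA_integer_, 3, 1), exposure = 1:3,
                    outcome = c(0, 1, 0))
  expect_error(suppressMessages(complete_case_filter(ch4)),
               class = "mrf_validation_error")
})

test_that("quantile categorization gives exact deciles and handles ties", {
  cq <- categorize_quantiles(1:100, k = 10)
  expect_equal(unname(table(cq$category)), rep(10L, 10), ignore_attr = TRUE)
  expect_equal(cq$map$n_categories, 10L)

  # ties at a boundary go to the lower category
  cq2 <- categorize_quantiles(c(1, 2, 2, 2, 3, 4), k = 2)
  med_cat <- cq2$category[2:4]
  expect_true(all(med_cat == med_cat[1]))
  expect_equal(cq2$category[5], cq2$category[6])
  expect_lt(med_cat[1], cq2$category[5])

  expect_warning(cqc <- categorize_quantiles(rep(7, 20), k = 10),
                 class = "mrf_degenerate_warning")
  expect_equal(cqc$map$n_categories, 1L)
  expect_true(all(cqc$category == 1L))
})

test_that("quantile categories match a rank-based oracle on skewed data", {
  set.seed(7)
  v <- exp(rnorm(10000))
  cq <- categorize_quantiles(v, k = 10)
  # oracle: assign by rank blocks, ties resolved to the lower block via the
  # maximal rank of each tied value
  r <- rank(v, ties.method = "max")
  oracle <- ceiling(r / (length(v) / 10))
  oracle <- match(oracle, sort(unique(oracle)))
  expect_equal(cq$category, oracle)

  # invariance under strictly monotone transforms
  cq2 <- categorize_quantiles(log(v), k = 10)
  expect_equal(cq2$category, cq$category)
  cq3 <- categorize_quantiles(rank(v, ties.method = "first"), k = 10)
  expect_equal(cq3$category, cq$category)
})

test_that("allele scores sum effect alleles and are order-invariant", {
  g <- rbind(c(0, 1, 2), c(2, 2, 2), c(0, 0, 0))
  ch <- toy_cohort(g, exposure = 1:3, outcome = c(0, 1, 0))
  sc <- build_allele_score(ch, k = 2)
  expect_equal(sc$score, c(3L, 6L, 0L))
  scp <- build_allele_score(ch, snps = c("g3", "g1", "g2"), k = 2)
  expect_equal(scp$score, sc$score)

  # all-homozygous-reference cohort: single category
  ch0 <- toy_cohort(matrix(0L, 4, 3), exposure = 1:4, outcome = c(0, 1, 0, 1))
  sc0 <- build_allele_score(ch0)
  expect_true(all(sc0$score == 0L))
  expect_equal(sc0$map$n_categories, 1L)

  # missing genotypes direct the user to the complete-case filter
  gna <- matrix(c(0L, NA), 2, 1)
  chna <- toy_cohort(gna, exposure = 1:2, outcome = c(0, 1))
  expect_error(build_allele_score(chna), class = "mrf_validation_error")
})

test_that("allele-score distribution matches its binomial expectation", {
  set.seed(11)
  n <- 20000
  g <- matrix(rbinom(n * 15, 2, 0.3), n, 15)
  ch <- toy_cohort(g, exposure = rnorm(n), outcome = rbinom(n, 1, 0.2))
  sc <- build_allele_score(ch)
  mu <- 2 * 15 * 0.3
  se <- sqrt(15 * 2 * 0.3 * 0.7 / n)
  expect_lt(abs(mean(sc$score) - mu), 4 * se)
  expect_lte(sc$map$n_categories, 10L)
  expect_true(all(tabulate(sc$category) > 0))
})

test_that("exposure preparation passes factors through in level order", {
  lev <- c("never", "monthly", "weekly", "daily")
  x <- factor(c("weekly", "never", "daily", "never", "monthly"),
              levels = lev)
  ch <- toy_cohort(matrix(1L, 5, 1), exposure = x, outcome = c(0, 1, 0, 1, 0))
  out <- prepare_exposure(ch)
  expect_equal(out$exposure_cat, c(3L, 1L, 4L, 1L, 2L))
  expect_equal(attr(out, "exposure_map")$levels, lev)

  chr <- toy_cohort(matrix(1L, 2, 1), exposure = c("a", "b"),
                    outcome = c(0, 1))
  expect_error(prepare_exposure(chr), class = "mrf_validation_error")
})

test_that("category maps serialize to JSON and back", {
  cq <- categorize_quantiles(1:100, k = 4)
  path <- withr::local_tempfile(fileext = ".json")
  category_map_json(cq$map, path)
  back <- jsonlite::fromJSON(path)
  expect_equal(back$boundaries, cq$map$boundaries)
  expect_equal(back$n_categories, cq$map$n_categories)
})
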