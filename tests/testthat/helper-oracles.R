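# Independent oracles and fixture builders shared across the suite.

# Exhaustive triple-loop evaluation of max_x sum_y max_z P(x,y|z),
# deliberately written as plain loops, independent of the package's
# vectorized path.
pearl_oracle <- function(probs) {
  nz <- dim(probs)[1]; nx <- dim(probs)[2]; ny <- dim(probs)[3]
  best_x <- -Inf
  for (ix in seq_len(nx)) {
    total <- 0
    for (iy in seq_len(ny)) {
      best_z <- -Inf
      for (iz in seq_len(nz)) {
        if (probs[iz, ix, iy] > best_z) best_z <- probs[iz, ix, iy]
      }
      total <- total + best_z
    }
    if (total > best_x) best_x <- total
  }
  best_x
}

# Random conditional joint table: |z| strata over nx exposure categories and
# ny outcome values, rows normalized within stratum.
random_joint_table <- function(nz, nx, ny = 2) {
  raw <- array(stats::rexp(nz * nx * ny), c(nz, nx, ny))
  tot <- apply(raw, 1, sum)
  sweep(raw, 1, tot, "/")
}

# Brute-force weighted tally of P(x,y|z), loop-based.
tally_oracle <- function(z, x, y, w) {
  zl <- sort(unique(z)); xl <- sort(unique(x)); yl <- sort(unique(y))
  out <- array(0, c(length(zl), length(xl), length(yl)),
               dimnames = list(as.character(zl), as.character(xl),
                               as.character(yl)))
  denom <- setNames(numeric(length(zl)), as.character(zl))
  for (i in seq_along(z)) {
    out[as.character(z[i]), as.character(x[i]), as.character(y[i])] <-
      out[as.character(z[i]), as.character(x[i]), as.character(y[i])] + w[i]
    denom[as.character(z[i])] <- denom[as.character(z[i])] + w[i]
  }
  sweep(out, 1, denom, "/")
}

# Minimal cohort fixture: genotypes g1..gJ, numeric exposure, binary outcome.
toy_cohort <- function(g, exposure, outcome, covariates = NULL) {
  g <- as.data.frame(g)
  names(g) <- paste0("g", seq_along(g))
  df <- dplyr::bind_cols(tibble::as_tibble(g),
                         tibble::tibble(exposure = exposure, outcome = outcome))
  covs <- character(0)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    names(covariates) <- paste0("c", seq_along(covariates))
    df <- dplyr::bind_cols(df, tibble::as_tibble(covariates))
    covs <- names(covariates)
  }
  as_mr_cohort(df, genotypes = names(g), exposure = "exposure",
               outcome = "outcome", covariates = covs)
}

# Random small cohort for property tests (complete cases, polymorphic-ish).
random_cohort <- function(n = 400, J = 3, k = 4) {
  g <- matrix(stats::rbinom(n * J, 2, stats::runif(J, 0.2, 0.5)[rep(seq_len(J), each = n)]),
              n, J)
  exposure <- stats::rnorm(n, 0.3 * rowSums(g), 1)
  outcome <- stats::rbinom(n, 1, stats::plogis(-0.5 + 0.2 * exposure))
  if (length(unique(outcome)) == 1) outcome[1] <- 1 - outcome[1]
  prepare_exposure(toy_cohort(g, exposure, outcome), k = k)
}

# association table with constant unit standard errors
new_assoc_for_test <- function(beta_exp, beta_out, se_exp = 0.01,
                               se_out = 0.02) {
  mrfalsify:::new_mr_assoc(tibble::tibble(
    snp = sprintf("s%02d", seq_along(beta_exp)),
    beta_exp = beta_exp, se_exp = se_exp,
    beta_out = beta_out, se_out = se_out))
}
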