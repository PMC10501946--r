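#' Fit a multinomial model for the instrument given covariates
#'
#' For the inverse-probability-weighted sensitivity analysis, the proposed
#' (categorical) instrument — in practice the allele-score category — is
#' modelled as multinomial logistic in the covariates (e.g. 10 principal
#' components), giving per-individual conditional probabilities
#' `P(Z = z | C)`. A binary instrument uses plain logistic regression. The
#' marginal level frequencies `P(Z = z)` are stored as the stabilizing
#' numerator. Models over very many instrument levels (joint SNP
#' cross-classifications) are refused: IPW is intended for the allele-score
#' instrument.
#'
#' @param z Instrument category vector (at least 2 observed levels).
#' @param covariates Numeric matrix or data frame of covariates, complete.
#' @param max_levels Refuse to fit beyond this many instrument levels.
#' @return An `mr_weight_model` holding the fitted model, level labels,
#'   marginal probabilities and the per-individual fitted probability
#'   matrix.
#' @export
fit_instrument_model <- function(z, covariates, max_levels = 25) {
  zf <- droplevels(factor(z))
  if (nlevels(zf) < 2) {
    stop_mrf("Instrument has a single observed level; no model to fit.",
             "mrf_validation_error")
  }
  if (nlevels(zf) > max_levels) {
    stop_mrf(sprintf(
      "Instrument has %d levels (> %d): per-stratum IPW models over many joint-genotype strata are not supported; weight the allele-score instrument instead.",
      nlevels(zf), max_levels), "mrf_validation_error")
  }
  C <- as.data.frame(covariates)
  if (anyNA(C)) {
    stop_mrf("Covariates must be complete.", "mrf_validation_error")
  }
  if (nrow(C) != length(zf)) {
    stop_mrf("Covariates must have one row per observation.", "mrf_validation_error")
  }
  names(C) <- make.names(names(C), unique = TRUE)
  dat <- cbind(data.frame(.z = zf), C)

  if (nlevels(zf) == 2) {
    sep_warned <- FALSE
    fit <- withCallingHandlers(
      glm(.z ~ ., data = dat, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          sep_warned <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    if (sep_warned) {
      stop_mrf("Apparent separation: the instrument is (near-)deterministic in a covariate.",
               "mrf_separation_error")
    }
    p1 <- fitted(fit)
    probs <- cbind(1 - p1, p1)
    colnames(probs) <- levels(zf)
    coefs <- coef(fit)
  } else {
    fit <- nnet::multinom(.z ~ ., data = dat, trace = FALSE, maxit = 200,
                          MaxNWts = 10000)
    probs <- predict(fit, type = "probs")
    coefs <- coef(fit)
  }
  big <- abs(coefs[!is.na(coefs)]) > 30
  if (any(big)) {
    nm <- names(coefs)[!is.na(coefs)][big]
    if (is.null(nm)) nm <- colnames(coefs)[col(coefs)[!is.na(coefs)][big]]
    stop_mrf(paste0("Apparent separation: runaway coefficient(s) for ",
                    fmt_names(unique(nm)),
                    "; the instrument is (near-)deterministic in a covariate."),
             "mrf_separation_error")
  }
  bad <- abs(rowSums(probs) - 1) > 1e-10
  if (any(bad)) {
    stop_mrf("Fitted conditional probabilities do not sum to 1.",
             "mrf_validation_error")
  }
  marginal <- as.numeric(table(zf) / length(zf))
  names(marginal) <- levels(zf)

  structure(list(fit = fit, instrument_levels = levels(zf),
                 marginal_probs = marginal, fitted_probs = probs,
                 z = zf, n = length(zf)),
            class = "mr_weight_model")
}

#' @export
print.mr_weight_model <- function(x, ...) {
  cat(sprintf("<mr_weight_model> %d instrument levels, n = %d\n",
              length(x$instrument_levels), x$n))
  cat("  marginal P(Z = z):",
      paste(sprintf("%s=%.3f", x$instrument_levels, x$marginal_probs),
            collapse = ", "), "\n")
  invisible(x)
}

#' Stabilized inverse-probability weights for the instrument
#'
#' Computes `w_i = P(Z = z_i) / P(Z = z_i | C_i)` from a fitted instrument
#' model. In the reweighted pseudo-population the instrument is independent
#' of the covariates, so residual population stratification captured by the
#' covariates no longer confounds the instrument–outcome relationship. Under
#' a correctly specified model the mean weight is close to 1. Optional
#' symmetric percentile truncation caps extreme weights.
#'
#' @param model An `mr_weight_model` from [fit_instrument_model()].
#' @param z Instrument categories for the rows to be weighted (default: the
#'   fitting data).
#' @param covariates Covariates for those rows (default: fitted
#'   probabilities from the training fit are reused).
#' @param truncate Optional length-2 vector of percentile bounds, e.g.
#'   `c(0.01, 0.99)`; default `NULL` (no truncation).
#' @return Numeric weight vector; a summary (mean, range, percentiles) is
#'   attached as the `summary` attribute.
#' @export
compute_stabilized_weights <- function(model, z = NULL, covariates = NULL,
                                       truncate = NULL) {
  stopifnot(inherits(model, "mr_weight_model"))
  if (is.null(z)) {
    zf <- model$z
    probs <- model$fitted_probs
  } else {
    zf <- factor(z, levels = model$instrument_levels)
    if (anyNA(zf)) {
      stop_mrf("`z` contains levels unseen by the fitted model.",
               "mrf_validation_error")
    }
    if (is.null(covariates)) {
      stop_mrf("Supply `covariates` along with `z`.", "mrf_validation_error")
    }
    C <- as.data.frame(covariates)
    names(C) <- make.names(names(C), unique = TRUE)
    if (length(model$instrument_levels) == 2) {
      p1 <- predict(model$fit, newdata = C, type = "response")
      probs <- cbind(1 - p1, p1)
    } else {
      probs <- predict(model$fit, newdata = C, type = "probs")
    }
  }
  idx <- cbind(seq_along(zf), as.integer(zf))
  denom <- probs[idx]
  if (any(denom <= 1e-12)) {
    stop_mrf("Fitted conditional probability is zero for an observed (z, C): positivity violated.",
             "mrf_positivity_error")
  }
  w <- model$marginal_probs[as.integer(zf)] / denom
  if (!is.null(truncate)) {
    stopifnot(length(truncate) == 2, truncate[1] < truncate[2])
    b <- quantile(w, truncate)
    w <- pmin(pmax(w, b[1]), b[2])
  }
  attr(w, "summary") <- tibble(mean = mean(w), min = min(w), max = max(w),
                               p01 = unname(quantile(w, 0.01)),
                               p50 = unname(quantile(w, 0.5)),
                               p99 = unname(quantile(w, 0.99)))
  unname_keep_attr(w)
}

unname_keep_attr <- function(w) {
  s <- attr(w, "summary")
  w <- as.numeric(w)
  attr(w, "summary") <- s
  w
}

#' Attach stabilized IP weights for the allele-score instrument to a cohort
#'
#' Convenience wrapper: builds the allele-score categories, fits the
#' instrument model on the declared covariates, computes stabilized weights
#' and writes them into the cohort `weight` column.
#'
#' @param cohort An `mr_cohort` with complete cases and declared covariates.
#' @param snps SNP set for the allele score (default: all genotype columns).
#' @param k Requested number of score categories.
#' @param truncate Optional percentile truncation, as in
#'   [compute_stabilized_weights()].
#' @return The cohort with its `weight` column replaced by the stabilized
#'   weights; the weight model is attached as the `weight_model` attribute.
#' @export
add_ipw_weights <- function(cohort, snps = NULL, k = 10, truncate = NULL) {
  roles <- cohort_roles(cohort)
  if (length(roles$covariates) == 0) {
    stop_mrf("Cohort declares no covariates to adjust for.", "mrf_schema_error")
  }
  sc <- build_allele_score(cohort, snps = snps, k = k)
  C <- as_tibble(cohort)[roles$covariates]
  model <- fit_instrument_model(sc$category, C)
  w <- compute_stabilized_weights(model)
  out <- as_tibble(cohort)
  out[[roles$weight]] <- as.numeric(w)
  out <- reattach_roles(out, cohort)
  attr(out, "weight_model") <- model
  attr(out, "weight_summary") <- attr(w, "summary")
  out
}
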