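#' Weighted empirical conditional joint distribution P(x, y | z)
#'
#' Tallies (optionally weighted) counts over the cross-classification of a
#' proposed instrument `z`, a categorical exposure `x` and an outcome `y`,
#' and normalizes within each instrument stratum:
#' `P(x, y | z) = sum(w[z, x, y]) / sum(w[z])`. Strata with zero total weight
#' are dropped; exposure and outcome level sets are the union over all
#' strata, with absent combinations getting probability 0. Rescaling all
#' weights by a positive constant leaves the distribution unchanged.
#'
#' @param z,x,y Equal-length vectors of instrument strata, exposure
#'   categories and outcome values (coercible to factors).
#' @param weights Optional nonnegative weights (default 1 per observation).
#' @return An `mr_joint`: list with `probs` (3-d array `[z, x, y]`),
#'   `z_levels`, `x_levels`, `y_levels` and `stratum_weights`.
#' @examples
#' d <- empirical_conditional_joint(z = rep(0:1, each = 4),
#'                                  x = rep(c(0, 0, 1, 1), 2),
#'                                  y = c(0, 1, 0, 1, 0, 0, 1, 1))
#' d$probs["0", "0", "0"]  # 0.25
#' @export
empirical_conditional_joint <- function(z, x, y, weights = NULL) {
  n <- length(z)
  if (length(x) != n || length(y) != n) {
    stop_mrf("`z`, `x` and `y` must have equal length.", "mrf_validation_error")
  }
  if (n == 0) stop_mrf("At least one observation is required.", "mrf_validation_error")
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) {
    stop_mrf("`weights` must match the observations in length.", "mrf_validation_error")
  }
  if (any(is.na(weights)) || any(weights < 0)) {
    stop_mrf("`weights` must be nonnegative and non-missing.", "mrf_validation_error")
  }
  if (sum(weights) == 0) {
    stop_mrf("All weights are zero.", "mrf_validation_error")
  }
  if (anyNA(z) || anyNA(x) || anyNA(y)) {
    stop_mrf("Missing values in z, x or y; apply complete_case_filter() first.",
             "mrf_validation_error")
  }

  zf <- factor(z)
  xf <- factor(x)
  yf <- factor(y)
  counts <- tapply(weights, list(zf, xf, yf), sum, default = 0)
  stratum_weights <- apply(counts, 1, sum)
  keep <- stratum_weights > 0
  counts <- counts[keep, , , drop = FALSE]
  stratum_weights <- stratum_weights[keep]
  probs <- sweep(counts, 1, stratum_weights, "/")

  structure(list(probs = probs,
                 z_levels = dimnames(probs)[[1]],
                 x_levels = dimnames(probs)[[2]],
                 y_levels = dimnames(probs)[[3]],
                 stratum_weights = stratum_weights),
            class = "mr_joint")
}

#' Construct an `mr_joint` directly from a probability array
#'
#' For analytic fixtures and population-level calculations: `probs` is an
#' array `[z, x, y]` whose slices sum to 1 within each z.
#'
#' @param probs 3-d array of conditional probabilities `P(x, y | z)`.
#' @param stratum_weights Optional positive total weight per stratum
#'   (default 1 each).
#' @export
as_mr_joint <- function(probs, stratum_weights = NULL) {
  stopifnot(is.array(probs), length(dim(probs)) == 3)
  if (is.null(dimnames(probs))) {
    dimnames(probs) <- lapply(dim(probs), function(d) as.character(seq_len(d) - 1))
  }
  sums <- apply(probs, 1, sum)
  if (any(abs(sums - 1) > 1e-12)) {
    stop_mrf("Each z stratum of `probs` must sum to 1 (within 1e-12).",
             "mrf_validation_error")
  }
  if (is.null(stratum_weights)) stratum_weights <- rep(1, dim(probs)[1])
  structure(list(probs = probs,
                 z_levels = dimnames(probs)[[1]],
                 x_levels = dimnames(probs)[[2]],
                 y_levels = dimnames(probs)[[3]],
                 stratum_weights = stratum_weights),
            class = "mr_joint")
}

#' @export
print.mr_joint <- function(x, ...) {
  cat(sprintf("<mr_joint> P(x, y | z): %d strata x %d exposure categories x %d outcome values\n",
              length(x$z_levels), length(x$x_levels), length(x$y_levels)))
  invisible(x)
}
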