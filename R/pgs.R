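#' Marginal per-SNP regression weights
#'
#' Estimates, for every SNP j and trait l, the slope of the univariate simple
#' linear regression of trait l on SNP j alone. These marginal effects are the
#' weights from which polygenic scores are aggregated. All p x q regressions
#' are computed in closed form from first and second moments, so the sweep is
#' a pair of matrix products even for tens of thousands of SNPs.
#'
#' SNPs with zero variance have no defined slope; their weight is set to 0 so
#' they contribute nothing to a score, and a warning reports how many were
#' flagged. Missing genotypes are a hard error: imputation (e.g.
#' [impute_family_mean()]) belongs upstream of weight estimation.
#'
#' @param genotypes N x p numeric matrix (or data frame) of additive allele
#'   counts in \{0, 1, 2\} (fractional values from mean imputation are
#'   accepted). Columns are SNPs.
#' @param traits N x q numeric matrix (or data frame) of quantitative traits.
#' @return An object of class `genejam_weights`: a list with `slopes` and
#'   `intercepts` (p x q matrices, SNPs in rows, traits in columns) and
#'   `undefined` (p x q logical, TRUE where the SNP had zero variance).
#' @examples
#' X <- matrix(c(0, 1, 2, 1), ncol = 1)
#' Y <- matrix(c(1, 3, 5, 3), ncol = 1)
#' marginal_weights(X, Y)$slopes  # exactly 2
#' @export
marginal_weights <- function(genotypes, traits) {
  X <- as_num_matrix(genotypes, "genotypes")
  Y <- as_num_matrix(traits, "traits")
  n <- nrow(X)
  if (nrow(Y) != n) {
    abort(sprintf("genotypes have %d rows but traits have %d.", n, nrow(Y)))
  }
  if (n < 3) abort("At least 3 samples are required for marginal regressions.")
  if (anyNA(X)) {
    abort("Missing genotypes: impute (see `impute_family_mean()`) before estimating weights.")
  }
  if (anyNA(Y)) abort("Missing trait values are not supported.")

  xm <- colMeans(X)
  ym <- colMeans(Y)
  # sample covariance between every SNP and every trait, denominator n - 1
  cxy <- (crossprod(X, Y) - n * tcrossprod(xm, ym)) / (n - 1)
  vx <- (colSums(X^2) - n * xm^2) / (n - 1)
  undefined <- vx <= .Machine$double.eps * max(1, max(abs(X)))^2
  vx_safe <- ifelse(undefined, 1, vx)
  slopes <- cxy / vx_safe
  slopes[undefined, ] <- 0
  if (any(undefined)) {
    warn(sprintf(
      "%d SNP(s) with zero variance: slopes set to 0 (no contribution to scores).",
      sum(undefined)
    ))
  }
  intercepts <- matrix(rep(ym, each = nrow(slopes)), nrow = nrow(slopes)) -
    slopes * xm
  snp_ids <- colnames(X) %||% default_ids(ncol(X), "snp")
  trait_ids <- colnames(Y) %||% default_ids(ncol(Y), "trait")
  dimnames(slopes) <- dimnames(intercepts) <- list(snp_ids, trait_ids)
  structure(
    list(
      slopes = slopes, intercepts = intercepts,
      undefined = matrix(undefined, nrow = length(undefined), ncol = ncol(Y),
                         dimnames = list(snp_ids, trait_ids))
    ),
    class = "genejam_weights"
  )
}

#' @export
print.genejam_weights <- function(x, ...) {
  cat(sprintf(
    "Marginal PGS weights: %d SNPs x %d traits (%d zero-variance SNPs)\n",
    nrow(x$slopes), ncol(x$slopes), sum(x$undefined[, 1])
  ))
  invisible(x)
}

#' Tidy marginal weights into a long tibble
#'
#' @param x A `genejam_weights` object.
#' @param ... Unused.
#' @return A tibble with columns `snp`, `trait`, `slope`, `intercept`.
#' @method tidy genejam_weights
#' @export
tidy.genejam_weights <- function(x, ...) {
  tibble(
    snp = rep(rownames(x$slopes), times = ncol(x$slopes)),
    trait = rep(colnames(x$slopes), each = nrow(x$slopes)),
    slope = as.vector(x$slopes),
    intercept = as.vector(x$intercepts)
  )
}

#' Aggregate marginal weights into polygenic scores
#'
#' Computes one polygenic score per trait as the weighted allele-count sum
#' z_il = sum_j x_ij * w_jl. Intercepts are deliberately not included: the
#' score is defined as the weighted sum of allele counts only, so scores are
#' location-shifted relative to the traits (irrelevant downstream, where
#' scores are standardized and regressions include an intercept).
#'
#' @param genotypes N x p genotype matrix with no missing entries.
#' @param weights A `genejam_weights` object from [marginal_weights()], or a
#'   p x q numeric matrix of slopes.
#' @return N x q numeric matrix of scores, columns named by trait.
#' @export
compute_scores <- function(genotypes, weights) {
  X <- as_num_matrix(genotypes, "genotypes")
  W <- if (inherits(weights, "genejam_weights")) weights$slopes else
    as_num_matrix(weights, "weights")
  if (anyNA(X)) abort("Missing genotypes: impute before computing scores.")
  if (ncol(X) != nrow(W)) {
    abort(sprintf(
      "genotypes have %d SNPs but weights have %d rows.", ncol(X), nrow(W)
    ))
  }
  Z <- X %*% W
  rownames(Z) <- rownames(X)
  Z
}
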