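#' Per-trait OLS step
#'
#' Fits, for each trait separately, the simple linear regression of trait on
#' its polygenic score (intercept + slope). This is the first step of the
#' FGLS iteration; its residuals seed the estimate of the cluster-block error
#' covariance.
#'
#' Traits whose score column has zero variance get an intercept-only fit
#' (slope 0) with a warning.
#'
#' @param scores N x q score matrix (one column per trait).
#' @param traits N x q trait matrix.
#' @return A list with `coef` (2 x q matrix, rows `xi` = intercept and
#'   `beta` = slope) and `residuals` (N x q matrix).
#' @export
ols_step <- function(scores, traits) {
  Z <- as_num_matrix(scores, "scores")
  Y <- as_num_matrix(traits, "traits")
  n <- nrow(Z)
  q <- ncol(Z)
  if (nrow(Y) != n || ncol(Y) != q) abort("`scores` and `traits` must be N x q with matching shapes.")
  if (n < 3) abort("At least 3 samples are required.")
  zm <- colMeans(Z)
  ym <- colMeans(Y)
  vz <- apply(Z, 2, var)
  degen <- vz <= .Machine$double.eps * max(1, max(abs(Z)))^2
  if (any(degen)) {
    warn(sprintf("%d degenerate score column(s): intercept-only OLS fit.", sum(degen)))
  }
  czy <- colSums((Z - rep(zm, each = n)) * (Y - rep(ym, each = n))) / (n - 1)
  beta <- ifelse(degen, 0, czy / ifelse(degen, 1, vz))
  xi <- ym - beta * zm
  fitted <- rep(xi, each = n) + Z * rep(beta, each = n)
  ids <- colnames(Y) %||% colnames(Z) %||% default_ids(q, "trait")
  coefs <- rbind(xi = xi, beta = beta)
  colnames(coefs) <- ids
  res <- Y - fitted
  colnames(res) <- ids
  list(coef = coefs, residuals = res)
}

#' Cluster-structured residual covariance
#'
#' Estimates the q x q within-individual error covariance R under the
#' constraint that traits in different clusters are uncorrelated: within each
#' connected component the block of R is the sample covariance (denominator
#' N - 1) of the corresponding residual columns, and all cross-component
#' entries are exactly zero. A block whose condition number exceeds 1e10 gets
#' a small ridge (`ridge * trace / block size`) added to its diagonal, with a
#' warning, so that path endpoints with very large clusters never produce a
#' singular weight matrix.
#'
#' @param residuals N x q residual matrix.
#' @param clusters A `genejam_clusters` object.
#' @param ridge Relative ridge added to near-singular blocks.
#' @return q x q block-diagonal (up to trait ordering) covariance matrix.
#' @export
cluster_covariance <- function(residuals, clusters, ridge = 1e-8) {
  U <- as_num_matrix(residuals, "residuals")
  stopifnot(inherits(clusters, "genejam_clusters"))
  q <- ncol(U)
  n <- nrow(U)
  if (length(clusters$labels) != q) abort("Cluster labels do not match residual columns.")
  R <- matrix(0, q, q)
  for (g in seq_len(clusters$n_components)) {
    members <- which(clusters$labels == g)
    if (length(members) > n - 1) {
      abort(sprintf(
        "Component %d has %d traits but only %d samples: increase N or use a sparser clustering.",
        g, length(members), n
      ))
    }
    blk <- cov(U[, members, drop = FALSE])
    if (length(members) > 1) {
      ev <- eigen(blk, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) <= 0 || max(ev) / min(ev) > 1e10) {
        bump <- ridge * sum(diag(blk)) / length(members)
        blk <- blk + diag(bump, length(members))
        warn(sprintf("Near-singular residual covariance block (component %d): ridge %g added.",
                     g, bump))
      }
    }
    R[members, members] <- blk
  }
  ids <- colnames(U) %||% default_ids(q, "trait")
  dimnames(R) <- list(ids, ids)
  R
}

#' Generalized least squares with a cluster-block error covariance
#'
#' Solves the weighted least-squares problem for the row-wise vectorized
#' system Y-vec = Z-design B + E, E ~ N(0, I_N (x) R), where R is
#' block-diagonal with respect to the clustering. Each cluster is an
#' independent seemingly-unrelated-regressions system, solved by accumulating
#' the per-individual normal equations with the block inverse of R; the
#' Nq x Nq covariance is never formed. Within a cluster with traits
#' l1..lm, the normal matrix is assembled from
#' `Rinv[l, l'] * crossprod(X_l, X_l')` with X_l = [1, z_l].
#'
#' @param scores N x q score matrix.
#' @param traits N x q trait matrix.
#' @param R q x q cluster-block covariance (from [cluster_covariance()]).
#' @param clusters A `genejam_clusters` object describing R's block structure.
#' @return A list with `coef` (2 x q matrix, rows `xi`, `beta`), `se`
#'   (q-vector of slope standard errors from the inverse normal matrix), and
#'   `vcov_diag` (2 x q matrix of coefficient variances).
#' @export
gls_solve <- function(scores, traits, R, clusters) {
  Z <- as_num_matrix(scores, "scores")
  Y <- as_num_matrix(traits, "traits")
  q <- ncol(Z)
  stopifnot(inherits(clusters, "genejam_clusters"))
  coefs <- matrix(NA_real_, 2, q)
  vdiag <- matrix(NA_real_, 2, q)
  for (g in seq_len(clusters$n_components)) {
    members <- which(clusters$labels == g)
    m <- length(members)
    Rg <- R[members, members, drop = FALSE]
    Rinv <- tryCatch(solve(Rg), error = function(e) {
      abort(sprintf("Singular residual covariance in component %d; cannot weight.", g))
    })
    # design blocks X_l = [1, z_l]; normal matrix A (2m x 2m), rhs c (2m)
    A <- matrix(0, 2 * m, 2 * m)
    cc <- numeric(2 * m)
    Xl <- lapply(members, function(l) cbind(1, Z[, l]))
    for (a in seq_len(m)) {
      ra <- (2 * a - 1):(2 * a)
      for (b in seq_len(m)) {
        rb <- (2 * b - 1):(2 * b)
        A[ra, rb] <- Rinv[a, b] * crossprod(Xl[[a]], Xl[[b]])
        cc[ra] <- cc[ra] + Rinv[a, b] * crossprod(Xl[[a]], Y[, members[b]])
      }
    }
    Ainv <- tryCatch(solve(A), error = function(e) {
      abort(sprintf("Singular normal matrix in component %d (collinear scores?).", g))
    })
    bhat <- Ainv %*% cc
    for (a in seq_len(m)) {
      coefs[, members[a]] <- bhat[(2 * a - 1):(2 * a)]
      vdiag[, members[a]] <- diag(Ainv)[(2 * a - 1):(2 * a)]
    }
  }
  ids <- colnames(Y) %||% colnames(Z) %||% default_ids(q, "trait")
  dimnames(coefs) <- dimnames(vdiag) <- list(c("xi", "beta"), ids)
  list(coef = coefs, se = sqrt(vdiag["beta", ]), vcov_diag = vdiag)
}

#' Iterated feasible generalized least squares
#'
#' Alternates between (i) estimating the cluster-block residual covariance R
#' from the current residuals and (ii) re-estimating the per-trait
#' intercepts/slopes by GLS under I_N (x) R, starting from per-trait OLS.
#' Iteration stops when the largest change in the coefficient vector,
#' relative to its largest magnitude, drops below `tol`, or after `max_iter`
#' covariance updates (then `converged = FALSE` with a warning).
#'
#' Standard errors are the square roots of the diagonal of the inverse
#' blockwise normal matrix at the final R, reported for the slope of each
#' trait (the coefficient carrying the genetic signal).
#'
#' @param scores N x q score matrix.
#' @param traits N x q trait matrix.
#' @param clusters A `genejam_clusters` object (e.g. from
#'   [trait_components()]); defaults to all-singleton clustering, in which
#'   case the fit is exactly per-trait OLS.
#' @param max_iter Maximum number of covariance updates.
#' @param tol Relative convergence tolerance on the coefficient vector.
#' @param ridge Relative ridge for near-singular covariance blocks.
#' @return An object of class `genejam_fgls`: list with `coef` (2 x q),
#'   `se` (q slope standard errors), `R` (q x q cluster-block residual
#'   covariance), `clusters`, `fitted`, `residuals`, `n_iter`, `converged`.
#' @export
fgls_fit <- function(scores, traits, clusters = NULL, max_iter = 100,
                     tol = 1e-6, ridge = 1e-8) {
  Z <- as_num_matrix(scores, "scores")
  Y <- as_num_matrix(traits, "traits")
  q <- ncol(Z)
  if (is.null(clusters)) {
    clusters <- trait_components(matrix(0, q, q))
  }
  ols <- ols_step(Z, Y)
  coefs <- ols$coef
  U <- ols$residuals
  n_iter <- 0L
  converged <- FALSE
  se <- rep(NA_real_, q)
  R <- NULL
  repeat {
    n_iter <- n_iter + 1L
    R <- cluster_covariance(U, clusters, ridge = ridge)
    wls <- gls_solve(Z, Y, R, clusters)
    delta <- max(abs(wls$coef - coefs)) / max(max(abs(coefs)), 1e-10)
    coefs <- wls$coef
    se <- wls$se
    fitted <- rep(coefs["xi", ], each = nrow(Z)) + Z * rep(coefs["beta", ], each = nrow(Z))
    U <- Y - fitted
    if (delta < tol) {
      converged <- TRUE
      break
    }
    if (n_iter >= max_iter) {
      warn(sprintf("FGLS did not converge in %d iterations (last relative change %.2e).",
                   max_iter, delta))
      break
    }
  }
  ids <- colnames(coefs)
  colnames(U) <- colnames(fitted) <- ids
  structure(
    list(coef = coefs, se = setNames(se, ids), R = R, clusters = clusters,
         fitted = fitted, residuals = U, n_iter = n_iter, converged = converged),
    class = "genejam_fgls"
  )
}

#' @export
print.genejam_fgls <- function(x, ...) {
  cat(sprintf(
    "FGLS fit: %d traits, %d cluster component(s), %d iteration(s), converged: %s\n",
    ncol(x$coef), x$clusters$n_components, x$n_iter, x$converged
  ))
  invisible(x)
}

#' Tidy an FGLS fit into per-trait rows
#'
#' @param x A `genejam_fgls` object.
#' @param ... Unused.
#' @return A tibble with columns `trait`, `xi` (intercept), `beta` (slope),
#'   `se_beta`, `component`, `component_size`.
#' @method tidy genejam_fgls
#' @export
tidy.genejam_fgls <- function(x, ...) {
  tibble(
    trait = colnames(x$coef),
    xi = unname(x$coef["xi", ]),
    beta = unname(x$coef["beta", ]),
    se_beta = unname(x$se),
    component = unname(x$clusters$labels),
    component_size = x$clusters$sizes[x$clusters$labels]
  )
}

#' @method glance genejam_fgls
#' @export
glance.genejam_fgls <- function(x, ...) {
  tibble(
    n = nrow(x$residuals), n_traits = ncol(x$coef),
    n_components = x$clusters$n_components,
    n_clustered = sum(x$clusters$nonsingleton),
    n_iter = x$n_iter, converged = x$converged
  )
}

#' Predict traits from an FGLS fit
#'
#' @param object A `genejam_fgls` object.
#' @param newdata N x q score matrix (same traits, same order, as the fit).
#'   Defaults to the training scores' fitted values.
#' @param ... Unused.
#' @return N x q matrix of predicted trait values `xi_l + beta_l * z_il`.
#' @export
predict.genejam_fgls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  Z <- as_num_matrix(newdata, "newdata")
  q <- ncol(object$coef)
  if (ncol(Z) != q) {
    abort(sprintf("Fit has %d traits but `newdata` has %d columns.", q, ncol(Z)))
  }
  out <- rep(object$coef["xi", ], each = nrow(Z)) +
    Z * rep(object$coef["beta", ], each = nrow(Z))
  colnames(out) <- colnames(object$coef)
  out
}
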