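#' Standardize polygenic scores and compute their correlation matrix
#'
#' Centres each score column to mean zero and scales it to unit variance, the
#' scale on which the precision structure of the scores is estimated. Columns
#' with (numerically) zero variance cannot be standardized; they are centred
#' only and flagged as degenerate, and the pipeline later forces them to be
#' singleton clusters.
#'
#' @param scores N x q numeric matrix of polygenic scores (one column per
#'   trait), or a data frame.
#' @return A list with `z` (standardized N x q matrix), `S` (q x q empirical
#'   correlation matrix of the standardized columns, identity rows/cols for
#'   degenerate traits), `degenerate` (logical q-vector), `center` and `scale`
#'   (the applied location/scale, for reuse on new data).
#' @export
standardize_scores <- function(scores) {
  Z <- as_num_matrix(scores, "scores")
  if (nrow(Z) < 3) abort("At least 3 samples are required to standardize scores.")
  ctr <- colMeans(Z)
  sds <- apply(Z, 2, sd)
  degenerate <- !is.finite(sds) | sds <= .Machine$double.eps * max(1, max(abs(Z)))
  if (any(degenerate)) {
    warn(sprintf("%d degenerate (zero-variance) score column(s): centred only, excluded from clustering.",
                 sum(degenerate)))
  }
  scl <- ifelse(degenerate, 1, sds)
  Zs <- sweep(sweep(Z, 2, ctr, "-"), 2, scl, "/")
  q <- ncol(Zs)
  S <- diag(q)
  ok <- !degenerate
  if (sum(ok) >= 2) S[ok, ok] <- cor(Zs[, ok, drop = FALSE])
  ids <- colnames(Z) %||% default_ids(q, "trait")
  dimnames(S) <- list(ids, ids)
  colnames(Zs) <- ids
  list(z = Zs, S = S, degenerate = setNames(degenerate, ids),
       center = setNames(ctr, ids), scale = setNames(scl, ids))
}

#' Regularization path for the graphical lasso
#'
#' Builds the grid of penalty values over which the trait graph is estimated.
#' The left endpoint is the smallest absolute off-diagonal entry of the score
#' correlation matrix and the right endpoint is its maximum absolute column
#' sum, so the path always spans from (near-)dense to fully disconnected
#' graphs for the matrix at hand. Interior points are linearly spaced by
#' default, or log-spaced on request (a left endpoint of 0 is nudged to 1e-4
#' on the log scale).
#'
#' @param S q x q score correlation matrix.
#' @param n_rho Number of grid points (>= 2).
#' @param scale `"linear"` or `"log"` spacing.
#' @return Strictly increasing numeric vector of length `n_rho`.
#' @examples
#' rho_path(matrix(c(1, .5, .5, 1), 2), n_rho = 3)  # 0.5 1.0 1.5
#' @export
rho_path <- function(S, n_rho = 50, scale = c("linear", "log")) {
  scale <- match.arg(scale)
  S <- as_num_matrix(S, "S")
  q <- ncol(S)
  if (q < 2) abort("Clustering needs at least 2 traits.")
  if (n_rho < 2) abort("`n_rho` must be at least 2.")
  off <- abs(S[upper.tri(S)])
  lo <- min(off)
  hi <- max(colSums(abs(S)))
  if (lo == 0 && scale == "log") lo <- 1e-4
  if (lo == 0) {
    # rho = 0 is only well-posed when S is invertible
    if (rcond_sym(S) < 1e-12) lo <- 1e-4
  }
  if (hi <= lo) hi <- lo + 1e-8
  if (scale == "log") exp(seq(log(lo), log(hi), length.out = n_rho))
  else seq(lo, hi, length.out = n_rho)
}

# reciprocal condition number of a symmetric matrix via its eigenvalues
rcond_sym <- function(S) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(ev)) == 0) return(0)
  min(abs(ev)) / max(abs(ev))
}

#' Graphical lasso: sparse precision estimation
#'
#' Maximizes the penalized Gaussian log-likelihood
#' `log det(P) - tr(S P) - rho * ||P||_1` over positive-definite precision
#' matrices P, with the l1 penalty applied to off-diagonal entries (set
#' `penalize_diagonal = TRUE` for the all-entries variant). The solver is the
#' standard blockwise coordinate-descent algorithm: each column of the working
#' covariance W is updated by solving a lasso subproblem by coordinate
#' descent, sweeping until the mean absolute change of W's off-diagonal is
#' below `tol * mean(|off-diagonal of S|)`.
#'
#' @param S q x q positive semi-definite correlation (or covariance) matrix.
#' @param rho Non-negative penalty. `rho = 0` requires invertible `S`.
#' @param penalize_diagonal Penalize diagonal entries too? Default `FALSE`;
#'   the sparsity pattern consumed downstream is essentially unaffected.
#' @param max_sweeps Maximum number of full column sweeps.
#' @param tol Relative convergence tolerance on the working covariance.
#' @return A list of class `genejam_precision` with `P` (q x q symmetric
#'   positive-definite precision estimate), `W` (its inverse, the regularized
#'   covariance), `rho`, and `n_sweeps`.
#' @export
graphical_lasso <- function(S, rho, penalize_diagonal = FALSE,
                            max_sweeps = 200, tol = 1e-6) {
  S <- as_num_matrix(S, "S")
  q <- ncol(S)
  if (nrow(S) != q || max(abs(S - t(S))) > 1e-8) abort("`S` must be symmetric.")
  if (rho < 0) abort("`rho` must be non-negative.")
  ev_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-8 * max(1, max(abs(S)))) abort("`S` must be positive semi-definite.")
  if (rho == 0 && rcond_sym(S) < 1e-12) {
    abort("rho = 0 requires an invertible correlation matrix.")
  }

  if (q == 1) {
    d <- S[1, 1] + if (penalize_diagonal) rho else 0
    P <- matrix(1 / d, 1, 1, dimnames = dimnames(S))
    return(structure(list(P = P, W = matrix(d, 1, 1), rho = rho, n_sweeps = 0L),
                     class = "genejam_precision"))
  }

  W <- S
  if (penalize_diagonal) diag(W) <- diag(S) + rho
  B <- matrix(0, q - 1, q)  # lasso coefficients per column
  off_mean <- mean(abs(S[upper.tri(S)]))
  thresh <- tol * max(off_mean, .Machine$double.eps)

  converged <- FALSE
  sweeps <- 0L
  for (sweep_i in seq_len(max_sweeps)) {
    W_old_off <- W[upper.tri(W)]
    for (j in seq_len(q)) {
      idx <- setdiff(seq_len(q), j)
      W11 <- W[idx, idx, drop = FALSE]
      s12 <- S[idx, j]
      beta <- lasso_cd(W11, s12, rho, B[, j])
      B[, j] <- beta
      w12 <- as.vector(W11 %*% beta)
      W[idx, j] <- w12
      W[j, idx] <- w12
    }
    sweeps <- sweep_i
    if (mean(abs(W[upper.tri(W)] - W_old_off)) < thresh) {
      converged <- TRUE
      break
    }
  }
  if (!converged && rho > 0) {
    abort(sprintf("Graphical lasso did not converge in %d sweeps at rho = %g.",
                  max_sweeps, rho))
  }

  # recover the precision matrix from the final coefficients
  P <- matrix(0, q, q)
  for (j in seq_len(q)) {
    idx <- setdiff(seq_len(q), j)
    pjj <- 1 / (W[j, j] - sum(W[idx, j] * B[, j]))
    P[j, j] <- pjj
    P[idx, j] <- -B[, j] * pjj
  }
  P <- (P + t(P)) / 2
  dimnames(P) <- dimnames(W) <- dimnames(S)
  structure(list(P = P, W = W, rho = rho, n_sweeps = sweeps),
            class = "genejam_precision")
}

# Coordinate-descent lasso for 0.5 b' W11 b - s12' b + rho ||b||_1.
lasso_cd <- function(W11, s12, rho, beta, max_iter = 1000L, tol = 1e-10) {
  m <- length(s12)
  if (m == 0) return(numeric(0))
  for (it in seq_len(max_iter)) {
    delta <- 0
    for (k in seq_len(m)) {
      r <- s12[k] - sum(W11[k, ] * beta) + W11[k, k] * beta[k]
      bk <- soft_threshold(r, rho) / W11[k, k]
      delta <- max(delta, abs(bk - beta[k]))
      beta[k] <- bk
    }
    if (delta < tol * max(1, max(abs(beta)))) break
  }
  beta
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

#' @export
print.genejam_precision <- function(x, ...) {
  q <- ncol(x$P)
  n_edges <- sum(abs(x$P[upper.tri(x$P)]) > 1e-8)
  cat(sprintf("Graphical-lasso precision estimate: q = %d, rho = %g, %d edge(s)\n",
              q, x$rho, n_edges))
  invisible(x)
}

#' Adjacency matrix from a precision estimate
#'
#' The trait graph has an edge between traits i and j exactly when the
#' estimated precision entry P_ij is non-zero (in magnitude above `tol`): a
#' non-zero precision entry means the two scores are conditionally dependent
#' given all others.
#'
#' @param precision A `genejam_precision` object or a symmetric q x q matrix.
#' @param tol Magnitude below which an entry counts as zero.
#' @return q x q binary symmetric adjacency matrix with zero diagonal.
#' @export
precision_adjacency <- function(precision, tol = 1e-8) {
  P <- if (inherits(precision, "genejam_precision")) precision$P else
    as_num_matrix(precision, "precision")
  A <- (abs(P) > tol) * 1
  diag(A) <- 0
  A <- ((A + t(A)) > 0) * 1  # symmetrize defensively
  dimnames(A) <- dimnames(P)
  A
}

#' Connected components of a trait adjacency graph
#'
#' Traits that are mutually reachable through edges form one cluster.
#' Components are labelled deterministically in order of their smallest
#' member index.
#'
#' @param adjacency q x q binary symmetric matrix with zero diagonal.
#' @return A list of class `genejam_clusters` with `adjacency`, `labels`
#'   (integer q-vector of component ids), `n_components`, `sizes` (size of
#'   each component) and `nonsingleton` (logical q-vector, TRUE for traits in
#'   components of size >= 2).
#' @export
trait_components <- function(adjacency) {
  A <- as_num_matrix(adjacency, "adjacency")
  q <- ncol(A)
  if (nrow(A) != q || any(A != t(A)) || any(diag(A) != 0) ||
      !all(A %in% c(0, 1))) {
    abort("`adjacency` must be a binary symmetric matrix with zero diagonal.")
  }
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  memb <- igraph::components(g)$membership
  # relabel so component 1 contains trait 1, etc.
  first_seen <- match(unique(memb), memb)
  relabel <- order(order(first_seen))
  labels <- relabel[match(memb, unique(memb))]
  sizes <- tabulate(labels)
  ids <- colnames(A) %||% default_ids(q, "trait")
  structure(
    list(adjacency = A, labels = setNames(as.integer(labels), ids),
         n_components = max(labels), sizes = sizes,
         nonsingleton = setNames(sizes[labels] >= 2, ids)),
    class = "genejam_clusters"
  )
}

#' @export
print.genejam_clusters <- function(x, ...) {
  cat(sprintf("Trait clustering: %d trait(s), %d component(s), %d clustered trait(s)\n",
              length(x$labels), x$n_components, sum(x$nonsingleton)))
  invisible(x)
}

#' @describeIn trait_components tidy method: one row per trait with its
#'   component label and component size.
#' @method tidy genejam_clusters
#' @param x A `genejam_clusters` object.
#' @param ... Unused.
#' @export
tidy.genejam_clusters <- function(x, ...) {
  tibble(
    trait = names(x$labels),
    component = unname(x$labels),
    component_size = x$sizes[x$labels],
    clustered = unname(x$nonsingleton)
  )
}
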