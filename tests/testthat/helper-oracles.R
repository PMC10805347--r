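# Independent oracles used across test files. These deliberately use naive
# formulations (dense matrices, loops, base solvers) so they share no code
# path with the package implementation.

# dense GLS oracle: literally builds the Nq x Nq covariance I_N (x) R and
# solves the normal equations of the row-wise vectorized system
dense_gls_oracle <- function(Z, Y, R) {
  n <- nrow(Z); q <- ncol(Z)
  Omega <- kronecker(diag(n), R)
  # row-wise vectorization: trait index fastest
  yv <- as.vector(t(Y))
  D <- matrix(0, n * q, 2 * q)
  for (i in seq_len(n)) {
    for (l in seq_len(q)) {
      row <- (i - 1) * q + l
      D[row, 2 * l - 1] <- 1
      D[row, 2 * l] <- Z[i, l]
    }
  }
  Oinv <- solve(Omega)
  A <- t(D) %*% Oinv %*% D
  bhat <- solve(A, t(D) %*% Oinv %*% yv)
  list(coef = matrix(bhat, nrow = 2), vcov = solve(A))
}

# KKT subgradient check for the graphical lasso with off-diagonal penalty:
# W = P^{-1} must satisfy W_ij - S_ij = rho * sign(P_ij) where P_ij != 0,
# |W_ij - S_ij| <= rho elsewhere (i != j), and W_ii = S_ii.
glasso_kkt_violation <- function(P, S, rho) {
  W <- solve(P)
  q <- ncol(S)
  viol <- max(abs(diag(W) - diag(S)))
  for (i in seq_len(q)) {
    for (j in seq_len(q)) {
      if (i == j) next
      d <- W[i, j] - S[i, j]
      if (abs(P[i, j]) > 1e-7) {
        viol <- max(viol, abs(d - rho * sign(P[i, j])))
      } else {
        viol <- max(viol, max(abs(d) - rho, 0))
      }
    }
  }
  viol
}

# transitive-closure component labels by repeated boolean matrix powering
closure_components_oracle <- function(A) {
  q <- ncol(A)
  Reach <- (A + diag(q)) > 0
  for (k in seq_len(q)) {
    Reach_new <- (Reach %*% Reach) > 0
    if (all(Reach_new == Reach)) break
    Reach <- Reach_new
  }
  labels <- integer(q)
  next_lab <- 0L
  for (i in seq_len(q)) {
    if (labels[i] == 0) {
      next_lab <- next_lab + 1L
      labels[Reach[i, ]] <- next_lab
    }
  }
  labels
}

# random positive semi-definite correlation matrix
random_corr <- function(q) {
  M <- matrix(rnorm(q * (q + 2)), q + 2, q)
  stats::cov2cor(crossprod(M))
}

# all-singleton clustering helper
singleton_clusters <- function(q) trait_components(matrix(0, q, q))

# clustering from an explicit edge list on q nodes
clusters_from_edges <- function(q, edges) {
  A <- matrix(0, q, q)
  for (e in edges) {
    A[e[1], e[2]] <- A[e[2], e[1]] <- 1
  }
  trait_components(A)
}
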