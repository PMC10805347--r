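test_that("OLS step matches lm() per trait and centres residuals", {
  set.seed(31)
  Z <- matrix(rnorm(60), 20, 3)
  Y <- matrix(rnorm(60), 20, 3)
  ols <- ols_step(Z, Y)
  for (l in 1:3) {
    fit <- lm(Y[, l] ~ Z[, l])
    expect_equal(unname(ols$coef["xi", l]), unname(coef(fit)[1]), tolerance = 1e-10)
    expect_equal(unname(ols$coef["beta", l]), unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(unname(ols$residuals[, l]), unname(residuals(fit)),
                 tolerance = 1e-10)
  }
  expect_true(all(abs(colMeans(ols$residuals)) < 1e-10))

  # identity relation: xi = 0, beta = 1, zero residuals
  ols_id <- ols_step(Z, Z)
  expect_equal(unname(ols_id$coef["xi", ]), rep(0, 3), tolerance = 1e-10)
  expect_equal(unname(ols_id$coef["beta", ]), rep(1, 3), tolerance = 1e-10)
  expect_true(max(abs(ols_id$residuals)) < 1e-10)

  # orthogonal score: beta 0, xi the trait mean
  z <- matrix(rep(c(-1, 1), 10), 20)
  y <- matrix(rep(c(2, 2, 4, 4), 5), 20)
  ols_o <- ols_step(z, y)
  expect_equal(unname(ols_o$coef["beta", 1]), 0)
  expect_equal(unname(ols_o$coef["xi", 1]), 3)
})

test_that("cluster covariance equals masked sample covariance", {
  set.seed(32)
  U <- matrix(rnorm(90), 30, 3)
  # all singletons: diagonal of sample variances
  Rs <- cluster_covariance(U, singleton_clusters(3))
  expect_equal(Rs, diag(apply(U, 2, var)), ignore_attr = TRUE)
  # one full component: the full sample covariance
  Rf <- cluster_covariance(U, clusters_from_edges(3, list(c(1, 2), c(2, 3))))
  expect_equal(Rf, cov(U), ignore_attr = TRUE)
  # components {1,2},{3}: masked covariance
  Rm <- cluster_covariance(U, clusters_from_edges(3, list(c(1, 2))))
  mask <- cov(U); mask[1:2, 3] <- mask[3, 1:2] <- 0
  expect_equal(Rm, mask, ignore_attr = TRUE)
  # component larger than N - 1 is an error
  expect_error(
    cluster_covariance(U[1:3, ], clusters_from_edges(3, list(c(1, 2), c(2, 3)))),
    "samples"
  )
})

test_that("gls_solve agrees with the dense-Omega oracle on small instances", {
  set.seed(33)
  for (r in 1:10) {
    n <- sample(4:6, 1)
    q <- sample(2:4, 1)
    Z <- matrix(rnorm(n * q), n, q)
    Y <- matrix(rnorm(n * q), n, q)
    R <- random_corr(q) * 2
    cl <- clusters_from_edges(q, lapply(seq_len(q - 1), function(i) c(i, i + 1)))
    out <- gls_solve(Z, Y, R, cl)
    oracle <- dense_gls_oracle(Z, Y, R)
    expect_equal(unname(out$coef), unname(oracle$coef), tolerance = 1e-8)
    # slope variances from the dense inverse normal matrix
    expect_equal(unname(out$se),
                 sqrt(diag(oracle$vcov)[seq(2, 2 * q, by = 2)]),
                 tolerance = 1e-8)
  }
})

test_that("GLS reduces to OLS under spherical or diagonal error covariance", {
  set.seed(34)
  Z <- matrix(rnorm(80), 20, 4)
  Y <- matrix(rnorm(80), 20, 4)
  ols <- ols_step(Z, Y)
  full_cl <- clusters_from_edges(4, list(c(1, 2), c(2, 3), c(3, 4)))
  # R = sigma^2 I within one big cluster
  out_sph <- gls_solve(Z, Y, diag(2.5, 4), full_cl)
  expect_equal(out_sph$coef, ols$coef, tolerance = 1e-8)
  # diagonal R with unequal variances: weights cancel per trait
  out_diag <- gls_solve(Z, Y, diag(c(1, 4, 9, 16)), full_cl)
  expect_equal(out_diag$coef, ols$coef, tolerance = 1e-8)
})

test_that("FGLS with all-singleton clustering is OLS with classical slope SEs", {
  set.seed(35)
  n <- 40
  Z <- matrix(rnorm(2 * n), n, 2)
  Y <- matrix(rnorm(2 * n), n, 2)
  fit <- fgls_fit(Z, Y)
  ols <- ols_step(Z, Y)
  expect_equal(fit$coef, ols$coef, tolerance = 1e-12)
  expect_equal(fit$n_iter, 1L)
  expect_true(fit$converged)
  # classical simple-regression slope SE with variance denominator n - 1
  for (l in 1:2) {
    s2 <- sum(fit$residuals[, l]^2) / (n - 1)
    se_classical <- sqrt(s2 / ((n - 1) * var(Z[, l])))
    expect_equal(unname(fit$se[l]), se_classical, tolerance = 1e-10)
  }
})

test_that("a single FGLS update matches a hand-stepped two-stage estimator", {
  set.seed(36)
  Z <- matrix(rnorm(60), 20, 3)
  Y <- matrix(rnorm(60), 20, 3)
  cl <- clusters_from_edges(3, list(c(1, 2)))
  fit1 <- suppressWarnings(fgls_fit(Z, Y, cl, max_iter = 1))
  ols <- ols_step(Z, Y)
  R1 <- cluster_covariance(ols$residuals, cl)
  step <- gls_solve(Z, Y, R1, cl)
  expect_equal(fit1$coef, step$coef)
  expect_equal(fit1$n_iter, 1L)
})

test_that("cluster separability: joint fit equals per-cluster fits", {
  set.seed(37)
  n <- 50
  Z <- matrix(rnorm(4 * n), n, 4)
  Y <- matrix(rnorm(4 * n), n, 4)
  cl <- clusters_from_edges(4, list(c(1, 2), c(3, 4)))
  joint <- fgls_fit(Z, Y, cl)
  sub12 <- fgls_fit(Z[, 1:2], Y[, 1:2], clusters_from_edges(2, list(c(1, 2))))
  sub34 <- fgls_fit(Z[, 3:4], Y[, 3:4], clusters_from_edges(2, list(c(1, 2))))
  expect_equal(unname(joint$coef[, 1:2]), unname(sub12$coef))
  expect_equal(unname(joint$coef[, 3:4]), unname(sub34$coef))
  expect_equal(unname(joint$se[1:2]), unname(sub12$se))
  expect_equal(unname(joint$se[3:4]), unname(sub34$se))
})

test_that("fit is equivariant under trait permutation", {
  set.seed(38)
  n <- 40
  Z <- matrix(rnorm(3 * n), n, 3)
  Y <- Z * 0.8 + matrix(rnorm(3 * n), n, 3)
  cl <- clusters_from_edges(3, list(c(1, 2)))
  fit <- fgls_fit(Z, Y, cl)
  perm <- c(3, 1, 2)
  Aperm <- cl$adjacency[perm, perm]
  fitp <- fgls_fit(Z[, perm], Y[, perm], trait_components(Aperm))
  expect_equal(unname(fitp$coef), unname(fit$coef[, perm]), tolerance = 1e-8)
  expect_equal(unname(fitp$se), unname(fit$se[perm]), tolerance = 1e-8)
  expect_equal(unname(fitp$R), unname(fit$R[perm, perm]), tolerance = 1e-8)
})

test_that("cluster covariance estimate is consistent for a known block R", {
  set.seed(39)
  R_true <- diag(4)
  R_true[1, 2] <- R_true[2, 1] <- 0.6
  R_true[3, 4] <- R_true[4, 3] <- -0.4
  cl <- clusters_from_edges(4, list(c(1, 2), c(3, 4)))
  n <- 500
  err_sum <- matrix(0, 4, 4)
  n_rep <- 20
  for (r in seq_len(n_rep)) {
    E <- matrix(rnorm(n * 4), n, 4) %*% chol(R_true)
    Z <- matrix(rnorm(n * 4), n, 4)
    Y <- 0.5 * Z + E
    fit <- fgls_fit(Z, Y, cl)
    err_sum <- err_sum + (fit$R - R_true)
  }
  # Monte-Carlo mean within ~3 standard errors of truth entrywise
  expect_lt(max(abs(err_sum / n_rep)), 3 / sqrt(n_rep * (n - 1)) * 3)
})

test_that("FGLS slopes are no more variable than OLS under strong residual correlation", {
  set.seed(40)
  n <- 300
  R_true <- matrix(0.8, 2, 2); diag(R_true) <- 1
  cl <- clusters_from_edges(2, list(c(1, 2)))
  n_rep <- 40
  wins <- 0
  beta_fgls <- beta_ols <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    Z <- matrix(rnorm(2 * n), n, 2)
    E <- matrix(rnorm(2 * n), n, 2) %*% chol(R_true)
    Y <- 0.3 * Z + E
    fgls <- fgls_fit(Z, Y, cl)
    ols <- ols_step(Z, Y)
    beta_fgls[r] <- fgls$coef["beta", 1]
    beta_ols[r] <- ols$coef["beta", 1]
    # paired comparison on the same data: reported FGLS SE vs classical OLS SE
    se_ols <- vapply(1:2, function(l) {
      s2 <- sum(ols$residuals[, l]^2) / (n - 1)
      sqrt(s2 / ((n - 1) * var(Z[, l])))
    }, numeric(1))
    wins <- wins + (mean(fgls$se) <= mean(se_ols))
  }
  expect_gte(wins / n_rep, 0.9)
  # empirical sampling variability of the estimator itself
  expect_lte(sd(beta_fgls), sd(beta_ols) * 1.02)
})

test_that("predict applies xi + beta * z and round-trips the training fit", {
  set.seed(41)
  Z <- matrix(rnorm(30), 15, 2)
  Y <- 1 + 2 * Z + matrix(rnorm(30, sd = .1), 15, 2)
  fit <- fgls_fit(Z, Y, clusters_from_edges(2, list(c(1, 2))))
  expect_equal(predict(fit, Z), fit$fitted)
  expect_equal(predict(fit), fit$fitted)
  # hand-computed 2x2 case
  Znew <- matrix(c(0, 1, 2, -1), 2)
  manual <- cbind(fit$coef["xi", 1] + fit$coef["beta", 1] * Znew[, 1],
                  fit$coef["xi", 2] + fit$coef["beta", 2] * Znew[, 2])
  expect_equal(unname(predict(fit, Znew)), manual, ignore_attr = TRUE)
  expect_error(predict(fit, Znew[, 1, drop = FALSE]), "traits")
})

test_that("tidy and glance summarize an FGLS fit", {
  set.seed(42)
  Z <- matrix(rnorm(60), 30, 2)
  Y <- Z + matrix(rnorm(60), 30, 2)
  fit <- fgls_fit(Z, Y, clusters_from_edges(2, list(c(1, 2))))
  td <- tidy(fit)
  expect_named(td, c("trait", "xi", "beta", "se_beta", "component",
                     "component_size"))
  expect_equal(nrow(td), 2)
  gl <- glance(fit)
  expect_equal(gl$n_traits, 2)
  expect_true(gl$converged)
})
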