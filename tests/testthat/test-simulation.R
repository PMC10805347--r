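test_that("Hardy-Weinberg genotypes have binomial genotype frequencies", {
  X <- simulate_genotypes(20000, 5, maf = 0.3, seed = 61)
  expect_true(all(X %in% 0:2))
  freqs <- table(factor(X, levels = 0:2)) / length(X)
  # binomial(2, 0.3) pmf: 0.49 / 0.42 / 0.09
  expect_equal(as.numeric(freqs), c(0.49, 0.42, 0.09), tolerance = 0.02)
  # per-SNP mean approx 2 * maf at maf = 0.5
  X5 <- simulate_genotypes(5000, 3, maf = 0.5, seed = 62)
  expect_true(all(abs(colMeans(X5) - 1) < 4 * sqrt(0.5 / 5000)))
  # determinism under seed
  expect_identical(simulate_genotypes(50, 10, 0.3, seed = 63),
                   simulate_genotypes(50, 10, 0.3, seed = 63))
  # maf range draws per-SNP frequencies
  Xr <- simulate_genotypes(2000, 50, maf = c(0.1, 0.5), seed = 64)
  expect_gt(var(colMeans(Xr)), var(colMeans(X5)))
  expect_error(simulate_genotypes(10, 2, maf = 0.7), "maf")
})

test_that("effect covariances match the design's moment targets and feasibility bounds", {
  # h2 = 0 everywhere: no genetic effects, unit noise
  d0 <- sim_design(n = 100, n_snps = 50, n_traits = 3, h2 = 0, rho = 0)
  cv0 <- effect_covariance(d0)
  expect_equal(cv0$Sigma_C, matrix(0, 3, 3))
  expect_equal(cv0$Sigma_E, diag(3))

  # infeasible: implied genetic correlation 0.5/0.3 > 1
  expect_error(sim_design(h2 = 0.3, rho = 0.5, tau_e = 0), "genetic correlation")
  # infeasible environmental correlation: tau_e |rho| > (1 - h2)
  expect_error(sim_design(h2 = 0.9, rho = 0.8, tau_e = 0.9),
               "environmental correlation")

  # diagonal terms: var(X C_l) = h2 / (1 - h2) by construction
  d <- sim_design(n = 100, n_snps = 200, n_traits = 2, h2 = 0.5, rho = 0.5)
  cv <- effect_covariance(d)
  v_x <- 2 * 0.3 * 0.7
  expect_equal(cv$Sigma_C[1, 1], 1 / (200 * v_x))  # V_A = 0.5/0.5 = 1
  expect_equal(cv$Sigma_E[1, 2], 0)  # tau_e = 0: all covariance genetic

  # environmental split moves covariance from Sigma_C to Sigma_E
  dt <- sim_design(n = 100, n_snps = 200, n_traits = 2, h2 = 0.5, rho = 0.5,
                   tau_e = 0.4)
  cvt <- effect_covariance(dt)
  expect_equal(cvt$Sigma_C[1, 2] * 200 * v_x + cvt$Sigma_E[1, 2],
               cv$Sigma_C[1, 2] * 200 * v_x)
  expect_equal(cvt$Sigma_E[1, 2] / (cvt$Sigma_C[1, 2] * 200 * v_x +
                                      cvt$Sigma_E[1, 2]), 0.4)
})

test_that("feasibility region matches the analytic constraints on a lattice", {
  for (h2 in c(0.1, 0.3, 0.5, 0.7)) {
    for (rho in c(0.1, 0.4, 0.7)) {
      for (tau_e in c(0, 0.3, 0.6, 1)) {
        feasible_g <- (1 - tau_e) * rho <= h2 + 1e-12
        feasible_e <- tau_e * rho <= (1 - h2) + 1e-12
        call_ok <- !inherits(
          tryCatch(sim_design(h2 = h2, rho = rho, tau_e = tau_e),
                   error = function(e) e),
          "error"
        )
        expect_equal(call_ok, feasible_g && feasible_e,
                     info = sprintf("h2=%g rho=%g tau_e=%g", h2, rho, tau_e))
      }
    }
  }
})

test_that("traits are genotype effects plus noise, reproducibly", {
  X <- simulate_genotypes(30, 20, 0.3, seed = 65)
  # Sigma_C = 0: Y = E exactly
  st <- simulate_traits(X, matrix(0, 2, 2), diag(2), seed = 66)
  expect_equal(st$Y, st$E, ignore_attr = TRUE)
  expect_equal(st$C, matrix(0, 20, 2), ignore_attr = TRUE)
  # Sigma_E = 0: Y = XC, fully heritable
  st2 <- simulate_traits(X, diag(0.01, 2), matrix(0, 2, 2), seed = 67)
  expect_equal(st2$Y, X %*% st2$C, ignore_attr = TRUE)
  # determinism
  st3 <- simulate_traits(X, diag(0.01, 2), diag(2), seed = 68)
  st4 <- simulate_traits(X, diag(0.01, 2), diag(2), seed = 68)
  expect_identical(st3$Y, st4$Y)
})

test_that("single-stage moments recover design heritability and correlation", {
  # large-sample moment-recovery oracle for the covariance reconstruction
  d <- sim_design(n = 20000, n_snps = 500, n_traits = 2, h2 = 0.5, rho = 0.5)
  cv <- effect_covariance(d)
  X <- simulate_genotypes(d$n, d$n_snps, d$maf, seed = 69)
  st <- simulate_traits(X, cv$Sigma_C, cv$Sigma_E, seed = 70)
  G <- X %*% st$C
  h2_hat <- apply(G, 2, var) / apply(st$Y, 2, var)
  # absolute +-0.05 recovery of the design moments
  expect_lt(max(abs(h2_hat - 0.5)), 0.05)
  expect_lt(abs(cor(st$Y[, 1], st$Y[, 2]) - 0.5), 0.05)
})

test_that("phenotypic correlation is recovered regardless of the environmental split", {
  d <- sim_design(n = 20000, n_snps = 300, n_traits = 2, h2 = 0.6, rho = 0.4,
                  tau_e = 0.5)
  cv <- effect_covariance(d)
  X <- simulate_genotypes(d$n, d$n_snps, d$maf, seed = 71)
  st <- simulate_traits(X, cv$Sigma_C, cv$Sigma_E, seed = 72)
  expect_lt(abs(cor(st$Y[, 1], st$Y[, 2]) - 0.4), 0.05)
})

test_that("two-stage studies are reproducible with the expected truth graph", {
  d <- sim_design(n = 150, n_snps = 100, n_traits = 4, h2 = 0.5, rho = 0.5)
  s1 <- simulate_study(d, seed = 73)
  s2 <- simulate_study(d, seed = 73)
  expect_identical(s1$Y, s2$Y)
  expect_identical(s1$Z, s2$Z)
  # pair architecture: exactly one true edge, between traits 1 and 2
  expect_equal(sum(s1$true_adjacency), 2)
  expect_equal(s1$true_adjacency[1, 2], 1)
  # all-shared architecture: complete graph
  da <- sim_design(n = 150, n_snps = 100, n_traits = 4, h2 = 0.1,
                   architecture = "all_shared")
  sa <- simulate_study(da, seed = 74)
  expect_equal(sa$true_adjacency, 1 - diag(4), ignore_attr = TRUE)
  # all-shared effect columns are identical up to sign of the shared draw
  expect_equal(cor(sa$C[, 1], sa$C[, 2]), 1, tolerance = 1e-10)
})

test_that("two-stage scores inherit the genetic correlation", {
  n_pos <- 0
  for (r in 1:15) {
    d <- sim_design(n = 400, n_snps = 300, n_traits = 3, h2 = 0.5, rho = 0.5)
    s <- simulate_study(d, seed = 200 + r)
    n_pos <- n_pos + (cor(s$Z[, 1], s$Z[, 2]) > 0)
  }
  expect_gte(n_pos, 14)
})
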