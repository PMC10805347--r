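#' Simulation design for a multi-trait GWAS study
#'
#' Describes the data-generating process used throughout the package's
#' simulation study: independent Hardy-Weinberg SNPs, Gaussian additive
#' effects with controlled per-trait heritability, a controlled phenotypic
#' correlation between a designated trait pair (traits 1 and 2), and an
#' optional fraction of that correlation attributable to shared environment
#' rather than shared genetics.
#'
#' Defaults are the study conditions of the package's reference simulation:
#' N = 1000 individuals, p = 10000 SNPs at minor-allele frequency 0.3,
#' q = 10 traits. `maf` may be a scalar or a range (then per-SNP allele
#' frequencies are drawn uniformly from it).
#'
#' @param n Sample size N.
#' @param n_snps Number of SNPs p.
#' @param n_traits Number of traits q (>= 2).
#' @param maf Minor-allele frequency in (0, 0.5]; scalar or length-2 range.
#' @param h2 Heritability of the designated pair (architecture `"pair"`) or
#'   of every trait (`"all_shared"`); scalar in [0, 1) or length-q vector.
#' @param rho Target phenotypic correlation between traits 1 and 2
#'   (architecture `"pair"` only), in (-1, 1).
#' @param tau_e Fraction of the between-trait phenotypic covariance
#'   attributable to environment, in [0, 1].
#' @param architecture `"pair"` (traits 1-2 share genetics, the rest are
#'   null) or `"all_shared"` (every trait gets the identical genetic effect
#'   vector: genetic correlation 1 among all traits).
#' @return A list of class `genejam_design`.
#' @export
sim_design <- function(n = 1000, n_snps = 10000, n_traits = 10, maf = 0.3,
                       h2 = 0.5, rho = 0.5, tau_e = 0,
                       architecture = c("pair", "all_shared")) {
  architecture <- match.arg(architecture)
  if (any(maf <= 0) || any(maf > 0.5) || !length(maf) %in% c(1, 2)) {
    abort("`maf` must be a scalar or range within (0, 0.5].")
  }
  if (n_traits < 2) abort("`n_traits` must be at least 2.")
  h2 <- if (length(h2) == 1 && architecture == "pair") {
    c(rep(h2, 2), rep(0, n_traits - 2))
  } else if (length(h2) == 1) {
    rep(h2, n_traits)
  } else h2
  if (length(h2) != n_traits || any(h2 < 0) || any(h2 >= 1)) {
    abort("`h2` must be length q with entries in [0, 1).")
  }
  if (abs(rho) >= 1) abort("`rho` must be in (-1, 1).")
  if (tau_e < 0 || tau_e > 1) abort("`tau_e` must be in [0, 1].")
  design <- structure(
    list(n = n, n_snps = n_snps, n_traits = n_traits, maf = maf, h2 = h2,
         rho = rho, tau_e = tau_e, architecture = architecture),
    class = "genejam_design"
  )
  effect_covariance(design)  # errors early if infeasible
  design
}

#' @export
print.genejam_design <- function(x, ...) {
  cat(sprintf(
    "Simulation design (%s): N = %d, p = %d, q = %d, maf = %s\n  h2 = %s, rho = %g, tau_e = %g\n",
    x$architecture, x$n, x$n_snps, x$n_traits,
    paste(x$maf, collapse = "-"),
    paste(unique(x$h2), collapse = "/"), x$rho, x$tau_e
  ))
  invisible(x)
}

#' Effect and noise covariances implied by a design
#'
#' Translates the design's heritability, phenotypic correlation and
#' environmental fraction into the covariance of the per-SNP genetic effect
#' rows (`Sigma_C`) and of the per-individual environmental noise rows
#' (`Sigma_E`), by moment matching with unit environmental variance:
#'
#' * V_A,l = h2_l / (1 - h2_l), so V_P,l = V_A,l + 1 and V_A/V_P = h2;
#' * `Sigma_C[l,l] = V_A,l / (p * V(X))` with V(X) = 2 pi (1 - pi) averaged
#'   over SNPs, so that var(X C_l) = V_A,l;
#' * `Sigma_C[l,l'] = (1 - tau_e) * rho * sqrt(V_P,l V_P,l') / (p * V(X))`
#'   and `Sigma_E[l,l'] = tau_e * rho * sqrt(V_P,l V_P,l')` for the
#'   designated pair, so that cov(Y_l, Y_l') = rho * sqrt(V_P,l V_P,l')
#'   regardless of how the covariance is split between genetics and
#'   environment.
#'
#' Not every (h2, rho, tau_e) combination is feasible: the implied genetic
#' correlation `(1 - tau_e) rho / sqrt(h2_l h2_l')` and environmental
#' correlation `tau_e rho / sqrt((1 - h2_l)(1 - h2_l'))` must both lie in
#' [-1, 1]; infeasible designs raise an error naming the violated bound.
#'
#' @param design A `genejam_design`.
#' @return List with q x q matrices `Sigma_C` and `Sigma_E`, and `v_x` (the
#'   average per-SNP variance used).
#' @export
effect_covariance <- function(design) {
  stopifnot(inherits(design, "genejam_design"))
  q <- design$n_traits
  p <- design$n_snps
  pi_bar <- mean(design$maf)
  v_x <- if (length(design$maf) == 2) {
    # E[2 pi (1 - pi)] for pi ~ Uniform(a, b)
    a <- design$maf[1]; b <- design$maf[2]
    2 * ((a + b) / 2 - (a^2 + a * b + b^2) / 3)
  } else 2 * pi_bar * (1 - pi_bar)
  h2 <- design$h2
  v_a <- h2 / (1 - h2)
  v_p <- v_a + 1

  Sigma_C <- diag(v_a / (p * v_x), q)
  Sigma_E <- diag(q)
  if (design$architecture == "all_shared") {
    # identical effect vectors across traits: genetic correlation exactly 1
    sdc <- sqrt(v_a / (p * v_x))
    Sigma_C <- tcrossprod(sdc)
  } else if (design$rho != 0) {
    l <- 1; l2 <- 2
    g_corr <- (1 - design$tau_e) * design$rho / sqrt(h2[l] * h2[l2])
    e_corr <- design$tau_e * design$rho / sqrt((1 - h2[l]) * (1 - h2[l2]))
    if (!is.finite(g_corr) || abs(g_corr) > 1 + 1e-12) {
      abort(sprintf(
        "Infeasible design: implied genetic correlation %.3g exceeds 1 (need (1 - tau_e)|rho| <= sqrt(h2_1 h2_2)).",
        g_corr
      ))
    }
    if (abs(e_corr) > 1 + 1e-12) {
      abort(sprintf(
        "Infeasible design: implied environmental correlation %.3g exceeds 1.",
        e_corr
      ))
    }
    cross <- design$rho * sqrt(v_p[l] * v_p[l2])
    Sigma_C[l, l2] <- Sigma_C[l2, l] <- (1 - design$tau_e) * cross / (p * v_x)
    Sigma_E[l, l2] <- Sigma_E[l2, l] <- design$tau_e * cross
  }
  for (M in list(Sigma_C, Sigma_E)) {
    ev <- min(eigen(M, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < -1e-10) abort("Infeasible design: implied covariance not PSD.")
  }
  list(Sigma_C = Sigma_C, Sigma_E = Sigma_E, v_x = v_x)
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Independent additive allele counts x_ij ~ Binomial(2, pi_j): genotype
#' frequencies pi^2, 2 pi (1 - pi), (1 - pi)^2 under random mating. With a
#' `maf` range, per-SNP allele frequencies are drawn uniformly from it.
#'
#' @param n,n_snps Dimensions.
#' @param maf Scalar frequency in (0, 0.5] or a length-2 range.
#' @param seed Optional integer seed (set once at entry).
#' @return n x n_snps integer-valued matrix with values in \{0, 1, 2\}.
#' @export
simulate_genotypes <- function(n, n_snps, maf = 0.3, seed = NULL) {
  if (any(maf <= 0) || any(maf > 0.5)) abort("`maf` must lie in (0, 0.5].")
  if (!is.null(seed)) set.seed(seed)
  pis <- if (length(maf) == 2) runif(n_snps, maf[1], maf[2]) else
    rep(maf, n_snps)
  X <- matrix(rbinom(n * n_snps, 2L, rep(pis, each = n)), nrow = n)
  colnames(X) <- default_ids(n_snps, "snp")
  X
}

# i.i.d. rows from N(0, Sigma) via the Cholesky factor (PSD-safe through a
# tiny diagonal nudge on exactly-singular matrices, e.g. genetic corr = 1)
rmvn_rows <- function(n, Sigma) {
  q <- ncol(Sigma)
  if (all(Sigma == 0)) return(matrix(0, n, q))
  ch <- tryCatch(chol(Sigma), error = function(e)
    chol(Sigma + diag(1e-12 * max(diag(Sigma)), q)))
  matrix(rnorm(n * q), n, q) %*% ch
}

#' Simulate traits from genotypes and effect/noise covariances
#'
#' Draws each SNP's effect row independently from N(0, Sigma_C) and each
#' individual's environmental row from N(0, Sigma_E), and returns
#' Y = X C + E.
#'
#' @param genotypes N x p genotype matrix.
#' @param Sigma_C q x q per-SNP effect covariance.
#' @param Sigma_E q x q environmental covariance.
#' @param seed Optional integer seed.
#' @return List with `Y` (N x q), `C` (p x q) and `E` (N x q).
#' @export
simulate_traits <- function(genotypes, Sigma_C, Sigma_E, seed = NULL) {
  X <- as_num_matrix(genotypes, "genotypes")
  if (!is.null(seed)) set.seed(seed)
  C <- rmvn_rows(ncol(X), Sigma_C)
  E <- rmvn_rows(nrow(X), Sigma_E)
  Y <- X %*% C + E
  colnames(Y) <- colnames(E) <- default_ids(ncol(Sigma_C), "trait")
  colnames(C) <- colnames(Y)
  list(Y = Y, C = C, E = E)
}

#' Two-stage simulated study
#'
#' Emulates score construction from an unrelated GWAS: stage 1 simulates a
#' training sample (X0, Y0) and estimates the marginal per-SNP weights on
#' it; stage 2 simulates an independent genotype sample with the same allele
#' frequencies and the *same* true effect matrix C, forms scores Z = X W-hat
#' with the stage-1 weights, and draws the analysis traits Y = X C + E with
#' fresh environmental noise. The analysis sample's scores therefore carry
#' only the genetic signal that survived the training-sample estimation.
#'
#' The true adjacency has an edge between two traits exactly when their
#' generating genetic covariance is non-zero.
#'
#' @param design A `genejam_design`.
#' @param seed Integer seed (both stages are drawn from this one stream, so
#'   the study is fully reproducible).
#' @return A list of class `genejam_study` with `Y`, `Z`, `X`, `C`, `E`,
#'   `true_adjacency`, `weights` (stage-1 `genejam_weights`), and `design`.
#' @export
simulate_study <- function(design, seed = 1) {
  stopifnot(inherits(design, "genejam_design"))
  cov_mats <- effect_covariance(design)
  set.seed(seed)
  # stage 1: training sample and marginal weights
  X0 <- simulate_genotypes(design$n, design$n_snps, design$maf)
  st1 <- simulate_traits(X0, cov_mats$Sigma_C, cov_mats$Sigma_E)
  W <- marginal_weights(X0, st1$Y)
  # stage 2: independent sample, same effects, fresh noise
  X <- simulate_genotypes(design$n, design$n_snps, design$maf)
  E <- rmvn_rows(design$n, cov_mats$Sigma_E)
  colnames(E) <- colnames(st1$Y)
  Y <- X %*% st1$C + E
  colnames(Y) <- colnames(st1$Y)
  Z <- compute_scores(X, W)

  A_true <- (abs(cov_mats$Sigma_C) > 0) * 1
  diag(A_true) <- 0
  ids <- colnames(Y)
  dimnames(A_true) <- list(ids, ids)
  structure(
    list(Y = Y, Z = Z, X = X, C = st1$C, E = E, true_adjacency = A_true,
         weights = W, design = design, seed = seed),
    class = "genejam_study"
  )
}

#' @export
print.genejam_study <- function(x, ...) {
  cat(sprintf("Simulated study: N = %d, p = %d, q = %d (%s architecture), %d true edge(s)\n",
              nrow(x$Y), ncol(x$X), ncol(x$Y), x$design$architecture,
              sum(x$true_adjacency) / 2))
  invisible(x)
}
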