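#' Rand index between two adjacency matrices
#'
#' Fraction of the q(q-1)/2 unordered trait pairs on which the two graphs
#' agree (both have the edge or both lack it). 1 means identical graphs.
#' This is edge-level agreement on the adjacency matrices themselves, the
#' package's default; set `co_membership = TRUE` to compare component
#' co-membership (transitive closure) instead - the two differ when an
#' estimated graph is not transitively closed.
#'
#' @param a_est,a_true q x q binary symmetric adjacency matrices with zero
#'   diagonal.
#' @param co_membership Compare component co-membership instead of edges.
#' @return Scalar in [0, 1].
#' @examples
#' a <- b <- matrix(0, 3, 3)
#' a[1, 2] <- a[2, 1] <- 1
#' b[1, 3] <- b[3, 1] <- 1
#' rand_index(a, b)  # 1/3
#' @export
rand_index <- function(a_est, a_true, co_membership = FALSE) {
  A <- as_num_matrix(a_est, "a_est")
  B <- as_num_matrix(a_true, "a_true")
  if (!all(dim(A) == dim(B))) abort("Adjacency matrices must have the same dimension.")
  if (co_membership) {
    A <- co_membership_matrix(A)
    B <- co_membership_matrix(B)
  }
  ut <- upper.tri(A)
  mean(A[ut] == B[ut])
}

co_membership_matrix <- function(A) {
  cl <- trait_components(A)
  M <- outer(cl$labels, cl$labels, "==") * 1
  diag(M) <- 0
  M
}

#' Per-trait root mean squared error
#'
#' @param traits N x q observed trait matrix.
#' @param predicted N x q predicted trait matrix.
#' @return Named numeric q-vector of per-trait RMSEs.
#' @export
trait_rmse <- function(traits, predicted) {
  Y <- as_num_matrix(traits, "traits")
  Yh <- as_num_matrix(predicted, "predicted")
  if (!all(dim(Y) == dim(Yh))) abort("`traits` and `predicted` must have the same shape.")
  out <- sqrt(colMeans((Y - Yh)^2))
  names(out) <- colnames(Y) %||% default_ids(ncol(Y), "trait")
  out
}

#' Monte-Carlo evaluation of the full pipeline on a simulation design
#'
#' Repeats, for `n_replicates` seeds derived deterministically from
#' `base_seed`: simulate a two-stage study, run the path-tuned pipeline on
#' its scores and traits, and score the selected model against the
#' generating truth - Rand index of the selected adjacency, exact-recovery
#' indicator, estimated residual correlation between the designated trait
#' pair, average SE at the selected penalty, and mean per-trait RMSE of the
#' selected fit on the replicate's own data.
#'
#' A replicate that errors is excluded and counted, never fatal.
#'
#' @param design A `genejam_design`.
#' @param n_replicates Number of replicates.
#' @param base_seed Integer seed for the replicate seed stream.
#' @param n_rho Penalty grid size passed to [genejam()].
#' @param ... Further arguments passed to [genejam()].
#' @return An object of class `genejam_replicates`: list with `replicates`
#'   (tibble: `replicate`, `seed`, `rand_index`, `exact_recovery`,
#'   `est_corr`, `avg_se`, `mean_rmse`, `n_components`, `fallback`),
#'   `summary` (one-row tibble with `mean_ri`, `mean_est_corr`,
#'   `mean_avg_se`, `mean_rmse`, `n_exact_recovery`, `n_failed`), and
#'   `design`.
#' @export
replicate_study <- function(design, n_replicates = 25, base_seed = 1,
                            n_rho = 50, ...) {
  stopifnot(inherits(design, "genejam_design"))
  set.seed(base_seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_replicates)
  rows <- vector("list", n_replicates)
  n_failed <- 0L
  for (i in seq_len(n_replicates)) {
    rows[[i]] <- tryCatch({
      study <- simulate_study(design, seed = seeds[i])
      fit <- suppressWarnings(
        suppressMessages(genejam(study$Z, study$Y, n_rho = n_rho, ...))
      )
      A_est <- if (fit$fallback) {
        matrix(0, design$n_traits, design$n_traits)
      } else fit$clusters$adjacency
      tibble(
        replicate = i, seed = seeds[i],
        rand_index = rand_index(A_est, study$true_adjacency),
        exact_recovery = all(A_est == study$true_adjacency),
        est_corr = estimated_correlation(fit$fit, 1, 2),
        avg_se = if (fit$fallback) NA_real_ else
          min(fit$path$avg_se, na.rm = TRUE),
        mean_rmse = mean(trait_rmse(study$Y, predict(fit$fit))),
        n_components = fit$fit$clusters$n_components,
        fallback = fit$fallback
      )
    }, error = function(e) {
      n_failed <<- n_failed + 1L
      warn(sprintf("Replicate %d failed: %s", i, conditionMessage(e)))
      NULL
    })
  }
  reps <- dplyr::bind_rows(rows)
  summary <- tibble(
    mean_ri = mean(reps$rand_index),
    mean_est_corr = mean(reps$est_corr),
    mean_avg_se = mean(reps$avg_se, na.rm = TRUE),
    mean_rmse = mean(reps$mean_rmse),
    n_exact_recovery = sum(reps$exact_recovery),
    n_replicates = nrow(reps),
    n_failed = n_failed
  )
  structure(list(replicates = reps, summary = summary, design = design,
                 base_seed = base_seed),
            class = "genejam_replicates")
}

#' @export
print.genejam_replicates <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Replicate study: %d replicate(s) (%d failed)\n  mean RI %.3f | exact recovery %d | mean est. corr %.3f | mean RMSE %.3f\n",
    s$n_replicates, s$n_failed, s$mean_ri, s$n_exact_recovery,
    s$mean_est_corr, s$mean_rmse
  ))
  invisible(x)
}

#' @describeIn replicate_study per-replicate metric rows.
#' @method tidy genejam_replicates
#' @param x A `genejam_replicates` object.
#' @param ... Unused.
#' @export
tidy.genejam_replicates <- function(x, ...) x$replicates

#' @describeIn replicate_study one-row aggregate summary.
#' @method glance genejam_replicates
#' @export
glance.genejam_replicates <- function(x, ...) x$summary
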