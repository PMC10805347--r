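#' Average standard error over clustered traits
#'
#' The tuning criterion: the mean slope standard error over traits that
#' belong to components of size at least two. Singleton traits are fitted by
#' plain per-trait OLS whatever the penalty, so they carry no information
#' about the clustering and are excluded; when no trait is clustered the
#' criterion is undefined (`NA`).
#'
#' @param se Numeric q-vector of per-trait slope standard errors.
#' @param clusters A `genejam_clusters` object.
#' @return Scalar mean, or `NA_real_` when all traits are singletons.
#' @export
average_se <- function(se, clusters) {
  stopifnot(inherits(clusters, "genejam_clusters"))
  if (length(se) != length(clusters$labels)) {
    abort("`se` length does not match the clustering.")
  }
  idx <- which(clusters$nonsingleton)
  if (length(idx) == 0) return(NA_real_)
  mean(se[idx])
}

#' Fit the genejam model along a regularization path
#'
#' Runs the full procedure: standardize the scores, build the penalty grid
#' from their correlation matrix, and for each penalty value (in increasing
#' order) estimate the sparse precision matrix, extract the trait graph and
#' its connected components, fit the cluster-block FGLS model and record the
#' average standard error of the clustered slopes. The path stops early at
#' the first penalty whose graph has no edges (larger penalties can only stay
#' empty). The selected penalty minimizes the average SE; ties are broken
#' toward the smaller penalty (denser clustering, erring on the side of
#' complexity). If no penalty clusters anything the fit falls back to
#' per-trait OLS with a message.
#'
#' Degenerate (zero-variance) score columns are excluded from the graph
#' estimation and forced to be singletons.
#'
#' @param scores N x q polygenic-score matrix (one column per trait).
#' @param traits N x q trait matrix.
#' @param n_rho Number of penalty grid points.
#' @param rho_scale `"linear"` or `"log"` grid spacing.
#' @param rho Optional explicit penalty grid (overrides `n_rho`/`rho_scale`).
#' @param adjacency_tol Magnitude threshold for declaring a precision entry
#'   zero.
#' @param penalize_diagonal Passed to [graphical_lasso()].
#' @param max_iter,tol,ridge Passed to [fgls_fit()].
#' @return An object of class `genejam_path`: list with `path` (tibble with
#'   one row per evaluated penalty: `rho`, `n_edges`, `n_components`,
#'   `n_clustered`, `avg_se`, `converged`), `rho_min`, `fit` (the selected
#'   `genejam_fgls`), `clusters` (selected clustering), `records` (per-rho
#'   clusterings and fits), `early_stopped_at` (grid index or `NA`), `S`
#'   (score correlation matrix), and `fallback` (TRUE if OLS fallback used).
#' @examples
#' set.seed(1)
#' z <- matrix(rnorm(200), 100, 2)
#' y <- z + matrix(rnorm(200), 100, 2)
#' fit <- genejam(z, y, n_rho = 10)
#' tidy(fit)
#' @export
genejam <- function(scores, traits, n_rho = 50,
                    rho_scale = c("linear", "log"), rho = NULL,
                    adjacency_tol = 1e-8, penalize_diagonal = FALSE,
                    max_iter = 100, tol = 1e-6, ridge = 1e-8) {
  rho_scale <- match.arg(rho_scale)
  Z <- as_num_matrix(scores, "scores")
  Y <- as_num_matrix(traits, "traits")
  q <- ncol(Z)
  if (ncol(Y) != q || nrow(Y) != nrow(Z)) {
    abort("`scores` and `traits` must both be N x q with matching shapes.")
  }
  if (q < 2) abort("Clustering needs at least 2 traits.")
  if (nrow(Z) < 3) abort("At least 3 samples are required.")
  ids <- colnames(Y) %||% colnames(Z) %||% default_ids(q, "trait")
  colnames(Z) <- colnames(Y) <- ids

  std <- standardize_scores(Z)
  active <- which(!std$degenerate)
  if (length(active) < 2) {
    inform("Fewer than 2 non-degenerate score columns: falling back to per-trait OLS.")
    fit <- fgls_fit(Z, Y)
    return(new_genejam_path(list(), NA_real_, fit, fit$clusters, NA_integer_,
                            std$S, grid = numeric(0), fallback = TRUE))
  }
  S_act <- std$S[active, active, drop = FALSE]
  grid <- rho %||% rho_path(S_act, n_rho = n_rho, scale = rho_scale)
  grid <- sort(grid)

  records <- list()
  early_stop <- NA_integer_
  for (r in seq_along(grid)) {
    rec <- tryCatch({
      gl <- graphical_lasso(S_act, grid[r], penalize_diagonal = penalize_diagonal)
      A <- matrix(0, q, q, dimnames = list(ids, ids))
      A[active, active] <- precision_adjacency(gl, tol = adjacency_tol)
      cl <- trait_components(A)
      if (sum(A) == 0) {
        list(rho = grid[r], clusters = cl, fit = NULL, avg_se = NA_real_,
             empty = TRUE, error = NA_character_)
      } else {
        fit <- fgls_fit(Z, Y, cl, max_iter = max_iter, tol = tol, ridge = ridge)
        list(rho = grid[r], clusters = cl, fit = fit,
             avg_se = average_se(fit$se, cl), empty = FALSE,
             error = NA_character_)
      }
    }, error = function(e) {
      list(rho = grid[r], clusters = NULL, fit = NULL, avg_se = NA_real_,
           empty = FALSE, error = conditionMessage(e))
    })
    records[[r]] <- rec
    if (isTRUE(rec$empty)) {
      early_stop <- r
      break
    }
  }

  avg_ses <- vapply(records, function(r) r$avg_se, numeric(1))
  if (all(is.na(avg_ses))) {
    inform("No penalty produced a non-singleton clustering: falling back to per-trait OLS.")
    fit <- fgls_fit(Z, Y)
    return(new_genejam_path(records, NA_real_, fit, fit$clusters, early_stop,
                            std$S, grid, fallback = TRUE))
  }
  best <- which(avg_ses == min(avg_ses, na.rm = TRUE))[1]  # ties -> smaller rho
  sel <- records[[best]]
  new_genejam_path(records, sel$rho, sel$fit, sel$clusters, early_stop,
                   std$S, grid, fallback = FALSE)
}

new_genejam_path <- function(records, rho_min, fit, clusters, early_stop,
                             S, grid, fallback) {
  path <- purrr::map_dfr(records, function(r) {
    tibble(
      rho = r$rho,
      n_edges = if (is.null(r$clusters)) NA_integer_ else
        as.integer(sum(r$clusters$adjacency) / 2),
      n_components = if (is.null(r$clusters)) NA_integer_ else
        r$clusters$n_components,
      n_clustered = if (is.null(r$clusters)) NA_integer_ else
        as.integer(sum(r$clusters$nonsingleton)),
      avg_se = r$avg_se,
      converged = if (is.null(r$fit)) NA else r$fit$converged,
      error = r$error
    )
  })
  structure(
    list(path = path, rho_min = rho_min, fit = fit, clusters = clusters,
         records = records, early_stopped_at = early_stop, S = S,
         grid = grid, fallback = fallback),
    class = "genejam_path"
  )
}

#' @export
print.genejam_path <- function(x, ...) {
  cat(sprintf("genejam path fit: %d penalty value(s) evaluated\n", nrow(x$path)))
  if (x$fallback) {
    cat("  no clustered solution; per-trait OLS fallback\n")
  } else {
    cat(sprintf("  selected rho = %.4g: %d component(s), %d clustered trait(s), avg SE %.4g\n",
                x$rho_min, x$clusters$n_components, sum(x$clusters$nonsingleton),
                min(x$path$avg_se, na.rm = TRUE)))
  }
  invisible(x)
}

#' @describeIn genejam per-trait coefficients of the selected fit.
#' @method tidy genejam_path
#' @param x A `genejam_path` object.
#' @param ... Unused.
#' @export
tidy.genejam_path <- function(x, ...) tidy(x$fit)

#' @describeIn genejam one-row summary of the selected model.
#' @method glance genejam_path
#' @export
glance.genejam_path <- function(x, ...) {
  dplyr::bind_cols(
    tibble(rho_min = x$rho_min, n_rho_evaluated = nrow(x$path),
           fallback = x$fallback,
           early_stopped = !is.na(x$early_stopped_at),
           avg_se_min = if (x$fallback) NA_real_ else
             min(x$path$avg_se, na.rm = TRUE)),
    glance(x$fit)
  )
}

#' Path diagnostics table
#'
#' One row per evaluated penalty with the number of edges, components,
#' clustered traits and the tuning criterion, mirroring the method's
#' diagnostics plots.
#'
#' @param x A `genejam_path` object.
#' @return A tibble.
#' @export
path_diagnostics <- function(x) {
  stopifnot(inherits(x, "genejam_path"))
  x$path
}

#' Estimated residual correlation between two traits
#'
#' Reads the correlation between two traits off the selected fit's
#' cluster-block residual covariance. Traits in different components are
#' structurally uncorrelated, so the value is 0 when the pair is not
#' clustered together.
#'
#' @param fit A `genejam_fgls` or `genejam_path` object.
#' @param l,l2 Trait indices (or names).
#' @return Scalar correlation.
#' @export
estimated_correlation <- function(fit, l = 1, l2 = 2) {
  if (inherits(fit, "genejam_path")) fit <- fit$fit
  stopifnot(inherits(fit, "genejam_fgls"))
  R <- fit$R
  if (is.character(l)) l <- match(l, colnames(R))
  if (is.character(l2)) l2 <- match(l2, colnames(R))
  if (R[l, l2] == 0) return(0)
  R[l, l2] / sqrt(R[l, l] * R[l2, l2])
}
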