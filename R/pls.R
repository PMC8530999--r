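#' Column standardization (population convention)
#'
#' Centers each column to mean 0 and scales it to population SD 1 (divide by
#' n). Both the imaging and behavior matrices are standardized this way before
#' the PLS cross-product, which makes the decomposed matrix a correlation-type
#' matrix and the singular values scale-free.
#'
#' @param M Numeric matrix.
#' @param allow_constant If `TRUE`, constant columns are centered and left at
#'   zero instead of raising an error (used inside resampling where a
#'   bootstrap draw can flatten a column).
#' @return List with `z` (standardized matrix), `means`, `sds`.
#' @export
standardize_columns <- function(M, allow_constant = FALSE) {
  M <- as.matrix(M)
  mu <- colMeans(M)
  Z <- sweep(M, 2, mu)
  s <- sqrt(colMeans(Z^2))
  zero <- s < 1e-15
  if (any(zero) && !allow_constant) {
    nm <- colnames(M)[zero]
    if (is.null(nm)) nm <- which(zero)
    stop("constant column(s) cannot be standardized: ", paste(nm, collapse = ", "))
  }
  s_safe <- ifelse(zero, 1, s)
  Z <- sweep(Z, 2, s_safe, "/")
  list(z = Z, means = mu, sds = s)
}

#' Bundle imaging, behavior and group labels for PLS
#'
#' @param X N x V deconfounded imaging matrix.
#' @param Y N x B behavior matrix (columns e.g. ALS, MADRS, YMRS).
#' @param groups Length-N vector of diagnostic group labels.
#' @return A list of class `brain_behavior_data`.
#' @export
brain_behavior_data <- function(X, Y, groups) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (!all(is.finite(X)) || !all(is.finite(Y))) {
    stop("X and Y must be finite everywhere")
  }
  if (nrow(X) != nrow(Y) || nrow(X) != length(groups)) {
    stop("X, Y and groups must agree on the number of participants")
  }
  if (nrow(Y) < ncol(Y) + 2) stop("too few participants for the behavior dimension")
  structure(list(X = X, Y = Y, groups = as.character(groups)),
            class = "brain_behavior_data")
}

#' Fit a PLS correlation model
#'
#' Decomposes the brain-behavior cross-correlation matrix
#' `R = t(Y_z) %*% X_z / (N - 1)` (both matrices column-standardized) by SVD.
#' Component k pairs the behavior salience `U[, k]` with the brain salience
#' `V[, k]`; its singular value measures the covariance the pair captures, and
#' `explained_covariance = d_k^2 / sum(d^2)`. Participant scores are the
#' projections `Lx = X_z %*% V` and `Ly = Y_z %*% U`. Each component's sign is
#' fixed so the largest-magnitude behavior-salience entry is positive, with
#' the brain side and scores flipped jointly.
#'
#' @param data A [brain_behavior_data()].
#' @return A list of class `pls_model` with elements `u` (B x C behavior
#'   saliences), `v` (V x C brain saliences), `d` (singular values,
#'   non-increasing), `explained`, `Lx`, `Ly`, the standardization moments and
#'   `groups`.
#' @export
pls_fit <- function(data) {
  stopifnot(inherits(data, "brain_behavior_data"))
  xs <- standardize_columns(data$X)
  ys <- standardize_columns(data$Y)
  n <- nrow(data$X)
  R <- crossprod(ys$z, xs$z) / (n - 1)
  sv <- svd(R)
  tol <- max(dim(R)) * .Machine$double.eps * max(sv$d, 0)
  rank <- sum(sv$d > tol)
  C <- max(1L, min(nrow(R), rank))
  u <- sv$u[, seq_len(C), drop = FALSE]
  v <- sv$v[, seq_len(C), drop = FALSE]
  d <- sv$d[seq_len(C)]
  for (k in seq_len(C)) {
    j <- which.max(abs(u[, k]))
    if (u[j, k] < 0) {
      u[, k] <- -u[, k]
      v[, k] <- -v[, k]
    }
  }
  explained <- sv$d^2 / sum(sv$d^2)
  structure(list(u = u, v = v, d = d,
                 explained = explained[seq_len(C)],
                 explained_all = explained,
                 Lx = xs$z %*% v, Ly = ys$z %*% u,
                 x_means = xs$means, x_sds = xs$sds,
                 y_means = ys$means, y_sds = ys$sds,
                 n = n, groups = data$groups,
                 behavior_names = colnames(data$Y)),
            class = "pls_model")
}

# Pearson correlation of each column of M with each column of scores;
# zero-variance columns give NA (flagged by the caller).
safe_cor <- function(M, scores) {
  M <- as.matrix(M)
  s <- apply(M, 2, stats::sd)
  out <- suppressWarnings(stats::cor(M, scores))
  out[s == 0, ] <- NA_real_
  out
}

#' Attach loadings to a fitted PLS model
#'
#' Loadings are Pearson correlations between the original variables and the
#' latent scores: `brain_loadings[v, k] = cor(X_orig[, v], Lx[, k])` and
#' `behavior_loadings[b, k] = cor(Y_orig[, b], Ly[, k])`. By default the
#' matrices the model was fitted on (i.e. post-deconfounding for X) are the
#' "original" data; pass the pre-deconfounding matrix explicitly to use the
#' other convention.
#'
#' @param model A `pls_model`.
#' @param X_orig,Y_orig Matrices whose columns are correlated with the scores;
#'   must have the same row order the model was fitted on.
#' @return The model with `brain_loadings` and `behavior_loadings` attached.
#' @export
compute_loadings <- function(model, X_orig, Y_orig) {
  stopifnot(inherits(model, "pls_model"))
  if (nrow(as.matrix(X_orig)) != model$n) stop("X_orig row count mismatch")
  model$brain_loadings <- safe_cor(X_orig, model$Lx)
  model$behavior_loadings <- safe_cor(Y_orig, model$Ly)
  if (anyNA(model$brain_loadings) || anyNA(model$behavior_loadings)) {
    warning("zero-variance column(s): loading set to NA")
  }
  model
}

#' Summarize one latent component
#'
#' @param model A fitted `pls_model` (loadings optional).
#' @param k Component index.
#' @param top_n Number of largest-|loading| voxels to tabulate.
#' @return A list of class `lc_report` with the score correlation
#'   `r = cor(Lx[, k], Ly[, k])`, the explained covariance fraction, the
#'   singular value, the permutation p if attached, the behavior loading
#'   table and the top brain loadings.
#' @export
report_component <- function(model, k = 1L, top_n = 10L) {
  if (!inherits(model, "pls_model")) stop("model must be a fitted pls_model")
  if (k < 1 || k > length(model$d)) stop("component index out of range")
  r <- stats::cor(model$Lx[, k], model$Ly[, k])
  behavior <- data.frame(
    measure = model$behavior_names %||% paste0("b", seq_len(nrow(model$u))),
    salience = model$u[, k],
    loading = if (!is.null(model$behavior_loadings)) model$behavior_loadings[, k] else NA_real_,
    z = if (!is.null(model$behavior_z)) model$behavior_z[, k] else NA_real_
  )
  top <- NULL
  if (!is.null(model$brain_loadings)) {
    ord <- order(abs(model$brain_loadings[, k]), decreasing = TRUE)
    idx <- ord[seq_len(min(top_n, length(ord)))]
    top <- data.frame(voxel = idx, loading = model$brain_loadings[idx, k],
                      z = if (!is.null(model$brain_z)) model$brain_z[idx, k] else NA_real_)
  }
  structure(list(component = k, r_scores = r,
                 singular_value = model$d[k],
                 explained_covariance = model$explained[k],
                 perm_p = if (!is.null(model$perm_p)) model$perm_p[k] else NA_real_,
                 behavior = behavior, top_brain = top),
            class = "lc_report")
}

#' @export
print.lc_report <- function(x, ...) {
  cat(sprintf("Latent component %d\n", x$component))
  cat(sprintf("  score correlation r = %.3f\n", x$r_scores))
  cat(sprintf("  explained covariance = %.1f%%\n", 100 * x$explained_covariance))
  if (!is.na(x$perm_p)) cat(sprintf("  permutation p = %.4g\n", x$perm_p))
  cat("  behavior loadings:\n")
  print(x$behavior, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS correlation model: %d participants, %d voxels, %d components\n",
              x$n, nrow(x$v), length(x$d)))
  tab <- data.frame(lc = seq_along(x$d), singular_value = x$d,
                    explained_cov = x$explained,
                    perm_p = if (!is.null(x$perm_p)) x$perm_p else NA_real_)
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
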