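#' Permute behavior rows within diagnostic groups
#'
#' Shuffles the rows of `Y` only among participants sharing a group label, so
#' that permutation-based inference is not driven by between-group
#' differences. Uses the current RNG state; callers seed it.
#'
#' @param Y N x B behavior matrix.
#' @param groups Length-N group labels.
#' @return Y with rows permuted within each group.
#' @export
permute_within_groups <- function(Y, groups) {
  Y <- as.matrix(Y)
  if (nrow(Y) != length(groups)) stop("groups length must match Y rows")
  perm <- seq_len(nrow(Y))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1) perm[idx] <- idx[sample.int(length(idx))]
  }
  Y[perm, , drop = FALSE]
}

# Deterministic per-replicate child seeds from one parent seed, so replicates
# are order-independent and reproducible.
child_seeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Procrustes alignment of a resampled singular structure
#'
#' Finds the orthogonal rotation `Q` minimizing `||u_ref - u %*% Q||_F` and
#' applies it to the resampled structure the standard way for PLS resampling:
#' the rotated, singular-value-weighted behavior basis `u %*% diag(d) %*% Q`
#' yields the aligned singular values as its column norms, and the brain side
#' is rotated consistently. With `method = "sign"` only per-component sign
#' flips (toward positive agreement with the reference) are applied.
#'
#' @param u_ref Reference behavior saliences (B x C).
#' @param u,d,v Resampled behavior saliences, singular values, brain
#'   saliences.
#' @param method `"rotation"` (full orthogonal Procrustes) or `"sign"`.
#' @return List with aligned `u`, `d`, `v` and the `rotation` used.
#' @export
procrustes_align <- function(u_ref, u, d, v = NULL, method = "rotation") {
  u_ref <- as.matrix(u_ref); u <- as.matrix(u)
  if (!all(dim(u_ref) == dim(u))) stop("u and u_ref dimensions must match")
  C <- ncol(u)
  if (method == "sign") {
    s <- sign(colSums(u_ref * u))
    s[s == 0] <- 1
    rot <- diag(s, C)
  } else {
    m <- crossprod(u, u_ref)
    sv <- svd(m)
    rot <- sv$u %*% t(sv$v)
  }
  ud <- u %*% (diag(d, C) %*% rot)
  d_rot <- sqrt(colSums(ud^2))
  d_safe <- ifelse(d_rot < 1e-300, 1, d_rot)
  u_rot <- sweep(ud, 2, d_safe, "/")
  v_rot <- NULL
  if (!is.null(v)) {
    vd <- as.matrix(v) %*% (diag(d, C) %*% rot)
    v_rot <- sweep(vd, 2, d_safe, "/")
  }
  list(u = u_rot, d = d_rot, v = v_rot, rotation = rot)
}

#' Group-restricted permutation test for PLS components
#'
#' Builds a null distribution of the singular values by refitting the PLS on
#' `n_perm` datasets in which the behavior rows are permuted within diagnostic
#' group (the imaging matrix is untouched). Each permuted singular structure
#' is procrustes-aligned to the observed one before its singular values enter
#' the null. P-values use the add-one correction
#' `p = (1 + #\{null >= observed\}) / (1 + n_perm)`.
#'
#' @param data The [brain_behavior_data()] the model was fitted on.
#' @param model The fitted `pls_model`.
#' @param n_perm Number of permutations.
#' @param procrustes Align permuted structure by rotation (`TRUE`, default)
#'   or leave unaligned.
#' @param seed Parent seed; spawns one child seed per permutation.
#' @return A list of class `permutation_result` with `null_singular_values`
#'   (n_perm x C), `perm_p`, `n_perm`, `procrustes_used`, `seed`.
#' @export
permutation_test <- function(data, model, n_perm = 1000L, procrustes = TRUE,
                             seed = 1L) {
  stopifnot(inherits(data, "brain_behavior_data"), inherits(model, "pls_model"))
  n_perm <- as.integer(n_perm)
  if (n_perm < 1) stop("n_perm must be at least 1")
  n <- model$n
  C <- length(model$d)
  Xz <- standardize_columns(data$X)$z
  Yz <- standardize_columns(data$Y)$z
  seeds <- child_seeds(seed, n_perm)
  null_d <- matrix(NA_real_, n_perm, C)
  for (i in seq_len(n_perm)) {
    set.seed(seeds[i])
    Yp <- permute_within_groups(Yz, data$groups)
    R <- crossprod(Yp, Xz) / (n - 1)
    sv <- svd(R, nu = C, nv = 0)
    dp <- sv$d[seq_len(C)]
    if (procrustes) {
      al <- procrustes_align(model$u, sv$u[, seq_len(C), drop = FALSE], dp)
      dp <- al$d
    }
    null_d[i, ] <- dp
  }
  perm_p <- vapply(seq_len(C), function(k) {
    (1 + sum(null_d[, k] >= model$d[k])) / (1 + n_perm)
  }, numeric(1))
  structure(list(n_perm = n_perm, null_singular_values = null_d,
                 perm_p = perm_p, procrustes_used = isTRUE(procrustes),
                 seed = as.integer(seed)),
            class = "permutation_result")
}

#' Draw one group-restricted bootstrap replicate of row indices
#'
#' Each group is resampled with replacement to exactly its own size, so every
#' replicate preserves the group composition. Uses the current RNG state.
#'
#' @param groups Length-N group labels.
#' @return Integer vector of N row indices.
#' @export
bootstrap_indices <- function(groups) {
  idx_by_group <- split(seq_along(groups), groups)
  unlist(lapply(idx_by_group, function(ii) {
    ii[sample.int(length(ii), length(ii), replace = TRUE)]
  }), use.names = FALSE)
}

#' Group-restricted bootstrap for loading reliability
#'
#' Draws `n_boot` bootstrap samples in which each diagnostic group is
#' resampled with replacement to its own size (rows drawn jointly from X and
#' Y), refits the PLS with standardization recomputed on the replicate,
#' procrustes-aligns the replicate saliences to the observed model, recomputes
#' the loadings, and estimates each loading's bootstrap SD. Reliability
#' z-scores divide the observed loading by that SD; entries with
#' `|z| >= threshold` are flagged as strong contributors.
#'
#' @param data The [brain_behavior_data()] the model was fitted on.
#' @param model Fitted `pls_model`; loadings are computed on `data` if absent.
#' @param n_boot Number of bootstrap replicates.
#' @param threshold Flagging threshold on `|z|` (default 3, roughly a 99%
#'   confidence statement).
#' @param procrustes Alignment method flag as in [permutation_test()].
#' @param seed Parent seed.
#' @return A list of class `bootstrap_result` with `brain_sd`, `behavior_sd`,
#'   `brain_z`, `behavior_z`, logical `brain_flag` / `behavior_flag`,
#'   `threshold`, `n_boot`, `seed`. Loadings whose bootstrap SD is exactly 0
#'   get `z = Inf` (with the loading's sign) and are flagged when nonzero.
#' @export
bootstrap_test <- function(data, model, n_boot = 1000L, threshold = 3,
                           procrustes = TRUE, seed = 1L) {
  stopifnot(inherits(data, "brain_behavior_data"), inherits(model, "pls_model"))
  n_boot <- as.integer(n_boot)
  if (n_boot < 2) stop("n_boot must be at least 2")
  tab <- table(data$groups)
  if (any(tab < 2)) {
    stop("every group needs >= 2 members for within-group bootstrap; too small: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  }
  if (is.null(model$brain_loadings)) {
    model <- compute_loadings(model, data$X, data$Y)
  }
  C <- length(model$d)
  n <- model$n
  seeds <- child_seeds(seed, n_boot)

  acc <- function(dim1) list(s = matrix(0, dim1, C), s2 = matrix(0, dim1, C),
                             n = matrix(0L, dim1, C))
  a_brain <- acc(ncol(data$X))
  a_beh <- acc(ncol(data$Y))
  add <- function(a, m) {
    ok <- is.finite(m)
    m0 <- ifelse(ok, m, 0)
    a$s <- a$s + m0
    a$s2 <- a$s2 + m0^2
    a$n <- a$n + ok
    a
  }

  for (i in seq_len(n_boot)) {
    set.seed(seeds[i])
    idx <- bootstrap_indices(data$groups)
    Xb <- data$X[idx, , drop = FALSE]
    Yb <- data$Y[idx, , drop = FALSE]
    Xbz <- standardize_columns(Xb, allow_constant = TRUE)$z
    Ybz <- standardize_columns(Yb, allow_constant = TRUE)$z
    R <- crossprod(Ybz, Xbz) / (n - 1)
    sv <- svd(R)
    ub <- sv$u[, seq_len(C), drop = FALSE]
    vb <- sv$v[, seq_len(C), drop = FALSE]
    db <- sv$d[seq_len(C)]
    al <- procrustes_align(model$u, ub, db, vb,
                           method = if (isTRUE(procrustes)) "rotation" else "sign")
    Lxb <- Xbz %*% al$v
    Lyb <- Ybz %*% al$u
    a_brain <- add(a_brain, safe_cor(Xb, Lxb))
    a_beh <- add(a_beh, safe_cor(Yb, Lyb))
  }

  boot_sd <- function(a) {
    m <- a$s / a$n
    var <- (a$s2 - a$n * m^2) / pmax(a$n - 1, 1)
    sqrt(pmax(var, 0))
  }
  brain_sd <- boot_sd(a_brain)
  behavior_sd <- boot_sd(a_beh)
  zed <- function(loading, sd) {
    z <- loading / sd
    z[sd == 0 & loading != 0] <- Inf * sign(loading[sd == 0 & loading != 0])
    z[sd == 0 & loading == 0] <- NA_real_
    z
  }
  brain_z <- zed(model$brain_loadings, brain_sd)
  behavior_z <- zed(model$behavior_loadings, behavior_sd)
  structure(list(n_boot = n_boot, threshold = threshold,
                 brain_sd = brain_sd, behavior_sd = behavior_sd,
                 brain_z = brain_z, behavior_z = behavior_z,
                 brain_flag = abs(brain_z) >= threshold,
                 behavior_flag = abs(behavior_z) >= threshold,
                 procrustes_used = isTRUE(procrustes),
                 seed = as.integer(seed)),
            class = "bootstrap_result")
}
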