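#' Analysis configuration
#'
#' All fixed constants of the end-to-end analysis in one place, each
#' overridable: band-pass 0.01-0.10 Hz, FD scrubbing at 0.5 mm with a
#' 1-before/2-after window, 240 s minimum retained duration, 50% gray-matter
#' threshold, 1000 permutations and 1000 bootstrap replicates, bootstrap-z
#' threshold 3, FDR level 0.05, clinical gates MADRS > 15 and YMRS > 7.
#'
#' @param f_lo,f_hi,fd_threshold_mm,n_before,n_after,min_seconds,gm_threshold
#'   Preprocessing constants (see [variability_config()]).
#' @param n_perm,n_boot,z_threshold,fdr_q Inference constants.
#' @param madrs_max,ymrs_max Clinical gates; exclusion iff strictly above.
#' @param seed Integer seed driving every stochastic stage.
#' @param groups_subset,scanner_subset Optional subset filters (character
#'   vectors of levels to keep) for control-analysis reruns.
#' @param procrustes,literal_fd,deconfound_behavior Flags.
#' @param loadings_source `"deconfounded"` (the matrix entering PLS) or
#'   `"original"` (pre-deconfounding maps) for the loading correlations.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(f_lo = 0.01, f_hi = 0.10, fd_threshold_mm = 0.5,
                            n_before = 1L, n_after = 2L, min_seconds = 240,
                            gm_threshold = 0.5, n_perm = 1000L, n_boot = 1000L,
                            z_threshold = 3, fdr_q = 0.05,
                            madrs_max = 15, ymrs_max = 7, seed = 1L,
                            groups_subset = NULL, scanner_subset = NULL,
                            procrustes = TRUE, literal_fd = FALSE,
                            deconfound_behavior = FALSE,
                            loadings_source = c("deconfounded", "original")) {
  loadings_source <- match.arg(loadings_source)
  stopifnot(fd_threshold_mm > 0, min_seconds > 0, n_perm >= 1, n_boot >= 2,
            z_threshold > 0, fdr_q > 0)
  structure(as.list(environment()), class = "analysis_config")
}

#' Participant flow accounting
#'
#' Applies per-group exclusion tallies sequentially to the recruited counts
#' and checks consistency (no stage may exclude more participants than a group
#' has left).
#'
#' @param recruited Named integer vector of recruited counts per group.
#' @param exclusions Named list: stage name -> named vector of per-group
#'   exclusion counts (groups absent from a stage lose nobody).
#' @return A list of class `participant_flow` with the per-stage remainders,
#'   `final` per-group counts and `final_total`.
#' @export
apply_participant_flow <- function(recruited, exclusions = list()) {
  if (is.null(names(recruited))) stop("recruited must be a named vector")
  remaining <- recruited
  stages <- list(recruited = recruited)
  for (st in names(exclusions)) {
    tally <- exclusions[[st]]
    if (any(tally < 0)) stop("negative exclusion tally in stage ", st)
    unknown <- setdiff(names(tally), names(recruited))
    if (length(unknown)) stop("unknown group(s) in stage ", st, ": ",
                              paste(unknown, collapse = ", "))
    for (g in names(tally)) {
      remaining[g] <- remaining[g] - tally[g]
      if (remaining[g] < 0) {
        stop("stage '", st, "' excludes more ", g,
             " participants than remain (inconsistent tallies)")
      }
    }
    stages[[st]] <- remaining
  }
  structure(list(stages = stages, final = remaining,
                 final_total = sum(remaining)),
            class = "participant_flow")
}

#' Run the full brain-behavior analysis
#'
#' Orchestrates the complete pipeline on a cohort table plus either
#' precomputed variability maps (`X`, participants x voxels, aligned with the
#' cohort rows) or a list of raw `bold_run`s: subset filters, clinical gates
#' (exclude MADRS > 15 or YMRS > 7, and rows with missing clinical scores),
#' variability extraction with the motion/duration gate (runs only),
#' confound residualization, PLS fit, group-restricted permutation and
#' bootstrap, and the post-hoc battery. Fully deterministic given
#' `config$seed`.
#'
#' @param cohort Cohort table (see [generate_cohort()] for the layout).
#' @param X Precomputed N x V map matrix, or `NULL` if `runs` is given.
#' @param runs Optional list of `bold_run` objects aligned with the cohort.
#' @param mask Optional `analysis_mask` applied when extracting maps from
#'   runs, and for restricting a precomputed `X` to in-mask voxels.
#' @param severity_cols,medication_cols Passed to [posthoc_battery()].
#' @param config An [analysis_config()].
#' @return A list of class `run_report`: `flow` (participant accounting),
#'   `model` (with loadings, permutation p and bootstrap z attached),
#'   `permutation`, `bootstrap`, `posthoc`, `components` summary table,
#'   `cohort_used`, and a `config` echo.
#' @export
run_all <- function(cohort, X = NULL, runs = NULL, mask = NULL,
                    severity_cols = character(), medication_cols = character(),
                    config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(X) && is.null(runs)) stop("supply precomputed maps X or raw runs")
  n0 <- nrow(cohort)
  keep <- rep(TRUE, n0)
  tally <- list()
  note <- function(label, drop) {
    tally[[label]] <<- tapply(drop, cohort$group, sum)[sort(unique(cohort$group))]
    keep <<- keep & !drop
  }

  if (!is.null(config$groups_subset)) {
    note("outside group subset", keep & !(cohort$group %in% config$groups_subset))
  }
  if (!is.null(config$scanner_subset)) {
    note("outside scanner subset", keep & !(cohort$scanner %in% config$scanner_subset))
  }
  clin <- c("als", "madrs", "ymrs")
  note("missing clinical scores",
       keep & apply(is.na(cohort[, clin]), 1, any))
  note("MADRS above 15", keep & !is.na(cohort$madrs) & cohort$madrs > config$madrs_max)
  note("YMRS above 7", keep & !is.na(cohort$ymrs) & cohort$ymrs > config$ymrs_max)

  if (!is.null(runs)) {
    if (length(runs) != n0) stop("runs must align with cohort rows")
    vcfg <- variability_config(config$f_lo, config$f_hi, config$fd_threshold_mm,
                               config$n_before, config$n_after,
                               config$min_seconds,
                               literal_fd = config$literal_fd)
    extracted <- vector("list", n0)
    short <- rep(FALSE, n0)
    for (i in which(keep)) {
      extracted[[i]] <- extract_variability(runs[[i]], mask = mask, config = vcfg)
      short[i] <- extracted[[i]]$verdict == "excluded"
    }
    note("insufficient scan time after scrubbing", keep & short)
    X <- matrix(NA_real_, n0, length(extracted[[which(keep)[1]]]$map$values))
    for (i in which(keep)) X[i, ] <- extracted[[i]]$map$values
    mean_fd_run <- vapply(seq_len(n0), function(i) {
      if (is.null(extracted[[i]])) NA_real_ else extracted[[i]]$mean_fd
    }, numeric(1))
    cohort$mean_fd <- ifelse(is.na(mean_fd_run), cohort$mean_fd, mean_fd_run)
    in_mask_cols <- if (is.null(mask)) seq_len(ncol(X)) else which(mask$include)
  } else {
    X <- as.matrix(X)
    if (nrow(X) != n0) stop("X rows must align with cohort rows")
    in_mask_cols <- if (is.null(mask)) seq_len(ncol(X)) else which(mask$include)
    if (!is.null(mask) && length(mask$include) != ncol(X)) {
      stop("mask length does not match the map voxel count")
    }
  }

  recruited <- table(cohort$group)
  flow <- apply_participant_flow(
    stats::setNames(as.integer(recruited), names(recruited)),
    lapply(tally, function(tl) {
      tl <- tl[!is.na(tl) & tl > 0]
      stats::setNames(as.integer(tl), names(tl))
    })
  )

  cohort_f <- cohort[keep, , drop = FALSE]
  Xf <- X[keep, in_mask_cols, drop = FALSE]
  if (anyNA(Xf)) stop("maps contain missing values among analyzed voxels")

  design <- encode_confounds(cohort_f)
  Xd <- residualize(Xf, design)
  Y <- as.matrix(cohort_f[, clin])
  if (isTRUE(config$deconfound_behavior)) Y <- residualize(Y, design)

  bb <- brain_behavior_data(Xd, Y, cohort_f$group)
  model <- pls_fit(bb)
  model <- compute_loadings(model,
                            if (config$loadings_source == "original") Xf else Xd,
                            Y)
  perm <- permutation_test(bb, model, n_perm = config$n_perm,
                           procrustes = config$procrustes, seed = config$seed)
  model$perm_p <- perm$perm_p
  boot <- bootstrap_test(bb, model, n_boot = config$n_boot,
                         threshold = config$z_threshold,
                         procrustes = config$procrustes, seed = config$seed)
  model$brain_z <- boot$brain_z
  model$behavior_z <- boot$behavior_z
  posthoc <- posthoc_battery(model, cohort_f, severity_cols, medication_cols,
                             q = config$fdr_q)

  components <- data.frame(
    lc = seq_along(model$d),
    singular_value = model$d,
    explained_cov = model$explained,
    perm_p = model$perm_p,
    r_scores = vapply(seq_along(model$d),
                      function(k) stats::cor(model$Lx[, k], model$Ly[, k]),
                      numeric(1)),
    n_flagged_voxels = colSums(boot$brain_flag, na.rm = TRUE)
  )

  structure(list(flow = flow, model = model, permutation = perm,
                 bootstrap = boot, posthoc = posthoc, components = components,
                 cohort_used = cohort_f, in_mask_cols = in_mask_cols,
                 config = config),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat("Brain-behavior variability analysis\n")
  cat(sprintf("  analyzed participants: %d (of %d recruited)\n",
              x$flow$final_total, sum(x$flow$stages$recruited)))
  cat("  per group:", paste(names(x$flow$final), x$flow$final,
                            sep = "=", collapse = ", "), "\n")
  cat("  components:\n")
  print(x$components, row.names = FALSE, digits = 4)
  invisible(x)
}
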