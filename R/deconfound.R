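#' Encode demographic and scanner confounds as a design matrix
#'
#' Builds the confound design used to residualize the imaging matrix before
#' PLS: age and mean framewise displacement enter as numeric columns, sex as a
#' single indicator, and scanner as treatment-coded indicators with the
#' lexicographically first level as reference. The intercept is implicit (it
#' is always added by [residualize()]). A categorical column observed at a
#' single level carries no information and is dropped with a warning.
#'
#' @param cohort Cohort table with columns `age`, `sex`, `scanner`, `mean_fd`.
#' @return A list of class `confound_design` with `matrix` (N x K),
#'   `column_names`, and `encoding` notes.
#' @export
encode_confounds <- function(cohort) {
  req <- c("age", "sex", "scanner", "mean_fd")
  missing_cols <- setdiff(req, names(cohort))
  if (length(missing_cols)) {
    stop("cohort is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  na_rows <- which(apply(cohort[, req], 1, function(r) any(is.na(r))))
  if (length(na_rows)) {
    stop("missing confound values in row(s): ", paste(na_rows, collapse = ", "))
  }

  cols <- list(age = as.numeric(cohort$age), mean_fd = as.numeric(cohort$mean_fd))
  encoding <- c("age: numeric", "mean_fd: numeric")

  sex_levels <- sort(unique(as.character(cohort$sex)))
  if (length(sex_levels) >= 2) {
    if (length(sex_levels) > 2) stop("sex must have at most two levels")
    cols[[paste0("sex", sex_levels[2])]] <-
      as.numeric(cohort$sex == sex_levels[2])
    encoding <- c(encoding,
                  sprintf("sex: indicator for %s (reference %s)",
                          sex_levels[2], sex_levels[1]))
  } else {
    warning("sex has a single level (", sex_levels, "); column dropped")
    encoding <- c(encoding, "sex: dropped (single level)")
  }

  sc_levels <- sort(unique(as.character(cohort$scanner)))
  if (length(sc_levels) >= 2) {
    for (lv in sc_levels[-1]) {
      cols[[lv]] <- as.numeric(cohort$scanner == lv)
    }
    encoding <- c(encoding,
                  sprintf("scanner: %d treatment indicators (reference %s)",
                          length(sc_levels) - 1, sc_levels[1]))
  } else {
    warning("scanner has a single level (", sc_levels, "); column dropped")
    encoding <- c(encoding, "scanner: dropped (single level)")
  }

  m <- do.call(cbind, cols)
  structure(list(matrix = m, column_names = colnames(m), encoding = encoding),
            class = "confound_design")
}

#' Residualize a matrix on a confound design
#'
#' Per-column least-squares residuals of `X` on the confound design plus an
#' intercept. Residual columns are mean-zero and orthogonal to every design
#' column; means are not added back (the PLS standardization downstream
#' absorbs location and scale).
#'
#' @param X N x V matrix (e.g. stacked variability maps).
#' @param design A `confound_design` from [encode_confounds()], or a plain
#'   numeric matrix.
#' @return N x V residual matrix.
#' @export
residualize <- function(X, design) {
  m <- if (inherits(design, "confound_design")) design$matrix else as.matrix(design)
  X <- as.matrix(X)
  if (nrow(m) != nrow(X)) stop("design rows must match X rows")
  if (nrow(X) <= ncol(m) + 1) stop("need more observations than design columns")
  ls_residuals(X, m, what = "confound")
}
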