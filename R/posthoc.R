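new_test_result <- function(name, statistic, df, p, n_used) {
  data.frame(name = name, statistic = statistic, df = df, p = p,
             fdr_sig = NA, n_used = n_used, stringsAsFactors = FALSE)
}

#' Two-sample t-test (pooled variance by default)
#'
#' @param a,b Numeric samples (NAs dropped, `n_used` records the remainder).
#' @param welch Use the Welch unequal-variance form instead of pooled.
#' @param name Label carried into the result row.
#' @return One-row data frame: `name`, `statistic`, `df`, `p`, `fdr_sig`
#'   (unset), `n_used`.
#' @export
two_sample_t <- function(a, b, welch = FALSE, name = "t") {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  if (stats::var(a) + stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(new_test_result(name, 0, length(a) + length(b) - 2, 1,
                             length(a) + length(b)))
    }
    stop("zero pooled variance with unequal means: t undefined")
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  new_test_result(name, unname(tt$statistic), unname(tt$parameter),
                  tt$p.value, length(a) + length(b))
}

#' One-way ANOVA
#'
#' @param values Numeric response.
#' @param groups Group labels (same length).
#' @param name Label carried into the result row.
#' @return One-row data frame with the F statistic, `(k-1, N-k)` df pair
#'   encoded as `"df1,df2"`, and p.
#' @export
oneway_anova <- function(values, groups, name = "anova") {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]; groups <- factor(groups[ok])
  if (nlevels(groups) < 2) stop("need at least two groups")
  if (any(table(groups) < 2)) stop("each group needs n >= 2")
  if (all(tapply(values, groups, stats::var) == 0)) {
    stop("zero within-group variance everywhere: F undefined")
  }
  ft <- stats::oneway.test(values ~ groups, var.equal = TRUE)
  new_test_result(name, unname(ft$statistic),
                  paste(unname(ft$parameter), collapse = ","),
                  ft$p.value, length(values))
}

#' Pearson chi-squared test on a contingency table
#'
#' No continuity correction (matches the convention for multi-df group-by-
#' category tables).
#'
#' @param contingency R x C matrix of counts.
#' @param name Label carried into the result row.
#' @return One-row data frame; df = (R-1)(C-1).
#' @export
chi_square_test <- function(contingency, name = "chisq") {
  contingency <- as.matrix(contingency)
  if (any(contingency < 0)) stop("counts must be non-negative")
  if (sum(contingency) == 0) stop("contingency table is all zero")
  keep_r <- rowSums(contingency) > 0
  keep_c <- colSums(contingency) > 0
  tab <- contingency[keep_r, keep_c, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("need at least two rows and two columns with positive margins")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  new_test_result(name, unname(ct$statistic), unname(ct$parameter),
                  ct$p.value, sum(tab))
}

#' Pearson correlation test
#'
#' @param x,y Numeric vectors; pairwise-complete rows are used.
#' @param name Label carried into the result row.
#' @return One-row data frame; `statistic` is the correlation r itself,
#'   df = n - 2, p from the two-sided t approximation.
#' @export
pearson_r_test <- function(x, y, name = "r") {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need n >= 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) stop("constant input: r undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  new_test_result(name, unname(ct$estimate), unname(ct$parameter),
                  ct$p.value, length(x))
}

#' Benjamini-Hochberg FDR flags
#'
#' Step-up procedure at level `q`: reject all hypotheses whose BH-adjusted
#' p-value is at most `q` (equivalently, all `p <= p_(k*)` with
#' `k* = max(k : p_(k) <= k q / m)`).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @param q FDR level.
#' @return Logical rejection flags, same length and order as the input.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (!length(p_values)) return(logical(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH") <= q
}

#' Post-hoc battery on PLS scores, demographics and clinical covariates
#'
#' Runs the standard follow-up on a fitted model: pairwise group t-tests on
#' the component's brain and behavior scores (one family), plus Pearson
#' correlations of the scores with continuous severity measures and t-tests of
#' the scores against binary medication flags (a second family). Each family
#' receives its own Benjamini-Hochberg pass at level `q`. Missing values are
#' handled per test (pairwise deletion, `n_used` recorded); a requested column
#' that is absent or entirely missing is skipped and listed in the
#' `"skipped"` attribute.
#'
#' @param model Fitted `pls_model`.
#' @param cohort Cohort table aligned with the model's rows (column `group`
#'   required).
#' @param severity_cols Names of continuous severity columns in `cohort`.
#' @param medication_cols Names of binary (0/1 or logical) medication columns.
#' @param component Component index to test.
#' @param q FDR level per family.
#' @return Data frame `measure, statistic, df, p, fdr_sig, n_used, family`.
#' @export
posthoc_battery <- function(model, cohort, severity_cols = character(),
                            medication_cols = character(), component = 1L,
                            q = 0.05) {
  stopifnot(inherits(model, "pls_model"))
  if (nrow(cohort) != model$n) stop("cohort rows must match the fitted model")
  k <- component
  scores <- list(brain = model$Lx[, k], behavior = model$Ly[, k])
  groups <- as.character(cohort$group)
  skipped <- character()

  rows_group <- list()
  for (side in names(scores)) {
    gs <- sort(unique(groups))
    for (i in seq_along(gs)) {
      for (j in seq_along(gs)) {
        if (i < j) {
          nm <- sprintf("%s_score %s vs %s", side, gs[i], gs[j])
          rows_group[[nm]] <- two_sample_t(scores[[side]][groups == gs[i]],
                                           scores[[side]][groups == gs[j]],
                                           name = nm)
        }
      }
    }
  }
  fam1 <- do.call(rbind, rows_group)
  if (!is.null(fam1)) {
    fam1$fdr_sig <- fdr_bh(fam1$p, q)
    fam1$family <- "scores_by_group"
  }

  rows_assoc <- list()
  for (col in severity_cols) {
    if (!col %in% names(cohort) || all(is.na(cohort[[col]]))) {
      skipped <- c(skipped, col)
      next
    }
    for (side in names(scores)) {
      nm <- sprintf("%s_score ~ %s", side, col)
      rows_assoc[[nm]] <- pearson_r_test(scores[[side]], cohort[[col]], name = nm)
    }
  }
  for (col in medication_cols) {
    if (!col %in% names(cohort) || all(is.na(cohort[[col]]))) {
      skipped <- c(skipped, col)
      next
    }
    flag <- as.logical(cohort[[col]])
    for (side in names(scores)) {
      nm <- sprintf("%s_score by %s", side, col)
      rows_assoc[[nm]] <- two_sample_t(scores[[side]][which(flag)],
                                       scores[[side]][which(!flag)], name = nm)
    }
  }
  fam2 <- do.call(rbind, rows_assoc)
  if (!is.null(fam2)) {
    fam2$fdr_sig <- fdr_bh(fam2$p, q)
    fam2$family <- "severity_medication"
  }

  out <- rbind(fam1, fam2)
  if (is.null(out)) {
    out <- data.frame(name = character(), statistic = numeric(), df = character(),
                      p = numeric(), fdr_sig = logical(), n_used = integer(),
                      family = character())
  }
  names(out)[names(out) == "name"] <- "measure"
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
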