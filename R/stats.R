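#' Cohort table
#'
#' Subjects-by-conditions matrix for one metric (e.g. within-DMN
#' connectivity), the input shape of the repeated-measures tests.
#'
#' @param x Numeric matrix or data frame, one row per subject, one column per
#'   condition; no missing cells, at least 2 subjects and 2 conditions.
#' @return A numeric matrix of class `cohort_table`.
#' @export
cohort_table <- function(x) {
  m <- as.matrix(x)
  if (anyNA(m)) stop("cohort table has missing cells")
  if (nrow(m) < 2 || ncol(m) < 2) stop("need >= 2 subjects and >= 2 conditions")
  if (is.null(colnames(m))) colnames(m) <- sprintf("cond%d", seq_len(ncol(m)))
  structure(m, class = c("cohort_table", "matrix", "array"))
}

.test_result <- function(test, statistic, p_value, ...) {
  structure(list(test = test, statistic = unname(statistic),
                 p_value = unname(p_value), ...),
            class = "lc_test_result")
}

#' @export
print.lc_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$test, x$statistic, x$p_value))
  if (!is.null(x$comparisons)) {
    cat("post-hoc pairwise comparisons (Bonferroni-corrected):\n")
    print(x$comparisons, row.names = FALSE)
  }
  invisible(x)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided paired comparison. Zero differences are dropped before ranking;
#' if all differences are zero the result is degenerate (statistic 0,
#' p = 1, flagged). By default the p-value comes from the tie-corrected
#' normal approximation (no continuity correction); with `exact = TRUE` and
#' no ties/zeros, the exact signed-rank distribution is used.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param exact Logical or `NULL` (let [stats::wilcox.test()] decide).
#' @return An `lc_test_result` with the positive-rank sum as the statistic
#'   and fields `n_used` (pairs after dropping zeros) and `degenerate`.
#' @export
wilcoxon_signed_rank <- function(x, y, exact = FALSE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  nz <- d != 0
  if (!any(nz)) {
    return(.test_result("Wilcoxon signed-rank", statistic = 0, p_value = 1,
                        n_used = 0L, degenerate = TRUE))
  }
  wt <- stats::wilcox.test(x, y, paired = TRUE, exact = exact, correct = FALSE)
  .test_result("Wilcoxon signed-rank", statistic = wt$statistic,
               p_value = wt$p.value, n_used = sum(nz), degenerate = FALSE)
}

#' Friedman rank test across matched conditions
#'
#' Nonparametric repeated-measures omnibus test over 3 or more conditions,
#' with the tie-corrected chi-square approximation on `k - 1` degrees of
#' freedom. A table whose rows are all constant yields statistic 0, p = 1.
#'
#' @param table A [cohort_table()] with at least 3 conditions.
#' @return An `lc_test_result` with field `df`.
#' @export
friedman_test <- function(table) {
  table <- cohort_table(table)
  if (ncol(table) < 3) stop("Friedman design needs >= 3 conditions")
  if (all(apply(table, 1, function(r) length(unique(r)) == 1L))) {
    return(.test_result("Friedman", statistic = 0, p_value = 1,
                        df = ncol(table) - 1L))
  }
  ft <- stats::friedman.test(unclass(table))
  .test_result("Friedman", statistic = ft$statistic, p_value = ft$p.value,
               df = unname(ft$parameter))
}

#' Post-hoc pairwise comparisons with Bonferroni correction
#'
#' All `k(k-1)/2` condition pairs compared by the paired Wilcoxon
#' signed-rank test; each raw p-value is multiplied by the number of pairs
#' and capped at 1. The Friedman omnibus result is reported alongside.
#'
#' @param table A [cohort_table()].
#' @param alpha Significance threshold used for the `relation` column
#'   (default 0.05).
#' @return The omnibus `lc_test_result` with a `comparisons` data frame:
#'   `pair`, `statistic`, `p_raw`, `p_corrected`, `relation` (`"A > B"`,
#'   `"B > A"` or `"A ~ B"` by corrected significance and mean ordering).
#' @export
posthoc_pairwise <- function(table, alpha = 0.05) {
  table <- cohort_table(table)
  omnibus <- if (ncol(table) >= 3) friedman_test(table) else
    .test_result("Friedman", statistic = NA_real_, p_value = NA_real_, df = NA)
  conds <- colnames(table)
  pairs <- utils::combn(length(conds), 2)
  m <- ncol(pairs)
  comp <- do.call(rbind, lapply(seq_len(m), function(q) {
    i <- pairs[1, q]; j <- pairs[2, q]
    wt <- wilcoxon_signed_rank(table[, i], table[, j])
    p_corr <- min(1, wt$p_value * m)
    rel <- if (p_corr < alpha) {
      if (mean(table[, i]) > mean(table[, j]))
        sprintf("%s > %s", conds[i], conds[j])
      else sprintf("%s > %s", conds[j], conds[i])
    } else sprintf("%s ~ %s", conds[i], conds[j])
    data.frame(pair = sprintf("%s-%s", conds[i], conds[j]),
               statistic = wt$statistic, p_raw = wt$p_value,
               p_corrected = p_corr, relation = rel, stringsAsFactors = FALSE)
  }))
  omnibus$comparisons <- comp
  omnibus
}

#' Spearman rank correlation
#'
#' Tie-corrected rank correlation with a two-sided p-value from the t
#' approximation on `n - 2` degrees of freedom. Constant input yields an
#' undefined coefficient, flagged via `degenerate`.
#'
#' @param x,y Numeric vectors of equal length, at least 5.
#' @return An `lc_test_result`; the statistic is rho.
#' @export
spearman_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 5) stop("need at least 5 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(.test_result("Spearman correlation", statistic = NA_real_,
                        p_value = NA_real_, degenerate = TRUE))
  }
  ct <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  .test_result("Spearman correlation", statistic = ct$estimate,
               p_value = ct$p.value, degenerate = FALSE)
}

#' Brain-behavior difference analysis
#'
#' For each subject, forms the score difference (T&E score minus EL score)
#' and the between-network connectivity difference (T&E learning minus EL
#' learning), then correlates the two difference vectors with Spearman's
#' rank correlation. This asks whether individuals whose DMN-FPN coupling
#' rose more under trial-and-error learning also benefited more from it
#' behaviorally.
#'
#' @param metrics Tidy metrics table from [subject_condition_metrics()]
#'   containing the between-network metric for conditions `el_cond` and
#'   `te_cond` for every subject.
#' @param scores Data frame with columns `subject`, `el_score`, `te_score`.
#' @param metric Metric name (default `"between_DMN_FPN"`).
#' @param el_cond,te_cond Condition labels of EL and T&E learning.
#' @return List with `differences` (data frame: `subject`, `score_diff`,
#'   `connectivity_diff`) and `test` (the Spearman `lc_test_result`).
#' @export
brain_behavior_analysis <- function(metrics, scores, metric = "between_DMN_FPN",
                                    el_cond = "el_learn", te_cond = "te_learn") {
  get_val <- function(subj, cond) {
    v <- metrics$value[metrics$subject == subj & metrics$condition == cond &
                         metrics$metric == metric]
    if (length(v) != 1)
      stop(sprintf("subject '%s' lacks a unique %s value for condition '%s'",
                   subj, metric, cond))
    v
  }
  diffs <- data.frame(
    subject = scores$subject,
    score_diff = scores$te_score - scores$el_score,
    connectivity_diff = vapply(scores$subject, function(s)
      get_val(s, te_cond) - get_val(s, el_cond), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(diffs) <- NULL
  test <- if (stats::sd(diffs$score_diff) == 0 ||
                stats::sd(diffs$connectivity_diff) == 0)
    .test_result("Spearman correlation", statistic = NA_real_,
                 p_value = NA_real_, degenerate = TRUE)
  else spearman_correlation(diffs$connectivity_diff, diffs$score_diff)
  list(differences = diffs, test = test)
}

#' Relation-pattern summary table
#'
#' Condenses post-hoc results for several metric families into the ordered
#' relation grammar `"A > B"` / `"A ~ B"`: a pair reads `A > B` when its
#' Bonferroni-corrected p-value is below `alpha` and condition A's mean
#' exceeds B's, otherwise the two conditions are tied (`~`).
#'
#' @param tables Named list of [cohort_table()] objects (one per metric
#'   family, e.g. `within_DMN`, `within_FPN`, `between_DMN_FPN`).
#' @param alpha Significance threshold (default 0.05).
#' @return Data frame with columns `family`, `pair`, `relation`,
#'   `p_corrected`.
#' @export
pattern_summary <- function(tables, alpha = 0.05) {
  out <- do.call(rbind, lapply(names(tables), function(fam) {
    res <- posthoc_pairwise(tables[[fam]], alpha = alpha)
    cbind(family = fam, res$comparisons[, c("pair", "relation", "p_corrected")])
  }))
  rownames(out) <- NULL
  out
}
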