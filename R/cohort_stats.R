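## Supporting cohort statistics: contingency-table tests for clinical
## covariates and DEG overlaps, rank-sum comparisons of activity scores
## (optionally stratified), and a clinical summary table.  No continuity
## correction is applied anywhere: the uncorrected Pearson chi-square is
## what reproduces the published clinical-table p-values.

#' Pearson chi-square test for an r x c contingency table
#'
#' No continuity correction; df = (r-1)(c-1); upper-tail p.
#'
#' @param table non-negative integer matrix, at least 2 x 2.
#' @return list: `statistic`, `df`, `p_value`.
#' @export
chi2_contingency <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2)
    stop("contingency table must be at least 2 x 2")
  if (any(table < 0)) stop("negative counts")
  if (sum(table) <= 0) stop("empty table")
  if (any(rowSums(table) == 0)) stop("zero row margin")
  if (any(colSums(table) == 0)) stop("zero column margin")
  res <- suppressWarnings(chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value)
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided by the point-probability rule: the p-value sums the
#' hypergeometric probabilities of all tables (with the observed margins)
#' no more probable than the observed one.
#'
#' @param table 2 x 2 non-negative integer matrix.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2)) stop("need a 2 x 2 table")
  if (any(table < 0)) stop("negative counts")
  fisher.test(table)$p.value
}

#' Wilcoxon rank-sum test
#'
#' Exact enumeration when both samples are small (total <= 20) and
#' tie-free; otherwise the normal approximation with tie and continuity
#' correction (the corrected approximation tracks the exact tail to within
#' about 0.01 already at group sizes of 8).
#'
#' @param x,y numeric vectors, each with >= 2 values.
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact computation;
#'   `NULL` (default) chooses by the rule above.
#' @return list: `statistic` (Mann-Whitney U of `x`), `p_value`,
#'   `exact`.
#' @export
wilcoxon_ranksum <- function(x, y, exact = NULL) {
  if (length(x) < 2 || length(y) < 2)
    stop("each sample needs at least 2 values")
  ties <- anyDuplicated(c(x, y)) > 0
  if (is.null(exact)) exact <- (length(x) + length(y) <= 20) && !ties
  if (exact && ties) stop("exact mode is undefined with ties")
  res <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE))
  list(statistic = unname(res$statistic), p_value = res$p.value,
       exact = exact)
}

#' Significance of the overlap of two gene sets
#'
#' Builds the 2 x 2 membership table of the two sets over the universe and
#' applies the uncorrected chi-square test.
#'
#' @param set_a,set_b gene sets (subsets of `universe`).
#' @param universe non-empty reference gene set.
#' @return list: `overlap_count`, `table` (2 x 2), `statistic`,
#'   `p_value`.
#' @export
deg_overlap_test <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  set_a <- unique(set_a); set_b <- unique(set_b)
  if (!all(set_a %in% universe) || !all(set_b %in% universe))
    stop("sets must be subsets of the universe")
  in_a <- universe %in% set_a
  in_b <- universe %in% set_b
  tab <- matrix(c(sum(in_a & in_b), sum(in_a & !in_b),
                  sum(!in_a & in_b), sum(!in_a & !in_b)),
                nrow = 2, byrow = TRUE,
                dimnames = list(a = c("in", "out"), b = c("in", "out")))
  chi <- chi2_contingency(tab)
  list(overlap_count = tab[1, 1], table = tab,
       statistic = chi$statistic, p_value = chi$p_value)
}

#' Stratified between-group activity comparison
#'
#' Within each level of a categorical stratum, compares the activity
#' scores between the two groups ([activity_difference()]).  Strata where
#' either group has fewer than 2 samples are reported as `NA` and flagged.
#'
#' @param activity named per-sample activity vector.
#' @param ann annotation data frame containing `stratum_col`.
#' @param stratum_col name of the stratum column.
#' @param group_col,ref group column / reference level.
#' @return data frame: `stratum`, `n_A`, `n_B`, `mean_diff`,
#'   `wilcoxon_p`, `degenerate`.
#' @export
stratified_activity_comparison <- function(activity, ann, stratum_col,
                                           group_col = "group",
                                           ref = NULL) {
  if (!stratum_col %in% names(ann))
    stop("unknown stratum column: ", stratum_col)
  lev <- group_levels(ann, group_col, ref)
  idx <- match(names(activity), ann$sample_id)
  if (anyNA(idx)) stop("activity samples missing from annotation")
  strat <- as.character(ann[[stratum_col]][idx])
  grp <- as.character(ann[[group_col]][idx])
  rows <- lapply(sort(unique(strat)), function(s) {
    sel <- strat == s
    n_a <- sum(sel & grp == lev[1]); n_b <- sum(sel & grp == lev[2])
    if (n_a < 2 || n_b < 2)
      return(data.frame(stratum = s, n_A = n_a, n_B = n_b,
                        mean_diff = NA_real_, wilcoxon_p = NA_real_,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    d <- activity_difference(activity[sel], ann[idx[sel], , drop = FALSE],
                             group_col, ref)
    data.frame(stratum = s, n_A = n_a, n_B = n_b,
               mean_diff = d$mean_diff, wilcoxon_p = d$wilcoxon_p,
               degenerate = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Clinical characteristics summary table
#'
#' Per group: mean/sd and median/IQR for continuous columns, n (%) for
#' categorical columns (percents rounded half away from zero to integer),
#' with a p-value per covariate from the rank-sum test (continuous) or the
#' uncorrected chi-square test (categorical).
#'
#' @param ann annotation data frame.
#' @param continuous_cols,categorical_cols column names to summarize.
#' @param group_col,ref group column / reference level.
#' @return data frame: `feature`, `type`, `summary_A`, `summary_B`,
#'   `p_value`.
#' @export
clinical_summary <- function(ann, continuous_cols = character(0),
                             categorical_cols = character(0),
                             group_col = "group", ref = NULL) {
  lev <- group_levels(ann, group_col, ref)
  bad <- setdiff(c(continuous_cols, categorical_cols), names(ann))
  if (length(bad)) stop("unknown columns: ", paste(bad, collapse = ", "))
  grp <- as.character(ann[[group_col]])
  pct <- function(n, tot) {  # round half away from zero
    p <- 100 * n / tot
    floor(p + 0.5)
  }
  rows <- list()
  for (cc in continuous_cols) {
    v <- as.numeric(ann[[cc]])
    a <- v[grp == lev[1]]; b <- v[grp == lev[2]]
    fmt <- function(u) sprintf("mean %.1f (sd %.1f); median %.1f (IQR %.1f, %.1f)",
                               mean(u), sd(u), median(u),
                               quantile(u, 0.25), quantile(u, 0.75))
    rows[[length(rows) + 1L]] <- data.frame(
      feature = cc, type = "continuous", summary_A = fmt(a),
      summary_B = fmt(b),
      p_value = wilcoxon_ranksum(a, b, exact = FALSE)$p_value,
      stringsAsFactors = FALSE)
  }
  for (cc in categorical_cols) {
    v <- as.character(ann[[cc]])
    tab <- table(factor(v), factor(grp, levels = lev))
    p <- chi2_contingency(as.matrix(tab))$p_value
    fmt <- function(col) paste(sprintf("%s %d (%d%%)", rownames(tab),
                                       tab[, col],
                                       pct(tab[, col], sum(tab[, col]))),
                               collapse = "; ")
    rows[[length(rows) + 1L]] <- data.frame(
      feature = cc, type = "categorical", summary_A = fmt(1L),
      summary_B = fmt(2L), p_value = p, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
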