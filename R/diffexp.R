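## Integrated hypothesis-testing differential expression.  Per gene, three
## statistics are computed between the two groups (Welch t, tie-corrected
## standardized rank sum, and log2-median-ratio), their empirical two-tailed
## p-values are taken against a sample-label permutation null, combined with
## Stouffer's signed rule, and corrected with Storey's q-value.  A gene is a
## DEG when q < fdr_cut and |lmr| exceeds a permutation-derived cutoff.

## per-gene ranks across samples and the tie-corrected rank-sum variance
rank_precompute <- function(expr, n1) {
  S <- ncol(expr)
  n2 <- S - n1
  ranks <- t(apply(expr, 1L, rank))
  tie_term <- apply(expr, 1L, function(v) {
    tt <- tabulate(match(v, unique(v)))
    sum(tt^3 - tt)
  })
  w_var <- n1 * n2 / 12 * ((S + 1) - tie_term / (S * (S - 1)))
  list(ranks = ranks, w_var = pmax(w_var, 0))
}

## order samples so group A comes first; returns index and n1
group_order <- function(expr, ann, group_col = "group", ref = NULL) {
  validate_expression(expr)
  validate_annotation(ann, expr, group_col = group_col)
  lev <- group_levels(ann, group_col, ref)
  grp <- ann[[group_col]][match(colnames(expr), ann$sample_id)]
  idx <- c(which(grp == lev[1]), which(grp == lev[2]))
  list(idx = idx, n1 = sum(grp == lev[1]), levels = lev)
}

#' Per-gene observed group statistics
#'
#' Welch's two-sample t (group A minus group B), the normal-standardized
#' Wilcoxon rank-sum statistic of group A with tie correction (positive
#' when A tends larger), and the log2-median-ratio
#' `lmr = median_A - median_B` of the (already log2-scale) values.
#'
#' @param expr genes x samples numeric matrix, log2 scale.
#' @param ann sample annotation data frame.
#' @param group_col name of the two-level group column.
#' @param ref optional group level to use as A (default: first in sort
#'   order).
#' @return data frame with columns `gene_id`, `t_stat`, `ranksum_z`,
#'   `lmr`, and `zero_variance` (genes flat in both groups have all three
#'   statistics set to 0 and are flagged; they can never become DEGs).
#' @export
compute_group_stats <- function(expr, ann, group_col = "group", ref = NULL) {
  ord <- group_order(expr, ann, group_col, ref)
  x <- expr[, ord$idx, drop = FALSE]
  pre <- rank_precompute(x, ord$n1)
  perms <- matrix(seq_len(ncol(x)) - 1L, ncol = 1L)
  st <- .perm_group_stats_cpp(x, pre$ranks, pre$w_var, perms, ord$n1)
  a <- seq_len(ord$n1)
  zv <- apply(x[, a, drop = FALSE], 1L, function(v) all(v == v[1L])) &
    apply(x[, -a, drop = FALSE], 1L, function(v) all(v == v[1L]))
  data.frame(gene_id = rownames(expr),
             t_stat = st$t_stat[, 1L],
             ranksum_z = st$ranksum_z[, 1L],
             lmr = st$lmr[, 1L],
             zero_variance = zv,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Permutation null distributions of the three statistics
#'
#' Shuffles the sample labels `n_perm` times (group sizes preserved;
#' permutations drawn uniformly, identity not excluded), recomputes the
#' three statistics for every gene, and pools the null values across genes
#' per statistic (`mode = "pooled"`, the default) or keeps them per gene
#' (`mode = "per_gene"`).  Pooling across genes gives the combined
#' empirical p-values much finer granularity than the per-gene resolution
#' of `1/n_perm`.
#'
#' @param expr genes x samples matrix.
#' @param ann annotation data frame.
#' @param n_perm number of label permutations.
#' @param seed integer seed; the null is deterministic given it.
#' @param mode `"pooled"` or `"per_gene"`.
#' @param chunk_size permutations processed per block (memory knob).
#' @param max_pool in pooled mode, cap on stored null values per
#'   statistic; when `n_genes * n_perm` exceeds it, a uniform random
#'   reservoir of that size is kept (logged).
#' @param group_col,ref see [compute_group_stats()].
#' @return object of class `perm_null`: sorted pooled vectors `t_stat`,
#'   `ranksum_z`, `lmr` (or genes x n_perm matrices in per-gene mode), plus
#'   `n_perm`, `mode`, `seed`.
#' @export
build_null <- function(expr, ann, n_perm = 10000, seed = 1L,
                       mode = c("pooled", "per_gene"),
                       chunk_size = 200L, max_pool = 6e6,
                       group_col = "group", ref = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_perm >= 1)
  ord <- group_order(expr, ann, group_col, ref)
  ## permutations index the matrix in its original (canonical) column
  ## order, so the null depends only on the group sizes -- swapping the
  ## group labels of a balanced design negates the null exactly
  x <- expr
  S <- ncol(x)
  pre <- rank_precompute(x, ord$n1)
  G <- nrow(x)
  keep_frac <- 1
  if (mode == "pooled" && as.numeric(G) * n_perm > max_pool) {
    keep_frac <- max_pool / (as.numeric(G) * n_perm)
    message("null pool exceeds max_pool; keeping a ",
            sprintf("%.1f%%", 100 * keep_frac), " reservoir per statistic")
  }
  acc <- list(t_stat = list(), ranksum_z = list(), lmr = list())
  withr::with_seed(seed, {
    done <- 0L
    while (done < n_perm) {
      nb <- min(chunk_size, n_perm - done)
      perms <- vapply(seq_len(nb), function(i) sample.int(S) - 1L,
                      integer(S))
      st <- .perm_group_stats_cpp(x, pre$ranks, pre$w_var, perms, ord$n1)
      for (nm in names(acc)) {
        v <- st[[nm]]
        if (mode == "pooled") {
          v <- as.vector(v)
          if (keep_frac < 1)
            v <- v[stats::runif(length(v)) < keep_frac]
        }
        acc[[nm]][[length(acc[[nm]]) + 1L]] <- v
      }
      done <- done + nb
    }
  })
  out <- lapply(acc, function(lst) {
    if (mode == "pooled") sort(unlist(lst, use.names = FALSE))
    else do.call(cbind, lst)
  })
  if (mode == "per_gene")
    out <- lapply(out, `rownames<-`, rownames(expr))
  structure(c(out, list(n_perm = n_perm, mode = mode, seed = seed)),
            class = "perm_null")
}

#' Two-tailed empirical p-value against a null sample
#'
#' `p = min(1, 2 * min(#\{null >= obs\} + 1, #\{null <= obs\} + 1) /
#' (N + 1))`; the add-one smoothing guarantees p > 0, which the Stouffer
#' combination requires.  Vectorized over `observed`.
#'
#' @param observed numeric vector of observed statistics.
#' @param null_samples numeric vector of null draws (any order).
#' @return p-values in (0, 1].
#' @export
empirical_p <- function(observed, null_samples) {
  if (!length(null_samples)) stop("empty null sample")
  s <- if (is.unsorted(null_samples)) sort(null_samples) else null_samples
  N <- length(s)
  cnt_le <- findInterval(observed, s)                  # null <= obs
  cnt_lt <- findInterval(observed, s, left.open = TRUE) # null < obs
  ge <- N - cnt_lt
  pmin(1, 2 * pmin(ge + 1, cnt_le + 1) / (N + 1))
}

#' Stouffer combination of the three per-gene p-values
#'
#' Each two-tailed p is mapped back to a signed normal quantile,
#' `z_i = sign_i * qnorm(1 - p_i / 2)` (a statistic of sign 0 contributes
#' z = 0), the three are averaged as `z = (z_t + z_r + z_l) / sqrt(3)`, and
#' `p_combined = 2 * (1 - pnorm(|z|))`.
#'
#' @param p_t,p_r,p_l numeric vectors of p-values in (0, 1].
#' @param signs numeric matrix (genes x 3) or vector of length 3 of
#'   direction signs (-1, 0, +1), taken from the signs of the observed
#'   statistics.
#' @return list with `z_combined` and `p_combined`.
#' @export
stouffer_combine <- function(p_t, p_r, p_l, signs) {
  p <- cbind(p_t, p_r, p_l)
  if (any(p <= 0) || any(p > 1)) stop("p-values must lie in (0, 1]")
  if (is.null(dim(signs))) signs <- matrix(signs, nrow = nrow(p),
                                           ncol = 3L, byrow = TRUE)
  z <- sign(signs) * qnorm(1 - p / 2)
  zc <- rowSums(z) / sqrt(3)
  list(z_combined = zc, p_combined = 2 * pnorm(-abs(zc)))
}

#' Storey q-values with fixed lambda
#'
#' `pi0 = min(1, #\{p > lambda\} / ((1 - lambda) * m))`, then the step-up
#' `q_(i) = min_\{j >= i\} pi0 * m * p_(j) / j` over genes sorted by p.
#' With `pi0 = 1` this reduces exactly to Benjamini-Hochberg.
#'
#' @param p_values p-values in (0, 1].
#' @param lambda tuning point for the null-proportion estimate
#'   (default 0.5).
#' @return q-values in [0, 1], monotone in p.
#' @export
storey_qvalues <- function(p_values, lambda = 0.5) {
  m <- length(p_values)
  if (!m) stop("empty p-value vector")
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must be in (0, 1]")
  pi0 <- min(1, sum(p_values > lambda) / ((1 - lambda) * m))
  o <- order(p_values)
  q <- pi0 * m * p_values[o] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' Permutation-derived log2-median-ratio cutoff
#'
#' The 95th percentile of the absolute null log2-median-ratio, pooled
#' across genes and `n_perm` label permutations.  This is the data-driven
#' effect-size threshold of the DEG rule.
#'
#' @param expr,ann,group_col,ref as in [compute_group_stats()].
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param probs percentile (default 0.95).
#' @return non-negative scalar cutoff.
#' @export
lmr_cutoff <- function(expr, ann, n_perm = 1000, seed = 1L, probs = 0.95,
                       group_col = "group", ref = NULL) {
  nul <- build_null(expr, ann, n_perm = n_perm, seed = seed,
                    mode = "pooled", group_col = group_col, ref = ref)
  unname(quantile(abs(nul$lmr), probs = probs))
}

#' Call differentially expressed genes
#'
#' A gene is up in A when `q < fdr_cut` and `lmr > lmr_cut`; up in B when
#' `q < fdr_cut` and `lmr < -lmr_cut`.  The two sets are disjoint by
#' construction.
#'
#' @param stats a GeneStatTable data frame with `gene_id`, `q_value`,
#'   `lmr`.
#' @param fdr_cut q-value threshold (default 0.05).
#' @param lmr_cut non-negative absolute log2-median-ratio threshold.
#' @return list with character vectors `up_in_A` and `up_in_B`.
#' @export
call_degs <- function(stats, fdr_cut = 0.05, lmr_cut) {
  if (lmr_cut < 0) stop("lmr_cut must be non-negative")
  sig <- stats$q_value < fdr_cut
  list(up_in_A = stats$gene_id[sig & stats$lmr > lmr_cut],
       up_in_B = stats$gene_id[sig & stats$lmr < -lmr_cut])
}

#' Run the full integrated differential-expression procedure
#'
#' Observed statistics, permutation null, per-statistic empirical
#' p-values, Stouffer combination, Storey q-values, permutation-derived
#' lmr cutoff, and DEG calls, in one call.
#'
#' @param expr genes x samples log2 matrix.
#' @param ann annotation data frame.
#' @param n_perm label permutations for the statistic null
#'   (default 10000).
#' @param n_perm_cutoff label permutations for the lmr cutoff
#'   (default 1000).
#' @param fdr q-value threshold for the DEG rule (default 0.05).
#' @param lmr_cut absolute lmr threshold; `NULL` (default) derives it via
#'   [lmr_cutoff()].
#' @param seed integer seed (the cutoff uses a derived sub-seed).
#' @param null_mode `"pooled"` (default) or `"per_gene"`.
#' @param lambda Storey lambda.
#' @param group_col,ref see [compute_group_stats()].
#' @return object of class `diffexp_result`: `stats` (the full
#'   GeneStatTable), `degs` (`up_in_A`/`up_in_B`), `lmr_cut`, `fdr`,
#'   `group_levels`, `n_perm`, `seed`.
#' @export
run_diffexp <- function(expr, ann, n_perm = 10000, n_perm_cutoff = 1000,
                        fdr = 0.05, lmr_cut = NULL, seed = 1L,
                        null_mode = c("pooled", "per_gene"), lambda = 0.5,
                        group_col = "group", ref = NULL) {
  null_mode <- match.arg(null_mode)
  obs <- compute_group_stats(expr, ann, group_col, ref)
  nul <- build_null(expr, ann, n_perm = n_perm, seed = seed,
                    mode = null_mode, group_col = group_col, ref = ref)
  if (null_mode == "pooled") {
    p_t <- empirical_p(obs$t_stat, nul$t_stat)
    p_r <- empirical_p(obs$ranksum_z, nul$ranksum_z)
    p_l <- empirical_p(obs$lmr, nul$lmr)
  } else {
    per_gene_p <- function(o, m) {
      vapply(seq_along(o), function(g) empirical_p(o[g], m[g, ]),
             numeric(1))
    }
    p_t <- per_gene_p(obs$t_stat, nul$t_stat)
    p_r <- per_gene_p(obs$ranksum_z, nul$ranksum_z)
    p_l <- per_gene_p(obs$lmr, nul$lmr)
  }
  comb <- stouffer_combine(p_t, p_r, p_l,
                           signs = cbind(sign(obs$t_stat),
                                         sign(obs$ranksum_z),
                                         sign(obs$lmr)))
  q <- storey_qvalues(comb$p_combined, lambda = lambda)
  if (is.null(lmr_cut))
    lmr_cut <- lmr_cutoff(expr, ann, n_perm = n_perm_cutoff,
                          seed = (seed + 1L) %% .Machine$integer.max,
                          group_col = group_col, ref = ref)
  tab <- cbind(obs,
               data.frame(p_t = p_t, p_r = p_r, p_l = p_l,
                          z_combined = comb$z_combined,
                          p_combined = comb$p_combined,
                          q_value = q))
  degs <- call_degs(tab, fdr_cut = fdr, lmr_cut = lmr_cut)
  tab$is_deg <- tab$gene_id %in% c(degs$up_in_A, degs$up_in_B)
  tab$direction <- ifelse(!tab$is_deg, "none",
                          ifelse(tab$lmr > 0, "up_in_A", "up_in_B"))
  structure(list(stats = tab, degs = degs, lmr_cut = lmr_cut, fdr = fdr,
                 group_levels = group_order(expr, ann, group_col,
                                            ref)$levels,
                 n_perm = n_perm, seed = seed),
            class = "diffexp_result")
}

#' @export
print.diffexp_result <- function(x, ...) {
  cat("integrated differential expression:", nrow(x$stats), "genes,",
      x$n_perm, "permutations\n")
  cat(sprintf("  lmr cutoff %.4f, FDR < %g\n", x$lmr_cut, x$fdr))
  cat("  DEGs up in", x$group_levels[1], ":", length(x$degs$up_in_A),
      "| up in", x$group_levels[2], ":", length(x$degs$up_in_B), "\n")
  invisible(x)
}
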