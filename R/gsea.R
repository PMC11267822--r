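## Preranked gene-set enrichment on the log2-median-ratio ranking.  The
## enrichment score is the Kolmogorov-Smirnov-style running sum: walking
## the ranked list, members of the set increment the sum by their weight
## (|score|^w, normalized; w = 0 gives the unweighted 1/k), non-members
## decrement by 1/(N - k); ES is the deviation of maximal absolute value.
## Significance comes from a gene-tag permutation null: random sets of the
## same size drawn from the ranked genes.

#' Rank genes by log2-median-ratio
#'
#' Descending order; ties broken by gene identifier (lexicographic) so the
#' ranking is deterministic.
#'
#' @param stats GeneStatTable data frame with `gene_id` and `lmr`.
#' @return named numeric vector of scores, in ranking order.
#' @export
rank_by_lmr <- function(stats) {
  o <- order(-stats$lmr, stats$gene_id, method = "radix")
  setNames(stats$lmr[o], stats$gene_id[o])
}

## ES from sorted hit positions; O(k).  Returns the signed extreme of the
## running sum (positive preferred on exact ties).
es_from_positions <- function(pos, wts, N) {
  k <- length(pos)
  nr <- sum(wts)
  cum <- if (nr > 0) cumsum(wts) / nr else seq_len(k) / k
  dec <- 1 / (N - k)
  after <- cum - (pos - seq_len(k)) * dec
  before <- c(0, cum[-k]) - (pos - seq_len(k)) * dec
  max_a <- max(after)
  min_b <- min(c(before, 0))
  if (max_a >= -min_b) {
    list(es = max_a, hit = which.max(after), positive = TRUE)
  } else {
    list(es = min_b, hit = which.min(before), positive = FALSE)
  }
}

#' Running-sum enrichment score of one gene set
#'
#' @param ranked named score vector from [rank_by_lmr()] (descending).
#' @param gene_set character vector of member genes.
#' @param weight_exponent 0 for the literal unweighted KS statistic, 1
#'   (default) to weight hits by |score| as in standard GSEA practice.
#' @return list: `es` in [-1, 1], `running_sum` (length N), `leading_edge`
#'   (hits at/before a positive extremum, at/after a negative one), and
#'   `n_hits`.
#' @export
enrichment_score <- function(ranked, gene_set, weight_exponent = 1) {
  N <- length(ranked)
  hits <- which(names(ranked) %in% gene_set)
  k <- length(hits)
  if (k == 0L) stop("gene set has empty intersection with the ranking")
  if (k == N) stop("gene set covers every ranked gene")
  wts <- abs(ranked[hits])^weight_exponent
  res <- es_from_positions(hits, wts, N)
  nr <- sum(wts)
  inc <- if (nr > 0) wts / nr else rep(1 / k, k)
  delta <- rep(-1 / (N - k), N)
  delta[hits] <- inc
  running <- cumsum(delta)
  le <- if (res$positive) names(ranked)[hits[seq_len(res$hit)]]
        else names(ranked)[hits[seq(res$hit, k)]]
  list(es = unname(res$es), running_sum = unname(running),
       leading_edge = le, n_hits = k)
}

#' Permutation significance of an enrichment score
#'
#' The null is built from `n_perm` random gene sets of the same size drawn
#' uniformly from the ranked genes (gene-tag permutation).  The p-value is
#' one-sided within the sign of the observed ES,
#' `p = (#\{same-sign nulls with |null| >= |es|\} + 1) /
#' (#\{same-sign nulls\} + 1)`, and `nes = es / mean(|same-sign null es|)`.
#'
#' @param ranked named score vector (descending).
#' @param gene_set member genes.
#' @param n_perm random sets (default 1000).
#' @param weight_exponent see [enrichment_score()].
#' @param seed integer seed.
#' @return list: `es`, `nes`, `p_value`, `leading_edge`, `n_hits`.
#' @export
gsea_significance <- function(ranked, gene_set, n_perm = 1000,
                              weight_exponent = 1, seed = 1L) {
  obs <- enrichment_score(ranked, gene_set, weight_exponent)
  N <- length(ranked)
  k <- obs$n_hits
  absr <- abs(ranked)^weight_exponent
  null_es <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      pos <- sort(sample.int(N, k))
      es_from_positions(pos, absr[pos], N)$es
    }, numeric(1))
  })
  same <- if (obs$es == 0) rep(TRUE, n_perm)
          else sign(null_es) == sign(obs$es)
  n_same <- sum(same)
  if (n_same == 0L) {
    warning("no same-sign null enrichment scores; p set to 1")
    p <- 1
    nes <- NA_real_
  } else {
    p <- (sum(abs(null_es[same]) >= abs(obs$es)) + 1) / (n_same + 1)
    nes <- obs$es / mean(abs(null_es[same]))
  }
  list(es = obs$es, nes = nes, p_value = p,
       leading_edge = obs$leading_edge, n_hits = k)
}

#' Preranked GSEA over a gene-set collection
#'
#' @param stats GeneStatTable data frame (ranked by [rank_by_lmr()]), or a
#'   named score vector already in ranking order.
#' @param collection named list of gene sets (e.g. from [read_gmt()]).
#' @param weight_exponent,n_perm,seed see [gsea_significance()].
#' @param min_size sets with fewer ranked members are skipped with a
#'   warning (default 2).
#' @return data frame: `set`, `n_hits`, `es`, `nes`, `p_value`,
#'   `leading_edge` (comma-joined).
#' @export
run_gsea <- function(stats, collection, weight_exponent = 1,
                     n_perm = 1000, seed = 1L, min_size = 2L) {
  ranked <- if (is.data.frame(stats)) rank_by_lmr(stats) else stats
  rows <- lapply(seq_along(collection), function(i) {
    nm <- names(collection)[i]
    k <- sum(names(ranked) %in% collection[[i]])
    if (k < min_size || k == length(ranked)) {
      warning("skipping set '", nm, "' (", k, " ranked members)")
      return(NULL)
    }
    r <- gsea_significance(ranked, collection[[i]], n_perm = n_perm,
                           weight_exponent = weight_exponent,
                           seed = (seed + i) %% .Machine$integer.max)
    data.frame(set = nm, n_hits = r$n_hits, es = r$es, nes = r$nes,
               p_value = r$p_value,
               leading_edge = paste(r$leading_edge, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
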