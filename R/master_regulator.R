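## Resampling-based master-regulator discovery.  For each TF, the observed
## count of regulon targets among the DEGs is compared to a null built by
## repeatedly drawing |DEG| genes uniformly without replacement from the
## measured gene universe (so the exact reference distribution is
## hypergeometric, which the tests exploit as an oracle).

#' Master-regulator resampling test
#'
#' @param tf_map named list: TF -> regulon (target gene ids).
#' @param deg_set character vector of DEG identifiers (must lie in
#'   `universe`).
#' @param universe character vector of all measured genes.
#' @param n_perm number of random draws (default 100000).
#' @param seed integer seed.
#' @param chunk_size draws processed per block.
#' @return data frame (one row per TF): `tf`, `n_targets_universe`,
#'   `n_targets_deg`, `p_empirical` (one-tailed, add-one smoothed),
#'   `fdr_bh`.
#' @export
mr_permutation_test <- function(tf_map, deg_set, universe,
                                n_perm = 100000, seed = 1L,
                                chunk_size = 1000L) {
  universe <- unique(universe)
  deg_set <- unique(deg_set)
  if (!all(deg_set %in% universe))
    stop("deg_set must be a subset of the universe")
  n_deg <- length(deg_set)
  if (n_deg > length(universe)) stop("more DEGs than universe genes")
  G <- length(universe)
  ## TF x gene membership over the universe
  memb <- vapply(tf_map, function(r) universe %in% r,
                 logical(G))                       # G x nTF
  n_univ <- colSums(memb)
  obs <- colSums(memb & universe %in% deg_set)
  empty <- n_univ == 0L
  if (any(empty))
    message(sum(empty), " TFs have no targets in the universe (p = 1)")

  exceed <- numeric(length(tf_map))
  if (n_deg > 0 && n_perm >= 1) {
    mt <- t(memb) * 1                              # nTF x G numeric
    withr::with_seed(seed, {
      done <- 0L
      while (done < n_perm) {
        nb <- min(chunk_size, n_perm - done)
        ind <- matrix(0, G, nb)
        for (b in seq_len(nb))
          ind[sample.int(G, n_deg), b] <- 1
        cnt <- mt %*% ind                          # nTF x nb null counts
        exceed <- exceed + rowSums(cnt >= obs)
        done <- done + nb
      }
    })
  }
  p <- (exceed + 1) / (n_perm + 1)
  p[empty] <- 1
  data.frame(tf = names(tf_map),
             n_targets_universe = unname(n_univ),
             n_targets_deg = unname(obs),
             p_empirical = unname(p),
             fdr_bh = bh_fdr(unname(p)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg false discovery rates
#'
#' Standard step-up BH with monotonization (thin validated wrapper around
#' `stats::p.adjust`).
#'
#' @param p_values p-values in (0, 1].
#' @return FDR values in (0, 1].
#' @export
bh_fdr <- function(p_values) {
  if (!length(p_values)) stop("empty p-value vector")
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must be in (0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Select master regulators
#'
#' Filters the MR table to `fdr < fdr_cut` and target count `> min_targets`
#' (counted among the DEGs by default, or in the universe with
#' `count = "universe"`), sorts ascending by (fdr, p, TF name) and keeps
#' the top `top_k`.
#'
#' @param table output of [mr_permutation_test()].
#' @param fdr_cut FDR threshold (default 0.01).
#' @param min_targets minimum target count, exclusive (default 5).
#' @param top_k maximum number of TFs returned (default 10).
#' @param count which target count the `min_targets` filter uses.
#' @return the selected rows, ordered; possibly zero rows.
#' @export
select_mrs <- function(table, fdr_cut = 0.01, min_targets = 5, top_k = 10,
                       count = c("deg", "universe")) {
  count <- match.arg(count)
  n_t <- if (count == "deg") table$n_targets_deg else table$n_targets_universe
  keep <- table$fdr_bh < fdr_cut & n_t > min_targets
  sel <- table[keep, , drop = FALSE]
  sel <- sel[order(sel$fdr_bh, sel$p_empirical, sel$tf), , drop = FALSE]
  head(sel, top_k)
}
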