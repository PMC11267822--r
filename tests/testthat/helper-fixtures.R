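# Shared fixture builders: everything is generated in code at test time.

# small two-group expression matrix with optional per-gene shift in group A
make_expr <- function(n_genes = 50, n1 = 8, n2 = 8, seed = 42,
                      shift = NULL, sd = 1, baseline = 8) {
  withr::with_seed(seed, {
    x <- matrix(rnorm(n_genes * (n1 + n2), baseline, sd), n_genes)
    if (!is.null(shift)) x[, seq_len(n1)] <- x[, seq_len(n1)] + shift
    dimnames(x) <- list(sprintf("g%03d", seq_len(n_genes)),
                        c(sprintf("a%02d", seq_len(n1)),
                          sprintf("b%02d", seq_len(n2))))
    x
  })
}

make_ann <- function(expr, n1 = sum(startsWith(colnames(expr), "a"))) {
  data.frame(sample_id = colnames(expr),
             group = rep(c("A", "B"), c(n1, ncol(expr) - n1)),
             stringsAsFactors = FALSE)
}

# brute-force KS running-sum enrichment score by explicit walk
brute_es <- function(N, hits, scores = rep(1, N), w = 0) {
  k <- length(hits)
  wts <- abs(scores[hits])^w
  run <- numeric(N)
  cur <- 0
  j <- 0
  for (i in seq_len(N)) {
    if (i %in% hits) {
      j <- j + 1
      cur <- cur + wts[j] / sum(wts)
    } else {
      cur <- cur - 1 / (N - k)
    }
    run[i] <- cur
  }
  run[which.max(abs(run))]
}

# two-sided Fisher p by full enumeration of tables with fixed margins
brute_fisher <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  probs <- dhyper(lo:hi, c1, n - c1, r1)
  obs <- dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
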