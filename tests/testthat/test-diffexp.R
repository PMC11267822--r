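test_that("observed statistics match hand values and scalar oracles", {
  # 3+3 fixture with medians by hand: lmr = 4 - 3 = 1
  x <- rbind(g1 = c(2, 4, 6, 1, 3, 5),
             g2 = c(7, 7, 7, 7, 7, 7))
  colnames(x) <- sprintf("s%d", 1:6)
  ann <- data.frame(sample_id = colnames(x),
                    group = rep(c("A", "B"), each = 3))
  st <- compute_group_stats(x, ann)
  expect_equal(st$lmr[1], 1)
  expect_equal(unlist(st[2, c("t_stat", "ranksum_z", "lmr")]),
               c(t_stat = 0, ranksum_z = 0, lmr = 0))
  expect_true(st$zero_variance[2])

  # Welch t and rank-sum z against the base scalar implementations
  y <- make_expr(n_genes = 30, n1 = 20, n2 = 20, seed = 10, shift = 1)
  anny <- make_ann(y)
  sty <- compute_group_stats(y, anny)
  a <- seq_len(20); b <- 21:40
  for (g in c(1, 7, 30)) {
    tt <- t.test(y[g, a], y[g, b], var.equal = FALSE)
    expect_equal(sty$t_stat[g], unname(tt$statistic), tolerance = 1e-12)
    wp <- wilcox.test(y[g, a], y[g, b], exact = FALSE,
                      correct = FALSE)$p.value
    expect_equal(2 * pnorm(-abs(sty$ranksum_z[g])), wp, tolerance = 1e-10)
    expect_equal(sty$lmr[g], median(y[g, a]) - median(y[g, b]))
  }
  # positive z means group A larger
  expect_true(all(sty$ranksum_z[sty$t_stat > 3] > 0))
})

test_that("empirical p-values follow the smoothed two-tailed formula", {
  expect_equal(empirical_p(1.5, c(-2, -1, 0, 1, 2)), 2 / 3)
  null999 <- seq(-1, 1, length.out = 999)
  expect_equal(empirical_p(5, null999), 0.002)    # beyond every null value
  expect_equal(empirical_p(0, null999), 1)        # at the median
  expect_true(all(empirical_p(rnorm(100), rnorm(1000)) > 0))
  expect_error(empirical_p(1, numeric(0)), "empty")
})

test_that("Stouffer combination matches its closed form", {
  r <- stouffer_combine(1, 1, 1, signs = c(1, -1, 1))
  expect_equal(r$z_combined, 0)
  expect_equal(r$p_combined, 1)

  r2 <- stouffer_combine(0.05, 0.05, 0.05, signs = c(1, 1, 1))
  expect_equal(r2$z_combined, sqrt(3) * qnorm(0.975), tolerance = 1e-12)
  expect_equal(r2$p_combined, 2 * (1 - pnorm(sqrt(3) * qnorm(0.975))),
               tolerance = 1e-12)

  r3 <- stouffer_combine(0.05, 0.05, 0.05, signs = c(1, 1, -1))
  expect_equal(abs(r3$z_combined), qnorm(0.975) / sqrt(3), tolerance = 1e-12)
  expect_gt(r3$p_combined, 0.05)  # discordant signs weaken the evidence

  expect_error(stouffer_combine(0, 0.5, 0.5, signs = c(1, 1, 1)), "\\(0, 1\\]")

  # monotone: lowering one input p never shrinks |z| when signs agree
  p_grid <- seq(0.01, 0.9, by = 0.01)
  z <- vapply(p_grid, function(p)
    abs(stouffer_combine(p, 0.2, 0.3, signs = c(1, 1, 1))$z_combined),
    numeric(1))
  expect_true(all(diff(z) <= 1e-12))
})

test_that("Storey q-values reduce to BH when pi0 is 1", {
  expect_equal(storey_qvalues(1), 1)
  p <- c(0.01, 0.02, 0.9, 0.95)   # pi0 = 2 / (0.5 * 4) = 1
  expect_equal(storey_qvalues(p), p.adjust(p, "BH"), tolerance = 1e-12)

  # general identity: q_storey = pi0 * q_BH (elementwise, capped at 1)
  withr::with_seed(11, {
    for (i in 1:5) {
      pv <- runif(200)^2
      pi0 <- min(1, sum(pv > 0.5) / (0.5 * length(pv)))
      expect_equal(storey_qvalues(pv), pmin(1, pi0 * p.adjust(pv, "BH")),
                   tolerance = 1e-12)
    }
  })
  # monotone in p
  pv <- runif(100)
  q <- storey_qvalues(pv)
  expect_true(all(diff(q[order(pv)]) >= -1e-12))
  expect_error(storey_qvalues(numeric(0)), "empty")
})

test_that("the lmr cutoff is the 95th percentile of the absolute null", {
  x <- matrix(5, 20, 12,
              dimnames = list(sprintf("g%d", 1:20), sprintf("s%d", 1:12)))
  ann <- data.frame(sample_id = colnames(x),
                    group = rep(c("A", "B"), each = 6))
  expect_equal(lmr_cutoff(x, ann, n_perm = 10, seed = 1), 0)

  y <- make_expr(n_genes = 40, n1 = 10, n2 = 10, seed = 2)
  cut <- lmr_cutoff(y, make_ann(y), n_perm = 50, seed = 3)
  expect_gte(cut, 0)
  # consistency with an explicitly built pooled null
  nul <- build_null(y, make_ann(y), n_perm = 50, seed = 3)
  expect_equal(cut, unname(quantile(abs(nul$lmr), 0.95)))
})

test_that("DEG calls apply the q/lmr rule with disjoint directions", {
  tab <- data.frame(gene_id = c("g1", "g2", "g3"),
                    q_value = c(0.01, 0.01, 0.2),
                    lmr = c(0.5, -0.5, 0.9))
  d <- call_degs(tab, fdr_cut = 0.05, lmr_cut = 0.1)
  expect_identical(d$up_in_A, "g1")
  expect_identical(d$up_in_B, "g2")
  expect_length(intersect(d$up_in_A, d$up_in_B), 0L)
  all1 <- transform(tab, q_value = 1)
  expect_identical(lengths(call_degs(all1, 0.05, 0.1)),
                   c(up_in_A = 0L, up_in_B = 0L))
  expect_error(call_degs(tab, 0.05, -1), "non-negative")
})

test_that("permutation nulls are deterministic, centred, and pooled", {
  x <- make_expr(n_genes = 100, n1 = 10, n2 = 10, seed = 4)
  ann <- make_ann(x)
  n1 <- build_null(x, ann, n_perm = 40, seed = 9)
  n2 <- build_null(x, ann, n_perm = 40, seed = 9)
  expect_identical(n1$t_stat, n2$t_stat)
  expect_identical(n1$lmr, n2$lmr)
  # CLT bound on the pooled t null mean
  N <- length(n1$t_stat)
  expect_lt(abs(mean(n1$t_stat)), 3 * sd(n1$t_stat) / sqrt(N))
  expect_equal(N, 100 * 40)
  # constant matrix: every null statistic is exactly 0
  cx <- matrix(3, 10, 8, dimnames = list(sprintf("g%d", 1:10),
                                         sprintf("s%d", 1:8)))
  cann <- data.frame(sample_id = colnames(cx),
                     group = rep(c("A", "B"), each = 4))
  nc <- build_null(cx, cann, n_perm = 5, seed = 1)
  expect_true(all(nc$t_stat == 0) && all(nc$lmr == 0))
})

test_that("per-statistic empirical p-values are calibrated under the null", {
  x <- make_expr(n_genes = 500, n1 = 20, n2 = 20, seed = 21)
  ann <- make_ann(x)
  res <- run_diffexp(x, ann, n_perm = 200, n_perm_cutoff = 100, seed = 21)
  for (p in list(res$stats$p_t, res$stats$p_r, res$stats$p_l))
    expect_lt(abs(mean(p < 0.05) - 0.05), 0.035)
})

test_that("swapping group labels negates statistics, keeps combined p", {
  x <- make_expr(n_genes = 80, n1 = 12, n2 = 12, seed = 5, shift = 0.4)
  ann <- make_ann(x)
  sA <- compute_group_stats(x, ann, ref = "A")
  sB <- compute_group_stats(x, ann, ref = "B")
  expect_equal(sA$t_stat, -sB$t_stat, tolerance = 1e-12)
  expect_equal(sA$ranksum_z, -sB$ranksum_z, tolerance = 1e-12)
  expect_equal(sA$lmr, -sB$lmr, tolerance = 1e-12)
  # with equal group sizes the same seed yields the same permutation
  # draws, so the null (and hence the lmr cutoff) is shared; the
  # two-tailed p-values agree up to the finite-sample asymmetry of the
  # sampled null
  rA <- run_diffexp(x, ann, n_perm = 100, n_perm_cutoff = 50, seed = 7,
                    ref = "A")
  rB <- run_diffexp(x, ann, n_perm = 100, n_perm_cutoff = 50, seed = 7,
                    ref = "B")
  expect_identical(rA$lmr_cut, rB$lmr_cut)
  expect_lt(max(abs(rA$stats$p_combined - rB$stats$p_combined)), 0.1)
  expect_gt(cor(rA$stats$p_combined, rB$stats$p_combined), 0.995)
})

test_that("pipeline p-values are invariant to gene row order", {
  x <- make_expr(n_genes = 60, n1 = 8, n2 = 8, seed = 6, shift = 0.5)
  ann <- make_ann(x)
  perm <- withr::with_seed(1, sample(nrow(x)))
  r1 <- run_diffexp(x, ann, n_perm = 80, n_perm_cutoff = 40, seed = 3)
  r2 <- run_diffexp(x[perm, ], ann, n_perm = 80, n_perm_cutoff = 40,
                    seed = 3)
  m <- match(r1$stats$gene_id, r2$stats$gene_id)
  expect_equal(r1$stats$p_combined, r2$stats$p_combined[m],
               tolerance = 1e-12)
})

test_that("per-gene null mode produces valid, coarser p-values", {
  x <- make_expr(n_genes = 40, n1 = 10, n2 = 10, seed = 8, shift = 1)
  ann <- make_ann(x)
  r <- run_diffexp(x, ann, n_perm = 50, n_perm_cutoff = 20, seed = 2,
                   null_mode = "per_gene")
  expect_true(all(r$stats$p_t > 0 & r$stats$p_t <= 1))
  expect_gte(min(r$stats$p_t), 2 / 51)  # resolution capped by n_perm
})
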