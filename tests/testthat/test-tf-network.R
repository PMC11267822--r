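test_that("single-gene activity is the population z-score of that gene", {
  x <- make_expr(n_genes = 5, n1 = 6, n2 = 6, seed = 31)
  act <- activity_score(x, "g001")
  v <- x["g001", ]
  z <- (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  expect_equal(act, z, tolerance = 1e-12)
  expect_equal(mean(act), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(act^2)), 1, tolerance = 1e-12)
})

test_that("activity scores sum to zero and drop degenerate genes", {
  x <- make_expr(n_genes = 30, n1 = 10, n2 = 10, seed = 32)
  act <- activity_score(x, rownames(x)[1:12])
  expect_equal(sum(act), 0, tolerance = 1e-9)

  x2 <- x
  x2["g003", ] <- 5   # constant gene inside the set
  expect_message(a2 <- activity_score(x2, rownames(x)[1:12]),
                 "zero-variance")
  expect_equal(a2, activity_score(x2[-3, ], rownames(x)[c(1:2, 4:12)]),
               tolerance = 1e-12)

  allc <- matrix(4, 3, 6, dimnames = list(c("c1", "c2", "c3"),
                                          sprintf("s%d", 1:6)))
  expect_error(activity_score(allc, c("c1", "c2")), "non-constant")
  expect_message(activity_score(x, c("g001", "nope")), "absent")
})

test_that("activity is invariant to gene-wise affine transforms", {
  x <- make_expr(n_genes = 20, n1 = 8, n2 = 8, seed = 33)
  set <- rownames(x)[1:7]
  a1 <- activity_score(x, set)
  x2 <- x * rep(runif(20, 1, 4), ncol(x)) + rep(rnorm(20), ncol(x))
  a2 <- activity_score(x2, set)
  expect_equal(a1, a2, tolerance = 1e-9)
})

test_that("network activity is the union-regulon activity", {
  x <- make_expr(n_genes = 40, n1 = 10, n2 = 10, seed = 34)
  tf_map <- list(T1 = rownames(x)[1:10], T2 = rownames(x)[1:10],
                 T3 = rownames(x)[5:20])
  expect_equal(network_activity(x, tf_map, "T1"),
               activity_score(x, tf_map$T1))
  # identical regulons: the union adds nothing
  expect_equal(network_activity(x, tf_map, c("T1", "T2")),
               activity_score(x, tf_map$T1))
  expect_equal(network_activity(x, tf_map, c("T1", "T3")),
               activity_score(x, rownames(x)[1:20]))
  expect_error(network_activity(x, tf_map, "T9"), "unknown")
})

test_that("activity differences have closed-form scale and symmetry", {
  # planted shift d on m targets with noise sd s: group activity
  # difference is approximately d * sqrt(m) / s
  m <- 16; d <- 0.8; s <- 0.5
  x <- make_expr(n_genes = 200, n1 = 50, n2 = 50, seed = 35, sd = s)
  set <- rownames(x)[1:m]
  x[set, 1:50] <- x[set, 1:50] + d
  ann <- make_ann(x)
  act <- activity_score(x, set)
  diff <- activity_difference(act, ann)
  # per-gene z sd after pooling both groups is sqrt(1 + (d/2s)^2 / ...);
  # use a generous 3-SE band around the dominant term d*sqrt(m)/s_total
  s_tot <- sqrt(s^2 + d^2 / 4)
  expect_lt(abs(diff$mean_diff - d * sqrt(m) / s_tot),
            3 * sqrt(1 / 50 + 1 / 50) * sqrt(m) * s / s_tot)
  expect_lt(diff$wilcoxon_p, 1e-6)

  swapped <- activity_difference(act, ann, ref = "B")
  expect_equal(swapped$mean_diff, -diff$mean_diff, tolerance = 1e-12)
  expect_equal(swapped$wilcoxon_p, diff$wilcoxon_p, tolerance = 1e-12)

  # identical groups: no difference
  y <- make_expr(n_genes = 30, n1 = 15, n2 = 15, seed = 36)
  d0 <- activity_difference(activity_score(y, rownames(y)[1:5]),
                            make_ann(y))
  expect_lt(abs(d0$mean_diff), 3 * sqrt(1 / 15 + 1 / 15))
  expect_gt(d0$wilcoxon_p, 0.01)
})

test_that("the network model counts targets and co-regulated DEGs", {
  x <- make_expr(n_genes = 30, n1 = 6, n2 = 6, seed = 37)
  ann <- make_ann(x)
  deg <- sprintf("g%03d", 1:10)
  tf_map <- list(T1 = sprintf("g%03d", 1:4),       # 4 DEG targets
                 T2 = sprintf("g%03d", 3:6),       # 4 DEG targets, 2 shared
                 T3 = sprintf("g%03d", 25:30))     # none
  mod <- build_network_model(tf_map, c("T1", "T2", "T3"), deg, x, ann)
  expect_equal(mod$nodes$size_value, c(0.4, 0.4, 0))
  e12 <- mod$edges[mod$edges$tf1 == "T1" & mod$edges$tf2 == "T2", ]
  expect_equal(e12$weight, 0.2)
  expect_false(any(mod$edges$tf1 == "T3" | mod$edges$tf2 == "T3"))
  expect_true(all(mod$edges$weight > 0 & mod$edges$weight <= 1))
  expect_true(all(mod$nodes$size_value >= 0 & mod$nodes$size_value <= 1))

  # regulon covering every DEG: size_value = 1
  tf_map$T4 <- deg
  mod2 <- build_network_model(tf_map, "T4", deg, x, ann)
  expect_equal(mod2$nodes$size_value, 1)
  expect_error(build_network_model(tf_map, "T1", character(0), x, ann),
               "empty DEG")
})

test_that("network export round-trips through GraphML and JSON", {
  x <- make_expr(n_genes = 30, n1 = 6, n2 = 6, seed = 38)
  ann <- make_ann(x)
  tf_map <- list(T1 = sprintf("g%03d", 1:6), T2 = sprintf("g%03d", 4:9),
                 T3 = sprintf("g%03d", 20:24))
  mod <- build_network_model(tf_map, names(tf_map), sprintf("g%03d", 1:12),
                             x, ann)
  for (fmt in c("graphml", "json")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    export_network(mod, f, fmt)
    back <- import_network(f, fmt)
    expect_equal(back$nodes[order(back$nodes$tf), ],
                 mod$nodes[order(mod$nodes$tf), ],
                 tolerance = 1e-12, ignore_attr = TRUE)
    key <- function(e) paste(pmin(e$tf1, e$tf2), pmax(e$tf1, e$tf2))
    expect_setequal(key(back$edges), key(mod$edges))
    expect_equal(back$edges$weight[order(key(back$edges))],
                 mod$edges$weight[order(key(mod$edges))],
                 tolerance = 1e-12)
    expect_equal(back$n_deg, mod$n_deg)
  }
  # isolated nodes (no edges) still serialize
  iso <- build_network_model(list(T1 = "g001", T3 = "g020"),
                             c("T1", "T3"), sprintf("g%03d", 1:5), x, ann)
  f <- withr::local_tempfile(fileext = ".graphml")
  export_network(iso, f, "graphml")
  expect_equal(nrow(import_network(f, "graphml")$nodes), 2)
  expect_error(export_network(iso, f, "dot"), "should be one of")
})

test_that("random regulons show no group difference on null data", {
  x <- make_expr(n_genes = 300, n1 = 30, n2 = 30, seed = 39)
  ann <- make_ann(x)
  fails <- 0L
  withr::with_seed(40, {
    for (i in 1:30) {
      set <- sample(rownames(x), 20)
      d <- activity_difference(activity_score(x, set), ann)
      if (abs(d$mean_diff) >= 3 * sqrt(1 / 30 + 1 / 30)) fails <- fails + 1L
    }
  })
  expect_lte(fails, 1L)
})
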