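## Synthetic two-group cohort generator.  The generative model is
## linear-additive on the log2 scale:
##
##   x[g, s] = baseline_g + sum_t r[g, t] * a[t, group(s)]
##             + direct_g * 1[s in group A] + Normal(0, sd_g)
##
## where r is regulon membership (0/1), a[t, A] = tf_activity_shift for
## planted active TFs (0 otherwise, and 0 in group B), and direct_g is a
## signed effect of magnitude effect_size for planted directly-differential
## genes.  Targets of active TFs are therefore true differential genes too,
## and appear in the ground truth alongside the directly planted ones.

#' Simulation configuration
#'
#' Builds and validates the configuration for [simulate_cohort()].  The
#' defaults define a cohort of 2000 genes and 60+60 samples with 10%
#' directly differential genes at one log2-unit effect, ten TF regulons of
#' 20--60 targets with 20% chained overlap, and three active TFs shifted by
#' one activity unit -- a scaled-down stand-in for a several-hundred-sample
#' prostatectomy cohort.
#'
#' @param n_genes number of genes.
#' @param n_samples_per_group integer pair: samples in groups A and B.
#' @param n_tfs number of transcription factors.
#' @param n_active_tfs how many TFs get a true between-group activity
#'   difference.
#' @param regulon_size_range integer pair: regulon sizes drawn uniformly in
#'   this range.
#' @param regulon_overlap fraction in [0,1] of targets shared between
#'   consecutive TFs (chained, so co-regulated targets exist).
#' @param frac_de_genes fraction of genes with a planted direct effect.
#' @param de_up_frac fraction of the direct differential genes shifted up
#'   in group A (the rest are shifted up in group B).
#' @param effect_size log2-units magnitude of the direct shift.
#' @param tf_activity_shift per-TF activity difference (group A minus B)
#'   for active TFs, in activity units; each covered target gene's mean
#'   shifts by this amount per covering active TF.
#' @param noise_sd log2-units residual standard deviation.
#' @param baseline_mean_range log2-units range for per-gene baselines.
#' @param baseline_sd_range optional range for per-gene noise SDs; when
#'   `NULL` every gene uses `noise_sd`.
#' @param strata_freqs named list of named probability vectors, one per
#'   categorical stratum (each must sum to 1).
#' @param group_labels character pair naming the two groups.
#' @param seed integer seed; all randomness derives from it.
#' @return validated config list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_samples_per_group = c(60, 60),
                       n_tfs = 10,
                       n_active_tfs = min(3, n_tfs),
                       regulon_size_range = c(20, 60),
                       regulon_overlap = 0.2,
                       frac_de_genes = 0.10,
                       de_up_frac = 0.5,
                       effect_size = 1.0,
                       tf_activity_shift = 1.0,
                       noise_sd = 0.5,
                       baseline_mean_range = c(4, 12),
                       baseline_sd_range = NULL,
                       strata_freqs = list(
                         gleason_category = c(lt7 = 0.25, eq7 = 0.55,
                                              gt7 = 0.20),
                         subtype = c(PCS1 = 0.02, PCS2 = 0.59, PCS3 = 0.39)),
                       group_labels = c("A", "B"),
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_samples_per_group = as.integer(n_samples_per_group),
              n_tfs = as.integer(n_tfs),
              n_active_tfs = as.integer(n_active_tfs),
              regulon_size_range = as.integer(regulon_size_range),
              regulon_overlap = regulon_overlap,
              frac_de_genes = frac_de_genes,
              de_up_frac = de_up_frac,
              effect_size = effect_size,
              tf_activity_shift = tf_activity_shift,
              noise_sd = noise_sd,
              baseline_mean_range = baseline_mean_range,
              baseline_sd_range = baseline_sd_range,
              strata_freqs = strata_freqs,
              group_labels = as.character(group_labels),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_genes > 0, all(cfg$n_samples_per_group > 0),
            cfg$n_tfs >= 0, cfg$n_active_tfs >= 0,
            cfg$n_active_tfs <= cfg$n_tfs,
            length(cfg$n_samples_per_group) == 2L,
            length(cfg$group_labels) == 2L,
            cfg$group_labels[1] != cfg$group_labels[2],
            cfg$noise_sd >= 0)
  for (f in c("regulon_overlap", "frac_de_genes", "de_up_frac"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("config field '", f, "' must be in [0, 1]")
  if (cfg$effect_size > 0 && cfg$frac_de_genes > 0 &&
      round(cfg$frac_de_genes * cfg$n_genes) < 1)
    stop("frac_de_genes * n_genes < 1 with a positive effect size")
  if (!is.null(cfg$strata_freqs)) {
    for (nm in names(cfg$strata_freqs)) {
      p <- cfg$strata_freqs[[nm]]
      if (is.null(names(p)) || any(!nzchar(names(p))))
        stop("stratum '", nm, "' frequencies must be named")
      if (abs(sum(p) - 1) > 1e-9)
        stop("stratum '", nm, "' frequencies must sum to 1")
    }
  }
  invisible(cfg)
}

## regulons with chained overlap: TF i+1 reuses a block of TF i's targets
build_regulons <- function(genes, cfg) {
  if (cfg$n_tfs == 0L) return(list())
  size_choices <- seq(cfg$regulon_size_range[1], cfg$regulon_size_range[2])
  sizes <- if (length(size_choices) == 1L)
    rep(size_choices, cfg$n_tfs) else
    sample(size_choices, cfg$n_tfs, replace = TRUE)
  tf_names <- sprintf("TF%02d", seq_len(cfg$n_tfs))
  regulons <- vector("list", cfg$n_tfs)
  names(regulons) <- tf_names
  for (i in seq_len(cfg$n_tfs)) {
    shared <- character(0)
    if (i > 1L && cfg$regulon_overlap > 0) {
      n_share <- round(cfg$regulon_overlap *
                         min(sizes[i - 1L], sizes[i]))
      if (n_share > 0)
        shared <- sample(regulons[[i - 1L]], n_share)
    }
    fresh <- sample(setdiff(genes, shared), sizes[i] - length(shared))
    regulons[[i]] <- sort(c(shared, fresh))
  }
  regulons
}

#' Generate a synthetic two-group cohort
#'
#' Draws an expression matrix, sample annotation (with strata), TF-target
#' map, and the ground truth of planted differential genes and active TFs,
#' all deterministically from `config$seed`.
#'
#' @param config a [sim_config()].
#' @return list of class `synthetic_cohort` with elements `expr`
#'   (genes x samples log2 matrix), `annotation` (data frame), `tf_targets`
#'   (named list of regulons), and `truth` (list with `de_genes` data frame
#'   of gene_id/direction/effect, `active_tfs`, and `effects`, the per-gene
#'   true group-A-minus-B mean difference).
#' @export
simulate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  cfg <- config
  res <- withr::with_seed(cfg$seed, {
    G <- cfg$n_genes
    n1 <- cfg$n_samples_per_group[1]; n2 <- cfg$n_samples_per_group[2]
    genes <- sprintf("g%05d", seq_len(G))
    samples <- c(sprintf("s%s%03d", cfg$group_labels[1], seq_len(n1)),
                 sprintf("s%s%03d", cfg$group_labels[2], seq_len(n2)))
    grp <- rep(cfg$group_labels, c(n1, n2))

    regulons <- build_regulons(genes, cfg)
    active <- if (cfg$n_active_tfs > 0)
      sort(sample(names(regulons), cfg$n_active_tfs)) else character(0)

    target_pool <- unique(unlist(regulons, use.names = FALSE))
    n_de <- round(cfg$frac_de_genes * G)
    free <- setdiff(genes, target_pool)
    if (n_de > length(free))
      stop("not enough non-target genes to plant ", n_de, " direct effects")
    direct <- if (n_de > 0) sample(free, n_de) else character(0)
    direct_eff <- numeric(0)
    if (n_de > 0) {
      n_up <- round(cfg$de_up_frac * n_de)
      sgn <- sample(rep(c(1, -1), c(n_up, n_de - n_up)))
      direct_eff <- cfg$effect_size * sgn
      names(direct_eff) <- direct
    }

    ## per-gene mean shift in group A (relative to B)
    eff <- setNames(numeric(G), genes)
    eff[direct] <- direct_eff
    for (tf in active)
      eff[regulons[[tf]]] <- eff[regulons[[tf]]] + cfg$tf_activity_shift

    baseline <- runif(G, cfg$baseline_mean_range[1],
                      cfg$baseline_mean_range[2])
    sd_g <- if (is.null(cfg$baseline_sd_range)) rep(cfg$noise_sd, G)
            else runif(G, cfg$baseline_sd_range[1], cfg$baseline_sd_range[2])
    x <- matrix(rnorm(G * (n1 + n2), mean = 0, sd = rep(sd_g, n1 + n2)),
                nrow = G)
    x <- x + baseline
    x[, grp == cfg$group_labels[1]] <-
      x[, grp == cfg$group_labels[1]] + eff
    dimnames(x) <- list(genes, samples)

    ann <- data.frame(sample_id = samples, group = grp,
                      stringsAsFactors = FALSE)

    de <- names(eff)[eff != 0]
    truth <- list(
      de_genes = data.frame(
        gene_id = de,
        direction = ifelse(eff[de] > 0, "up_in_A", "up_in_B"),
        effect = unname(eff[de]),
        stringsAsFactors = FALSE),
      active_tfs = active,
      effects = eff)
    list(expr = x, annotation = ann, tf_targets = regulons, truth = truth)
  })
  res$annotation <- generate_strata(res$annotation, cfg)
  res$config <- cfg
  class(res) <- "synthetic_cohort"
  res
}

#' Assign categorical strata to samples
#'
#' Each sample receives independent draws from the configured stratum
#' frequencies; deterministic given `config$seed` (a fixed sub-seed is
#' derived so the assignment does not depend on when this is called).
#'
#' @param annotation annotation data frame with `sample_id`.
#' @param config a [sim_config()] with non-`NULL` `strata_freqs`.
#' @return the annotation with one extra column per stratum.
#' @export
generate_strata <- function(annotation, config) {
  if (is.null(config$strata_freqs)) return(annotation)
  validate_sim_config(config)
  n <- nrow(annotation)
  sub_seed <- (config$seed + 7919L) %% .Machine$integer.max
  withr::with_seed(sub_seed, {
    for (nm in names(config$strata_freqs)) {
      p <- config$strata_freqs[[nm]]
      annotation[[nm]] <- sample(names(p), n, replace = TRUE, prob = p)
    }
  })
  annotation
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic cohort:", nrow(x$expr), "genes x", ncol(x$expr),
      "samples\n")
  cat("  groups:", paste(names(table(x$annotation$group)),
                         table(x$annotation$group), collapse = ", "), "\n")
  cat("  true differential genes:", nrow(x$truth$de_genes),
      "| active TFs:", length(x$truth$active_tfs), "of",
      length(x$tf_targets), "\n")
  invisible(x)
}
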