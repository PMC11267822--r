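## End-to-end orchestration: (simulate) -> degs -> gsea -> mr -> network ->
## stats, with one master seed, TSV outputs and a JSON manifest.  Every
## stage is a plain call into the module functions, so deleting the output
## directory and re-running with the same config reproduces every file
## bit-identically except the manifest timestamps.

cfg_error <- function(...) {
  stop(structure(class = c("config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

#' Pipeline configuration
#'
#' Defaults mirror the analysis constants of the underlying study design:
#' 10000 label permutations for the differential-expression null, 1000 for
#' the lmr cutoff and the GSEA null, 100000 draws for the master-regulator
#' null, DEG FDR 0.05, MR FDR 0.01 with more than 5 targets and top 10
#' TFs.
#'
#' @param out_dir output directory.
#' @param expr,annotations,tf_targets,gene_sets input file paths
#'   (expression TSV, annotation TSV, two-column TF-target TSV, GMT).
#'   When `expr` is `NULL`, a synthetic cohort is generated from `sim` and
#'   written into `out_dir`.
#' @param sim a [sim_config()] used when simulating (its seed is replaced
#'   by `seed`).
#' @param n_perm_de,n_perm_cutoff,n_perm_mr,n_perm_gsea permutation
#'   counts.
#' @param fdr_de,fdr_mr FDR thresholds.
#' @param min_targets,top_k master-regulator selection constants.
#' @param gsea_weight GSEA weight exponent (0 or 1).
#' @param group_col,ref group column and reference (A) level.
#' @param seed master seed; per-stage sub-seeds are derived from it.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            expr = NULL, annotations = NULL,
                            tf_targets = NULL, gene_sets = NULL,
                            sim = sim_config(),
                            n_perm_de = 10000, n_perm_cutoff = 1000,
                            n_perm_mr = 100000, n_perm_gsea = 1000,
                            fdr_de = 0.05, fdr_mr = 0.01,
                            min_targets = 5, top_k = 10, gsea_weight = 1,
                            group_col = "group", ref = NULL,
                            seed = 1L) {
  cfg <- list(out_dir = out_dir, expr = expr, annotations = annotations,
              tf_targets = tf_targets, gene_sets = gene_sets, sim = sim,
              n_perm_de = n_perm_de, n_perm_cutoff = n_perm_cutoff,
              n_perm_mr = n_perm_mr, n_perm_gsea = n_perm_gsea,
              fdr_de = fdr_de, fdr_mr = fdr_mr,
              min_targets = min_targets, top_k = top_k,
              gsea_weight = gsea_weight, group_col = group_col,
              ref = ref, seed = as.integer(seed))
  for (f in c("n_perm_de", "n_perm_cutoff", "n_perm_mr", "n_perm_gsea"))
    if (cfg[[f]] < 1) cfg_error(f, " must be >= 1")
  for (f in c("fdr_de", "fdr_mr"))
    if (cfg[[f]] <= 0 || cfg[[f]] >= 1) cfg_error(f, " must be in (0, 1)")
  if (!cfg$gsea_weight %in% c(0, 1)) cfg_error("gsea_weight must be 0 or 1")
  if (is.null(cfg$expr) && is.null(cfg$sim))
    cfg_error("either input paths or a simulation config is required")
  class(cfg) <- "pipeline_config"
  cfg
}

## TSV writer with the package-wide float convention (6 significant digits)
write_tsv <- function(df, path, digits = 6) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes every stage with derived sub-seeds and writes the stage
#' outputs plus `manifest.json` (inputs, seeds, per-stage runtimes,
#' output files) under `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory stage results
#'   (`diffexp`, `gsea`, `mr`, `selected`, `network`, `stratified`) and
#'   the manifest.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) cfg_error("not a pipeline_config")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outp <- function(f) file.path(config$out_dir, f)
  manifest <- list(package_version = as.character(utils::packageVersion("ihtnet")),
                   seed = config$seed, stages = list())
  timed <- function(name, fun) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fun(), error = function(e) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(e))
      jsonlite::write_json(manifest, outp("manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(
      status = "ok",
      runtime_s = round(proc.time()[["elapsed"]] - t0, 2))
    res
  }

  ## --- inputs -----------------------------------------------------------
  dat <- timed("inputs", function() {
    if (is.null(config$expr)) {
      sim <- config$sim
      sim$seed <- config$seed
      coh <- simulate_cohort(sim)
      write_expression(coh$expr, outp("expression.tsv"))
      write_annotations(coh$annotation, outp("annotations.tsv"))
      write_tf_targets(coh$tf_targets, outp("tf_targets.tsv"))
      jsonlite::write_json(coh$truth[c("de_genes", "active_tfs")],
                           outp("truth.json"), auto_unbox = TRUE,
                           digits = NA)
      list(expr = coh$expr, ann = coh$annotation,
           tf_map = coh$tf_targets, simulated = TRUE)
    } else {
      for (f in c("expr", "annotations"))
        if (!file.exists(config[[f]]))
          stop("input file not found: ", config[[f]])
      list(expr = read_expression(config$expr),
           ann = read_annotations(config$annotations,
                                  group_col = config$group_col),
           tf_map = if (!is.null(config$tf_targets))
             read_tf_targets(config$tf_targets) else NULL,
           simulated = FALSE)
    }
  })

  ## --- differential expression -----------------------------------------
  de <- timed("degs", function() {
    res <- run_diffexp(dat$expr, dat$ann, n_perm = config$n_perm_de,
                       n_perm_cutoff = config$n_perm_cutoff,
                       fdr = config$fdr_de, seed = config$seed,
                       group_col = config$group_col, ref = config$ref)
    write_tsv(res$stats, outp("gene_stats.tsv"))
    writeLines(res$degs$up_in_A, outp("degs_up_A.txt"))
    writeLines(res$degs$up_in_B, outp("degs_up_B.txt"))
    res
  })

  ## --- gene-set enrichment ---------------------------------------------
  gs <- NULL
  if (!is.null(config$gene_sets)) {
    gs <- timed("gsea", function() {
      coll <- read_gmt(config$gene_sets)
      res <- run_gsea(de$stats, coll, weight_exponent = config$gsea_weight,
                      n_perm = config$n_perm_gsea,
                      seed = (config$seed + 101L) %% .Machine$integer.max)
      write_tsv(res, outp("enrichment.tsv"))
      res
    })
  }

  ## --- master regulators & network -------------------------------------
  mr <- sel <- net <- strat <- NULL
  if (!is.null(dat$tf_map) && length(dat$tf_map)) {
    deg_union <- c(de$degs$up_in_A, de$degs$up_in_B)
    mr <- timed("mr", function() {
      tab <- mr_permutation_test(dat$tf_map, deg_union,
                                 universe = rownames(dat$expr),
                                 n_perm = config$n_perm_mr,
                                 seed = (config$seed + 202L) %%
                                   .Machine$integer.max)
      write_tsv(tab, outp("mr_table.tsv"))
      tab
    })
    sel <- select_mrs(mr, fdr_cut = config$fdr_mr,
                      min_targets = config$min_targets,
                      top_k = config$top_k)
    writeLines(sel$tf, outp("selected_mrs.txt"))
    if (nrow(sel) && length(deg_union)) {
      net <- timed("network", function() {
        model <- build_network_model(dat$tf_map, sel$tf, deg_union,
                                     dat$expr, dat$ann,
                                     group_col = config$group_col,
                                     ref = config$ref)
        export_network(model, outp("network.graphml"), "graphml")
        export_network(model, outp("network.json"), "json")
        act <- network_activity(dat$expr, dat$tf_map, sel$tf)
        write_tsv(data.frame(sample_id = names(act),
                             network_activity = unname(act)),
                  outp("activity.tsv"))
        list(model = model, activity = act)
      })
      strat_cols <- setdiff(names(dat$ann),
                            c("sample_id", config$group_col))
      if (length(strat_cols)) {
        strat <- timed("stats", function() {
          out <- do.call(rbind, lapply(strat_cols, function(sc) {
            d <- stratified_activity_comparison(
              net$activity, dat$ann, sc, group_col = config$group_col,
              ref = config$ref)
            cbind(stratum_col = sc, d)
          }))
          write_tsv(out, outp("stratified_activity.tsv"))
          out
        })
      }
    }
  }

  manifest$inputs <- if (dat$simulated) "simulated" else
    list(expr = config$expr, annotations = config$annotations,
         tf_targets = config$tf_targets, gene_sets = config$gene_sets)
  manifest$outputs <- list.files(config$out_dir)
  jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(diffexp = de, gsea = gs, mr = mr, selected = sel,
                 network = net, stratified = strat, manifest = manifest))
}
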