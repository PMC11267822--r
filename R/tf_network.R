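## TF / network activity scoring and the co-regulation network model.
## Activity of a gene set in a sample is the sum of the set members'
## z-scored expressions divided by sqrt(set size); standardization is over
## ALL samples jointly (group-blind, population sd), so between-group
## activity differences remain interpretable and every scored set has
## sample-mean zero.

#' Z-score activity of a gene set per sample
#'
#' Each usable gene is standardized across all samples with the population
#' (1/n) variance; per-sample activity is the sum of the standardized
#' values over the set divided by the square root of the number of genes
#' used.  Zero-variance genes are dropped with a message; genes absent
#' from the matrix are ignored.
#'
#' @param expr genes x samples log2 matrix.
#' @param gene_set character vector of member genes.
#' @return named numeric vector of activities, one per sample.
#' @export
activity_score <- function(expr, gene_set) {
  validate_expression(expr)
  genes <- intersect(unique(gene_set), rownames(expr))
  n_absent <- length(unique(gene_set)) - length(genes)
  if (n_absent > 0)
    message(n_absent, " set genes absent from the expression matrix")
  if (!length(genes)) stop("gene set has no genes in the expression matrix")
  x <- expr[genes, , drop = FALSE]
  n <- ncol(x)
  mu <- rowMeans(x)
  sd_pop <- sqrt(rowMeans((x - mu)^2))
  usable <- sd_pop > 0
  if (!all(usable))
    message(sum(!usable), " zero-variance set genes dropped")
  if (!any(usable)) stop("no usable (non-constant) genes in the set")
  z <- (x[usable, , drop = FALSE] - mu[usable]) / sd_pop[usable]
  colSums(z) / sqrt(sum(usable))
}

#' Activity of the union regulon of several TFs
#'
#' The network activity is [activity_score()] of the union of the given
#' TFs' target sets (each gene counted once).
#'
#' @param expr genes x samples matrix.
#' @param tf_map named list TF -> regulon.
#' @param top_tfs character vector of TF names (must be in `tf_map`).
#' @return per-sample activity vector.
#' @export
network_activity <- function(expr, tf_map, top_tfs) {
  missing <- setdiff(top_tfs, names(tf_map))
  if (length(missing)) stop("unknown TFs: ", paste(missing, collapse = ", "))
  activity_score(expr, unique(unlist(tf_map[top_tfs], use.names = FALSE)))
}

#' Between-group activity difference
#'
#' Mean activity of group A minus group B, with a two-sided Wilcoxon
#' rank-sum p-value.
#'
#' @param activity named per-sample activity vector.
#' @param ann annotation data frame.
#' @param group_col,ref group column / reference level (A).
#' @return list: `mean_diff`, `wilcoxon_p`, `n_A`, `n_B`.
#' @export
activity_difference <- function(activity, ann, group_col = "group",
                                ref = NULL) {
  lev <- group_levels(ann, group_col, ref)
  grp <- ann[[group_col]][match(names(activity), ann$sample_id)]
  if (anyNA(grp)) stop("activity samples missing from annotation")
  a <- activity[grp == lev[1]]
  b <- activity[grp == lev[2]]
  if (length(a) < 2 || length(b) < 2)
    stop("each group needs at least 2 samples")
  w <- wilcoxon_ranksum(a, b)
  list(mean_diff = mean(a) - mean(b), wilcoxon_p = w$p_value,
       n_A = length(a), n_B = length(b))
}

#' Build the co-regulation network model of the top TFs
#'
#' Nodes are the given TFs with `size_value` = |regulon intersect DEG| /
#' |DEG| and `color_value` = mean activity difference (group A minus B) of
#' the TF's regulon.  Undirected edges connect TF pairs that co-regulate at
#' least one DEG, weighted by |regulon_i intersect regulon_j intersect DEG|
#' / |DEG|.
#'
#' @param tf_map named list TF -> regulon.
#' @param top_tfs TFs to include as nodes.
#' @param deg_set non-empty DEG identifier vector.
#' @param expr,ann expression matrix and annotation for the activity
#'   difference.
#' @param group_col,ref group column / reference level.
#' @return object of class `tf_network_model`: `nodes` data frame (`tf`,
#'   `size_value`, `color_value`), `edges` data frame (`tf1`, `tf2`,
#'   `weight`), and `n_deg`.
#' @export
build_network_model <- function(tf_map, top_tfs, deg_set, expr, ann,
                                group_col = "group", ref = NULL) {
  deg_set <- unique(deg_set)
  if (!length(deg_set)) stop("empty DEG set")
  missing <- setdiff(top_tfs, names(tf_map))
  if (length(missing)) stop("unknown TFs: ", paste(missing, collapse = ", "))
  reg_deg <- lapply(tf_map[top_tfs], intersect, y = deg_set)
  nodes <- data.frame(
    tf = top_tfs,
    size_value = lengths(reg_deg) / length(deg_set),
    color_value = vapply(top_tfs, function(tf) {
      activity_difference(activity_score(expr, tf_map[[tf]]), ann,
                          group_col, ref)$mean_diff
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  pairs <- if (length(top_tfs) >= 2) utils::combn(top_tfs, 2) else
    matrix(character(0), nrow = 2)
  edges <- data.frame(tf1 = pairs[1, ], tf2 = pairs[2, ],
                      weight = apply(pairs, 2, function(pr) {
                        length(intersect(reg_deg[[pr[1]]],
                                         reg_deg[[pr[2]]])) /
                          length(deg_set)
                      }), stringsAsFactors = FALSE)
  edges <- edges[edges$weight > 0, , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, n_deg = length(deg_set)),
            class = "tf_network_model")
}

#' @export
print.tf_network_model <- function(x, ...) {
  cat("TF co-regulation network:", nrow(x$nodes), "nodes,",
      nrow(x$edges), "edges over", x$n_deg, "DEGs\n")
  invisible(x)
}

#' Export a network model to GraphML or JSON node-link
#'
#' Node attributes `size_value`/`color_value` and edge attribute `weight`
#' round-trip losslessly through either format (see [import_network()]).
#'
#' @param model a `tf_network_model`.
#' @param path output file path.
#' @param format `"graphml"` or `"json"`.
#' @export
export_network <- function(model, path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::graph_from_data_frame(
      if (nrow(model$edges)) model$edges else
        data.frame(tf1 = character(0), tf2 = character(0),
                   weight = numeric(0)),
      directed = FALSE, vertices = model$nodes)
    igraph::graph_attr(g, "n_deg") <- model$n_deg
    igraph::write_graph(g, path, format = "graphml")
  } else {
    jsonlite::write_json(
      list(directed = FALSE, n_deg = model$n_deg,
           nodes = model$nodes, links = model$edges),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Import a network model written by [export_network()]
#'
#' @param path file path.
#' @param format `"graphml"` or `"json"`.
#' @return a `tf_network_model`.
#' @export
import_network <- function(path, format = c("graphml", "json")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    vd <- igraph::as_data_frame(g, what = "vertices")
    ed <- igraph::as_data_frame(g, what = "edges")
    nodes <- data.frame(tf = vd$name, size_value = vd$size_value,
                        color_value = vd$color_value,
                        stringsAsFactors = FALSE, row.names = NULL)
    edges <- data.frame(tf1 = ed$from, tf2 = ed$to,
                        weight = if (nrow(ed)) ed$weight else numeric(0),
                        stringsAsFactors = FALSE, row.names = NULL)
    n_deg <- igraph::graph_attr(g, "n_deg")
  } else {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    nodes <- as.data.frame(j$nodes, stringsAsFactors = FALSE)
    edges <- if (length(j$links))
      as.data.frame(j$links, stringsAsFactors = FALSE) else
      data.frame(tf1 = character(0), tf2 = character(0),
                 weight = numeric(0))
    n_deg <- j$n_deg
  }
  structure(list(nodes = nodes, edges = edges, n_deg = as.numeric(n_deg)),
            class = "tf_network_model")
}
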