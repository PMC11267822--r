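## Readers/writers and validators for the formats the pipeline touches:
## expression TSV (genes x samples), sample annotation TSV, GMT gene sets,
## and two-column TF -> target edge lists.  Gene/sample identifier matching
## throughout the package is exact string match after whitespace trimming.

#' Validate a gene-by-sample expression matrix
#'
#' Checks the invariants the pipeline relies on: a numeric matrix with
#' unique, non-empty gene rownames and sample colnames, at least two
#' samples, and no missing values.
#'
#' @param expr numeric matrix, genes in rows, samples in columns,
#'   log2-scale values.
#' @return `expr`, invisibly, after validation.
#' @export
validate_expression <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expression must be a numeric matrix")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(expr)))
    stop("duplicate gene identifiers in expression matrix")
  if (anyDuplicated(colnames(expr)))
    stop("duplicate sample identifiers in expression matrix")
  if (ncol(expr) < 2) stop("expression matrix needs at least 2 samples")
  if (anyNA(expr)) stop("expression matrix contains missing values")
  invisible(expr)
}

#' Validate a sample annotation table against an expression matrix
#'
#' @param ann data frame with columns `sample_id` and `group` (plus any
#'   number of categorical strata columns).
#' @param expr optional expression matrix; when given, every expression
#'   sample must have exactly one annotation row.
#' @param group_col name of the two-level group column.
#' @return `ann`, invisibly.
#' @export
validate_annotation <- function(ann, expr = NULL, group_col = "group") {
  if (!is.data.frame(ann)) stop("annotation must be a data frame")
  if (!all(c("sample_id", group_col) %in% names(ann)))
    stop("annotation must contain 'sample_id' and '", group_col, "' columns")
  if (anyDuplicated(ann$sample_id))
    stop("duplicate sample_id in annotation")
  grp <- as.character(ann[[group_col]])
  lev <- sort(unique(grp))
  if (length(lev) != 2L)
    stop("group column must have exactly 2 observed levels, found ",
         length(lev))
  if (any(table(grp) < 2L)) stop("each group needs at least 2 samples")
  if (!is.null(expr)) {
    missing <- setdiff(colnames(expr), ann$sample_id)
    if (length(missing))
      stop("samples without annotation: ", paste(head(missing, 5),
           collapse = ", "))
  }
  invisible(ann)
}

#' Two observed group levels, in sorted order
#'
#' The first level plays the role of group A (e.g. the Black cohort in a
#' disparity contrast) in all signed statistics; pass `ref` to override
#' which level is A.
#' @param ann annotation data frame.
#' @param group_col group column name.
#' @param ref optional level to use as group A.
#' @return character vector of length 2: c(A, B).
#' @export
group_levels <- function(ann, group_col = "group", ref = NULL) {
  lev <- sort(unique(as.character(ann[[group_col]])))
  if (length(lev) != 2L) stop("need exactly two group levels")
  if (!is.null(ref)) {
    if (!ref %in% lev) stop("ref level '", ref, "' not present")
    lev <- c(ref, setdiff(lev, ref))
  }
  lev
}

#' Read a gene-by-sample expression matrix from TSV/CSV
#'
#' First column holds gene identifiers, header holds sample identifiers.
#' Duplicate gene rows are collapsed by `duplicate_policy`; genes with any
#' missing value are dropped with a message (permutation statistics assume
#' complete rows).
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @param duplicate_policy `"first"` keeps the first occurrence of a
#'   duplicated gene id (with a warning); `"mean"` averages duplicates.
#' @return validated numeric matrix (genes x samples).
#' @export
read_expression <- function(path, sep = "\t",
                            duplicate_policy = c("first", "mean")) {
  duplicate_policy <- match.arg(duplicate_policy)
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("expression input needs >= 2 sample columns")
  genes <- trimws(as.character(df[[1L]]))
  vals <- df[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      if (length(bad))
        stop("non-numeric value in column '", names(vals)[j],
             "', data row ", bad[1L])
      vals[[j]] <- as.numeric(v)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  colnames(m) <- trimws(colnames(m))
  if (anyDuplicated(genes)) {
    if (duplicate_policy == "first") {
      warning(sum(duplicated(genes)), " duplicate gene rows dropped ",
              "(policy 'first')")
      m <- m[!duplicated(genes), , drop = FALSE]
    } else {
      m <- rowsum(m, group = genes, reorder = FALSE) /
        as.vector(table(factor(genes, levels = unique(genes))))
      message("duplicate gene rows averaged (policy 'mean')")
    }
  }
  drop <- rowSums(is.na(m)) > 0
  if (any(drop)) {
    message(sum(drop), " genes with missing values dropped")
    m <- m[!drop, , drop = FALSE]
  }
  validate_expression(m)
  m
}

#' Write an expression matrix as TSV
#'
#' @param expr numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @param digits significant digits for serialization (default 6).
#' @export
write_expression <- function(expr, path, digits = 6) {
  validate_expression(expr)
  df <- data.frame(gene_id = rownames(expr),
                   signif(expr, digits = digits),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample annotation TSV
#'
#' @param path TSV with a `sample_id` column, a group column and optional
#'   categorical strata columns.
#' @param group_col name of the group column.
#' @return data frame of annotations (character columns).
#' @export
read_annotations <- function(path, group_col = "group") {
  ann <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  for (j in seq_along(ann))
    if (is.character(ann[[j]])) ann[[j]] <- trimws(ann[[j]])
  validate_annotation(ann, group_col = group_col)
  ann
}

#' Write a sample annotation TSV
#' @param ann annotation data frame.
#' @param path output path.
#' @export
write_annotations <- function(ann, path) {
  write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, `name TAB description TAB gene TAB ...`.
#' Duplicate members within a line are deduplicated.
#'
#' @param path GMT file path.
#' @return named list of character vectors; per-set descriptions in
#'   `attr(, "description")`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character(0)
  for (i in seq_along(lines)) {
    f <- trimws(strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]])
    if (length(f) < 3L)
      stop("GMT parse error at line ", i, ": fewer than 3 fields")
    nm <- f[1L]
    if (nm %in% names(sets)) stop("duplicate gene set name: ", nm)
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members)) stop("empty gene set at line ", i, ": ", nm)
    sets[[nm]] <- members
    desc[nm] <- f[2L]
  }
  attr(sets, "description") <- desc
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description optional named character vector of descriptions;
#'   defaults to the `description` attribute or `"na"`.
#' @export
write_gmt <- function(sets, path, description = NULL) {
  if (is.null(description)) description <- attr(sets, "description")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(description) && !is.na(description[nm]))
      description[[nm]] else "na"
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read TF-to-target interactions from a two-column edge list
#'
#' @param path TSV with columns TF, target; an optional header row is
#'   detected by the names `tf`/`TF` in the first field.
#' @return named list: TF name -> character vector of target genes
#'   (regulon).  Duplicate edges are counted once; self-edges retained.
#' @export
read_tf_targets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(list())
  first <- trimws(strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]])
  if (tolower(first[1L]) %in% c("tf", "regulator", "source"))
    lines <- lines[-1L]
  edges <- lapply(seq_along(lines), function(i) {
    f <- trimws(strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]])
    f <- f[nzchar(f)]
    if (length(f) != 2L)
      stop("TF-target parse error at line ", i, ": expected 2 fields")
    f
  })
  tf <- vapply(edges, `[`, character(1), 1L)
  tg <- vapply(edges, `[`, character(1), 2L)
  lapply(split(tg, factor(tf, levels = unique(tf))), unique)
}

#' Write TF-to-target interactions as a two-column TSV
#' @param tf_map named list TF -> targets.
#' @param path output path.
#' @export
write_tf_targets <- function(tf_map, path) {
  df <- data.frame(
    tf = rep(names(tf_map), lengths(tf_map)),
    target = unlist(tf_map, use.names = FALSE),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
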