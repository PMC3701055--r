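#' Read a gene expression matrix from tab-delimited text
#'
#' The canonical in-memory representation is a plain numeric matrix with
#' genes in rows (rownames = gene IDs) and samples in columns (colnames =
#' sample IDs), the layout used throughout the toolkit. Gene-ID matching is
#' exact and case-sensitive everywhere.
#'
#' Rows containing non-numeric or missing cells are either dropped (the
#' default, with the number of dropped genes recorded in the
#' `"n_dropped"` attribute and reported via a message) or rejected with an
#' error; values are never imputed.
#'
#' @param path tab-delimited text file. The first row and first column hold
#'   identifiers; the body is numeric.
#' @param orientation `"genes_in_rows"` (default) or `"genes_in_columns"`;
#'   the result is always genes x samples.
#' @param drop_missing drop genes with missing/non-numeric values
#'   (`TRUE`, default) or raise an error (`FALSE`).
#' @return numeric matrix (genes x samples) with attribute `n_dropped`.
#' @export
read_expression <- function(path,
                            orientation = c("genes_in_rows",
                                            "genes_in_columns"),
                            drop_missing = TRUE) {
  orientation <- match.arg(orientation)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          row.names = NULL, stringsAsFactors = FALSE,
                          check.names = FALSE, comment.char = "")
  ids <- as.character(df[[1L]])
  body <- df[, -1L, drop = FALSE]
  if (anyDuplicated(ids)) {
    stop("duplicate identifiers in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- suppressWarnings(
    vapply(body, function(col) as.numeric(as.character(col)),
           numeric(nrow(df))))
  if (nrow(df) == 1L) m <- matrix(m, nrow = 1L)
  rownames(m) <- ids
  colnames(m) <- names(body)
  if (orientation == "genes_in_columns") m <- t(m)

  bad <- apply(m, 1L, function(r) any(!is.finite(r)))
  n_dropped <- sum(bad)
  if (n_dropped > 0L) {
    if (!drop_missing) {
      stop("non-numeric or missing values in rows: ",
           paste(rownames(m)[bad], collapse = ", "))
    }
    message("read_expression: dropped ", n_dropped,
            " gene(s) with missing/non-numeric values")
    m <- m[!bad, , drop = FALSE]
  }
  if (ncol(m) < 3L) stop("need at least 3 samples, got ", ncol(m))
  attr(m, "n_dropped") <- n_dropped
  m
}

#' Write an expression matrix as tab-delimited text
#' @param expr numeric matrix, genes x samples.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a transcription-factor list (one ID per line)
#' @param path text file, one gene ID per line.
#' @return character vector of unique IDs.
#' @export
read_tf_list <- function(path) {
  ids <- readLines(path)
  ids <- trimws(ids)
  unique(ids[nzchar(ids)])
}

#' Intersect a TF list with the genes of an expression matrix
#'
#' IDs absent from the matrix are dropped with a warning giving the count;
#' an empty intersection is an error because every regression-based method
#' needs at least one candidate regulator.
#'
#' @param tfs character vector of TF IDs.
#' @param expr expression matrix (genes x samples).
#' @return character vector of TF IDs present in `expr`, in matrix order.
#' @export
match_tfs <- function(tfs, expr) {
  keep <- rownames(expr)[rownames(expr) %in% tfs]
  n_missing <- length(setdiff(tfs, rownames(expr)))
  if (n_missing > 0L) {
    warning(n_missing, " TF id(s) not present in the expression matrix")
  }
  if (length(keep) == 0L) stop("no TF ids match the expression matrix")
  keep
}

#' Read a gold-standard edge list
#'
#' Three tab-separated columns: regulator, target, label (0 or 1). Label 1
#' marks a known interaction, 0 a known non-interaction; pairs absent from
#' the file are of unknown status and are ignored by the evaluation module.
#'
#' @param path input file.
#' @param directed are the listed pairs directed regulator->target edges?
#' @return data.frame of class `grn_gold` with columns `regulator`,
#'   `target`, `label` and attribute `directed`.
#' @export
read_gold_standard <- function(path, directed = TRUE) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("regulator", "target", "label"))
  gold_standard(df$regulator, df$target, df$label, directed = directed)
}

#' Construct a gold standard from vectors
#' @param regulator,target character vectors.
#' @param label 0/1 integer vector.
#' @param directed logical.
#' @return a `grn_gold` data.frame.
#' @export
gold_standard <- function(regulator, target, label, directed = TRUE) {
  regulator <- as.character(regulator)
  target <- as.character(target)
  label <- as.integer(label)
  if (!all(label %in% c(0L, 1L))) stop("gold labels must be 0 or 1")
  if (any(regulator == target)) stop("gold standard contains self-edges")
  key <- if (directed) paste(regulator, target, sep = "\r")
         else pair_key(regulator, target)
  if (anyDuplicated(key)) {
    conflict <- tapply(label, key, function(l) length(unique(l)) > 1L)
    if (any(conflict)) {
      stop("conflicting labels for pair(s): ",
           paste(gsub("\r", " -> ", names(conflict)[conflict][1:min(5, sum(conflict))]),
                 collapse = ", "))
    }
    keep <- !duplicated(key)
    regulator <- regulator[keep]; target <- target[keep]
    label <- label[keep]
  }
  structure(data.frame(regulator = regulator, target = target,
                       label = label, stringsAsFactors = FALSE),
            directed = directed, class = c("grn_gold", "data.frame"))
}

#' Write a gold standard as 3-column TSV
#' @param gold a `grn_gold` object.
#' @param path output path.
#' @export
write_gold_standard <- function(gold, path) {
  utils::write.table(as.data.frame(gold), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read tabular protein-similarity search output (12-column "outfmt 6")
#'
#' The standard layout: query, subject, percent identity, alignment
#' length, mismatches, gap opens, query start/end, subject start/end,
#' E-value, bit score.
#'
#' @param path tab-separated file with 12 columns, no header.
#' @return data.frame with typed columns.
#' @export
read_blast_table <- function(path) {
  cols <- c("query_id", "subject_id", "pct_identity", "aln_len",
            "mismatches", "gap_opens", "q_start", "q_end",
            "s_start", "s_end", "evalue", "bit_score")
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) != 12L) {
    stop("expected 12 tab-separated columns, found ", ncol(df))
  }
  names(df) <- cols
  if (any(df$evalue < 0)) stop("negative E-value in ", path)
  if (any(!is.finite(df$bit_score))) stop("non-finite bit score in ", path)
  df
}

#' Read a gene-to-term annotation table
#'
#' Two tab-separated columns (gene ID, term ID), one pair per line; a gene
#' may appear on many lines. An optional third column holds a free-text
#' description.
#'
#' @param path input file.
#' @return named list mapping gene ID to a character vector of term IDs.
#' @export
read_annotation <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          fill = TRUE)
  split(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Read a two-column alias map (e.g. probeset ID to gene ID)
#'
#' @param path tab-separated file: original ID, alias.
#' @return named character vector (names = original IDs).
#' @export
read_alias_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Rename genes of an expression matrix through an alias map
#'
#' IDs without an alias are kept unchanged; the mapping must not create
#' duplicates.
#'
#' @param expr expression matrix.
#' @param map named character vector from [read_alias_map()].
#' @return the matrix with translated rownames.
#' @export
apply_alias <- function(expr, map) {
  ids <- rownames(expr)
  hit <- ids %in% names(map)
  ids[hit] <- unname(map[ids[hit]])
  if (anyDuplicated(ids)) stop("alias map creates duplicate gene ids")
  rownames(expr) <- ids
  expr
}
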