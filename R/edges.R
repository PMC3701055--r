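#' Construct a ranked edge list
#'
#' The ranked edge list is the common currency of the toolkit: every
#' inference algorithm emits one, Borda integration consumes several, and
#' the evaluation module scores them against gold standards. Edges are
#' sorted by descending score with a deterministic lexicographic tie-break
#' on (regulator, target), so the rank of every edge is reproducible —
#' essential because downstream rank aggregation operates on ranks, not raw
#' scores.
#'
#' @param regulator,target character vectors of gene identifiers.
#' @param score numeric vector; larger means more confident. Methods whose
#'   native output is a p-value store `1 - p`.
#' @param directed logical; if `FALSE` each unordered pair is stored once in
#'   canonical orientation (lexicographically smaller ID first).
#' @param method character tag identifying the producing method.
#' @param extra optional data.frame of per-edge metadata columns (e.g. the
#'   sign of a correlation, or a PDAG orientation mark), row-aligned with
#'   the edges.
#' @return A data.frame of class `grn_edges` with columns `regulator`,
#'   `target`, `score` (plus any metadata), sorted, with attributes
#'   `directed` and `method`.
#' @examples
#' ranked_edges(c("g1", "g2"), c("g3", "g1"), c(0.2, 0.9),
#'              directed = TRUE, method = "demo")
#' @export
ranked_edges <- function(regulator, target, score,
                         directed = TRUE, method = "unknown",
                         extra = NULL) {
  regulator <- as.character(regulator)
  target <- as.character(target)
  score <- as.numeric(score)
  stopifnot(length(regulator) == length(target),
            length(target) == length(score))
  if (any(!is.finite(score))) stop("edge scores must be finite")
  if (any(regulator == target)) stop("self-edges are not allowed")

  if (!directed) {
    swap <- target < regulator
    tmp <- regulator[swap]
    regulator[swap] <- target[swap]
    target[swap] <- tmp
    # orientation metadata travels with the pair: flip marks on swap
    if (!is.null(extra) && "direction" %in% names(extra)) {
      d <- extra$direction
      extra$direction[swap] <- ifelse(d[swap] == "->", "<-",
                                      ifelse(d[swap] == "<-", "->",
                                             d[swap]))
    }
  }
  key <- paste(regulator, target, sep = "\r")
  if (anyDuplicated(key)) {
    dups <- unique(key[duplicated(key)])
    stop("duplicate edges: ",
         paste(gsub("\r", " -> ", utils::head(dups, 5L)), collapse = ", "))
  }
  df <- data.frame(regulator = regulator, target = target, score = score,
                   stringsAsFactors = FALSE)
  if (!is.null(extra)) {
    stopifnot(is.data.frame(extra), nrow(extra) == nrow(df))
    df <- cbind(df, extra)
  }
  ord <- order(-df$score, df$regulator, df$target, method = "radix")
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, directed = directed, method = method,
            class = c("grn_edges", "data.frame"))
}

#' @export
print.grn_edges <- function(x, ...) {
  cat(sprintf("Ranked edge list [%s]: %d edges, %s\n",
              attr(x, "method"), nrow(x),
              if (isTRUE(attr(x, "directed"))) "directed" else "undirected"))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more edges\n")
  invisible(x)
}

#' Write a ranked edge list to a tab-delimited file
#'
#' Scores are printed with 9 significant digits so that a write/read
#' round-trip reproduces scores to well below 1e-9 relative error.
#'
#' @param edges a `grn_edges` object.
#' @param path output file path.
#' @param header write a header line? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
write_edges <- function(edges, path, header = TRUE) {
  stopifnot(inherits(edges, "grn_edges"))
  df <- as.data.frame(edges)
  df$score <- sprintf("%.9g", df$score)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = header)
  invisible(path)
}

#' Read a ranked edge list written by [write_edges()]
#'
#' @param path input file path.
#' @param directed,method attributes to attach (the TSV does not store
#'   them).
#' @param header does the file carry a header line?
#' @return a `grn_edges` object.
#' @export
read_edges <- function(path, directed = TRUE, method = "unknown",
                       header = TRUE) {
  if (file.size(path) == 0) {
    return(ranked_edges(character(), character(), numeric(),
                        directed = directed, method = method))
  }
  df <- utils::read.table(path, sep = "\t", header = header,
                          stringsAsFactors = FALSE,
                          colClasses = c("character", "character", NA))
  names(df)[1:3] <- c("regulator", "target", "score")
  extra <- if (ncol(df) > 3L) df[, -(1:3), drop = FALSE] else NULL
  ranked_edges(df$regulator, df$target, as.numeric(df$score),
               directed = directed, method = method, extra = extra)
}
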