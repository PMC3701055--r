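#' Extract a subnetwork around a gene list
#'
#' Keeps the immediate connections of the seed genes: every edge with at
#' least one endpoint in `seeds` (`mode = "neighbors_of_seeds"`), or only
#' edges whose regulator endpoint is a seed TF
#' (`mode = "tf_first_connections"`, for which a TF list must be given).
#' The result can be truncated to the `top_edges` most confident edges.
#'
#' @param net a `grn_edges` network.
#' @param seeds character vector of gene IDs of interest.
#' @param mode `"neighbors_of_seeds"` (default) or
#'   `"tf_first_connections"`.
#' @param top_edges keep at most this many edges, by score (default
#'   `Inf`).
#' @param tfs TF list used by `"tf_first_connections"`; for undirected
#'   networks either endpoint being a seed TF qualifies.
#' @return a `grn_edges` subnetwork (possibly empty, with a warning when
#'   no seed occurs in the network).
#' @export
subnetwork <- function(net, seeds,
                       mode = c("neighbors_of_seeds",
                                "tf_first_connections"),
                       top_edges = Inf, tfs = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(net, "grn_edges"))
  nodes <- unique(c(net$regulator, net$target))
  if (!any(seeds %in% nodes)) {
    warning("no seed gene occurs in the network")
  }
  keep <- switch(mode,
    neighbors_of_seeds =
      net$regulator %in% seeds | net$target %in% seeds,
    tf_first_connections = {
      if (is.null(tfs)) stop("mode 'tf_first_connections' needs a TF list")
      stf <- intersect(seeds, tfs)
      if (isTRUE(attr(net, "directed"))) net$regulator %in% stf
      else net$regulator %in% stf | net$target %in% stf
    })
  sub <- net[keep, , drop = FALSE]
  if (is.finite(top_edges) && nrow(sub) > top_edges) {
    sub <- sub[seq_len(top_edges), , drop = FALSE]   # already score-sorted
  }
  rownames(sub) <- NULL
  structure(sub, directed = attr(net, "directed"),
            method = attr(net, "method"),
            class = c("grn_edges", "data.frame"))
}

# Best hit(s) per query under the standard ordering: bit score descending,
# then E-value ascending, then subject ID. All hits tying the best on
# exact (bit_score, evalue) are eligible regardless of max_hits; otherwise
# the top max_hits are kept.
best_hits <- function(tab, max_hits) {
  ord <- order(tab$query_id, -tab$bit_score, tab$evalue, tab$subject_id,
               method = "radix")
  tab <- tab[ord, , drop = FALSE]
  out <- lapply(split(tab, tab$query_id), function(q) {
    tie <- q$bit_score == q$bit_score[1L] & q$evalue == q$evalue[1L]
    n_keep <- max(sum(tie), min(max_hits, nrow(q)))
    unique(q$subject_id[seq_len(n_keep)])
  })
  out
}

#' Reciprocal-best-hit ortholog pairs from pairwise similarity tables
#'
#' Two genes in different genomes are called orthologs when each is among
#' the other's best similarity hits. Hits are first filtered at
#' `evalue_threshold`, then sorted by descending bit score (ties broken by
#' ascending E-value, then subject ID); hits tying the best hit on both
#' bit score and E-value all count as best hits ("multiple orthologs").
#' For species with a recent genome duplication the per-query hit budget
#' can be raised (e.g. `max_hits_ab = 2` to allow each query from genome A
#' its best two hits in the duplicated genome B).
#'
#' @param ab similarity table of genome A queried against genome B
#'   ([read_blast_table()] layout).
#' @param ba the reciprocal table (B queried against A).
#' @param evalue_threshold maximum E-value (default 1e-6).
#' @param max_hits_ab,max_hits_ba best-hit budget per query in each
#'   direction (default 1).
#' @return data.frame with columns `gene_a`, `gene_b`, one row per
#'   reciprocal pair, sorted.
#' @export
rbh_orthologs <- function(ab, ba, evalue_threshold = 1e-6,
                          max_hits_ab = 1L, max_hits_ba = 1L) {
  ab <- ab[ab$evalue <= evalue_threshold, , drop = FALSE]
  ba <- ba[ba$evalue <= evalue_threshold, , drop = FALSE]
  best_ab <- best_hits(ab, max_hits_ab)
  best_ba <- best_hits(ba, max_hits_ba)
  pairs <- list()
  for (a in names(best_ab)) {
    for (b in best_ab[[a]]) {
      if (!is.null(best_ba[[b]]) && a %in% best_ba[[b]]) {
        pairs[[length(pairs) + 1L]] <- c(a, b)
      }
    }
  }
  if (length(pairs) == 0L) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      stringsAsFactors = FALSE))
  }
  m <- do.call(rbind, pairs)
  df <- unique(data.frame(gene_a = m[, 1L], gene_b = m[, 2L],
                          stringsAsFactors = FALSE))
  df[order(df$gene_a, df$gene_b), , drop = FALSE]
}

#' Build metagene (cross-species ortholog) clusters
#'
#' Takes reciprocal-best-hit pair sets for each species pair and merges
#' them into clusters: nodes are (species, gene) pairs and clusters are
#' the connected components of the union ortholog graph. Components in
#' which a species contributes more members than its allowance (1 by
#' default; 2 for species listed in `duplicated_species`) are kept but
#' flagged rather than silently resolved. Metagene IDs are assigned
#' deterministically from the sorted member lists, so they are stable
#' across runs and input orderings.
#'
#' @param pairsets named list; each element a data.frame with columns
#'   `gene_a`, `gene_b` and the element name of the form
#'   `"speciesA-speciesB"` naming the two genomes.
#' @param duplicated_species species allowed 2 members per cluster.
#' @return data.frame with columns `metagene_id`, `species`, `gene_id`,
#'   `flagged`; each (species, gene) belongs to at most one metagene and
#'   every cluster spans >= 2 species.
#' @export
build_metagenes <- function(pairsets, duplicated_species = character(0)) {
  edges <- do.call(rbind, lapply(names(pairsets), function(nm) {
    sp <- strsplit(nm, "-", fixed = TRUE)[[1L]]
    if (length(sp) != 2L) {
      stop("pairset names must look like 'speciesA-speciesB'")
    }
    df <- pairsets[[nm]]
    data.frame(from = paste(sp[1L], df$gene_a, sep = "|"),
               to = paste(sp[2L], df$gene_b, sep = "|"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges) || nrow(edges) == 0L) {
    return(data.frame(metagene_id = character(), species = character(),
                      gene_id = character(), flagged = logical(),
                      stringsAsFactors = FALSE))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  members <- lapply(members, sort)
  # deterministic IDs: clusters ordered by their sorted member vectors
  ord <- order(vapply(members, `[[`, "", 1L), method = "radix")
  members <- members[ord]
  rows <- lapply(seq_along(members), function(k) {
    mm <- members[[k]]
    sp <- sub("\\|.*$", "", mm)
    gid <- sub("^[^|]*\\|", "", mm)
    allow <- ifelse(sp %in% duplicated_species, 2L, 1L)
    flag <- any(table(sp) > tapply(allow, sp, max)[names(table(sp))])
    data.frame(metagene_id = sprintf("MG%06d", k), species = sp,
               gene_id = gid, flagged = flag, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Translate network node IDs to metagene IDs
#'
#' @param net a `grn_edges` network.
#' @param metagenes metagene table from [build_metagenes()].
#' @param species which species' gene IDs the network uses.
#' @return the network on metagene IDs; edges with an untranslatable
#'   endpoint are dropped and counted in attribute `n_dropped`.
#' @export
translate_to_metagenes <- function(net, metagenes, species) {
  mg <- metagenes[metagenes$species == species, , drop = FALSE]
  map <- stats::setNames(mg$metagene_id, mg$gene_id)
  reg <- unname(map[net$regulator])
  tgt <- unname(map[net$target])
  keep <- !is.na(reg) & !is.na(tgt) & reg != tgt
  out <- ranked_edges(reg[keep], tgt[keep], net$score[keep],
                      directed = isTRUE(attr(net, "directed")),
                      method = attr(net, "method"))
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Overlay multiple networks into a composite
#'
#' Takes the edge union of two or more networks (optionally after
#' translating every network onto metagene IDs) and labels each composite
#' edge with the sources that predicted it, so shared and source-specific
#' structure can be queried directly.
#'
#' @param nets named list of `grn_edges` objects; names identify the
#'   source (algorithm or species).
#' @param metagenes optional metagene table; requires `species` giving,
#'   per network, which species' IDs it uses.
#' @param species character vector aligned with `nets` (only with
#'   `metagenes`).
#' @return data.frame: `regulator`, `target`, one logical column per
#'   source, `n_sources`, `sources` (comma-joined), and per-source score
#'   columns; sorted by `n_sources` descending.
#' @export
compare_networks <- function(nets, metagenes = NULL, species = NULL) {
  stopifnot(is.list(nets), length(nets) >= 2L)
  if (is.null(names(nets)) || any(!nzchar(names(nets)))) {
    names(nets) <- paste0("net", seq_along(nets))
  }
  if (!is.null(metagenes)) {
    stopifnot(length(species) == length(nets))
    nets <- lapply(seq_along(nets), function(i)
      translate_to_metagenes(nets[[i]], metagenes, species[i]))
    names(nets) <- if (!is.null(names(species))) names(species)
                   else species
  }
  keys <- lapply(nets, function(x) pair_key(x$regulator, x$target))
  universe <- unique(unlist(keys))
  parts <- strsplit(universe, "\r", fixed = TRUE)
  out <- data.frame(regulator = vapply(parts, `[[`, "", 1L),
                    target = vapply(parts, `[[`, "", 2L),
                    stringsAsFactors = FALSE)
  for (nm in names(nets)) {
    k <- keys[[nm]]
    first <- !duplicated(k)
    present <- universe %in% k
    out[[paste0("in_", nm)]] <- present
    sc <- stats::setNames(nets[[nm]]$score[first], k[first])
    out[[paste0("score_", nm)]] <- unname(sc[universe])
  }
  pres <- as.matrix(out[, paste0("in_", names(nets)), drop = FALSE])
  out$n_sources <- rowSums(pres)
  out$sources <- apply(pres, 1L, function(s)
    paste(names(nets)[s], collapse = ","))
  out <- out[order(-out$n_sources, out$regulator, out$target), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chi-square annotation-term enrichment of a gene set
#'
#' For every term annotating at least one universe gene, builds the 2x2
#' table (in subnetwork vs not) x (has term vs not) and computes the
#' 1-degree-of-freedom Pearson chi-square statistic without continuity
#' correction, with the p-value from the upper tail. Terms with a zero
#' expected count in any cell are skipped. Raw p-values are always
#' reported; a Benjamini-Hochberg adjusted column is added for
#' convenience.
#'
#' @param subnet_genes character vector, subset of `universe`.
#' @param universe character vector of all analysed genes.
#' @param annot named list gene -> character vector of term IDs
#'   ([read_annotation()]).
#' @return data.frame per term: counts, `chi2`, `pvalue`, `p_adjust`,
#'   `direction` ("enriched"/"depleted"), sorted by p-value.
#' @export
go_enrichment <- function(subnet_genes, universe, annot) {
  if (!all(subnet_genes %in% universe)) {
    stop("subnet_genes must be a subset of the universe")
  }
  universe <- unique(universe)
  subnet_genes <- unique(subnet_genes)
  ann <- annot[names(annot) %in% universe]
  terms <- sort(unique(unlist(ann)))
  n <- length(universe)
  n_in <- length(subnet_genes)
  rows <- lapply(terms, function(tm) {
    has <- names(ann)[vapply(ann, function(ts) tm %in% ts, TRUE)]
    a <- sum(subnet_genes %in% has)          # in subnet, has term
    b <- n_in - a                            # in subnet, no term
    c_ <- length(has) - a                    # outside, has term
    d <- n - n_in - c_                       # outside, no term
    tab <- matrix(c(a, b, c_, d), 2L)
    expd <- outer(rowSums(tab), colSums(tab)) / n
    if (any(expd == 0)) return(NULL)         # degenerate margin
    chi2 <- sum((tab - expd)^2 / expd)
    p <- stats::pchisq(chi2, df = 1L, lower.tail = FALSE)
    data.frame(term = tm, n_subnet_term = a, n_subnet = n_in,
               n_universe_term = a + c_, n_universe = n,
               chi2 = chi2, pvalue = p,
               direction = if (a / n_in >= (a + c_) / n) "enriched"
                           else "depleted",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(term = character(), n_subnet_term = integer(),
                      n_subnet = integer(), n_universe_term = integer(),
                      n_universe = integer(), chi2 = numeric(),
                      pvalue = numeric(), p_adjust = numeric(),
                      direction = character(), stringsAsFactors = FALSE))
  }
  out$p_adjust <- stats::p.adjust(out$pvalue, method = "BH")
  out <- out[order(out$pvalue, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
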