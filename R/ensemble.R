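#' Borda-count integration of ranked edge lists
#'
#' Combines K >= 2 ranked edge lists into one composite network by rank
#' aggregation: every list is truncated to its `top_k` best edges, each
#' edge appearing in at least one truncated list is rescored by its
#' average rank across all K lists, and edges absent from a list receive
#' the penalty rank `top_k + 1`. The integrative score is the negated
#' average rank, so better (smaller) average ranks sort first; ties break
#' lexicographically as everywhere else.
#'
#' Direction handling when directed and undirected lists are mixed: the
#' composite is keyed by the unordered pair; a directed list contributes
#' the better of its two orientation ranks to the pair, and the composite
#' edge is reported directed only if at least one method directed it and
#' no method directed it the opposite way.
#'
#' @param lists list of `grn_edges` objects (length >= 2).
#' @param top_k truncation depth per list (default `Inf` = no
#'   truncation; the penalty rank is then max list length + 1).
#' @return `grn_edges` list with metadata columns `avg_rank`,
#'   `n_supporting` and `supporting` (comma-joined method tags), plus
#'   per-method rank columns `rank_<method>`.
#' @export
borda_integrate <- function(lists, top_k = Inf) {
  if (!is.list(lists) || length(lists) < 2L) {
    stop("need at least 2 edge lists to integrate")
  }
  stopifnot(all(vapply(lists, inherits, TRUE, "grn_edges")))
  K <- length(lists)
  tags <- vapply(seq_len(K), function(i) {
    tg <- attr(lists[[i]], "method")
    if (is.null(tg) || tg == "unknown") paste0("m", i) else tg
  }, character(1))
  if (anyDuplicated(tags)) tags <- make.unique(tags, sep = "_")

  all_directed <- all(vapply(lists, function(x)
    isTRUE(attr(x, "directed")), TRUE))

  trunc_len <- integer(K)
  ranks <- vector("list", K)       # per list: named rank vector (+dir info)
  dirinfo <- vector("list", K)
  for (i in seq_len(K)) {
    x <- lists[[i]]
    ntop <- min(nrow(x), if (is.finite(top_k)) top_k else nrow(x))
    x <- x[seq_len(ntop), , drop = FALSE]
    trunc_len[i] <- ntop
    rk <- seq_len(ntop)
    if (all_directed) {
      key <- paste(x$regulator, x$target, sep = "\r")
      ranks[[i]] <- stats::setNames(rk, key)
      dirinfo[i] <- list(NULL)
    } else {
      key <- pair_key(x$regulator, x$target)
      # directed list: both orientations map to the pair; keep best rank
      # and remember which orientation it came from
      first <- !duplicated(key)
      ranks[[i]] <- stats::setNames(rk[first], key[first])
      if (isTRUE(attr(lists[[i]], "directed"))) {
        dirinfo[[i]] <- stats::setNames(
          paste(x$regulator, x$target, sep = "\r")[first], key[first])
      } else if ("direction" %in% names(x)) {
        # PDAG-style metadata on canonical pairs
        mark <- x$direction[first]
        ori <- ifelse(mark == "->",
                      paste(x$regulator, x$target, sep = "\r")[first],
               ifelse(mark == "<-",
                      paste(x$target, x$regulator, sep = "\r")[first],
                      NA_character_))
        dirinfo[[i]] <- stats::setNames(ori, key[first])
      } else {
        dirinfo[i] <- list(NULL)
      }
    }
  }
  penalty <- if (is.finite(top_k)) top_k + 1 else max(trunc_len) + 1

  universe <- unique(unlist(lapply(ranks, names)))
  rank_mat <- matrix(penalty, length(universe), K,
                     dimnames = list(universe, tags))
  for (i in seq_len(K)) {
    rank_mat[names(ranks[[i]]), i] <- ranks[[i]]
  }
  avg_rank <- rowMeans(rank_mat)
  support <- rank_mat < penalty

  parts <- strsplit(universe, "\r", fixed = TRUE)
  reg <- vapply(parts, `[[`, "", 1L)
  tgt <- vapply(parts, `[[`, "", 2L)

  if (!all_directed) {
    # resolve composite direction from supporting directed methods
    dirs <- rep(NA_character_, length(universe))
    conflict <- rep(FALSE, length(universe))
    for (i in seq_len(K)) {
      di <- dirinfo[[i]]
      if (is.null(di)) next
      hit <- match(names(di), universe)
      ok <- !is.na(hit) & !is.na(di) & support[cbind(hit, i)]
      h <- hit[ok]; d <- di[ok]
      newc <- !is.na(dirs[h]) & dirs[h] != d
      conflict[h[newc]] <- TRUE
      dirs[h][is.na(dirs[h])] <- d[is.na(dirs[h])]
    }
    dirs[conflict] <- NA_character_
    dirmark <- ifelse(is.na(dirs), "--",
                      ifelse(dirs == paste(reg, tgt, sep = "\r"),
                             "->", "<-"))
  }

  extra <- data.frame(avg_rank = avg_rank,
                      n_supporting = rowSums(support),
                      supporting = apply(support, 1L, function(s)
                        paste(tags[s], collapse = ",")),
                      stringsAsFactors = FALSE)
  for (i in seq_len(K)) {
    extra[[paste0("rank_", tags[i])]] <-
      ifelse(support[, i], rank_mat[, i], NA_integer_)
  }
  if (!all_directed) extra$direction <- dirmark
  ranked_edges(reg, tgt, -avg_rank,
               directed = all_directed, method = "integrative",
               extra = extra)
}

# Restrict a prediction to the gold universe and return per-rank labels.
# If the prediction is undirected and the gold is directed, the gold is
# collapsed to unordered pairs (label = max over orientations).
align_pred_gold <- function(pred, gold) {
  pred_dir <- isTRUE(attr(pred, "directed"))
  gold_dir <- isTRUE(attr(gold, "directed"))
  if (!pred_dir && gold_dir) {
    key <- pair_key(gold$regulator, gold$target)
    lab <- tapply(gold$label, key, max)
    gkey <- names(lab)
    glab <- as.integer(lab)
    pkey <- pair_key(pred$regulator, pred$target)
  } else if (pred_dir && !gold_dir) {
    # directed prediction vs undirected gold: collapse prediction pairs,
    # keeping the better-ranked orientation
    gkey <- pair_key(gold$regulator, gold$target)
    glab <- gold$label
    pkey <- pair_key(pred$regulator, pred$target)
    first <- !duplicated(pkey)
    pred <- pred[first, , drop = FALSE]
    pkey <- pkey[first]
  } else if (gold_dir) {
    gkey <- paste(gold$regulator, gold$target, sep = "\r")
    glab <- gold$label
    pkey <- paste(pred$regulator, pred$target, sep = "\r")
  } else {
    gkey <- pair_key(gold$regulator, gold$target)
    glab <- gold$label
    pkey <- pair_key(pred$regulator, pred$target)
  }
  m <- match(pkey, gkey)
  keep <- !is.na(m)
  list(labels_ranked = glab[m[keep]],          # in prediction order
       P = sum(glab == 1L), N = sum(glab == 0L))
}

#' DREAM-style AUPR/AUROC evaluation of a ranked edge list
#'
#' The evaluable universe is the set of pairs labelled in the gold
#' standard; unlabelled pairs are ignored, not counted as negatives. The
#' prediction is truncated to its `top_k` best edges and swept from the
#' top; gold pairs missing from the truncated list complete the curves
#' under the assumption that the remainder is randomly ordered (a linear
#' ROC segment to (1, 1), and the closed-form expected precision-recall
#' tail), so AUCs are well defined even for truncated predictions. Areas
#' are trapezoidal.
#'
#' @param pred a `grn_edges` prediction.
#' @param gold a `grn_gold` standard with at least one positive and one
#'   negative label.
#' @param top_k truncation depth (default 100000).
#' @return list of class `grn_eval`: `aupr`, `auroc`, `roc` and `pr`
#'   curve data.frames, `counts` (P, N, L, TP, FP at the truncation
#'   point), `top_k`.
#' @export
evaluate_auc <- function(pred, gold, top_k = 100000L) {
  stopifnot(inherits(pred, "grn_edges"), inherits(gold, "grn_gold"))
  ntop <- min(nrow(pred), top_k)
  al <- align_pred_gold(pred[seq_len(ntop), , drop = FALSE], gold)
  P <- al$P; N <- al$N
  if (P == 0L || N == 0L) {
    stop("gold standard must contain >= 1 positive and >= 1 negative")
  }
  lab <- al$labels_ranked
  L <- length(lab)
  if (L == 0L && nrow(pred) > 0L) {
    stop("no overlap between prediction and gold-standard universe")
  }
  tp <- cumsum(lab == 1L)
  fp <- cumsum(lab == 0L)
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / N)
  prec <- if (L > 0L) tp / seq_len(L) else numeric(0)
  rec <- tp / P

  trap <- function(x, y) sum(diff(x) * (utils::head(y, -1) +
                                          utils::tail(y, -1)) / 2)
  auroc <- trap(fpr, tpr)
  tpl <- if (L > 0L) tp[L] else 0L
  fpl <- if (L > 0L) fp[L] else 0L
  remP <- P - tpl
  remN <- N - fpl
  # random-remainder ROC tail: straight line to (1, 1)
  auroc <- auroc + (1 - fpr[L + 1L]) * (tpr[L + 1L] + 1) / 2

  # PR head: trapezoid over recall; curve starts at recall 0 with the
  # precision of the first prediction
  if (L > 0L) {
    aupr <- trap(c(0, rec), c(prec[1L], prec))
  } else {
    aupr <- 0
  }
  # PR tail: remainder uniformly mixed; TP(t) = tpl + t*remP,
  # rank(t) = L + t*(remP + remN), t in [0, 1];
  # integral of precision d(recall) has closed form
  M <- remP + remN
  if (remP > 0L && M > 0L) {
    if (L == 0L) {
      aupr <- aupr + (remP / P) * (remP / M)
    } else {
      aupr <- aupr + (remP / P) *
        ((remP / M) + (tpl - L * remP / M) * log((L + M) / L) / M)
    }
  }
  structure(list(
    aupr = aupr, auroc = auroc,
    roc = data.frame(fpr = fpr, tpr = tpr),
    pr = data.frame(recall = rec, precision = prec),
    counts = list(P = P, N = N, L = L, TP = tpl, FP = fpl),
    top_k = top_k), class = "grn_eval")
}

#' @export
print.grn_eval <- function(x, ...) {
  cat(sprintf("AUPR = %.4f  AUROC = %.4f  (universe: %d+, %d-; %d ranked)\n",
              x$aupr, x$auroc, x$counts$P, x$counts$N, x$counts$L))
  invisible(x)
}

#' Directionality accuracy of a partially directed prediction
#'
#' Scores the edges of a PDAG prediction (the `edges` component of
#' [plpc()], carrying `"->"`/`"<-"`/`"--"` marks) against a directed gold
#' standard: `n_tp` counts predicted edges whose unordered pair is a gold
#' positive (direction ignored), and `n_tp_correct_direction` counts
#' directed predicted edges whose orientation matches a gold positive.
#' `directed_precision` is the fraction of directed predictions that are
#' correctly directed true edges; when nothing is directed it is reported
#' as 0 with `undefined = TRUE`.
#'
#' @param edges a `grn_edges` list with a `direction` metadata column.
#' @param gold a directed `grn_gold`.
#' @return list: `n_edges`, `n_directed`, `n_tp`,
#'   `n_tp_correct_direction`, `directed_precision`, `undefined`.
#' @export
evaluate_directionality <- function(edges, gold) {
  stopifnot("direction" %in% names(edges),
            isTRUE(attr(gold, "directed")))
  pos <- gold[gold$label == 1L, , drop = FALSE]
  pos_pair <- unique(pair_key(pos$regulator, pos$target))
  pos_dirkey <- paste(pos$regulator, pos$target, sep = "\r")

  pairk <- pair_key(edges$regulator, edges$target)
  is_dir <- edges$direction %in% c("->", "<-")
  orient <- ifelse(edges$direction == "->",
                   paste(edges$regulator, edges$target, sep = "\r"),
                   paste(edges$target, edges$regulator, sep = "\r"))
  n_tp <- sum(pairk %in% pos_pair)
  n_tpc <- sum(is_dir & orient %in% pos_dirkey)
  n_dir <- sum(is_dir)
  list(n_edges = nrow(edges),
       n_directed = n_dir,
       n_tp = n_tp,
       n_tp_correct_direction = n_tpc,
       directed_precision = if (n_dir > 0L) n_tpc / n_dir else 0,
       undefined = n_dir == 0L)
}
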