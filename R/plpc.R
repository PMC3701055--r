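#' Fisher-z conditional-independence test for partial correlations
#'
#' Tests whether a partial correlation `r`, estimated from `n` samples
#' given a conditioning set of size `k`, is compatible with zero:
#' \eqn{z = \tanh^{-1}(r)}, statistic \eqn{\sqrt{n-k-3}\,|z|}, two-sided
#' p-value from the standard normal. When `n - k - 3 <= 0` the test has no
#' degrees of freedom and is reported as undecidable (`NA` p-value); the
#' skeleton search then conservatively keeps the edge.
#'
#' @param r partial correlation in (-1, 1).
#' @param n number of samples.
#' @param k size of the conditioning set.
#' @param alpha significance level in (0, 1).
#' @return list with `independent` (logical, `NA` if undecidable),
#'   `pvalue`, `statistic`.
#' @export
fisher_z_ci_test <- function(r, n, k, alpha = 0.01) {
  stopifnot(alpha > 0, alpha < 1)
  if (n - k - 3 <= 0) {
    return(list(independent = NA, pvalue = NA_real_,
                statistic = NA_real_))
  }
  r <- max(-1 + 1e-15, min(1 - 1e-15, r))
  z <- 0.5 * log((1 + r) / (1 - r))
  stat <- sqrt(n - k - 3) * abs(z)
  p <- 2 * stats::pnorm(stat, lower.tail = FALSE)
  list(independent = p > alpha, pvalue = p, statistic = stat)
}

#' Partial correlation from a correlation matrix
#'
#' Partial correlation of variables `i` and `j` given the set `S`,
#' computed from the inverse of the correlation submatrix on
#' \{i, j\} union S: \eqn{-\Omega_{ij}/\sqrt{\Omega_{ii}\Omega_{jj}}}.
#' Singular submatrices fall back to the Moore-Penrose pseudo-inverse.
#'
#' @param corr full correlation matrix.
#' @param i,j variable indices (or names).
#' @param S conditioning set of indices/names, excluding i and j.
#' @return the partial correlation.
#' @export
partial_correlation <- function(corr, i, j, S = integer(0)) {
  if (length(S) == 0L) return(corr[i, j])
  idx <- c(i, j, S)
  sub <- corr[idx, idx, drop = FALSE]
  om <- tryCatch(solve(sub), error = function(e) MASS::ginv(sub))
  r <- -om[1L, 2L] / sqrt(om[1L, 1L] * om[2L, 2L])
  max(-1, min(1, r))
}

# Lexicographic subsets of size k from a candidate vector already sorted
# by gene ID. Returns a list of integer vectors (positions in `cand`).
subsets_of <- function(cand, k) {
  if (k == 0L) return(list(integer(0)))
  if (length(cand) < k) return(list())
  utils::combn(cand, k, simplify = FALSE)
}

#' Bounded-order, order-independent skeleton search
#'
#' Starts from the complete undirected graph and, for conditioning-set
#' sizes l = 0, 1, ..., `ord`, tests every currently adjacent pair (i, j)
#' for conditional independence given subsets of size l drawn from the
#' neighbourhoods of i and of j (smaller neighbourhood first; subsets in
#' lexicographic gene-ID order). An edge is removed at the first
#' independence found, and the separating set recorded. Crucially, the
#' neighbourhoods used at level l are frozen at the start of the level and
#' deletions applied only when the level completes — the "stable" device
#' that makes the output invariant to gene ordering and to how the pair
#' list is partitioned across workers. Bounding l by `ord` is what makes
#' the search tractable for thousands of genes.
#'
#' @param expr expression matrix (genes x samples).
#' @param alpha CI-test significance level (default 0.01).
#' @param ord maximum conditioning-set size (default 8).
#' @param workers parallel workers for the per-edge tests of a level;
#'   never affects results.
#' @return object of class `grn_skeleton`: list with `genes`, logical
#'   adjacency matrix `adj`, `sepset` (list keyed by removed pair),
#'   `pmax` matrix of the largest p-value seen per pair, `n`.
#' @export
plpc_skeleton <- function(expr, alpha = 0.01, ord = 8L, workers = 1L) {
  n <- ncol(expr)
  if (n <= ord + 3) stop("need n_samples > ord + 3")
  corr <- pearson_matrix(expr)
  skeleton_from_corr(corr, n, alpha = alpha, ord = ord, workers = workers)
}

#' Skeleton search from a correlation matrix
#'
#' Workhorse behind [plpc_skeleton()]; exposed so that exact covariance
#' structures (e.g. the closed-form covariance of a structural equation
#' model) can be analysed directly with a nominal sample size.
#'
#' @param corr correlation matrix with gene dimnames.
#' @param n nominal sample count used by the CI tests.
#' @inheritParams plpc_skeleton
#' @export
skeleton_from_corr <- function(corr, n, alpha = 0.01, ord = 8L,
                               workers = 1L) {
  genes <- rownames(corr)
  p <- nrow(corr)
  # work in the lexicographic gene ordering internally: this makes subset
  # enumeration (and hence recorded sepsets) permutation-invariant
  lex <- order(genes, method = "radix")
  corr <- corr[lex, lex, drop = FALSE]
  genes <- genes[lex]

  adj <- matrix(TRUE, p, p, dimnames = list(genes, genes))
  diag(adj) <- FALSE
  pmax_m <- matrix(-Inf, p, p, dimnames = list(genes, genes))
  sepset <- list()

  for (l in 0:ord) {
    nb <- lapply(seq_len(p), function(i) which(adj[i, ]))  # frozen
    if (all(vapply(nb, length, 1L) - 1L < l)) break
    pairs <- which(adj & upper.tri(adj), arr.ind = TRUE)
    if (nrow(pairs) == 0L) break

    test_pair <- function(k) {
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      cand_i <- setdiff(nb[[i]], j)
      cand_j <- setdiff(nb[[j]], i)
      # smaller frozen neighbourhood first; tie -> side of the smaller id
      sides <- if (length(cand_j) < length(cand_i)) list(cand_j, cand_i)
               else list(cand_i, cand_j)
      best_p <- -Inf
      for (cand in sides) {
        for (S in subsets_of(cand, l)) {
          if (n - l - 3 <= 0) next
          r <- partial_correlation(corr, i, j, S)
          tst <- fisher_z_ci_test(r, n, l, alpha)
          if (is.finite(tst$pvalue)) best_p <- max(best_p, tst$pvalue)
          if (isTRUE(tst$independent)) {
            return(list(remove = TRUE, S = S, pmax = best_p))
          }
        }
      }
      list(remove = FALSE, S = NULL, pmax = best_p)
    }

    res <- apply_parallel(seq_len(nrow(pairs)), test_pair, workers)
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1L]; j <- pairs[k, 2L]
      pmax_m[i, j] <- pmax_m[j, i] <- max(pmax_m[i, j], res[[k]]$pmax)
      if (res[[k]]$remove) {
        adj[i, j] <- adj[j, i] <- FALSE
        sepset[[pair_key(genes[i], genes[j])]] <- genes[res[[k]]$S]
      }
    }
  }
  structure(list(genes = genes, adj = adj, sepset = sepset,
                 pmax = pmax_m, n = n, alpha = alpha, ord = ord),
            class = "grn_skeleton")
}

#' Orient v-structures in a skeleton
#'
#' For every unshielded triple i - k - j (i and j non-adjacent), orients
#' i -> k <- j exactly when k is absent from the recorded separating set
#' of (i, j). Conflicting proposals (an edge pushed in both directions by
#' overlapping triples) leave the edge undirected and are counted in the
#' `conflicts` field.
#'
#' @param skel a `grn_skeleton`.
#' @return object of class `grn_pdag`: the skeleton plus a `dir` matrix
#'   (`dir[i, j] = TRUE` means i -> j) and `conflicts` count.
#' @export
orient_v_structures <- function(skel) {
  genes <- skel$genes
  p <- length(genes)
  adj <- skel$adj
  # proposed[i, j] = TRUE: some triple wants i -> j
  proposed <- matrix(FALSE, p, p, dimnames = list(genes, genes))
  for (k in seq_len(p)) {
    nbk <- which(adj[k, ])
    if (length(nbk) < 2L) next
    for (a in seq_along(nbk)) {
      for (b in seq_along(nbk)) {
        if (b <= a) next
        i <- nbk[a]; j <- nbk[b]
        if (adj[i, j]) next                       # shielded
        ss <- skel$sepset[[pair_key(genes[i], genes[j])]]
        if (is.null(ss)) next                     # pair never separated
        if (!(genes[k] %in% ss)) {
          proposed[i, k] <- TRUE
          proposed[j, k] <- TRUE
        }
      }
    }
  }
  conflict <- proposed & t(proposed)
  dir <- proposed & !conflict
  structure(list(genes = genes, adj = adj, dir = dir,
                 sepset = skel$sepset, pmax = skel$pmax, n = skel$n,
                 alpha = skel$alpha, ord = skel$ord,
                 conflicts = sum(conflict & upper.tri(conflict))),
            class = "grn_pdag")
}

# Would adding u -> v create a directed cycle through existing directed
# edges? Simple reachability check on the directed part.
creates_cycle <- function(dir, u, v) {
  # cycle iff v already reaches u through directed edges
  seen <- rep(FALSE, nrow(dir))
  stack <- v
  while (length(stack)) {
    x <- stack[[1L]]; stack <- stack[-1L]
    if (x == u) return(TRUE)
    if (seen[x]) next
    seen[x] <- TRUE
    stack <- c(stack, which(dir[x, ]))
  }
  FALSE
}

#' Apply Meek's orientation-propagation rules to a PDAG
#'
#' Repeats rules R1-R4 until no rule fires, never creating a new
#' v-structure or a directed cycle; an orientation that would do either is
#' skipped and counted as a conflict. The result is the maximally oriented
#' graph compatible with the skeleton and its v-structures.
#'
#' @param pdag a `grn_pdag`.
#' @return the completed `grn_pdag` (idempotent on already-complete
#'   input).
#' @export
apply_meek_rules <- function(pdag) {
  adj <- pdag$adj
  dir <- pdag$dir
  p <- nrow(adj)
  und <- function() adj & !dir & !t(dir)

  orient <- function(i, j) {
    # orient i -> j unless it contradicts an existing direction or closes
    # a directed cycle
    if (dir[j, i] || creates_cycle(dir, i, j)) return(FALSE)
    if (dir[i, j]) return(FALSE)
    dir[i, j] <<- TRUE
    TRUE
  }

  repeat {
    changed <- FALSE
    u <- und()
    for (b in seq_len(p)) for (c in seq_len(p)) {
      if (!u[b, c]) next
      # R1: a -> b, b - c, a and c non-adjacent  =>  b -> c
      for (a in which(dir[, b])) {
        if (!adj[a, c] && a != c) {
          if (orient(b, c)) { changed <- TRUE; break }
        }
      }
      if (changed) break
      # R2: b -> x -> c with b - c  =>  b -> c
      if (any(dir[b, ] & dir[, c])) {
        if (orient(b, c)) { changed <- TRUE; break }
      }
      # R3: b - c, b - d1, b - d2, d1 -> c, d2 -> c, d1,d2 non-adjacent
      ds <- which(u[b, ] & dir[, c])
      if (length(ds) >= 2L) {
        hit <- FALSE
        for (x in seq_along(ds)) for (y in seq_along(ds)) {
          if (y <= x) next
          if (!adj[ds[x], ds[y]]) { hit <- TRUE; break }
        }
        if (hit && orient(b, c)) { changed <- TRUE; break }
      }
      # R4: b - c, b - d, d -> e, e -> c, b adjacent to e, c,d non-adj
      for (d in which(u[b, ])) {
        es <- which(dir[d, ] & dir[, c] & adj[b, ])
        if (length(es) && !adj[c, d] && c != d) {
          if (orient(b, c)) { changed <- TRUE; break }
        }
      }
      if (changed) break
    }
    if (!changed) break
  }
  pdag$dir <- dir
  pdag
}

#' Bounded-order constraint-based network inference
#'
#' Full pipeline: stable bounded-order skeleton search
#' ([plpc_skeleton()]), v-structure orientation
#' ([orient_v_structures()]) and Meek-rule completion
#' ([apply_meek_rules()]). Every surviving edge is emitted with
#' confidence `1 - pmax` (pmax being the largest p-value observed across
#' that pair's CI tests — the closer the pair ever came to looking
#' independent, the lower the confidence), and the orientation is carried
#' as metadata (`"->"`, `"<-"`, or `"--"` on the canonical pair).
#'
#' @inheritParams plpc_skeleton
#' @return list with components `pdag` (a `grn_pdag`) and `edges` (an
#'   undirected `grn_edges` list with a `direction` metadata column).
#' @export
plpc <- function(expr, alpha = 0.01, ord = 8L, workers = 1L) {
  skel <- plpc_skeleton(expr, alpha = alpha, ord = ord, workers = workers)
  plpc_finish(skel)
}

#' @rdname plpc
#' @param skel a `grn_skeleton`, e.g. from [skeleton_from_corr()].
#' @export
plpc_finish <- function(skel) {
  pdag <- apply_meek_rules(orient_v_structures(skel))
  edges <- pdag_edges(pdag)
  list(pdag = pdag, edges = edges)
}

#' Ranked edge list of a PDAG
#' @param pdag a `grn_pdag`.
#' @return undirected `grn_edges` list with `direction` metadata on the
#'   canonical (lexicographically ordered) pair.
#' @export
pdag_edges <- function(pdag) {
  idx <- which(pdag$adj & upper.tri(pdag$adj), arr.ind = TRUE)
  g <- pdag$genes
  if (nrow(idx) == 0L) {
    return(ranked_edges(character(), character(), numeric(),
                        directed = FALSE, method = "plpc",
                        extra = NULL))
  }
  dirmark <- vapply(seq_len(nrow(idx)), function(k) {
    i <- idx[k, 1L]; j <- idx[k, 2L]
    if (pdag$dir[i, j]) "->" else if (pdag$dir[j, i]) "<-" else "--"
  }, character(1))
  score <- 1 - pmin(pmax(pdag$pmax[idx], 0), 1)
  ranked_edges(g[idx[, 1L]], g[idx[, 2L]], score,
               directed = FALSE, method = "plpc",
               extra = data.frame(direction = dirmark,
                                  stringsAsFactors = FALSE))
}

#' Write a PDAG edge list with orientation marks
#'
#' Four-column TSV: regulator, target, score, mark in \{"--", "->",
#' "<-"\}.
#' @param edges the `edges` component returned by [plpc()].
#' @param path output path.
#' @export
write_pdag <- function(edges, path) {
  stopifnot("direction" %in% names(edges))
  write_edges(edges, path)
}
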