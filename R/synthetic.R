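#' Specification of a synthetic benchmark network
#'
#' Bundles the parameters of the known-truth generator. Defaults describe
#' a small but non-trivial benchmark: 50 genes of which 20 are
#' transcription factors, mean TF out-degree 2, regulatory weights of
#' magnitude 0.5-1.5 with random sign, observation noise SD 0.5, and 200
#' steady-state samples — a regime in which all implemented algorithms
#' beat random guessing comfortably without the problem being trivial.
#'
#' @param n_genes total genes.
#' @param n_tfs number of transcription factors (only TFs get out-edges);
#'   the TFs are the first `n_tfs` genes in topological order.
#' @param n_samples steady-state samples to draw.
#' @param topology `"erdos_renyi"` (each admissible TF->gene pair present
#'   independently) or `"scale_free_out"` (heavy-tailed TF out-degrees).
#' @param mean_out_degree expected out-degree per TF.
#' @param w_min,w_max range of |regulatory weight|; the sign is + or -
#'   with equal probability.
#' @param noise_sd SD of the additive Gaussian noise on each gene.
#' @param seed RNG seed.
#' @return list of class `grn_synth_spec`.
#' @export
synthetic_spec <- function(n_genes = 50L, n_tfs = 20L, n_samples = 200L,
                           topology = c("erdos_renyi", "scale_free_out"),
                           mean_out_degree = 2, w_min = 0.5, w_max = 1.5,
                           noise_sd = 0.5, seed = 1L) {
  topology <- match.arg(topology)
  stopifnot(n_tfs <= n_genes, n_tfs >= 1L, n_samples >= 3L,
            w_min <= w_max, w_min >= 0, noise_sd >= 0,
            mean_out_degree >= 0)
  structure(list(n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
                 n_samples = as.integer(n_samples), topology = topology,
                 mean_out_degree = mean_out_degree, w_min = w_min,
                 w_max = w_max, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "grn_synth_spec")
}

#' Generate a random weighted regulatory DAG
#'
#' Genes are placed in a fixed topological order (gene ids `G001`,
#' `G002`, ...; the first `n_tfs` are TFs) and edges run only from a TF to
#' a gene later in the order, so the graph is acyclic by construction and
#' only TFs have out-edges. Under `erdos_renyi` each admissible pair is an
#' edge independently with the probability matching `mean_out_degree`;
#' under `scale_free_out` per-TF out-degrees are drawn from a Zipf-like
#' tail (normalised to the same expected edge count) before targets are
#' chosen uniformly. The weight matrix of a DAG is nilpotent, so the
#' spectral radius is 0 and the linear system below is automatically
#' stable.
#'
#' @param spec a `grn_synth_spec`.
#' @return list of class `grn_dag`: `genes`, `tfs`, weight matrix `W`
#'   (`W[p, t]` = effect of parent p on target t; nonzero only for
#'   edges), `edges` data.frame.
#' @export
generate_dag <- function(spec) {
  set.seed(derive_seed(spec$seed, "dag"))
  p <- spec$n_genes
  genes <- sprintf("G%03d", seq_len(p))
  tfs <- genes[seq_len(spec$n_tfs)]
  W <- matrix(0, p, p, dimnames = list(genes, genes))
  # admissible (i, j): i a TF, j after i in topological order
  adm <- which(outer(seq_len(p) <= spec$n_tfs, rep(TRUE, p), `&`) &
                 upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  n_adm <- nrow(adm)
  n_expect <- spec$n_tfs * spec$mean_out_degree
  if (n_expect > 0 && n_adm > 0) {
    if (spec$topology == "erdos_renyi") {
      keep <- stats::runif(n_adm) < min(1, n_expect / n_adm)
      sel <- adm[keep, , drop = FALSE]
    } else {
      # heavy-tailed out-degrees: d_i proportional to a Zipf(1.6) draw,
      # rescaled to the expected total edge count
      raw <- (1 / stats::runif(spec$n_tfs))^(1 / 1.6)
      deg <- round(raw / sum(raw) * n_expect)
      sel_list <- lapply(seq_len(spec$n_tfs), function(i) {
        tgt_pool <- which(seq_len(p) > i)
        d <- min(deg[i], length(tgt_pool))
        if (d == 0L) return(NULL)
        cbind(i, sample(tgt_pool, d))
      })
      sel <- do.call(rbind, sel_list)
      if (is.null(sel)) sel <- matrix(integer(), 0L, 2L)
    }
    if (nrow(sel) > 0) {
      w <- stats::runif(nrow(sel), spec$w_min, spec$w_max) *
        sample(c(-1, 1), nrow(sel), replace = TRUE)
      W[sel] <- w
    }
  }
  idx <- which(W != 0, arr.ind = TRUE)
  edges <- data.frame(regulator = genes[idx[, 1L]],
                      target = genes[idx[, 2L]],
                      weight = W[idx], stringsAsFactors = FALSE)
  edges <- edges[order(edges$regulator, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(genes = genes, tfs = tfs, W = W, edges = edges),
            class = "grn_dag")
}

#' Simulate steady-state expression from a weighted DAG
#'
#' Independent samples by ancestral sampling of the linear-Gaussian
#' structural model \eqn{x_g = \sum_{p \in pa(g)} w_{pg} x_p +
#' \varepsilon_g}: root genes are standard normal, every other gene adds
#' Gaussian noise of SD `noise_sd` to the weighted sum of its parents.
#' Identical seeds give identical matrices.
#'
#' @param dag a `grn_dag`.
#' @param spec the `grn_synth_spec` used to build it (supplies
#'   `n_samples`, `noise_sd`, `seed`).
#' @return expression matrix (genes x samples).
#' @export
simulate_expression <- function(dag, spec) {
  set.seed(derive_seed(spec$seed, "expr"))
  p <- length(dag$genes)
  n <- spec$n_samples
  x <- matrix(0, p, n, dimnames = list(dag$genes,
                                       sprintf("S%03d", seq_len(n))))
  has_parent <- colSums(dag$W != 0) > 0
  for (g in seq_len(p)) {          # gene index = topological order
    if (!has_parent[g]) {
      x[g, ] <- stats::rnorm(n)
    } else {
      pa <- which(dag$W[, g] != 0)
      x[g, ] <- drop(dag$W[pa, g] %*% x[pa, , drop = FALSE]) +
        stats::rnorm(n, sd = spec$noise_sd)
    }
  }
  x
}

#' Closed-form covariance of the linear-Gaussian structural model
#'
#' \eqn{\Sigma = (I - W)^{-T} D (I - W)^{-1}} where D holds the per-gene
#' noise variances (1 for roots, `noise_sd`^2 otherwise). Useful as an
#' exact oracle and for infinite-sample analyses.
#'
#' @inheritParams simulate_expression
#' @return genes x genes covariance matrix.
#' @export
sem_covariance <- function(dag, spec) {
  p <- length(dag$genes)
  has_parent <- colSums(dag$W != 0) > 0
  D <- diag(ifelse(has_parent, spec$noise_sd^2, 1), p)
  A <- solve(diag(p) - t(dag$W))   # x = A' eps in topological order
  S <- A %*% D %*% t(A)
  dimnames(S) <- list(dag$genes, dag$genes)
  S
}

#' Export the gold standard of a known DAG
#'
#' All true edges are labelled 1; negatives are drawn uniformly (without
#' replacement) from the admissible TF->gene non-edges, mirroring the
#' convention that only regulator-outgoing pairs are evaluable.
#'
#' @param dag a `grn_dag`.
#' @param n_negatives `"all"` (default) for the complete TF x target
#'   labelling, or an integer count of sampled negatives.
#' @param seed RNG seed for negative sampling.
#' @return a directed `grn_gold`.
#' @export
export_gold <- function(dag, n_negatives = "all", seed = 1L) {
  pos <- dag$edges[, c("regulator", "target")]
  p <- length(dag$genes)
  ntf <- length(dag$tfs)
  adm <- expand.grid(regulator = dag$tfs, target = dag$genes,
                     stringsAsFactors = FALSE)
  adm <- adm[adm$regulator != adm$target, , drop = FALSE]
  posk <- paste(pos$regulator, pos$target, sep = "\r")
  negs <- adm[!(paste(adm$regulator, adm$target, sep = "\r") %in% posk), ,
              drop = FALSE]
  if (!identical(n_negatives, "all")) {
    n_negatives <- as.integer(n_negatives)
    set.seed(derive_seed(seed, "gold_neg"))
    negs <- negs[sample.int(nrow(negs), min(n_negatives, nrow(negs))), ,
                 drop = FALSE]
  }
  gold_standard(c(pos$regulator, negs$regulator),
                c(pos$target, negs$target),
                c(rep(1L, nrow(pos)), rep(0L, nrow(negs))),
                directed = TRUE)
}

#' Generate a complete synthetic benchmark dataset
#'
#' Convenience wrapper: DAG + expression + TF list + gold standard.
#'
#' @param spec a `grn_synth_spec` (or arguments forwarded to
#'   [synthetic_spec()]).
#' @param ... forwarded to [synthetic_spec()] when `spec` is missing.
#' @return list of class `grn_synth`: `spec`, `dag`, `expr`, `tfs`,
#'   `gold`.
#' @export
synthetic_dataset <- function(spec = NULL, ...) {
  if (is.null(spec)) spec <- synthetic_spec(...)
  stopifnot(inherits(spec, "grn_synth_spec"))
  dag <- generate_dag(spec)
  expr <- simulate_expression(dag, spec)
  gold <- export_gold(dag, n_negatives = "all")
  structure(list(spec = spec, dag = dag, expr = expr, tfs = dag$tfs,
                 gold = gold), class = "grn_synth")
}
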