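# Independent oracles and small fixture builders used across test files.
# These deliberately re-derive quantities by different routes than the
# package implementation.

# Recursive-formula partial correlation:
# pcor(i,j | S) = (pcor(i,j|S\k) - pcor(i,k|S\k) pcor(j,k|S\k)) /
#                 sqrt((1-pcor(i,k|S\k)^2)(1-pcor(j,k|S\k)^2))
pcor_recursive <- function(corr, i, j, S) {
  if (length(S) == 0L) return(corr[i, j])
  k <- S[[1L]]
  rest <- S[-1L]
  rij <- pcor_recursive(corr, i, j, rest)
  rik <- pcor_recursive(corr, i, k, rest)
  rjk <- pcor_recursive(corr, j, k, rest)
  (rij - rik * rjk) / sqrt((1 - rik^2) * (1 - rjk^2))
}

# Exhaustive-threshold AUPR/AUROC for a prediction that ranks EVERY gold
# pair (no random-remainder completion needed). labels_ranked: 0/1 vector
# in rank order. Trapezoidal areas; PR curve starts at (0, precision of
# the first prediction) — same curve conventions, independent arithmetic.
auc_exhaustive <- function(labels_ranked) {
  P <- sum(labels_ranked == 1)
  N <- sum(labels_ranked == 0)
  L <- length(labels_ranked)
  tpr <- fpr <- prec <- rec <- numeric(L)
  for (k in seq_len(L)) {          # threshold after rank k
    tp <- sum(labels_ranked[1:k] == 1)
    fp <- k - tp
    tpr[k] <- tp / P; fpr[k] <- fp / N
    prec[k] <- tp / k; rec[k] <- tp / P
  }
  trap <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
  list(auroc = trap(c(0, fpr), c(0, tpr)),
       aupr = trap(c(0, rec), c(prec[1], prec)))
}

# Brute-force CPDAG of a DAG by enumerating its Markov equivalence class:
# all acyclic orientations of the skeleton sharing the DAG's v-structure
# set; an edge is directed in the CPDAG iff oriented identically in every
# member. amat: p x p logical, amat[i,j] = TRUE means i -> j.
v_structures_of <- function(amat) {
  p <- nrow(amat)
  adj <- amat | t(amat)
  out <- character(0)
  for (k in seq_len(p)) {
    pa <- which(amat[, k])
    if (length(pa) < 2L) next
    for (a in seq_along(pa)) for (b in seq_along(pa)) {
      if (b <= a) next
      if (!adj[pa[a], pa[b]]) {
        out <- c(out, paste(sort(c(pa[a], pa[b]))[1],
                            sort(c(pa[a], pa[b]))[2], k))
      }
    }
  }
  sort(out)
}

is_acyclic <- function(amat) {
  p <- nrow(amat)
  m <- amat
  for (i in seq_len(p)) m <- (m %*% amat) > 0 | m
  !any(diag(m))
}

cpdag_enumerate <- function(amat) {
  p <- nrow(amat)
  skel <- which(amat | t(amat), arr.ind = TRUE)
  skel <- skel[skel[, 1] < skel[, 2], , drop = FALSE]
  ne <- nrow(skel)
  target_v <- v_structures_of(amat)
  dir_all <- NULL
  for (mask in 0:(2^ne - 1)) {
    cand <- matrix(FALSE, p, p)
    for (e in seq_len(ne)) {
      if (bitwAnd(mask, bitwShiftL(1L, e - 1L)) > 0L) {
        cand[skel[e, 2], skel[e, 1]] <- TRUE
      } else {
        cand[skel[e, 1], skel[e, 2]] <- TRUE
      }
    }
    if (!is_acyclic(cand)) next
    if (!identical(v_structures_of(cand), target_v)) next
    dir_all <- if (is.null(dir_all)) list(cand) else c(dir_all, list(cand))
  }
  # compelled edge i->j iff directed i->j in every equivalent DAG
  comp <- Reduce(`&`, dir_all)
  list(skeleton = amat | t(amat), compelled = comp,
       n_members = length(dir_all))
}

# Sample from a small linear-Gaussian SEM given a weighted adjacency
# matrix in topological order (W[i,j] = effect of i on j).
sample_sem <- function(W, n, noise_sd = 1, seed = 1) {
  set.seed(seed)
  p <- nrow(W)
  x <- matrix(0, p, n)
  for (g in seq_len(p)) {
    pa <- which(W[, g] != 0)
    x[g, ] <- if (length(pa)) {
      drop(t(W[pa, g]) %*% x[pa, , drop = FALSE]) + rnorm(n, sd = noise_sd)
    } else rnorm(n)
  }
  rownames(x) <- sprintf("V%02d", seq_len(p))
  x
}

# Random 6-node DAG over a fixed topological order with given edge prob.
random_dag_amat <- function(p, prob, seed) {
  set.seed(seed)
  amat <- matrix(FALSE, p, p)
  for (i in 1:(p - 1)) for (j in (i + 1):p) {
    if (runif(1) < prob) amat[i, j] <- TRUE
  }
  amat
}

# Correlation matrix of a linear-Gaussian SEM, computed from first
# principles (independent of grnkit::sem_covariance).
sem_corr <- function(W, noise_sd = 1) {
  p <- nrow(W)
  roots <- colSums(W != 0) == 0
  D <- diag(ifelse(roots, 1, noise_sd^2), p)
  A <- solve(diag(p) - t(W))
  S <- A %*% D %*% t(A)
  cov2cor(S)
}

# Tiny expression fixture written to a temp TSV.
write_expr_fixture <- function(mat, path = tempfile(fileext = ".tsv")) {
  df <- data.frame(gene_id = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
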