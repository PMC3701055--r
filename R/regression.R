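#' GENIE3-style tree-ensemble network inference
#'
#' Each gene in turn is treated as a regression target and predicted from
#' the expression of the candidate regulators (the TF list, minus the
#' target itself) with a random forest; a regulator's score is its total
#' variance-reduction importance, normalised per target so the
#' importances of every target sum to one before pooling into the global
#' ranking (this keeps high-variance targets from dominating).
#'
#' The decomposition is per target gene, and each target's forest is grown
#' from a seed derived deterministically from `(seed, target id)`, so the
#' output is byte-identical for any `workers` count.
#'
#' @param expr expression matrix (genes x samples).
#' @param tfs character vector of candidate regulator IDs (subset of the
#'   matrix genes; see [match_tfs()]).
#' @param n_trees trees per target ensemble (default 1000).
#' @param candidate_fraction `"sqrt"` (default; mtry = sqrt(#regulators))
#'   or `"all"`.
#' @param seed integer base seed.
#' @param workers parallel workers; never affects results.
#' @return directed `grn_edges` list (TF -> target).
#' @export
genie3 <- function(expr, tfs, n_trees = 1000L,
                   candidate_fraction = c("sqrt", "all"),
                   seed = 1L, workers = 1L) {
  candidate_fraction <- match.arg(candidate_fraction)
  tfs <- match_tfs(tfs, expr)
  targets <- rownames(expr)
  xt <- t(expr)                    # samples x genes

  per_target <- function(tg) {
    preds <- setdiff(tfs, tg)
    if (length(preds) == 0L) return(NULL)
    y <- xt[, tg]
    if (stats::var(y) == 0) {
      return(data.frame(regulator = preds, target = tg,
                        score = 0, stringsAsFactors = FALSE))
    }
    mtry <- if (candidate_fraction == "sqrt")
      max(1L, floor(sqrt(length(preds)))) else length(preds)
    dat <- data.frame(xt[, preds, drop = FALSE], check.names = FALSE)
    fit <- ranger::ranger(
      x = dat, y = y, num.trees = n_trees, mtry = mtry,
      importance = "impurity", num.threads = 1L,
      seed = derive_seed(seed, tg))
    imp <- fit$variable.importance
    imp[!is.finite(imp) | imp < 0] <- 0
    tot <- sum(imp)
    if (tot > 0) imp <- imp / tot
    data.frame(regulator = names(imp), target = tg, score = unname(imp),
               stringsAsFactors = FALSE)
  }

  res <- apply_parallel(targets, per_target, workers)
  df <- do.call(rbind, res)
  ranked_edges(df$regulator, df$target, df$score,
               directed = TRUE, method = "genie3")
}

# Least-angle regression: returns the indices of the first `steps`
# variables to enter the active set, in entry order. X is assumed centred
# (columns) and y centred; columns are NOT rescaled here, so differential
# column scaling acts as a soft preference — exactly the hook stability
# selection's randomisation uses.
lars_entry_order <- function(X, y, steps) {
  p <- ncol(X)
  steps <- min(steps, p)
  mu <- rep(0, nrow(X))
  active <- integer(0)
  for (st in seq_len(steps)) {
    cvec <- drop(crossprod(X, y - mu))
    inactive <- setdiff(seq_len(p), active)
    if (length(inactive) == 0L) break
    j <- inactive[which.max(abs(cvec[inactive]))]
    if (abs(cvec[j]) < 1e-12) break   # nothing left correlated
    active <- c(active, j)
    s <- sign(cvec[active])
    s[s == 0] <- 1
    XA <- X[, active, drop = FALSE] * rep(s, each = nrow(X))
    G <- crossprod(XA)
    Gi1 <- tryCatch(solve(G, rep(1, length(active))),
                    error = function(e) NULL)
    if (is.null(Gi1) || any(!is.finite(Gi1)) || sum(Gi1) <= 0) break
    A <- 1 / sqrt(sum(Gi1))
    u <- drop(XA %*% (A * Gi1))      # equiangular direction
    C <- abs(cvec[j])
    inactive <- setdiff(seq_len(p), active)
    if (length(inactive) == 0L) break
    a <- drop(crossprod(X[, inactive, drop = FALSE], u))
    cand <- c((C - cvec[inactive]) / (A - a),
              (C + cvec[inactive]) / (A + a))
    cand <- cand[is.finite(cand) & cand > 1e-12]
    gamma <- if (length(cand)) min(cand) else C / A
    mu <- mu + gamma * u
  }
  active
}

#' TIGRESS-style stability-selection network inference
#'
#' For each target gene, the candidate regulators are repeatedly
#' reweighted and the data resampled: in each of `n_resamples` runs, a
#' random half of the samples is drawn without replacement, each
#' regulator's (unit-normalised) column is multiplied by an independent
#' weight uniform on \[`alpha`, 1\], and least-angle regression is run for
#' `lars_steps` steps. A regulator's score is either its selection
#' frequency within `lars_steps` steps (`scoring = "frequency"`) or the
#' area under its selection-frequency curve over steps 1..L
#' (`scoring = "area"`, the default — less sensitive to the choice of L).
#'
#' Per-(target, resample) seeds are derived from `(seed, target id)`, so
#' output does not depend on `workers`.
#'
#' @inheritParams genie3
#' @param n_resamples number of resampling runs per target (default 1000;
#'   around 100 is adequate for small benchmark problems).
#' @param lars_steps number of LARS steps L (default 5); clipped with a
#'   warning if >= the number of candidate regulators.
#' @param alpha randomisation strength in (0, 1\]: regulator weights are
#'   drawn uniformly from \[alpha, 1\]. `alpha = 1` disables reweighting.
#' @param scoring `"area"` (default) or `"frequency"`.
#' @return directed `grn_edges` list (TF -> target).
#' @export
tigress <- function(expr, tfs, n_resamples = 1000L, lars_steps = 5L,
                    alpha = 0.2, scoring = c("area", "frequency"),
                    seed = 1L, workers = 1L) {
  scoring <- match.arg(scoring)
  stopifnot(alpha > 0, alpha <= 1, n_resamples >= 1L, lars_steps >= 1L)
  tfs <- match_tfs(tfs, expr)
  targets <- rownames(expr)
  xt <- t(expr)
  n <- nrow(xt)
  half <- floor(n / 2)
  if (lars_steps >= length(tfs)) {
    warning("lars_steps >= number of candidate regulators; clipped")
  }

  per_target <- function(tg) {
    preds <- setdiff(tfs, tg)
    np <- length(preds)
    if (np == 0L) return(NULL)
    L <- min(lars_steps, np)
    X0 <- xt[, preds, drop = FALSE]
    y0 <- xt[, tg]
    # selection-frequency curve: sel[l, j] = #resamples where regulator j
    # entered within the first l steps
    sel <- matrix(0, L, np)
    set.seed(derive_seed(seed, tg))
    for (r in seq_len(n_resamples)) {
      idx <- sample.int(n, half)
      w <- stats::runif(np, alpha, 1)
      X <- scale(X0[idx, , drop = FALSE])
      X[!is.finite(X)] <- 0
      X <- X * rep(w, each = half)
      y <- y0[idx] - mean(y0[idx])
      if (stats::var(y) == 0) next
      ord <- lars_entry_order(X, y, L)
      for (l in seq_along(ord)) {
        sel[l:L, ord[l]] <- sel[l:L, ord[l]] + 1
      }
    }
    freq <- sel / n_resamples
    score <- if (scoring == "frequency") freq[L, ] else colMeans(freq)
    data.frame(regulator = preds, target = tg, score = score,
               stringsAsFactors = FALSE)
  }

  res <- apply_parallel(targets, per_target, workers)
  df <- do.call(rbind, res)
  ranked_edges(df$regulator, df$target, df$score,
               directed = TRUE, method = "tigress")
}
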