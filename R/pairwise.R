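#' Pearson correlation matrix over genes
#'
#' Genes with zero variance get correlation 0 to every partner (and 1 on
#' the diagonal); their count is recorded in the `"n_zero_var"` attribute.
#'
#' @param expr expression matrix (genes x samples).
#' @return symmetric genes x genes correlation matrix with unit diagonal.
#' @export
pearson_matrix <- function(expr) {
  v <- apply(expr, 1L, stats::var)
  zero <- !is.finite(v) | v == 0
  cc <- suppressWarnings(stats::cor(t(expr)))
  cc[zero, ] <- 0
  cc[, zero] <- 0
  diag(cc) <- 1
  attr(cc, "n_zero_var") <- sum(zero)
  cc
}

#' Relevance (co-expression) network
#'
#' Thresholds the pairwise Pearson correlation matrix: a pair is kept when
#' r >= `pos_threshold` or r <= `neg_threshold`. The edge score is |r|;
#' the sign is retained in a `sign` metadata column. With
#' `emit_all = TRUE` every pair is emitted scored by |r| regardless of the
#' thresholds — the form consumed by rank aggregation and AUC evaluation,
#' where truncation happens downstream.
#'
#' @param expr expression matrix.
#' @param pos_threshold,neg_threshold correlation cut-offs in \[-1, 1\];
#'   `neg_threshold <= pos_threshold` required. The default (0.9, -1)
#'   keeps strong positive co-expression only: r = -1 is the only value
#'   passing a negative threshold of -1.
#' @param emit_all emit all pairs, ignoring the thresholds?
#' @return undirected `grn_edges` list.
#' @export
relevance_network <- function(expr, pos_threshold = 0.9,
                              neg_threshold = -1, emit_all = FALSE) {
  stopifnot(pos_threshold >= -1, pos_threshold <= 1,
            neg_threshold >= -1, neg_threshold <= 1)
  if (neg_threshold > pos_threshold) {
    stop("neg_threshold must be <= pos_threshold")
  }
  cc <- pearson_matrix(expr)
  ut <- which(upper.tri(cc), arr.ind = TRUE)
  r <- cc[ut]
  keep <- if (emit_all) rep(TRUE, length(r))
          else (r >= pos_threshold | r <= neg_threshold)
  if (!any(keep)) warning("all gene pairs filtered out")
  g <- rownames(cc)
  ranked_edges(g[ut[keep, 1L]], g[ut[keep, 2L]], abs(r[keep]),
               directed = FALSE, method = "rn",
               extra = data.frame(sign = sign(r[keep])))
}

# Schafer-Strimmer analytic shrinkage of the correlation matrix toward the
# identity: lambda* = sum Var(r_ij) / sum r_ij^2 over off-diagonal entries,
# clipped to [0, 1]. Var(r_ij) is the unbiased estimate from the products
# of standardized observations.
shrunk_correlation <- function(expr) {
  n <- ncol(expr)
  x <- t(scale(t(expr)))          # genes x samples, rows standardized
  x[!is.finite(x)] <- 0           # zero-variance genes
  r <- tcrossprod(x) / (n - 1)
  diag(r) <- 1
  # Var(r_ij): w_kij = x_ik x_jk; var = n/(n-1)^3 * sum_k (w_kij - mean_w)^2
  sw <- tcrossprod(x)             # sum_k w_kij = (n-1) r_ij
  sw2 <- tcrossprod(x^2)          # sum_k w_kij^2
  varr <- n / (n - 1)^3 * (sw2 - sw^2 / n)
  off <- upper.tri(r)
  denom <- sum(r[off]^2)
  lambda <- if (denom > 0) sum(varr[off]) / denom else 1
  lambda <- min(1, max(0, lambda))
  rs <- (1 - lambda) * r
  diag(rs) <- 1
  attr(rs, "lambda") <- lambda
  rs
}

#' Graphical Gaussian model network via shrinkage partial correlation
#'
#' Estimates the gene-gene correlation matrix with an analytically chosen
#' shrinkage intensity toward the identity (the closed-form intensity that
#' minimises expected squared loss), inverts it, and converts the inverse
#' to partial correlations. All pairs are emitted ranked by |partial
#' correlation|, with the signed value kept as metadata. Shrinkage keeps
#' the estimate positive definite even when genes outnumber samples.
#'
#' @param expr expression matrix (>= 2 genes).
#' @return undirected `grn_edges` list with attribute `lambda` (the
#'   shrinkage intensity used).
#' @export
ggm_network <- function(expr) {
  stopifnot(nrow(expr) >= 2L)
  rs <- shrunk_correlation(expr)
  om <- solve(rs)
  d <- sqrt(diag(om))
  pc <- -om / tcrossprod(d)
  diag(pc) <- 1
  ut <- which(upper.tri(pc), arr.ind = TRUE)
  g <- rownames(expr)
  el <- ranked_edges(g[ut[, 1L]], g[ut[, 2L]], abs(pc[ut]),
                     directed = FALSE, method = "ggm",
                     extra = data.frame(sign = sign(pc[ut])))
  attr(el, "lambda") <- attr(rs, "lambda")
  el
}

# B-spline basis weights for one gene: n x bins matrix, rows sum to 1.
# Values are affinely mapped to [0, 1]; a constant gene maps to 0.5.
bspline_weights <- function(x, bins, spline_order) {
  rng <- range(x)
  z <- if (rng[2] > rng[1]) (x - rng[1]) / (rng[2] - rng[1])
       else rep(0.5, length(x))
  k <- spline_order
  n_inner <- bins - k
  knots <- c(rep(0, k), if (n_inner > 0) seq_len(n_inner) / (n_inner + 1),
             rep(1, k))
  w <- splines::splineDesign(knots, z, ord = k, outer.ok = FALSE)
  w
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Mutual information matrix between genes
#'
#' Two estimators are offered. The default B-spline estimator generalises
#' histogram binning by spreading each observation over adjacent bins with
#' B-spline basis weights, which reduces the discretisation sensitivity of
#' plain binning. The `gaussian` estimator uses the closed form
#' \eqn{-\frac{1}{2}\log(1 - r^2)} on the Pearson correlation — exact for
#' bivariate normal data and much faster.
#'
#' @param expr expression matrix.
#' @param estimator `"bspline"` (default) or `"gaussian"`.
#' @param bins number of bins (default 10); must satisfy
#'   `bins >= spline_order >= 1`.
#' @param spline_order B-spline order (default 3; order 1 is a plain
#'   histogram).
#' @return symmetric nonnegative genes x genes matrix of MI in nats.
#' @export
mutual_information_matrix <- function(expr,
                                      estimator = c("bspline", "gaussian"),
                                      bins = 10L, spline_order = 3L) {
  estimator <- match.arg(estimator)
  p <- nrow(expr)
  g <- rownames(expr)
  if (estimator == "gaussian") {
    r <- pearson_matrix(expr)
    r2 <- pmin(r^2, 1 - 1e-12)
    mi <- -0.5 * log(1 - r2)
    diag(mi) <- -0.5 * log(1e-12)   # self-MI: finite stand-in for infinity
    dimnames(mi) <- list(g, g)
    return(mi)
  }
  stopifnot(bins >= spline_order, spline_order >= 1L)
  n <- ncol(expr)
  w <- lapply(seq_len(p), function(i)
    bspline_weights(expr[i, ], bins, spline_order))
  hx <- vapply(w, function(wi) entropy_nats(colMeans(wi)), numeric(1))
  mi <- matrix(0, p, p, dimnames = list(g, g))
  for (i in seq_len(p)) {
    for (j in i:p) {
      joint <- crossprod(w[[i]], w[[j]]) / n
      mi[i, j] <- mi[j, i] <- hx[i] + hx[j] - entropy_nats(as.vector(joint))
    }
  }
  pmax(mi, 0)
}

#' CLR (context likelihood of relatedness) network
#'
#' Corrects raw mutual information for each gene's background MI
#' distribution: for gene i, \eqn{z_i(j) = \max(0, (MI_{ij} - \mu_i)/\sigma_i)}
#' where \eqn{\mu_i, \sigma_i} are the mean and standard deviation of row i
#' of the MI matrix excluding the diagonal. The edge score combines both
#' contexts as \eqn{\sqrt{z_i(j)^2 + z_j(i)^2}}. A gene whose background
#' has zero spread contributes z = 0 for all its pairs.
#'
#' @inheritParams mutual_information_matrix
#' @return undirected `grn_edges` list over all gene pairs.
#' @export
clr_network <- function(expr, estimator = c("bspline", "gaussian"),
                        bins = 10L, spline_order = 3L) {
  mi <- mutual_information_matrix(expr, estimator = match.arg(estimator),
                                  bins = bins, spline_order = spline_order)
  clr_from_mi(mi)
}

#' CLR scores from a precomputed MI matrix
#' @param mi symmetric MI matrix with gene dimnames.
#' @return undirected `grn_edges` list.
#' @export
clr_from_mi <- function(mi) {
  p <- nrow(mi)
  z <- matrix(0, p, p)
  for (i in seq_len(p)) {
    bg <- mi[i, -i]
    mu <- mean(bg)
    s <- stats::sd(bg)
    z[i, ] <- if (is.finite(s) && s > 0) pmax(0, (mi[i, ] - mu) / s) else 0
  }
  sc <- sqrt(z^2 + t(z)^2)
  ut <- which(upper.tri(sc), arr.ind = TRUE)
  g <- rownames(mi)
  ranked_edges(g[ut[, 1L]], g[ut[, 2L]], sc[ut],
               directed = FALSE, method = "clr")
}
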