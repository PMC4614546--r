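#' Rank products statistic for cancer-vs-normal differential expression
#'
#' For every one of the K = n_cancer x n_normal pairwise cancer-vs-normal
#' comparisons, genes are ranked by log2 fold change (rank 1 = most
#' up-regulated for the up statistic, most down-regulated for the down
#' statistic; ties get average ranks). The rank product of a gene is the
#' geometric mean of its K ranks, so a gene ranked first in every comparison
#' attains the minimum RP of 1.
#'
#' @param x An \code{\link{expr_set}} or a log2 expression matrix.
#' @param group Group labels ("cancer"/"normal"); taken from the
#'   \code{expr_set} when omitted.
#' @return data.frame with columns gene_id, rp_up, rp_down; attributes
#'   \code{log_up}/\code{log_down} (mean log rank, the scale used internally)
#'   and \code{K}.
#' @export
rank_product_statistic <- function(x, group = NULL) {
  X <- as_expr_matrix(x)
  if (is.null(group) && inherits(x, "expr_set")) group <- x$group
  group <- as.character(group)
  ic <- which(group == "cancer"); io <- which(group == "normal")
  if (length(ic) < 1 || length(io) < 1)
    stop("insufficient replicates: need samples in both groups")
  G <- nrow(X)
  K <- length(ic) * length(io)
  # G x K matrix of log2 fold changes, one column per (cancer, normal) pair
  D <- X[, rep(ic, each = length(io)), drop = FALSE] -
    X[, rep(io, times = length(ic)), drop = FALSE]
  log_up <- rowMeans(log(apply(-D, 2, rank, ties.method = "average")))
  log_down <- rowMeans(log(apply(D, 2, rank, ties.method = "average")))
  out <- data.frame(gene_id = rownames(X),
                    rp_up = exp(log_up), rp_down = exp(log_down),
                    stringsAsFactors = FALSE)
  attr(out, "log_up") <- log_up
  attr(out, "log_down") <- log_down
  attr(out, "K") <- K
  out
}

# Null mean-log-ranks under the within-comparison rank-permutation null
# (independent uniform rank permutations in each comparison). Each gene's
# rank in a uniform random permutation is marginally uniform on 1..G, and the
# expected false-positive count is a sum of per-gene marginal probabilities,
# so E[#null <= t] = G * P(mean_k log U_k <= t) with U_k i.i.d. uniform on
# {1..G}; i.i.d. marginal sampling estimates the permutation expectation
# without bias at much lower cost. Returns sorted null values.
rp_null_rank <- function(G, K, n_null) {
  lg <- log(seq_len(G))
  s <- numeric(n_null)
  for (k in seq_len(K))
    s <- s + lg[sample.int(G, n_null, replace = TRUE)]
  sort(s / K)
}

# Exact rank-permutation null: all G^K rank tuples (marginal enumeration).
rp_null_rank_exact <- function(G, K) {
  lg <- log(seq_len(G))
  s <- lg
  if (K > 1) for (k in seq_len(K - 1)) s <- as.vector(outer(s, lg, "+"))
  sort(s / K)
}

# All permutations of 1..n as an n! x n integer matrix.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

# Residual-permutation injection null. Each injected null gene takes one
# observed gene's within-group-centered residuals, permutes them across the
# sample positions, and is ranked against the *observed* fold-change
# landscape of every comparison (its rank in comparison k is its position
# among the G observed fold changes, i.e. 1 + #{observed d <= d_null}).
# Centering removes the signal from the null; reusing one residual
# permutation across all K comparisons keeps their shared-sample correlation;
# and ranking against the observed landscape preserves the rank compression
# that many true DEGs impose on null genes. Returns sorted null mean log
# ranks (down and up) and the number of null copies per gene.
rp_null_residual <- function(X, ic, io, B, exact = FALSE) {
  G <- nrow(X); n <- ncol(X)
  R <- X
  R[, ic] <- X[, ic, drop = FALSE] - rowMeans(X[, ic, drop = FALSE])
  R[, io] <- X[, io, drop = FALSE] - rowMeans(X[, io, drop = FALSE])
  a <- rep(ic, each = length(io)); b <- rep(io, times = length(ic))
  K <- length(a)
  Dsort <- Msort <- vector("list", K)
  for (k in seq_len(K)) {
    d <- X[, a[k]] - X[, b[k]]
    Dsort[[k]] <- sort(d)
    Msort[[k]] <- sort(-d)
  }
  if (exact) {
    if (n > 7) stop("exact residual enumeration infeasible for n > 7 samples")
    perms <- all_permutations(n)
    np <- nrow(perms)
    P <- t(perms)[, rep(seq_len(np), times = G), drop = FALSE]
    src <- rep(seq_len(G), each = np)
    per_gene <- np
  } else {
    n_null <- G * B
    # one random permutation of sample positions per injected gene, drawn
    # jointly: order by (row, uniform key) yields a permutation per row
    lin <- order(rep(seq_len(n_null), times = n), stats::runif(n_null * n))
    P <- matrix((lin - 1L) %/% n_null + 1L, n, n_null)
    src <- rep(seq_len(G), B)
    per_gene <- B
  }
  n_null <- length(src)
  RT <- matrix(R[cbind(rep(src, each = n), as.vector(P))], n, n_null)
  Sd <- Su <- numeric(n_null)
  for (k in seq_len(K)) {
    d <- RT[a[k], ] - RT[b[k], ]
    Sd <- Sd + log(findInterval(d, Dsort[[k]]) + 1)
    Su <- Su + log(findInterval(-d, Msort[[k]]) + 1)
  }
  list(down = sort(Sd / K), up = sort(Su / K), per_gene = per_gene)
}

#' Permutation-based pfp (FDR) for rank products
#'
#' Estimates, for each gene and direction, the expected number of null genes
#' with a rank product at least as extreme, divided by the gene's rank in the
#' observed list: the percentage of false prediction (pfp). Values are
#' clipped to \[0, 1\] and monotonized step-up (non-decreasing in observed RP
#' rank).
#'
#' Two permutation nulls are available. \code{null = "residual"} (default)
#' injects null genes built from permuted within-group-centered residuals
#' into the observed fold-change landscape; it preserves both the correlation
#' among the K = n1 x n2 pairwise comparisons (which share samples) and the
#' rank compression that abundant true DEGs impose on null genes, and is
#' therefore approximately calibrated for unpaired two-class data.
#' \code{null = "rank"} draws independent uniform rank permutations within
#' each comparison — the textbook rank-products null for independent
#' replicate experiments; with pairwise-comparison layouts it ignores the
#' shared-sample correlation and is markedly anti-conservative, so it is kept
#' for replication of that convention and for exact small-instance
#' verification, not as the default.
#'
#' @inheritParams rank_product_statistic
#' @param n_permutations Number of permutations (null copies per gene).
#' @param seed Integer seed for the permutation null.
#' @param null Null scheme: \code{"residual"} (residual-permutation
#'   injection) or \code{"rank"} (within-comparison rank permutation).
#' @param exact Enumerate the null exhaustively instead of sampling: all n!
#'   residual permutations per gene for \code{null = "residual"} (feasible
#'   for n <= 7 samples), all G^K rank tuples for \code{null = "rank"}
#'   (feasible for G^K <= 2e6).
#' @return data.frame gene_id, rp_up, rp_down, pfp_up, pfp_down.
#' @export
estimate_pfp <- function(x, group = NULL, n_permutations = 100, seed = NULL,
                         null = c("residual", "rank"), exact = FALSE) {
  null <- match.arg(null)
  if (n_permutations < 1) stop("`n_permutations` must be at least 1")
  rp <- rank_product_statistic(x, group)
  G <- nrow(rp)
  K <- attr(rp, "K")
  if (!is.null(seed)) set.seed(seed)
  if (null == "rank") {
    if (exact) {
      if (G^K > 2e6) stop("exact null enumeration infeasible for G^K > 2e6")
      ns <- rp_null_rank_exact(G, K)
      per_gene <- length(ns) / G
    } else {
      ns <- rp_null_rank(G, K, G * n_permutations)
      per_gene <- n_permutations
    }
    null_up <- null_down <- ns
  } else {
    X <- as_expr_matrix(x)
    if (is.null(group) && inherits(x, "expr_set")) group <- x$group
    group <- as.character(group)
    ic <- which(group == "cancer"); io <- which(group == "normal")
    nl <- rp_null_residual(X, ic, io, n_permutations, exact = exact)
    null_up <- nl$up; null_down <- nl$down
    per_gene <- nl$per_gene
  }
  pfp_one <- function(s_obs, null_sorted) {
    efp <- findInterval(s_obs + 1e-12, null_sorted) / per_gene
    r <- rank(s_obs, ties.method = "max")
    pfp <- pmin(efp / r, 1)
    # step-up monotonization: non-decreasing in observed RP rank
    ord <- order(s_obs)
    pfp[ord] <- rev(cummin(rev(pfp[ord])))
    pfp
  }
  rp$pfp_up <- pfp_one(attr(rp, "log_up"), null_up)
  rp$pfp_down <- pfp_one(attr(rp, "log_down"), null_down)
  rp
}

#' Call differentially expressed genes at a pfp threshold
#'
#' Takes the union of the up- and down-regulated gene lists passing the
#' threshold; a gene significant in both directions is contradictory and is
#' dropped with a warning.
#'
#' @param pfp A data.frame from \code{\link{estimate_pfp}}.
#' @param fdr_threshold pfp (FDR) cutoff in (0, 1\]; 1 returns every gene (in
#'   its better direction).
#' @param origin Label recording which dataset the list came from.
#' @return A DEG list: data.frame gene_id, direction ("up"/"down"),
#'   rank_product, pfp, origin.
#' @export
call_degs <- function(pfp, fdr_threshold = 0.10, origin = NA_character_) {
  if (fdr_threshold <= 0 || fdr_threshold > 1)
    stop("`fdr_threshold` must be in (0, 1]")
  sig_up <- if (fdr_threshold >= 1) rep(TRUE, nrow(pfp)) else pfp$pfp_up < fdr_threshold
  sig_down <- if (fdr_threshold >= 1) pfp$rp_down < pfp$rp_up else pfp$pfp_down < fdr_threshold
  if (fdr_threshold >= 1) sig_up <- !sig_down
  both <- sig_up & sig_down
  if (any(both)) {
    warning(sum(both), " gene(s) significant in both directions dropped: ",
            paste(utils::head(pfp$gene_id[both], 5), collapse = ", "))
    sig_up[both] <- sig_down[both] <- FALSE
  }
  out <- rbind(
    data.frame(gene_id = pfp$gene_id[sig_up],
               direction = rep("up", sum(sig_up)),
               rank_product = pfp$rp_up[sig_up], pfp = pfp$pfp_up[sig_up],
               stringsAsFactors = FALSE),
    data.frame(gene_id = pfp$gene_id[sig_down],
               direction = rep("down", sum(sig_down)),
               rank_product = pfp$rp_down[sig_down], pfp = pfp$pfp_down[sig_down],
               stringsAsFactors = FALSE))
  out$origin <- rep(origin, nrow(out))
  out[order(out$pfp, out$rank_product), , drop = FALSE]
}

#' Differential expression by rank products, end to end
#'
#' Convenience wrapper: rank products, permutation pfp, DEG call.
#'
#' @inheritParams estimate_pfp
#' @inheritParams call_degs
#' @export
deg_analysis <- function(x, group = NULL, fdr_threshold = 0.10,
                         n_permutations = 100, seed = NULL,
                         origin = NA_character_) {
  if (is.null(group) && inherits(x, "expr_set")) group <- x$group
  if (sum(group == "cancer") < 2 || sum(group == "normal") < 2)
    stop("insufficient replicates: need at least 2 samples per group")
  pfp <- estimate_pfp(x, group, n_permutations = n_permutations, seed = seed)
  call_degs(pfp, fdr_threshold = fdr_threshold, origin = origin)
}
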