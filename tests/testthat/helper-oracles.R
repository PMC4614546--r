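# Independent brute-force oracles used to verify the package's statistics.
# These deliberately avoid the code paths (and closed-form distribution
# functions where the check is about the distribution itself) that they test.

# P(at least k overlap) by enumerating every size-L2 subset of the background.
oracle_hyper_tail <- function(L, L1, L2, k) {
  set1 <- seq_len(L1)
  draws <- utils::combn(L, L2)
  hits <- apply(draws, 2, function(s) sum(s %in% set1) >= k)
  mean(hits)
}

# P(at least s of k direction matches) by enumerating all 2^k match vectors.
oracle_binom_tail <- function(k, s) {
  if (k > 20) stop("oracle infeasible")
  counts <- rowSums(as.matrix(expand.grid(rep(list(0:1), k))))
  mean(counts >= s)
}

# Two-sided Fisher exact p for a 2x2 table (rows = groups): sum of the
# probabilities of all tables with the same margins whose probability does
# not exceed the observed one (point-probability method).
oracle_fisher_2x2 <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  lo <- max(0, r1 - (n - c1)); hi <- min(r1, c1)
  logp <- function(x) {
    lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1)
  }
  p_obs <- logp(a)
  xs <- lo:hi
  sum(exp(logp(xs))[logp(xs) <= p_obs + 1e-7])
}

# Rank products by direct loops: for each cancer-normal pair, rank fold
# changes by explicit sorting; geometric mean of ranks per gene.
oracle_rank_product <- function(X, group) {
  ic <- which(group == "cancer"); io <- which(group == "normal")
  G <- nrow(X)
  up <- down <- matrix(NA_real_, G, 0)
  for (i in ic) for (j in io) {
    d <- X[, i] - X[, j]
    up <- cbind(up, rank(-d))
    down <- cbind(down, rank(d))
  }
  K <- ncol(up)
  list(rp_up = apply(up, 1, function(r) prod(r)^(1 / K)),
       rp_down = apply(down, 1, function(r) prod(r)^(1 / K)),
       K = K)
}

# pfp under the within-comparison rank-permutation null by full enumeration
# of all (G!)^K rank assignments (feasible only for tiny G, K).
oracle_pfp_rank_exact <- function(X, group) {
  ic <- which(group == "cancer"); io <- which(group == "normal")
  G <- nrow(X)
  obs <- oracle_rank_product(X, group)
  perms <- oracle_perms(G)
  np <- nrow(perms)
  K <- obs$K
  # all K-tuples of permutations: mean log rank of gene 1..G in each tuple
  tuples <- rep(list(seq_len(np)), K)
  grid <- as.matrix(expand.grid(tuples))
  null_vals <- matrix(NA_real_, nrow(grid) * G, 1)
  cnt <- 0
  null_s <- numeric(0)
  for (t in seq_len(nrow(grid))) {
    s <- rep(0, G)
    for (kk in seq_len(K)) s <- s + log(perms[grid[t, kk], ])
    null_s <- c(null_s, s / K)
  }
  per_gene <- length(null_s) / G
  pfp_for <- function(rp_obs) {
    s_obs <- log(rp_obs)
    efp <- vapply(s_obs, function(t) sum(null_s <= t + 1e-12), 0) / per_gene
    r <- rank(s_obs, ties.method = "max")
    pfp <- pmin(efp / r, 1)
    ord <- order(s_obs)
    pfp[ord] <- rev(cummin(rev(pfp[ord])))
    pfp
  }
  list(pfp_up = pfp_for(obs$rp_up), pfp_down = pfp_for(obs$rp_down))
}

# All permutations of 1..n, rows = permutations (independent of the package's
# recursive generator: built via expand.grid filtering).
oracle_perms <- function(n) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), n)))
  grid[apply(grid, 1, function(r) length(unique(r)) == n), , drop = FALSE]
}

# pfp under the residual-permutation injection null by full enumeration:
# every gene's centered residuals are permuted in all n! ways and ranked
# against the observed fold-change landscape.
oracle_pfp_residual_exact <- function(X, group) {
  ic <- which(group == "cancer"); io <- which(group == "normal")
  G <- nrow(X); n <- ncol(X)
  obs <- oracle_rank_product(X, group)
  R <- X
  R[, ic] <- X[, ic, drop = FALSE] - rowMeans(X[, ic, drop = FALSE])
  R[, io] <- X[, io, drop = FALSE] - rowMeans(X[, io, drop = FALSE])
  perms <- oracle_perms(n)
  a <- rep(ic, each = length(io)); b <- rep(io, times = length(ic))
  K <- length(a)
  D <- sapply(seq_len(K), function(k) X[, a[k]] - X[, b[k]])
  null_down <- null_up <- numeric(0)
  for (g in seq_len(G)) for (p in seq_len(nrow(perms))) {
    rg <- R[g, perms[p, ]]
    sd_ <- su_ <- 0
    for (k in seq_len(K)) {
      dn <- rg[a[k]] - rg[b[k]]
      sd_ <- sd_ + log(sum(D[, k] <= dn) + 1)
      su_ <- su_ + log(sum(-D[, k] <= -dn) + 1)
    }
    null_down <- c(null_down, sd_ / K)
    null_up <- c(null_up, su_ / K)
  }
  per_gene <- nrow(perms)
  pfp_for <- function(rp_obs, null_s) {
    s_obs <- log(rp_obs)
    efp <- vapply(s_obs, function(t) sum(null_s <= t + 1e-12), 0) / per_gene
    r <- rank(s_obs, ties.method = "max")
    pfp <- pmin(efp / r, 1)
    ord <- order(s_obs)
    pfp[ord] <- rev(cummin(rev(pfp[ord])))
    pfp
  }
  list(pfp_up = pfp_for(obs$rp_up, null_up),
       pfp_down = pfp_for(obs$rp_down, null_down))
}

# Benjamini-Hochberg step-up by explicit sorting.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Breslow partial log-likelihood for a single binary/numeric covariate.
oracle_breslow_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Maximum partial-likelihood estimate by golden-section search on the
# hand-written Breslow likelihood.
oracle_cox_beta <- function(time, event, x) {
  stats::optimize(function(b) -oracle_breslow_loglik(b, time, event, x),
                  interval = c(-10, 10), tol = 1e-9)$minimum
}

# Harrell's C by exhaustive pair enumeration (ties in risk count 1/2).
oracle_cindex <- function(time, event, risk) {
  num <- den <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    # comparable: the smaller observed time must be an event
    first <- if (time[i] < time[j]) i else if (time[j] < time[i]) j else NA
    if (is.na(first)) next      # equal times: comparable only if one event? skip ties in time
    if (event[first] != 1) next
    other <- if (first == i) j else i
    den <- den + 1
    if (risk[first] > risk[other]) num <- num + 1
    else if (risk[first] == risk[other]) num <- num + 0.5
  }
  num / den
}

# Two-group log-rank chi-square by explicit risk-set arithmetic.
oracle_logrank <- function(time, event, group) {
  g <- as.integer(as.factor(group))
  stopifnot(length(unique(g)) == 2)
  times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & g == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Small deterministic expression fixture: G genes x (nc + nn) samples.
toy_matrix <- function(G = 6, nc = 3, nn = 3, seed = 1, sd = 1) {
  set.seed(seed)
  X <- matrix(rnorm(G * (nc + nn), 8, sd), G,
              dimnames = list(sprintf("g%02d", seq_len(G)),
                              sprintf("s%02d", seq_len(nc + nn))))
  list(X = X, group = rep(c("cancer", "normal"), c(nc, nn)))
}
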