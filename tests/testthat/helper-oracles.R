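# Independent oracles used to validate the package's own implementations.
# These are deliberately written as plain, scalar, step-by-step arithmetic
# so that they share no code path with the vectorised implementations.

# Weir & Cockerham (1984) variance components from per-population genotype
# counts (hom_ref, het, hom_alt), one population per list element.
oracle_wc_theta <- function(pop_counts) {
  r <- length(pop_counts)
  n <- sapply(pop_counts, sum)
  p <- sapply(pop_counts, function(cnt) (2 * cnt[3] + cnt[2]) / (2 * sum(cnt)))
  h <- sapply(pop_counts, function(cnt) cnt[2] / sum(cnt))
  nbar <- mean(n)
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / sum(n)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / sum(n)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, theta = a / (a + b + cc))
}

# exhaustive-enumeration two-sided Fisher p for a 2x2 table: sum of the
# hypergeometric probabilities of every table with the observed margins
# whose probability is <= the observed one (relative tolerance 1 + 1e-7)
oracle_fisher_2x2 <- function(m) {
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  a_range <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(a_range, c1, n - c1, r1)
  p_obs <- stats::dhyper(m[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# direct rank-sum Kruskal-Wallis H with tie correction
oracle_kruskal_H <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  rk <- rank(x)
  offsets <- c(0, cumsum(sapply(groups, length)))
  H <- 0
  for (i in seq_along(groups)) {
    ri <- rk[(offsets[i] + 1):offsets[i + 1]]
    H <- H + sum(ri)^2 / length(ri)
  }
  H <- 12 / (N * (N + 1)) * H - 3 * (N + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# direct evaluation of the Dunn z statistic for one pair of groups
oracle_dunn_z <- function(groups, i, j) {
  x <- unlist(groups)
  N <- length(x)
  rk <- rank(x)
  offsets <- c(0, cumsum(sapply(groups, length)))
  mr <- function(k) mean(rk[(offsets[k] + 1):offsets[k + 1]])
  ties <- table(x)
  v <- (N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))) *
    (1 / length(groups[[i]]) + 1 / length(groups[[j]]))
  (mr(i) - mr(j)) / sqrt(v)
}

# adjusted Rand index between two label vectors
oracle_ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# interval Jaccard overlap for 1-based inclusive intervals
interval_jaccard <- function(a1, a2, b1, b2) {
  inter <- max(0, min(a2, b2) - max(a1, b1) + 1)
  union <- (a2 - a1 + 1) + (b2 - b1 + 1) - inter
  inter / union
}
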