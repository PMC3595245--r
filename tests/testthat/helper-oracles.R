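# Independent oracles, deliberately written from first principles and kept
# apart from the implementation paths they check.

# Cohen's kappa via an explicit 2x2 contingency table
oracle_kappa <- function(x, y) {
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
  tab <- table(factor(x, levels = c(0, 1)), factor(y, levels = c(0, 1)))
  n <- sum(tab)
  po <- (tab[1, 1] + tab[2, 2]) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  (po - pe) / (1 - pe)
}

# Spearman rho as Pearson correlation of average ranks
oracle_spearman <- function(a, b) {
  stats::cor(rank(a), rank(b), method = "pearson")
}

# exact two-sided binomial p at p0 = 1/2: sum the probabilities of all
# outcomes no more likely than the observed one (enumerates the full
# outcome distribution; weights are the 2^n sequence counts)
oracle_binom_two_sided <- function(k, n) {
  probs <- choose(n, 0:n) / 2^n
  sum(probs[probs <= probs[k + 1] * (1 + 1e-12)])
}

# Ward agglomeration via the Lance-Williams update on squared Euclidean
# distances; returns merge heights on the same scale as hclust ward.D2
# (square roots of the Ward merge costs), lowest-index pair on ties
oracle_ward_heights <- function(X) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))^2
  size <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    best <- c(NA, NA)
    best_d <- Inf
    for (ii in seq_along(active)) {
      for (jj in seq_along(active)) {
        if (jj <= ii) next
        d <- D[active[ii], active[jj]]
        if (d < best_d - 1e-12) {
          best_d <- d
          best <- c(active[ii], active[jj])
        }
      }
    }
    i <- best[1]; j <- best[2]
    heights[step] <- sqrt(best_d)
    ni <- size[i]; nj <- size[j]
    for (k in setdiff(active, c(i, j))) {
      nk <- size[k]
      D[i, k] <- D[k, i] <-
        ((ni + nk) * D[i, k] + (nj + nk) * D[j, k] - nk * best_d) /
        (ni + nj + nk)
    }
    size[i] <- ni + nj
    active <- setdiff(active, j)
  }
  heights
}

# one-sample two-sided t on a vector of differences, by the formula
oracle_paired_t <- function(d) {
  n <- length(d)
  t <- mean(d) / (stats::sd(d) / sqrt(n))
  list(statistic = t, p_value = 2 * stats::pt(-abs(t), df = n - 1))
}
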