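# Independent oracles and small fixtures used across the suite.

# Brute-force two-sided Fisher p for a 2x2 table: explicit enumeration of
# the hypergeometric support with factorial-product probabilities
# (independent of the dhyper-based implementation path).
brute_fisher_2x2 <- function(m, tol = 1e-7) {
  n <- sum(m); r1 <- sum(m[1, ]); c1 <- sum(m[, 1])
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  pr <- vapply(ks, function(k) {
    exp(lchoose(r1, k) + lchoose(n - r1, c1 - k) - lchoose(n, c1))
  }, numeric(1))
  pobs <- pr[ks == m[1, 1]]
  min(1, sum(pr[pr <= pobs * (1 + tol)]))
}

# Brute-force Freeman-Halton p for small r x c tables: exhaustive
# enumeration (expand.grid over bounded compositions, column by column)
# of every non-negative table with the observed margins, probabilities
# from the closed-form multivariate hypergeometric expression.
brute_fisher_rxc <- function(m, tol = 1e-7) {
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  logK <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1)
  logp <- function(x) logK - sum(lgamma(x + 1))
  lp_obs <- logp(m)
  R <- length(rs); C <- length(cs)
  lps <- numeric(0)

  compositions <- function(total, caps) {
    # all vectors 0 <= x <= caps summing to total
    grid <- expand.grid(lapply(caps[-length(caps)], function(cp) 0:cp))
    last <- total - rowSums(grid)
    ok <- last >= 0 & last <= caps[length(caps)]
    t(as.matrix(cbind(grid, last)[ok, , drop = FALSE]))
  }
  fill <- function(tab, col, rem) {
    if (col == C) {          # last column is forced by the row remainders
      tab[, C] <- rem
      lps <<- c(lps, logp(tab))
      return(invisible())
    }
    comps <- compositions(cs[col], rem)
    for (k in seq_len(ncol(comps))) {
      tab[, col] <- comps[, k]
      fill(tab, col + 1L, rem - comps[, k])
    }
  }
  fill(matrix(0L, R, C), 1L, rs)
  min(1, sum(exp(lps[lps <= lp_obs + log1p(tol)])))
}

# random small count table (not margin-conditioned)
random_table <- function(nr, nc, total) {
  cells <- as.vector(stats::rmultinom(1, total, rep(1, nr * nc)))
  matrix(cells, nr, nc)
}

ref_simplified <- function() {
  simplify_table(reference_cohort()$lesions, "unknown/other")
}
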