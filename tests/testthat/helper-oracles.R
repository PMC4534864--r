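# Independent oracles used across tests.  These are written straight from
# the defining formulas, separately from the package internals.

# PhiPT from the sums-of-squared-distances definition, by explicit loops.
brute_phipt <- function(d, groups) {
  n <- nrow(d)
  ssd_tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    ssd_tot <- ssd_tot + d[i, j]
  ssd_tot <- ssd_tot / n
  ssd_w <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ng <- length(idx)
    if (ng < 2) next
    s <- 0
    for (a in seq_len(ng - 1)) for (b in (a + 1):ng)
      s <- s + d[idx[a], idx[b]]
    ssd_w <- ssd_w + s / ng
  }
  k <- length(unique(groups))
  ngs <- table(groups)
  msa <- (ssd_tot - ssd_w) / (k - 1)
  msw <- ssd_w / (n - k)
  n0 <- (n - sum(ngs^2) / n) / (k - 1)
  va <- max(0, (msa - msw) / n0)
  if (va + msw <= 0) 0 else va / (va + msw)
}

# exact permutation p-value by enumerating every distinct two-group
# assignment (independent of the package's enumeration)
brute_phipt_pvalue <- function(d, groups) {
  obs <- brute_phipt(d, groups)
  lv <- unique(groups)
  n1 <- sum(groups == lv[1])
  combos <- utils::combn(nrow(d), n1)
  stats <- apply(combos, 2, function(idx) {
    g <- rep(lv[2], nrow(d))
    g[idx] <- lv[1]
    brute_phipt(d, g)
  })
  mean(stats >= obs - 1e-12)
}

# NB convolution exact test oracle: group sums of iid NB(mu, phi) are
# NB(n*mu, phi/n); condition on the total and sum minimum-likelihood
# outcomes.  Uses R's aggregated NB density, not the package's lgamma form.
oracle_nb_exact <- function(y1, t, n1, n2, phi, mu = 10) {
  if (t == 0) return(1)
  y <- 0:t
  if (phi == 0) {
    pr <- dbinom(y, t, n1 / (n1 + n2))
  } else {
    pr <- dnbinom(y, size = n1 / phi, mu = n1 * mu) *
      dnbinom(t - y, size = n2 / phi, mu = n2 * mu)
    pr <- pr / sum(pr)
  }
  sum(pr[pr <= pr[y1 + 1] * (1 + 1e-12)])
}

# trimmed weighted mean-of-M TMM factor for one sample against a
# reference, from the published definition
oracle_tmm_pair <- function(y, yr, trim_m = 0.30, trim_a = 0.05) {
  n <- sum(y); nr <- sum(yr)
  keep0 <- y > 0 & yr > 0
  y <- y[keep0]; yr <- yr[keep0]
  M <- log2((y / n) / (yr / nr))
  A <- (log2(y / n) + log2(yr / nr)) / 2
  w <- 1 / ((n - y) / (n * y) + (nr - yr) / (nr * yr))
  nn <- length(M)
  loM <- floor(nn * trim_m) + 1; hiM <- nn + 1 - loM
  loA <- floor(nn * trim_a) + 1; hiA <- nn + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM &
    rank(A) >= loA & rank(A) <= hiA
  2^(sum(M[keep] * w[keep]) / sum(w[keep]))
}

# grid-search conditional MLE of the per-tag NB dispersion
oracle_tag_dispersion <- function(y, groups, grid = exp(seq(log(1e-6),
                                                            log(10),
                                                            length.out = 2001))) {
  ll <- vapply(grid, function(phi) {
    r <- 1 / phi
    tot <- 0
    for (k in unique(groups)) {
      yk <- y[groups == k]
      nk <- length(yk)
      tot <- tot + sum(lgamma(yk + r)) + lgamma(nk * r) -
        lgamma(sum(yk) + nk * r) - nk * lgamma(r)
    }
    tot
  }, numeric(1))
  grid[which.max(ll)]
}

small_sim <- function(...) {
  args <- list(n_tags = 60, n_true_dmrs = 8, lib_size_range = c(500, 900),
               n_loci = 40, n_condition_loci = 10, n_tissue_loci = 8)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}
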