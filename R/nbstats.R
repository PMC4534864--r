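#' Trimmed mean of M-values normalization factors
#'
#' Computes between-library scaling factors from a doubly trimmed,
#' precision-weighted mean of per-tag log2 ratios.  The reference library is
#' the one whose 75th count-proportion percentile is closest to the mean
#' such percentile.  For every other library, tags positive in both are
#' used to form M (log2 ratio of depth-normalized counts) and A (average
#' log2 abundance); the most extreme `trim_m` fraction of M and `trim_a`
#' fraction of A are discarded on each side; the factor is 2 to the
#' weighted mean of the surviving M, weights the inverse asymptotic
#' binomial variance.  Factors are rescaled to a unit geometric mean.
#'
#' @param counts non-negative matrix, tags x samples.
#' @param lib_size per-sample library sizes (default column sums).
#' @param trim_m,trim_a two-sided trim fractions for M and A (defaults 0.30
#'   and 0.05).
#' @return numeric vector of normalization factors, one per sample,
#'   multiplying to 1 in geometric mean.
#' @export
tmm_factors <- function(counts, lib_size = colSums(counts),
                        trim_m = 0.30, trim_a = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("need >= 2 samples")
  if (any(counts < 0)) stop("counts must be non-negative")
  q75 <- vapply(seq_len(ncol(counts)), function(j)
    quantile(counts[, j] / lib_size[j], 0.75, names = FALSE), numeric(1))
  ref <- which.min(abs(q75 - mean(q75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    tmm_pair(counts[, j], counts[, ref], lib_size[j], lib_size[ref],
             trim_m, trim_a)
  }, numeric(1))
  f / exp(mean(log(f)))
}

tmm_pair <- function(y, yr, n, nr, trim_m, trim_a) {
  pos <- y > 0 & yr > 0
  if (!any(pos)) {
    warning("sample shares no positive tags with the reference; factor 1")
    return(1)
  }
  y <- y[pos]; yr <- yr[pos]
  m <- log2((y / n) / (yr / nr))
  a <- (log2(y / n) + log2(yr / nr)) / 2
  v <- (n - y) / (n * y) + (nr - yr) / (nr * yr)
  if (max(abs(m)) < 1e-6) return(1)
  nn <- length(m)
  lo_m <- floor(nn * trim_m) + 1; hi_m <- nn + 1 - lo_m
  lo_a <- floor(nn * trim_a) + 1; hi_a <- nn + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m &
    rank(a) >= lo_a & rank(a) <= hi_a
  if (!any(keep)) return(1)
  2^(sum(m[keep] / v[keep]) / sum(1 / v[keep]))
}

# --- quantile-to-quantile pseudo-counts -------------------------------------

# Map a count observed under NB(mu_in, phi) to the equivalent quantile of
# NB(mu_out, phi), using the mid-P cumulative probability of the input and
# linear interpolation between integer quantiles of the output, so pseudo
# counts vary continuously.  phi = 0 uses the Poisson.
q2q_nbinom <- function(y, mu_in, mu_out, phi) {
  out <- numeric(length(y))
  mu_in <- rep_len(mu_in, length(y))
  mu_out <- rep_len(mu_out, length(y))
  zero_in <- mu_in <= 0 | mu_out <= 0
  out[zero_in] <- y[zero_in] # nothing to equalize
  i <- which(!zero_in)
  if (length(i) == 0) return(out)
  y <- y[i]
  mu_in <- mu_in[i]
  mu_out <- mu_out[i]
  if (phi < 1e-10) {
    cdf <- function(q, mu) ppois(q, mu)
    qtl <- function(p, mu) qpois(p, mu)
  } else {
    r <- 1 / phi
    cdf <- function(q, mu) pnbinom(q, size = r, mu = mu)
    qtl <- function(p, mu) qnbinom(p, size = r, mu = mu)
  }
  # mid-P cumulative probability of the observed count under the input law
  fmid_in <- (cdf(y - 1, mu_in) + cdf(y, mu_in)) / 2
  p <- pmin(pmax(fmid_in, 1e-300), 1 - 1e-12) # numeric guard at CDF ends
  # invert the output law's mid-P CDF, interpolating linearly between the
  # integer knots fmid(k) = (F(k-1) + F(k)) / 2; identical input and
  # output laws then map y exactly to itself
  k <- qtl(p, mu_out)
  fm <- function(k) (cdf(k - 1, mu_out) + cdf(k, mu_out)) / 2
  fmk <- fm(k)
  lowr <- p < fmk
  kl <- ifelse(lowr, k - 1, k)
  f0 <- ifelse(lowr, fm(k - 1), fmk)
  f1 <- ifelse(lowr, fmk, fm(k + 1))
  frac <- ifelse(f1 > f0, (p - f0) / (f1 - f0), 0)
  out[i] <- pmax(0, kl + frac)
  out
}

#' Equalize effective library sizes via quantile-adjusted pseudo-counts
#'
#' Maps every count to the scale of a common library size (the geometric
#' mean of the effective sizes `lib_size * norm_factors`) by
#' quantile-to-quantile matching under a working NB dispersion, using the
#' per-tag, per-group mean proportion as the NB mean.
#'
#' @param counts tags x samples matrix.
#' @param groups group label per sample.
#' @param dispersion working dispersion for the mapping.
#' @param lib_size,norm_factors per-sample sizes and factors (defaults:
#'   column sums and 1).
#' @return list with `pseudo` (matrix), `common_lib_size`, and `lambda`
#'   (tag x group mean proportions).
#' @export
nb_pseudo_counts <- function(counts, groups, dispersion,
                             lib_size = colSums(counts),
                             norm_factors = rep(1, ncol(counts))) {
  counts <- as.matrix(counts)
  eff <- lib_size * norm_factors
  nstar <- exp(mean(log(eff)))
  groups <- as.character(groups)
  lv <- unique(groups)
  lambda <- vapply(lv, function(k) {
    j <- groups == k
    rowSums(counts[, j, drop = FALSE]) / sum(eff[j])
  }, numeric(nrow(counts)))
  if (is.null(dim(lambda)))
    lambda <- matrix(lambda, nrow = nrow(counts),
                     dimnames = list(NULL, lv))
  pseudo <- counts
  for (j in seq_len(ncol(counts))) {
    lam <- lambda[, groups[j]]
    pseudo[, j] <- q2q_nbinom(counts[, j], mu_in = lam * eff[j],
                              mu_out = lam * nstar, phi = dispersion)
  }
  list(pseudo = pseudo, common_lib_size = nstar, lambda = lambda)
}

# per-tag conditional NB log-likelihood given group totals, summed over
# groups; vectorized over tags. Groups with one sample contribute 0.
cond_loglik <- function(pseudo, groups, phi) {
  r <- 1 / phi
  ll <- numeric(nrow(pseudo))
  for (k in unique(groups)) {
    yk <- pseudo[, groups == k, drop = FALSE]
    nk <- ncol(yk)
    z <- rowSums(yk)
    ll <- ll + rowSums(lgamma(yk + r)) + lgamma(nk * r) -
      lgamma(z + nk * r) - nk * lgamma(r)
  }
  ll
}

#' Common NB dispersion by quantile-adjusted conditional maximum likelihood
#'
#' Equalizes effective library sizes to their geometric mean through
#' quantile-to-quantile pseudo-counts, then maximizes the conditional
#' (given group totals) negative-binomial log-likelihood summed over all
#' tags, searching `phi` on the log scale in \[1e-6, 10\].  The
#' pseudo-count/estimate pair is iterated twice, starting from a working
#' dispersion of 0.01.
#'
#' @inheritParams nb_pseudo_counts
#' @param lib_size,norm_factors as in [nb_pseudo_counts()].
#' @return the estimate `phi` (scalar), with the final pseudo-counts in
#'   `attr(, "pseudo")` and the common library size in
#'   `attr(, "common_lib_size")`.
#' @export
common_dispersion <- function(counts, groups,
                              lib_size = colSums(counts),
                              norm_factors = rep(1, ncol(counts))) {
  counts <- as.matrix(counts)
  if (all(counts == 0)) {
    warning("all-zero matrix: returning the lower dispersion bound")
    return(structure(1e-6, pseudo = counts, common_lib_size = 0))
  }
  phi <- 0.01
  for (it in 1:2) {
    pq <- nb_pseudo_counts(counts, groups, phi, lib_size, norm_factors)
    obj <- function(lph) sum(cond_loglik(pq$pseudo, groups, exp(lph)))
    opt <- optimize(obj, c(log(1e-6), log(10)), maximum = TRUE,
                    tol = 1e-6)
    if (opt$objective - obj(log(1e-6)) < 1e-8) {
      phi <- 1e-6 # flat or boundary likelihood
    } else phi <- exp(opt$maximum)
  }
  structure(phi, pseudo = pq$pseudo,
            common_lib_size = pq$common_lib_size)
}

#' Empirical-Bayes tagwise NB dispersions by weighted likelihood
#'
#' Each tag maximizes its own conditional log-likelihood plus `prior_n`
#' times the average per-tag conditional log-likelihood of the whole
#' matrix, shrinking individual estimates toward the common value: as
#' `prior_n` grows the tagwise estimates collapse onto the common
#' dispersion, and at `prior_n = 0` they are the per-tag conditional MLEs.
#'
#' @inheritParams common_dispersion
#' @param phi_common common dispersion (used to build the pseudo-counts;
#'   typically the result of [common_dispersion()]).
#' @param prior_n empirical-Bayes prior weight, in units of "tags worth" of
#'   shared likelihood (default 10).
#' @return numeric vector of per-tag dispersions.
#' @export
tagwise_dispersion <- function(counts, groups, phi_common, prior_n = 10,
                               lib_size = colSums(counts),
                               norm_factors = rep(1, ncol(counts))) {
  counts <- as.matrix(counts)
  pseudo <- attr(phi_common, "pseudo")
  if (!is.null(pseudo) && nrow(pseudo) != nrow(counts)) pseudo <- NULL
  if (is.null(pseudo))
    pseudo <- nb_pseudo_counts(counts, groups, as.numeric(phi_common),
                               lib_size, norm_factors)$pseudo
  lgrid <- seq(log(1e-6), log(10), length.out = 81)
  llm <- vapply(lgrid, function(l) cond_loglik(pseudo, groups, exp(l)),
                numeric(nrow(pseudo)))
  shared <- splinefun(lgrid, colMeans(llm))
  vapply(seq_len(nrow(pseudo)), function(g) {
    yg <- pseudo[g, , drop = FALSE]
    obj <- function(l) cond_loglik(yg, groups, exp(l)) +
      prior_n * shared(l)
    opt <- optimize(obj, range(lgrid), maximum = TRUE, tol = 1e-6)
    if (opt$objective - obj(lgrid[1]) < 1e-8) 1e-6 else exp(opt$maximum)
  }, numeric(1))
}

#' Exact two-sided p-value for a two-group NB comparison
#'
#' Conditional on the total pseudo-count `t`, the group-1 sum follows the
#' convolution distribution of NB variables with equal means (a negative
#' hypergeometric), enumerated directly over `0:t`.  The two-sided p-value
#' is the minimum-likelihood sum: all outcomes whose probability does not
#' exceed that of the observed split (ties included with 1e-12 relative
#' tolerance).  `phi = 0` reduces to the exact binomial test.
#'
#' @param y1 observed group-1 total (integer in `0:t`).
#' @param t total count in both groups.
#' @param n1,n2 group sizes (equal effective library sizes assumed).
#' @param phi NB dispersion.
#' @return p-value in (0, 1\]; `t = 0` gives 1.
#' @export
nb_exact_pvalue <- function(y1, t, n1, n2, phi) {
  if (t == 0) return(1)
  y <- 0:t
  if (phi < 1e-10) {
    lp <- dbinom(y, t, n1 / (n1 + n2), log = TRUE)
  } else {
    r <- 1 / phi
    lp <- lgamma(y + n1 * r) - lgamma(y + 1) +
      lgamma(t - y + n2 * r) - lgamma(t - y + 1)
  }
  lp <- lp - max(lp)
  pr <- exp(lp)
  pr <- pr / sum(pr)
  pobs <- pr[y1 + 1]
  sum(pr[pr <= pobs * (1 + 1e-12)])
}

#' Two-group NB exact test for every tag
#'
#' Rounds group pseudo-count sums, enumerates the conditional distribution
#' per tag ([nb_exact_pvalue()]) and reports the log2 fold-change of
#' normalized group means with a prior count of 0.125 per observation.
#' `pair` orders the contrast: positive `logFC` means more abundant in
#' `pair[2]`.
#'
#' @inheritParams common_dispersion
#' @param dispersion scalar or per-tag NB dispersion.
#' @param pair two group labels, reference first (default: unique group
#'   labels in order of appearance).
#' @param pseudo optional precomputed pseudo-count matrix (otherwise built
#'   with the median dispersion).
#' @return `data.frame` with `tag`, `logFC`, `pvalue`, `phase`
#'   (`up_in_<pair[1]>`, `up_in_<pair[2]>`, or `none`).
#' @export
exact_test <- function(counts, groups, dispersion,
                       lib_size = colSums(counts),
                       norm_factors = rep(1, ncol(counts)),
                       pair = NULL, pseudo = NULL) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  lib_size <- if (missing(lib_size)) colSums(counts) else lib_size
  norm_factors <- if (missing(norm_factors)) rep(1, ncol(counts)) else
    norm_factors
  if (is.null(pair)) pair <- unique(groups)
  stopifnot(length(pair) == 2)
  keep <- groups %in% pair
  counts <- counts[, keep, drop = FALSE]
  groups <- groups[keep]
  if (is.null(pseudo))
    pseudo <- nb_pseudo_counts(counts, groups, median(dispersion),
                               lib_size[keep],
                               norm_factors[keep])$pseudo
  phi <- rep_len(dispersion, nrow(counts))
  j1 <- groups == pair[1]
  n1 <- sum(j1); n2 <- sum(!j1)
  s1 <- round(rowSums(pseudo[, j1, drop = FALSE]))
  s2 <- round(rowSums(pseudo[, !j1, drop = FALSE]))
  p <- vapply(seq_len(nrow(counts)), function(g)
    nb_exact_pvalue(s1[g], s1[g] + s2[g], n1, n2, phi[g]), numeric(1))
  lfc <- log2(s2 / n2 + 0.125) - log2(s1 / n1 + 0.125)
  lfc[s1 + s2 == 0] <- 0
  phase <- ifelse(lfc > 0, phase_label(pair[2]),
                  ifelse(lfc < 0, phase_label(pair[1]), "none"))
  tags <- rownames(counts) %||% as.character(seq_len(nrow(counts)))
  data.frame(tag = tags, logFC = lfc, pvalue = p, phase = phase,
             stringsAsFactors = FALSE, row.names = NULL)
}

# "in_vitro" phases as up_in_vitro, not up_in_in_vitro
phase_label <- function(cond) paste0("up_in_", sub("^in_", "", cond))

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' @param p vector of p-values in \[0, 1\].
#' @return q-values in input order (empty input gives empty output).
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  p.adjust(p, method = "BH")
}
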