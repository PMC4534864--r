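test_that("TMM factors satisfy identity, depth and scale invariances", {
  set.seed(1)
  a <- rnbinom(500, mu = 50, size = 5) + 1L
  expect_equal(tmm_factors(cbind(a, a)), c(1, 1))
  # doubling the depth is absorbed by the library size, not the factor
  expect_equal(tmm_factors(cbind(a, 2L * a)), c(1, 1))
  y <- matrix(rnbinom(500 * 4, mu = 50, size = 5), 500, 4)
  f0 <- tmm_factors(y)
  y2 <- y
  y2[, 3] <- y2[, 3] * 7L
  # rescaling a library cancels in M and A; only the precision weights
  # shift, so the factors agree closely rather than to machine accuracy
  expect_equal(tmm_factors(y2), f0, tolerance = 0.01)
  expect_error(tmm_factors(y[, 1, drop = FALSE]), "2 samples")
})

test_that("TMM matches the trimmed weighted-mean oracle on a fixture", {
  set.seed(2)
  base <- rnbinom(20, mu = 200, size = 20) + 10L
  y <- cbind(A = base, B = base)
  y[1:2, "B"] <- y[1:2, "B"] * 16L # two inflated tags in B
  f <- tmm_factors(y)
  # reference is A (identical upper quartiles pick the first nearest);
  # the oracle computes B's factor from the published definition
  fb <- oracle_tmm_pair(y[, "B"], y[, "A"])
  expected <- c(1, fb) / exp(mean(log(c(1, fb))))
  expect_equal(f, expected, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("TMM agrees with the reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(3)
  y <- matrix(rnbinom(2000 * 5, mu = 80, size = 5), 2000, 5)
  y[1:60, 2] <- y[1:60, 2] * 6L
  expect_equal(tmm_factors(y),
               edgeR::calcNormFactors(edgeR::DGEList(counts = y))$
                 samples$norm.factors,
               tolerance = 1e-10)
})

test_that("quantile mapping is exact on identity and monotone", {
  set.seed(4)
  y <- rnbinom(300, mu = 40, size = 5)
  expect_equal(epifidelity:::q2q_nbinom(y, 40, 40, 0.2), as.numeric(y))
  up <- epifidelity:::q2q_nbinom(sort(unique(y)), 40, 90, 0.2)
  expect_true(all(diff(up) > 0))
  expect_equal(mean(epifidelity:::q2q_nbinom(y, 40, 80, 0.2)) / mean(y), 2,
               tolerance = 0.05)
  expect_equal(epifidelity:::q2q_nbinom(c(0, 3), 0, 0, 0.2), c(0, 3))
})

test_that("common dispersion recovers the simulation truth", {
  grp <- rep(c("A", "B"), each = 6)
  set.seed(7)
  y_pois <- matrix(rpois(2000 * 12, 80), 2000, 12)
  expect_lte(as.numeric(common_dispersion(y_pois, grp)), 0.01)
  set.seed(8)
  y_nb <- matrix(rnbinom(2000 * 12, mu = 80, size = 5), 2000, 12)
  phi <- as.numeric(common_dispersion(y_nb, grp))
  expect_gte(phi, 0.17)
  expect_lte(phi, 0.23)
})

test_that("degenerate inputs hit the documented lower bound", {
  grp <- c("A", "A", "B", "B")
  expect_warning(phi0 <- common_dispersion(matrix(0L, 5, 4), grp),
                 "all-zero")
  expect_equal(as.numeric(phi0), 1e-6)
  flat <- matrix(7L, 1, 4)
  expect_equal(as.numeric(common_dispersion(flat, grp)), 1e-6)
})

test_that("tagwise dispersion shrinks toward the common value", {
  set.seed(9)
  grp <- rep(c("A", "B"), each = 6)
  y <- matrix(rnbinom(200 * 12, mu = 80, size = 5), 200, 12)
  phi_c <- common_dispersion(y, grp)

  # enormous prior collapses every tag onto the shared optimum
  tw_inf <- tagwise_dispersion(y, grp, phi_c, prior_n = 1e9)
  expect_lt(max(abs(log(tw_inf / as.numeric(phi_c)))), 1e-3)

  # zero prior equals the per-tag conditional MLE (grid-search oracle)
  tw0 <- tagwise_dispersion(y, grp, phi_c, prior_n = 0)
  pseudo <- attr(phi_c, "pseudo")
  for (g in 1:10) {
    ref <- oracle_tag_dispersion(pseudo[g, ], grp)
    if (ref > 2e-6 && ref < 9) # interior optima only
      expect_equal(log(tw0[g]), log(ref), tolerance = 0.02)
  }

  # spread decreases monotonically with the prior weight
  spread <- vapply(c(1, 10, 100), function(pn)
    sd(log(tagwise_dispersion(y, grp, phi_c, prior_n = pn))), numeric(1))
  expect_true(all(diff(spread) < 0))
})

test_that("the exact test matches enumeration oracles", {
  # minimum-likelihood NB convolution, totals up to 200
  set.seed(10)
  for (i in 1:40) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    t <- sample(1:200, 1)
    y1 <- sample(0:t, 1)
    phi <- sample(c(0, 0.05, 0.2, 1), 1)
    expect_equal(nb_exact_pvalue(y1, t, n1, n2, phi),
                 oracle_nb_exact(y1, t, n1, n2, phi), tolerance = 1e-9)
  }
  # phi = 0 with equal group sizes is the exact binomial(t, 1/2)
  expect_equal(nb_exact_pvalue(3, 12, 4, 4, 0),
               binom.test(3, 12, 0.5)$p.value, tolerance = 1e-12)
  # observed split at the mode includes every outcome
  expect_equal(nb_exact_pvalue(6, 12, 3, 3, 0.1), 1)
  # zero total is uninformative
  expect_equal(nb_exact_pvalue(0, 0, 3, 3, 0.1), 1)
})

test_that("exact test is symmetric in the group labels", {
  set.seed(11)
  grp <- rep(c("field", "in_vitro"), each = 4)
  y <- matrix(rnbinom(50 * 8, mu = 60, size = 5), 50, 8)
  a <- exact_test(y, grp, dispersion = 0.2,
                  pair = c("field", "in_vitro"))
  b <- exact_test(y, grp, dispersion = 0.2,
                  pair = c("in_vitro", "field"))
  expect_equal(a$pvalue, b$pvalue, tolerance = 1e-12)
  expect_equal(a$logFC, -b$logFC, tolerance = 1e-12)
  # phase names the more-abundant condition, so it travels with the
  # labels: reversing the contrast order must not change it
  expect_equal(a$phase, b$phase)
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.07, 5)), rep(0.07, 5))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  p <- c(0.001, 0.3, 0.02, 1)
  expect_true(all(bh_fdr(p) >= p))
})
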