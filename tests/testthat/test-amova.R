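test_that("binary distance is the count of differing loci", {
  m <- rbind(a = c(1, 0, 1, 1), b = c(1, 0, 1, 1), c = c(0, 1, 0, 0))
  d <- binary_distance(m)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 4) # full complement over 4 loci
  m2 <- matrix(rbinom(80, 1, 0.5), 8, 10)
  d2 <- binary_distance(m2)
  expect_equal(d2[1, 2], sum(m2[1, ] != m2[2, ]))
  expect_true(isSymmetric(d2))
  expect_true(all(diag(d2) == 0))
})

test_that("degenerate group structures give PhiPT 0 and 1", {
  # all samples identical: no variance anywhere
  m <- matrix(1, 6, 5)
  r0 <- amova_phipt(binary_distance(m), rep(c("a", "b"), each = 3),
                    n_perm = 99, seed = 1)
  expect_equal(r0$phipt, 0)
  # perfect structure: zero within, positive between
  m1 <- rbind(matrix(0, 3, 6), matrix(1, 3, 6))
  r1 <- amova_phipt(binary_distance(m1), rep(c("a", "b"), each = 3),
                    n_perm = 99, seed = 1)
  expect_equal(r1$phipt, 1)
  expect_lte(r1$p_value, 0.1) # best of the 20 assignments, with ties
})

test_that("PhiPT and its exact p-value match the brute-force oracle", {
  set.seed(404)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    n1 <- sample(2:(n - 2), 1)
    m <- matrix(rbinom(n * 12, 1, runif(1, 0.3, 0.7)), n, 12)
    groups <- sample(rep(c("a", "b"), c(n1, n - n1)))
    d <- binary_distance(m)
    res <- amova_phipt(d, groups, n_perm = 999, seed = 1)
    expect_equal(res$phipt, brute_phipt(d, groups), tolerance = 1e-12)
    expect_true(res$exact)
    expect_equal(res$p_value, brute_phipt_pvalue(d, groups),
                 tolerance = 1e-12)
  }
})

test_that("PhiPT is invariant to sample order and locus duplication", {
  set.seed(11)
  m <- matrix(rbinom(60, 1, 0.5), 6, 10)
  g <- rep(c("a", "b"), each = 3)
  base <- amova_phipt(binary_distance(m), g, n_perm = 99)$phipt
  ord <- sample(6)
  expect_equal(amova_phipt(binary_distance(m[ord, ]), g[ord],
                           n_perm = 99)$phipt, base)
  expect_equal(amova_phipt(binary_distance(cbind(m, m)), g,
                           n_perm = 99)$phipt, base)
})

test_that("permutation p-values are near-nominal under the null", {
  # 5v5 samples, 30 independent loci, no group effect; exact enumeration
  # of the 252 assignments per dataset
  set.seed(2024)
  n_data <- 1000
  rej <- logical(n_data)
  for (i in seq_len(n_data)) {
    m <- matrix(rbinom(10 * 30, 1, 0.5), 10, 30)
    p <- amova_phipt(binary_distance(m), rep(c("a", "b"), each = 5),
                     n_perm = 300)$p_value
    rej[i] <- p <= 0.05
  }
  env <- 2.576 * sqrt(0.05 * 0.95 / n_data)
  expect_gte(mean(rej), 0.05 - env - 0.006) # discreteness is conservative
  expect_lte(mean(rej), 0.05 + env)
})

test_that("errors on unusable group structures", {
  d <- binary_distance(matrix(rbinom(40, 1, 0.5), 4, 10))
  expect_error(amova_phipt(d, rep("a", 4)), "2 groups")
  expect_error(amova_phipt(d, c("a", "a", "b", "b"), n_perm = 0), "n_perm")
})

test_that("pcoa recovers planted Euclidean configurations", {
  # all-zero distances give all-zero coordinates
  z <- matrix(0, 4, 4)
  expect_true(all(pcoa(z)$coordinates == 0))

  # three collinear points with squared distances 1, 1, 4: one positive
  # eigenvalue, original distances reproduced
  d3 <- rbind(c(0, 1, 4), c(1, 0, 1), c(4, 1, 0))
  p3 <- pcoa(d3)
  expect_equal(sum(p3$eigenvalues > 1e-9), 1)
  dd <- as.matrix(dist(p3$coordinates))^2
  expect_equal(unname(dd), unname(d3), tolerance = 1e-9)

  # round trip from a random planted 2-D cloud
  set.seed(5)
  pts <- matrix(rnorm(16), 8, 2)
  d8 <- as.matrix(dist(pts))^2
  p8 <- pcoa(d8)
  expect_lt(max(abs(as.matrix(dist(p8$coordinates))^2 - d8)), 1e-9)
  expect_true(all(diff(p8$eigenvalues) <= 1e-9))
  expect_lt(max(abs(colMeans(p8$coordinates))), 1e-9)
})

test_that("pcoa agrees with an independent implementation", {
  skip_if_not_installed("ape")
  set.seed(6)
  m <- matrix(rbinom(7 * 20, 1, 0.5), 7, 20)
  d <- binary_distance(m)
  mine <- pcoa(d)
  ref <- ape::pcoa(as.dist(sqrt(d)))
  k <- min(ncol(mine$coordinates), ncol(ref$vectors))
  for (j in seq_len(k))
    expect_equal(abs(mine$coordinates[, j]), abs(ref$vectors[, j]),
                 tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("diagnostic markers require fixed differences", {
  m <- rbind(s1 = c(1, 1, 1), s2 = c(1, 0, 0), s3 = c(0, 0, 1),
             s4 = c(0, 1, 1))
  g <- c("field", "field", "in_vitro", "in_vitro")
  res <- diagnostic_markers(m, g)
  # locus 1 fixed 1-vs-0 -> diagnostic; loci 2 and 3 have intermediate
  # frequencies in at least one group -> not diagnostic
  expect_equal(names(res$diagnostic$all), "1")
  # per-cultivar intersection requires consistency in every stratum
  m2 <- rbind(m, m)
  rownames(m2) <- paste0("s", 1:8)
  g2 <- rep(g, 2)
  by <- rep(c("cv1", "cv2"), each = 4)
  m2[5, 1] <- 0 # cv2 no longer fixed at locus 1
  res2 <- diagnostic_markers(m2, g2, by = by)
  expect_equal(length(res2$all), 0)
})

test_that("tissue divergence averages skip missing cultivars", {
  tab <- data.frame(
    tissue_pair = "Ylv-Mlv", enzyme = "HpaII", condition = "field",
    cultivar = paste0("c", 1:5),
    phipt = c(0.208, NA, 0.171, 0.259, 0.000)
  )
  out <- tissue_divergence_summary(tab)
  expect_equal(out$average, 0.1595)
  expect_equal(out$n_cultivars, 4)
  # single value passes through; all-missing yields NA
  one <- tissue_divergence_summary(data.frame(
    tissue_pair = "x", enzyme = "e", condition = "c", cultivar = "k",
    phipt = 0.42))
  expect_equal(one$average, 0.42)
  none <- tissue_divergence_summary(data.frame(
    tissue_pair = "x", enzyme = "e", condition = "c",
    cultivar = c("k1", "k2"), phipt = c(NA, NA)))
  expect_true(is.na(none$average))
  expect_error(tissue_divergence_summary(transform(tab, phipt = 2)),
               "0, 1")
})
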