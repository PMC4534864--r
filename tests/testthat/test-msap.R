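peaks_df <- function(sample_id, enzyme, size_bp, height = 100) {
  data.frame(sample_id = sample_id, enzyme = enzyme, size_bp = size_bp,
             height = height, stringsAsFactors = FALSE)
}

test_that("binning clusters by single linkage with same-sample exclusion", {
  pk <- peaks_df(c("s1", "s2", "s1"), "HpaII", c(100.1, 100.3, 250.0))
  cat1 <- bin_peaks(pk, tolerance_bp = 0.5)
  expect_equal(sort(cat1$center), c(100.2, 250.0))

  # two peaks of one sample inside one tolerance window force two bins
  pk2 <- peaks_df("s1", "HpaII", c(100.1, 100.4), height = c(50, 80))
  cat2 <- bin_peaks(pk2, tolerance_bp = 0.5)
  expect_equal(nrow(cat2), 2)

  # deterministic and ordered by size
  pk3 <- peaks_df(c("a", "b", "c"), "MspI", c(310.2, 110.0, 110.2))
  expect_identical(bin_peaks(pk3), bin_peaks(pk3[c(3, 1, 2), ]))
  expect_false(is.unsorted(bin_peaks(pk3)$center))

  expect_equal(nrow(bin_peaks(pk[0, ])), 0)
  expect_error(bin_peaks(pk, tolerance_bp = 0), "tolerance")
})

test_that("binary scoring applies the closed 100-580 window and threshold", {
  pk <- peaks_df(rep("s1", 4), "HpaII", c(99.9, 100.0, 580.0, 580.1))
  catalog <- bin_peaks(pk, tolerance_bp = 0.05)
  m <- score_binary(pk, catalog)
  centers <- attr(m, "loci")$center
  expect_setequal(round(centers, 1), c(100.0, 580.0)) # bounds inclusive
  expect_true(all(m == 1))

  # zero heights never score as present under the default threshold
  pk0 <- peaks_df(c("s1", "s2"), "HpaII", c(200, 200), height = 0)
  m0 <- score_binary(pk0, bin_peaks(pk0))
  expect_true(all(m0 == 0))

  # metadata samples without peaks yield warned all-zero rows
  meta <- data.frame(sample_id = c("s1", "s2"))
  expect_warning(m2 <- score_binary(pk, catalog, metadata = meta), "s2")
  expect_true(all(m2["s2", ] == 0))
})

test_that("scoring is invariant to record order", {
  cfg <- small_sim(seed = 21)
  ms <- simulate_msap_profiles(cfg)
  catalog <- bin_peaks(ms$peaks)
  m1 <- score_binary(ms$peaks, catalog, metadata = ms$metadata)
  shuf <- ms$peaks[sample(nrow(ms$peaks)), ]
  m2 <- score_binary(shuf, catalog, metadata = ms$metadata)
  expect_identical(unclass(m1), unclass(m2))
})

test_that("height matrix sums peaks, windows 50-550 and low-filters", {
  pk <- peaks_df(c("s1", "s2", "s3"), "HpaII", c(200, 200, 200),
                 height = c(0, 60, 100))
  catalog <- bin_peaks(pk)
  hm <- build_height_matrix(pk, catalog,
                            low_filter = list(type = "mean", min = 50))
  expect_equal(ncol(hm), 1) # mean 53.3 passes
  hm2 <- build_height_matrix(pk, catalog,
                             low_filter = list(type = "mean", min = 60))
  expect_equal(ncol(hm2), 0) # mean 53.3 fails

  # all-zero locus removed by any positive filter
  pk0 <- peaks_df(c("s1", "s2"), "HpaII", c(300, 300), height = 0)
  hm0 <- build_height_matrix(pk0, bin_peaks(pk0),
                             low_filter = list(type = "total", min = 1e-9))
  expect_equal(ncol(hm0), 0)

  # split peaks of one sample in one bin are summed
  pk3 <- rbind(peaks_df("s1", "HpaII", c(200.0, 200.2), height = c(10, 20)),
               peaks_df("s2", "HpaII", 200.1, height = 5))
  cat3 <- bin_peaks(peaks_df(c("s1", "s2"), "HpaII", c(200.0, 200.2)))
  hm3 <- build_height_matrix(pk3, cat3)
  expect_equal(sum(hm3["s1", ]), 30)
})

test_that("quantitative loci inside the qualitative window have binary bins", {
  cfg <- small_sim(seed = 22)
  ms <- simulate_msap_profiles(cfg)
  catalog <- bin_peaks(ms$peaks)
  hpa_cat <- catalog[catalog$enzyme == "HpaII", ]
  attr(hpa_cat, "tolerance_bp") <- attr(catalog, "tolerance_bp")
  pk <- ms$peaks[ms$peaks$enzyme == "HpaII", ]
  bm <- score_binary(pk, hpa_cat, metadata = ms$metadata)
  hm <- build_height_matrix(pk, hpa_cat, metadata = ms$metadata)
  hin <- attr(hm, "loci")
  hin <- hin[hin$center >= 100 & hin$center <= 580, ]
  expect_true(all(hin$bin_id %in% attr(bm, "loci")$bin_id))
})

test_that("marker origin classification separates enzyme patterns", {
  g <- c("field", "field", "in_vitro", "in_vitro")
  base <- matrix(1L, 4, 3, dimnames = list(paste0("s", 1:4), NULL))
  mk <- function(cols) {
    m <- base
    for (j in seq_along(cols)) m[, j] <- cols[[j]]
    loci <- data.frame(enzyme = "HpaII",
                       bin_id = paste0("b", seq_len(ncol(m))),
                       center = c(100, 200, 300))
    attr(loci, "tolerance_bp") <- 0.5
    structure(m, loci = loci, class = c("epilocus_matrix", "matrix"))
  }
  hpa <- mk(list(c(1, 1, 0, 0), c(1, 1, 0, 0), c(1, 1, 1, 1)))
  msp <- mk(list(c(1, 1, 1, 1), c(0, 0, 1, 1), c(1, 1, 1, 1)))
  cls <- classify_marker_origin(hpa, msp, g)
  expect_equal(cls$origin, c("epigenetic_only", "genetic_or_epigenetic",
                             "monomorphic"))
  rownames(msp)[1] <- "other"
  expect_error(classify_marker_origin(hpa, msp, g), "same samples")
})

test_that("isoschizomer presence pairs map to methylation states", {
  expect_equal(call_methylation_state(c(1, 0, 1, 0), c(1, 1, 0, 0)),
               c("unmethylated", "internal_mC", "hemi_external_mC",
                 "hypermethylated_or_absent"))
  expect_error(call_methylation_state(2, 1), "0 or 1")
})

test_that("planted methylation states are recovered without drop-out", {
  cfg <- small_sim(seed = 31, dropout_prob = 0)
  ms <- simulate_msap_profiles(cfg)
  catalog <- bin_peaks(ms$peaks)
  meta <- ms$metadata
  mats <- lapply(c("HpaII", "MspI"), function(ez) {
    sub <- catalog[catalog$enzyme == ez, ]
    attr(sub, "tolerance_bp") <- attr(catalog, "tolerance_bp")
    score_binary(ms$peaks[ms$peaks$enzyme == ez, ], sub, metadata = meta,
                 size_window = c(50, 600))
  })
  truth <- ms$truth
  got <- character(0)
  want <- character(0)
  for (i in seq_len(nrow(truth$locus))) {
    jh <- which(abs(attr(mats[[1]], "loci")$center -
                      truth$locus$size_bp[i]) < 0.5)
    jm <- which(abs(attr(mats[[2]], "loci")$center -
                      truth$locus$size_bp[i]) < 0.5)
    for (s in sample(nrow(meta), 8)) {
      gkey <- paste(meta$condition[s], meta$tissue[s], sep = "|")
      hp <- if (length(jh) == 1) mats[[1]][s, jh] else 0L
      mp <- if (length(jm) == 1) mats[[2]][s, jm] else 0L
      got <- c(got, call_methylation_state(hp, mp))
      want <- c(want, unname(truth$state[i, gkey]))
    }
  }
  expect_gt(length(got), 100)
  expect_identical(got, want)
})

test_that("enzyme partition counts unique and shared loci", {
  mk <- function(centers, ez) {
    m <- matrix(1L, 2, length(centers))
    loci <- data.frame(enzyme = ez, bin_id = paste0(ez, centers),
                       center = centers)
    attr(loci, "tolerance_bp") <- 0.5
    structure(m, loci = loci, class = c("epilocus_matrix", "matrix"))
  }
  p <- enzyme_partition(mk(c(100, 200, 300), "HpaII"),
                        mk(c(200, 300, 400, 500), "MspI"))
  expect_equal(unname(p), c(1, 2, 2, 5))
  expect_equal(p[["n_total"]],
               p[["n_unique_hpa"]] + p[["n_unique_msp"]] + p[["n_shared"]])
  # disjoint catalogs share nothing; identical ones have no uniques
  expect_equal(enzyme_partition(mk(100, "HpaII"),
                                mk(300, "MspI"))[["n_shared"]], 0)
  same <- enzyme_partition(mk(c(100, 200), "HpaII"), mk(c(100, 200), "MspI"))
  expect_equal(unname(same[c("n_unique_hpa", "n_unique_msp")]), c(0, 0))
})
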