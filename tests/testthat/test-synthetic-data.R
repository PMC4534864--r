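test_that("invalid configuration fields are rejected by name", {
  expect_error(sim_config(n_varieties = 0), "n_varieties")
  expect_error(sim_config(dispersion = -0.1), "dispersion")
  expect_error(sim_config(n_true_dmrs = 50, n_tags = 10), "n_true_dmrs")
  expect_error(sim_config(conditions = c("field", "field")), "conditions")
  expect_error(sim_config(lib_size_range = c(10, 5)), "lib_size_range")
  expect_error(sim_config(dropout_prob = 1.5), "dropout_prob")
})

test_that("the design grid honours missing cells and replicate structure", {
  meta <- sample_metadata(sim_config())
  expect_equal(nrow(meta), 5 * 2 * 3 * 3 - 3) # one dropped cell
  expect_false(any(meta$variety == "v4" & meta$condition == "field" &
                     meta$tissue == "mature_leaf"))
  full <- sample_metadata(sim_config(missing_cells = NULL))
  expect_equal(nrow(full), 90)
  expect_false(anyDuplicated(full$sample_id) > 0)
})

test_that("all generators are byte-identical under a fixed seed", {
  cfg <- small_sim(seed = 7)
  expect_identical(simulate_msap_profiles(cfg), simulate_msap_profiles(cfg))
  expect_identical(simulate_tag_counts(cfg), simulate_tag_counts(cfg))
  g1 <- simulate_toy_genome(cfg)
  g2 <- simulate_toy_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$planted, g2$planted)
  expect_identical(simulate_gbs_reads(cfg, g1)$reads,
                   simulate_gbs_reads(cfg, g2)$reads)
})

test_that("planted condition-responsive MSAP loci drive scored differences", {
  cfg <- small_sim(seed = 3, dropout_prob = 0)
  ms <- simulate_msap_profiles(cfg)
  catalog <- bin_peaks(ms$peaks)
  meta <- ms$metadata
  for (ez in c("HpaII", "MspI")) {
    m <- score_binary(ms$peaks[ms$peaks$enzyme == ez, ],
                      catalog[catalog$enzyme == ez, ], metadata = meta)
    loci <- attr(m, "loci")
    truth <- ms$truth
    # every locus where field and in-vitro states imply opposite presence
    # must separate the conditions perfectly (no drop-out configured)
    ezc <- if (ez == "HpaII") 1 else 2
    for (i in which(truth$locus$condition_responsive)) {
      j <- which(abs(loci$center - truth$locus$size_bp[i]) < 0.5)
      if (length(j) != 1) next
      pf <- truth$presence[truth$state[i, "field|young_leaf"], ezc]
      pv <- truth$presence[truth$state[i, "in_vitro|young_leaf"], ezc]
      if (pf == pv) next
      sel_f <- meta$condition == "field" & meta$tissue == "young_leaf"
      sel_v <- meta$condition == "in_vitro" & meta$tissue == "young_leaf"
      expect_true(all(m[sel_f, j] == pf))
      expect_true(all(m[sel_v, j] == pv))
    }
  }
})

test_that("tag counts follow the requested NB model", {
  # dispersion 0 reduces to Poisson: variance tracks the mean
  # equal library sizes so cross-sample variance is purely the count law
  cfg0 <- small_sim(seed = 5, dispersion = 0, n_true_dmrs = 0,
                    n_tags = 200, lib_size_range = c(25000, 25000))
  tc <- simulate_tag_counts(cfg0)
  mu_hat <- rowMeans(tc$counts)
  v_hat <- apply(tc$counts, 1, var)
  keep <- mu_hat > 20
  expect_lt(abs(median(v_hat[keep] / mu_hat[keep]) - 1), 0.15)

  # planted effect separates the group means by about 2^logfc
  cfg <- small_sim(seed = 5, effect_logfc = 3, n_tags = 200,
                   n_true_dmrs = 40, dispersion = 0.1,
                   lib_size_range = c(20000, 30000))
  tc <- simulate_tag_counts(cfg)
  meta <- tc$metadata
  tr <- tc$truth
  ratio <- vapply(tr$true_dmr_ids, function(id) {
    mf <- mean(tc$counts[id, meta$condition == "field"])
    mv <- mean(tc$counts[id, meta$condition == "in_vitro"])
    if (tr$phase[id] == "up_in_field") mf / mv else mv / mf
  }, numeric(1))
  expect_lt(abs(median(log2(ratio)) - 3), 0.5)
})

test_that("toy genome plants every compartment with exact bookkeeping", {
  cfg <- small_sim(seed = 9)
  gs <- simulate_toy_genome(cfg)
  expect_setequal(unique(gs$planted$compartment),
                  c("exon", "intron", "upstream_5kb", "downstream_5kb",
                    "intergenic"))
  expect_true(all(gs$planted$end - gs$planted$start == cfg$tag_length))
  expect_true(all(startsWith(gs$planted$sequence, "CGG")))
  flank <- gs$planted$compartment %in% c("upstream_5kb", "downstream_5kb")
  expect_true(all(gs$planted$distance[flank] >= 0 &
                    gs$planted$distance[flank] <= 5000))
  # planted sequence actually occurs at the recorded interval
  chr <- as.character(gs$genome[["chr1"]])
  for (i in sample(nrow(gs$planted), 10)) {
    sub <- substring(chr, gs$planted$start[i] + 1, gs$planted$end[i])
    expected <- if (gs$planted$strand[i] == "+") gs$planted$sequence[i] else
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(gs$planted$sequence[i])))
    expect_identical(sub, expected)
  }
})

test_that("read simulation logs contaminants and honours zero-contamination", {
  cfg <- small_sim(seed = 13, contaminant_fraction = 0)
  rs <- simulate_gbs_reads(cfg)
  dm <- demultiplex(rs$reads$sequence, rs$barcodes)
  expect_equal(dm$log$n_retained, dm$log$n_input) # 100% retained
  expect_equal(rs$truth$n_contaminant, 0)

  cfg2 <- small_sim(seed = 13, contaminant_fraction = 0.1)
  rs2 <- simulate_gbs_reads(cfg2)
  expect_equal(sum(rs2$truth$contaminants), rs2$truth$n_contaminant)
  expect_equal(nrow(rs2$reads), rs2$truth$n_valid + rs2$truth$n_contaminant)
})
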