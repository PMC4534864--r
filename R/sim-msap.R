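#' Simulate MSAP peak tables with planted methylation states
#'
#' Generates per-sample HpaII and MspI peak tables (fragment size and
#' fluorescence height) driven by a planted CCGG methylation state per locus
#' and sample group.  The isoschizomer logic maps each state to enzyme
#' presence: unmethylated cuts with both enzymes, internal-cytosine
#' methylation (CmCGG) cuts with MspI only, hemimethylated external cytosine
#' (mCCGG) cuts with HpaII only, and hypermethylation cuts with neither.
#'
#' Present peaks get lognormal heights; absent loci emit no record (height
#' 0), keeping binary scoring unambiguous.  An amplification drop-out
#' probability removes a present peak at random.  Fragment sizes are fixed
#' per locus in \[50, 600\] bp with a small per-observation sizing jitter so
#' binning has real work to do.
#'
#' @param config a [sim_config()] object.
#' @return list with `peaks` (`data.frame`: `sample_id`, `enzyme`, `size_bp`,
#'   `height`), `metadata` (see [sample_metadata()]), and `truth` — per-locus
#'   fragment size, planted state per condition/tissue, and flags for
#'   condition- and tissue-responsive loci.
#' @export
simulate_msap_profiles <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 11))
  meta <- sample_metadata(config)
  states <- c("unmethylated", "internal_mC", "hemi_external_mC",
              "hypermethylated_or_absent")
  presence <- rbind( # rows: states; cols: HpaII, MspI
    unmethylated = c(1, 1),
    internal_mC = c(0, 1),
    hemi_external_mC = c(1, 0),
    hypermethylated_or_absent = c(0, 0)
  )

  n <- config$n_loci
  # well-separated locus sizes so default binning recovers them
  sizes <- sort(50 + (seq_len(n) - 0.5) / n * 550 +
                  runif(n, -0.3, 0.3) * 550 / n / 2)
  cond_loci <- seq_len(config$n_condition_loci)
  tissue_loci <- config$n_condition_loci + seq_len(config$n_tissue_loci)

  base_state <- sample(states, n, replace = TRUE,
                       prob = c(0.45, 0.25, 0.15, 0.15))
  # planted condition effect: a *different* state in the second condition,
  # identical across varieties and tissues (a consistent RdDM-like mark)
  alt_state <- vapply(base_state, function(s)
    sample(setdiff(states, s), 1), character(1))

  # state lookup per locus x (condition, tissue)
  groups <- expand.grid(condition = config$conditions,
                        tissue = config$tissues,
                        stringsAsFactors = FALSE)
  state_tab <- matrix(base_state, nrow = n, ncol = nrow(groups))
  colnames(state_tab) <- paste(groups$condition, groups$tissue, sep = "|")
  for (g in seq_len(nrow(groups))) {
    if (groups$condition[g] == config$conditions[2])
      state_tab[cond_loci, g] <- alt_state[cond_loci]
  }
  # tissue-responsive loci: their state rotates with tissue (both
  # conditions); the cycle order makes every tissue pair differ in both
  # enzymes' presence patterns
  rot <- c("unmethylated", "internal_mC", "hypermethylated_or_absent",
           "hemi_external_mC")
  for (g in seq_len(nrow(groups))) {
    shift <- match(groups$tissue[g], config$tissues) - 1
    idx <- (match(state_tab[tissue_loci, g], rot) + shift - 1) %% 4 + 1
    state_tab[tissue_loci, g] <- rot[idx]
  }

  recs <- vector("list", nrow(meta) * 2)
  k <- 0
  for (i in seq_len(nrow(meta))) {
    gkey <- paste(meta$condition[i], meta$tissue[i], sep = "|")
    st <- state_tab[, gkey]
    for (ez in c(1, 2)) {
      pres <- presence[st, ez] == 1
      pres[pres] <- runif(sum(pres)) >= config$dropout_prob
      if (!any(pres)) next
      k <- k + 1
      recs[[k]] <- data.frame(
        sample_id = meta$sample_id[i],
        enzyme = c("HpaII", "MspI")[ez],
        size_bp = sizes[pres] + runif(sum(pres), -0.15, 0.15),
        height = rlnorm(sum(pres), meanlog = log(1000),
                        sdlog = config$peak_sdlog),
        stringsAsFactors = FALSE
      )
    }
  }
  peaks <- do.call(rbind, recs[seq_len(k)])
  rownames(peaks) <- NULL

  truth <- list(
    locus = data.frame(
      locus_id = sprintf("L%03d", seq_len(n)),
      size_bp = sizes,
      condition_responsive = seq_len(n) %in% cond_loci,
      tissue_responsive = seq_len(n) %in% tissue_loci,
      stringsAsFactors = FALSE
    ),
    state = state_tab,
    states = states,
    presence = presence
  )
  list(peaks = peaks, metadata = meta, truth = truth, config = config)
}
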