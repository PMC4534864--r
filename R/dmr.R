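#' Per-variety differential-abundance tests
#'
#' For every variety with samples in both propagation systems, subsets the
#' count matrix, runs the NB pipeline (TMM factors, common +
#' empirical-Bayes tagwise dispersion, exact test, BH FDR within variety)
#' for the field versus in-vitro contrast with tissues pooled within
#' condition.  Varieties missing a condition are excluded with a warning.
#'
#' @param counts tag x sample matrix.
#' @param metadata sample metadata with `sample_id`, `variety`,
#'   `condition` (see [sample_metadata()]).
#' @param pair the two condition labels, reference first (default
#'   `c("field", "in_vitro")`).
#' @param prior_n empirical-Bayes weight for tagwise dispersion; `NULL`
#'   uses the common dispersion for every tag.
#' @param fdr FDR threshold recorded alongside the results (used by
#'   [summarize_differential()] and [consensus_dmrs()]).
#' @return named list (one element per variety) of `data.frame`s with
#'   `tag`, `logFC`, `pvalue`, `qvalue`, `phase`, `observed` (tag seen in
#'   >= 1 sample of the variety); class `variety_tests`.
#' @export
per_variety_tests <- function(counts, metadata,
                              pair = c("field", "in_vitro"),
                              prior_n = 10, fdr = 0.05) {
  counts <- as.matrix(counts)
  meta <- metadata[match(colnames(counts), metadata$sample_id), ,
                   drop = FALSE]
  if (anyNA(meta$sample_id))
    stop("every count column needs a metadata row")
  out <- list()
  for (v in unique(meta$variety)) {
    j <- which(meta$variety == v)
    gr <- meta$condition[j]
    if (!all(pair %in% gr)) {
      warning(sprintf("variety %s lacks a condition: excluded", v))
      next
    }
    cv <- counts[, j, drop = FALSE]
    nf <- tmm_factors(cv)
    phi_c <- common_dispersion(cv, gr, norm_factors = nf)
    phi <- if (is.null(prior_n)) rep(as.numeric(phi_c), nrow(cv)) else
      tagwise_dispersion(cv, gr, phi_c, prior_n = prior_n,
                         norm_factors = nf)
    res <- exact_test(cv, gr, dispersion = phi, norm_factors = nf,
                      pair = pair, pseudo = attr(phi_c, "pseudo"))
    res$qvalue <- bh_fdr(res$pvalue)
    res$observed <- rowSums(cv) > 0
    out[[v]] <- res[, c("tag", "logFC", "pvalue", "qvalue", "phase",
                        "observed")]
  }
  structure(out, pair = pair, fdr = fdr, class = "variety_tests")
}

#' Cross-variety phase-conserved consensus DMRs
#'
#' A tag is a micropropagation-induced consensus DMR iff (a) it is
#' significant (q < `fdr`) with the same phase in at least `min_varieties`
#' varieties, (b) no variety is significant with the opposite phase, and
#' (c) when `require_observed_all` is set, the tag was observed in every
#' variety (the operational stand-in for "no variety-specific SNPs").
#'
#' @param results a `variety_tests` object from [per_variety_tests()].
#' @param fdr per-variety significance threshold on the q-value.
#' @param min_varieties minimal number of same-phase significant varieties
#'   (default 4 of 5).
#' @param require_observed_all require presence in every variety.
#' @return `data.frame` of class `dmr_set`: one row per tag with
#'   `n_up_field`, `n_up_vitro` (significant varieties by phase),
#'   `n_varieties_supporting`, `consensus` flag and `consensus_phase`.
#' @export
consensus_dmrs <- function(results, fdr = 0.05, min_varieties = 4,
                           require_observed_all = TRUE) {
  stopifnot(inherits(results, "variety_tests"))
  if (min_varieties > length(results))
    stop(sprintf("min_varieties = %d exceeds the %d varieties tested",
                 min_varieties, length(results)))
  pair <- attr(results, "pair")
  ph_ref <- phase_label(pair[1])
  ph_alt <- phase_label(pair[2])
  tags <- results[[1]]$tag
  sig <- vapply(results, function(r) r$qvalue < fdr, logical(length(tags)))
  phase <- vapply(results, function(r) r$phase, character(length(tags)))
  obs <- vapply(results, function(r) r$observed, logical(length(tags)))
  n_ref <- rowSums(sig & phase == ph_ref)
  n_alt <- rowSums(sig & phase == ph_alt)
  support <- pmax(n_ref, n_alt)
  same_phase <- n_ref == 0 | n_alt == 0
  consensus <- support >= min_varieties & same_phase
  if (require_observed_all) consensus <- consensus & rowSums(!obs) == 0
  cphase <- ifelse(!consensus, NA_character_,
                   ifelse(n_ref >= n_alt, ph_ref, ph_alt))
  out <- data.frame(tag = tags, n_up_field = n_ref, n_up_vitro = n_alt,
                    n_varieties_supporting = support,
                    consensus = consensus, consensus_phase = cphase,
                    stringsAsFactors = FALSE)
  structure(out, fdr = fdr, min_varieties = min_varieties,
            class = c("dmr_set", "data.frame"))
}

#' Per-variety and consensus differential-abundance summaries
#'
#' For test results, counts significantly more-abundant tags per condition
#' and variety (total = sum of the two phases).  A plain `data.frame` of
#' already-tabulated per-variety counts (columns `up_in_vitro`,
#' `up_in_field`) is also accepted and totalled, so published count tables
#' can be checked directly.
#'
#' @param results a `variety_tests` object, or a `data.frame` with columns
#'   `variety`, `up_in_vitro`, `up_in_field`.
#' @param fdr significance threshold when summarizing test results.
#' @return `data.frame` with `variety`, `up_in_vitro`, `up_in_field`,
#'   `total`.
#' @export
summarize_differential <- function(results, fdr = 0.05) {
  if (inherits(results, "variety_tests")) {
    pair <- attr(results, "pair")
    tab <- do.call(rbind, lapply(names(results), function(v) {
      r <- results[[v]]
      sig <- r$qvalue < fdr
      data.frame(
        variety = v,
        up_in_vitro = sum(sig & r$phase == phase_label(pair[2])),
        up_in_field = sum(sig & r$phase == phase_label(pair[1])),
        stringsAsFactors = FALSE
      )
    }))
  } else {
    stopifnot(all(c("variety", "up_in_vitro", "up_in_field") %in%
                    names(results)))
    tab <- results[, c("variety", "up_in_vitro", "up_in_field")]
  }
  tab$total <- tab$up_in_vitro + tab$up_in_field
  rownames(tab) <- NULL
  tab
}

#' Consensus fraction of unique tags, as a printed percentage
#'
#' @param n_consensus number of consensus DMR tags.
#' @param n_unique number of unique tags surveyed.
#' @param digits decimals of the reported percentage (default 2).
#' @return percentage, rounded.
#' @export
consensus_fraction <- function(n_consensus, n_unique, digits = 2) {
  round(100 * n_consensus / n_unique, digits)
}
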