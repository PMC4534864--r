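#' Simulate an msGBS tag-abundance matrix with planted DMRs
#'
#' Draws integer tag counts from a negative binomial whose mean is
#' `lib_size * relative_abundance * condition_effect`.  The first
#' `n_true_dmrs` tags carry a planted propagation-system effect of magnitude
#' `effect_logfc` (log2), applied symmetrically (+/- half the effect in each
#' condition, so the two group means differ by `2^effect_logfc`-fold) in
#' `dmr_varieties` of the varieties, with a per-tag phase; all other tags
#' have no condition effect.  `dispersion = 0` gives Poisson counts.
#'
#' @param config a [sim_config()] object.
#' @return list with `counts` (integer matrix, tags x samples), `metadata`,
#'   and `truth` (`true_dmr_ids`, per-tag `phase`, the varieties carrying
#'   each effect, and per-tag relative abundances).
#' @export
simulate_tag_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$dispersion < 0) stop_field("dispersion", "must be >= 0")
  set.seed(child_seed(config$seed, 23))
  meta <- sample_metadata(config)
  nt <- config$n_tags
  ns <- nrow(meta)
  tag_ids <- sprintf("tag_%05d", seq_len(nt))

  rel <- rgamma(nt, shape = 0.7)
  rel <- rel / sum(rel)
  lib <- runif(ns, config$lib_size_range[1], config$lib_size_range[2])

  dmr_idx <- seq_len(config$n_true_dmrs)
  phase <- rep("none", nt)
  phase[dmr_idx] <- sample(c("up_in_field", "up_in_vitro"),
                           length(dmr_idx), replace = TRUE)
  varieties <- paste0("v", seq_len(config$n_varieties))
  affected <- lapply(dmr_idx, function(i)
    sort(sample(varieties, config$dmr_varieties)))

  half <- 2^(config$effect_logfc / 2)
  mu <- outer(rel, lib) # tags x samples baseline mean
  for (j in seq_len(ns)) {
    vj <- meta$variety[j]
    in_second <- meta$condition[j] == config$conditions[2] # in_vitro
    for (k in seq_along(dmr_idx)) {
      if (!(vj %in% affected[[k]])) next
      i <- dmr_idx[k]
      up_vitro <- phase[i] == "up_in_vitro"
      fac <- if (in_second == up_vitro) half else 1 / half
      mu[i, j] <- mu[i, j] * fac
    }
  }

  counts <- matrix(0L, nt, ns, dimnames = list(tag_ids, meta$sample_id))
  if (config$dispersion == 0) {
    counts[] <- rpois(nt * ns, lambda = as.vector(mu))
  } else {
    counts[] <- rnbinom(nt * ns, mu = as.vector(mu),
                        size = 1 / config$dispersion)
  }

  truth <- list(
    true_dmr_ids = tag_ids[dmr_idx],
    phase = setNames(phase, tag_ids),
    affected_varieties = setNames(affected, tag_ids[dmr_idx]),
    relative_abundance = setNames(rel, tag_ids),
    lib_size = setNames(lib, meta$sample_id)
  )
  list(counts = counts, metadata = meta, truth = truth, config = config)
}
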