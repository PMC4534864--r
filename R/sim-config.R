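#' Configuration for the synthetic experiment generator
#'
#' Collects every tunable of the simulated study design: a clonal-propagation
#' comparison of five varieties grown either in the field or by meristem
#' culture, sampled in three tissues with three biological replicates.  The
#' defaults reproduce that design at desk scale; `missing_cells` removes whole
#' variety x condition x tissue cells so that missing-data code paths are
#' exercised.
#'
#' @param n_varieties number of varieties (default 5).
#' @param conditions propagation systems; exactly two labels, first is the
#'   reference (field) condition.
#' @param tissues tissue labels sampled from every plant.
#' @param n_replicates biological replicates per design cell.
#' @param missing_cells `data.frame` with columns `variety`, `condition`,
#'   `tissue` naming design cells to drop, or `NULL` for the complete design.
#'   The default drops the field mature-leaf cell of variety `v4`.
#' @param n_loci number of MSAP epiloci (fragments) to simulate.
#' @param n_condition_loci how many loci carry a planted propagation-system
#'   methylation difference (shared across varieties).
#' @param n_tissue_loci how many loci carry a planted tissue-specific state.
#' @param n_tags number of msGBS 64-mer tags.
#' @param n_true_dmrs number of tags planted with a condition effect
#'   (candidate DMRs); must not exceed `n_tags`.
#' @param dmr_varieties in how many varieties each planted DMR responds
#'   (default: all of them).
#' @param effect_logfc log2 fold change between conditions for planted DMRs.
#' @param dispersion negative-binomial dispersion of tag counts (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param lib_size_range min/max expected reads per sample.
#' @param barcode_length length (nt) of the sample barcodes.
#' @param tag_length tag length in nt, including the leading CGG cut-site
#'   remnant (default 64).
#' @param dropout_prob probability that a truly present MSAP peak fails to
#'   amplify in a given sample.
#' @param peak_sdlog sdlog of the lognormal peak-height model.
#' @param contaminant_fraction fraction of structurally invalid msGBS reads
#'   (corrupt barcode, corrupt cut site, short read) added on top of the
#'   valid ones.
#' @param seed integer seed; identical config + seed gives byte-identical
#'   output.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_varieties = 5,
                       conditions = c("field", "in_vitro"),
                       tissues = c("young_leaf", "mature_leaf", "root"),
                       n_replicates = 3,
                       missing_cells = default_missing_cells(),
                       n_loci = 160,
                       n_condition_loci = 30,
                       n_tissue_loci = 20,
                       n_tags = 2000,
                       n_true_dmrs = 40,
                       dmr_varieties = n_varieties,
                       effect_logfc = 3,
                       dispersion = 0.2,
                       lib_size_range = c(5e4, 1e5),
                       barcode_length = 6,
                       tag_length = 64,
                       dropout_prob = 0.02,
                       peak_sdlog = 0.4,
                       contaminant_fraction = 0.05,
                       seed = 1) {
  cfg <- list(
    n_varieties = n_varieties, conditions = conditions, tissues = tissues,
    n_replicates = n_replicates, missing_cells = missing_cells,
    n_loci = n_loci, n_condition_loci = n_condition_loci,
    n_tissue_loci = n_tissue_loci,
    n_tags = n_tags, n_true_dmrs = n_true_dmrs,
    dmr_varieties = dmr_varieties, effect_logfc = effect_logfc,
    dispersion = dispersion, lib_size_range = lib_size_range,
    barcode_length = barcode_length, tag_length = tag_length,
    dropout_prob = dropout_prob, peak_sdlog = peak_sdlog,
    contaminant_fraction = contaminant_fraction, seed = seed
  )
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @export
default_missing_cells <- function() {
  data.frame(variety = "v4", condition = "field", tissue = "mature_leaf",
             stringsAsFactors = FALSE)
}

validate_sim_config <- function(cfg) {
  chk_count <- function(field, min = 1) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < min ||
        v != round(v))
      stop_field(field, sprintf("must be a single integer >= %d", min))
  }
  for (f in c("n_varieties", "n_replicates", "n_loci", "n_tags",
              "barcode_length", "tag_length"))
    chk_count(f)
  for (f in c("n_condition_loci", "n_tissue_loci", "n_true_dmrs",
              "dmr_varieties"))
    chk_count(f, min = 0)
  if (length(cfg$conditions) != 2 || anyDuplicated(cfg$conditions))
    stop_field("conditions", "exactly two distinct labels required")
  if (length(cfg$tissues) < 1 || anyDuplicated(cfg$tissues))
    stop_field("tissues", "distinct labels required")
  if (!is.numeric(cfg$dispersion) || cfg$dispersion < 0)
    stop_field("dispersion", "must be >= 0")
  if (cfg$n_true_dmrs > cfg$n_tags)
    stop_field("n_true_dmrs", "cannot exceed n_tags")
  if (cfg$dmr_varieties > cfg$n_varieties)
    stop_field("dmr_varieties", "cannot exceed n_varieties")
  if (cfg$n_condition_loci + cfg$n_tissue_loci > cfg$n_loci)
    stop_field("n_condition_loci",
               "n_condition_loci + n_tissue_loci cannot exceed n_loci")
  if (length(cfg$lib_size_range) != 2 || any(cfg$lib_size_range <= 0) ||
      diff(cfg$lib_size_range) < 0)
    stop_field("lib_size_range", "must be an increasing positive pair")
  for (f in c("dropout_prob", "contaminant_fraction")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop_field(f, "must lie in [0, 1]")
  }
  if (!is.numeric(cfg$effect_logfc)) stop_field("effect_logfc", "numeric")
  if (!is.numeric(cfg$peak_sdlog) || cfg$peak_sdlog < 0)
    stop_field("peak_sdlog", "must be >= 0")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || is.na(cfg$seed))
    stop_field("seed", "must be a single number")
  if (!is.null(cfg$missing_cells)) {
    mc <- cfg$missing_cells
    if (!is.data.frame(mc) ||
        !all(c("variety", "condition", "tissue") %in% names(mc)))
      stop_field("missing_cells",
                 "needs columns variety, condition, tissue")
  }
  structure(cfg, class = "sim_config")
}

#' Sample metadata implied by a design configuration
#'
#' Expands the full variety x condition x tissue x replicate grid, drops the
#' configured missing cells, and assigns stable sample identifiers.
#'
#' @param config a [sim_config()] object.
#' @return `data.frame` with columns `sample_id`, `variety`, `condition`,
#'   `tissue`, `replicate`.
#' @export
sample_metadata <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  varieties <- paste0("v", seq_len(config$n_varieties))
  grid <- expand.grid(
    replicate = seq_len(config$n_replicates),
    tissue = config$tissues,
    condition = config$conditions,
    variety = varieties,
    stringsAsFactors = FALSE
  )[, c("variety", "condition", "tissue", "replicate")]
  if (!is.null(config$missing_cells) && nrow(config$missing_cells) > 0) {
    key <- function(d) paste(d$variety, d$condition, d$tissue, sep = "|")
    grid <- grid[!(key(grid) %in% key(config$missing_cells)), , drop = FALSE]
  }
  grid$sample_id <- sprintf("%s_%s_%s_r%d", grid$variety, grid$condition,
                            grid$tissue, grid$replicate)
  rownames(grid) <- NULL
  grid[, c("sample_id", "variety", "condition", "tissue", "replicate")]
}
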