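#' Pipeline configuration
#'
#' Bundles every tunable of the two analysis tracks with the simulation
#' design.  Unknown keys are rejected so configuration typos fail loudly.
#'
#' @param sim a [sim_config()] object.
#' @param bin_tolerance MSAP binning tolerance (bp).
#' @param size_window_binary closed size window for qualitative scoring.
#' @param size_window_height closed size window for peak-height analysis.
#' @param presence_threshold binary scoring height threshold.
#' @param low_filter low-intensity epilocus filter (see
#'   [build_height_matrix()]).
#' @param n_perm AMOVA permutations.
#' @param trim_m,trim_a TMM trim fractions.
#' @param prior_n empirical-Bayes tagwise prior weight.
#' @param fdr FDR threshold for differential calls.
#' @param min_varieties consensus support requirement.
#' @param window gene-annotation flank width (bp).
#' @param tag_len msGBS tag length.
#' @param min_samples prevalence filter for tags.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            bin_tolerance = 0.5,
                            size_window_binary = c(100, 580),
                            size_window_height = c(50, 550),
                            presence_threshold = 0,
                            low_filter = list(type = "mean", min = 1),
                            n_perm = 999,
                            trim_m = 0.30, trim_a = 0.05,
                            prior_n = 10, fdr = 0.05,
                            min_varieties = 4, window = 5000,
                            tag_len = 64, min_samples = 3) {
  cfg <- list(sim = sim, bin_tolerance = bin_tolerance,
              size_window_binary = size_window_binary,
              size_window_height = size_window_height,
              presence_threshold = presence_threshold,
              low_filter = low_filter, n_perm = n_perm,
              trim_m = trim_m, trim_a = trim_a, prior_n = prior_n,
              fdr = fdr, min_varieties = min_varieties, window = window,
              tag_len = tag_len, min_samples = min_samples)
  validate_pipeline_config(cfg)
}

validate_pipeline_config <- function(cfg) {
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(cfg), known)
  if (length(extra) > 0)
    stop(sprintf("unknown config key(s): %s", paste(extra, collapse = ", ")))
  if (!inherits(cfg$sim, "sim_config"))
    cfg$sim <- do.call(sim_config, cfg$sim)
  stopifnot(cfg$n_perm >= 1, cfg$fdr > 0, cfg$fdr < 1,
            cfg$min_varieties >= 1, cfg$window >= 0, cfg$tag_len > 3)
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys match the arguments of
#'   [pipeline_config()] (the `sim` block matching [sim_config()]).
#' @return `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  do.call(pipeline_config, y)
}

#' Run the MSAP analysis track
#'
#' From per-sample peak tables to the qualitative and quantitative
#' results: locus catalog, binary matrices per enzyme, per-cultivar
#' field-versus-in-vitro PhiPT with permutation p-values, tissue-pair PhiPT
#' per condition with cross-cultivar averages, fixed-difference diagnostic
#' markers, PCoA coordinates per cultivar, and per-cultivar NB tests on
#' peak heights (rounded to integers for the count machinery).
#'
#' @param peaks peak `data.frame` (or CSV path).
#' @param metadata sample metadata (`sample_id`, `variety`, `condition`,
#'   `tissue`, `replicate`).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, result tables are written
#'   as CSV with a config-hash + seed header.
#' @return list of class `msap_track` with elements `catalog`, `binary`
#'   (per enzyme), `condition_phipt`, `tissue_phipt`, `tissue_averages`,
#'   `diagnostic`, `pcoa` (per cultivar), `quantitative` (per enzyme
#'   per-cultivar significant counts), `partition`.
#' @export
run_msap_track <- function(peaks, metadata, config = pipeline_config(),
                           out_dir = NULL) {
  if (is.character(peaks)) peaks <- read_peak_table(peaks)
  check_metadata(metadata, config)
  seed <- config$sim$seed
  catalog <- bin_peaks(peaks, config$bin_tolerance)
  enzymes <- c("HpaII", "MspI")
  binm <- lapply(enzymes, function(ez)
    score_binary(peaks[peaks$enzyme == ez, , drop = FALSE],
                 catalog[catalog$enzyme == ez, , drop = FALSE] |>
                   keep_tol(catalog),
                 metadata = metadata,
                 size_window = config$size_window_binary,
                 presence_threshold = config$presence_threshold))
  names(binm) <- enzymes

  conditions <- unique(metadata$condition)
  # per-cultivar condition contrast, per enzyme
  rows <- list()
  for (v in unique(metadata$variety)) {
    sel <- metadata$variety == v
    for (ez in enzymes) {
      m <- binm[[ez]][sel, , drop = FALSE]
      res <- amova_phipt(binary_distance(m), metadata$condition[sel],
                         n_perm = config$n_perm,
                         seed = child_seed(seed, 71))
      rows[[length(rows) + 1]] <- data.frame(
        variety = v, enzyme = ez, phipt = res$phipt,
        p_value = res$p_value, n_perm = res$n_perm,
        stringsAsFactors = FALSE)
    }
  }
  condition_phipt <- do.call(rbind, rows)

  # tissue-pair contrasts within each condition
  tissues <- unique(metadata$tissue)
  rows <- list()
  for (v in unique(metadata$variety)) for (ez in enzymes)
    for (cond in conditions)
      for (pair in combn_pairs(tissues)) {
        sel <- metadata$variety == v & metadata$condition == cond &
          metadata$tissue %in% pair
        if (length(unique(metadata$tissue[sel])) < 2) next # missing cell
        m <- binm[[ez]][sel, , drop = FALSE]
        res <- amova_phipt(binary_distance(m), metadata$tissue[sel],
                           n_perm = config$n_perm,
                           seed = child_seed(seed, 73))
        rows[[length(rows) + 1]] <- data.frame(
          tissue_pair = paste(pair, collapse = "-"), enzyme = ez,
          condition = cond, cultivar = v, phipt = res$phipt,
          p_value = res$p_value, stringsAsFactors = FALSE)
      }
  tissue_phipt <- do.call(rbind, rows)
  tissue_averages <- tissue_divergence_summary(tissue_phipt)

  combined <- cbind(binm$HpaII, binm$MspI)
  pcoa_per_cultivar <- lapply(split(seq_len(nrow(metadata)),
                                    metadata$variety), function(i)
    pcoa(binary_distance(combined[i, , drop = FALSE])))

  diag <- diagnostic_markers(combined, metadata$condition,
                             by = metadata$variety)

  # quantitative peak-height track: NB machinery on rounded heights
  quant <- list()
  for (ez in enzymes) {
    hm <- build_height_matrix(peaks[peaks$enzyme == ez, , drop = FALSE],
                              catalog[catalog$enzyme == ez, , drop = FALSE] |>
                                keep_tol(catalog),
                              metadata = metadata,
                              size_window = config$size_window_height,
                              low_filter = config$low_filter)
    cm <- t(round(unclass(hm)))
    res <- per_variety_tests(cm, metadata, pair = conditions,
                             prior_n = config$prior_n, fdr = config$fdr)
    quant[[ez]] <- summarize_differential(res, fdr = config$fdr)
  }

  partition <- enzyme_partition(binm$HpaII, binm$MspI,
                                tolerance = config$bin_tolerance)

  out <- structure(list(catalog = catalog, binary = binm,
                        condition_phipt = condition_phipt,
                        tissue_phipt = tissue_phipt,
                        tissue_averages = tissue_averages,
                        diagnostic = diag, pcoa = pcoa_per_cultivar,
                        quantitative = quant, partition = partition,
                        config = config), class = "msap_track")
  if (!is.null(out_dir)) write_msap_track(out, out_dir)
  out
}

keep_tol <- function(sub, full) {
  attr(sub, "tolerance_bp") <- attr(full, "tolerance_bp")
  sub
}

combn_pairs <- function(x) {
  if (length(x) < 2) return(list())
  cc <- combn(sort(x), 2)
  lapply(seq_len(ncol(cc)), function(j) cc[, j])
}

check_metadata <- function(metadata, config) {
  need <- c("sample_id", "variety", "condition", "tissue")
  if (!all(need %in% names(metadata)))
    stop("metadata needs sample_id, variety, condition, tissue")
  bad_c <- setdiff(unique(metadata$condition), config$sim$conditions)
  if (length(bad_c) > 0)
    stop(sprintf("unknown condition label(s): %s",
                 paste(bad_c, collapse = ", ")))
  bad_t <- setdiff(unique(metadata$tissue), config$sim$tissues)
  if (length(bad_t) > 0)
    stop(sprintf("unknown tissue label(s): %s",
                 paste(bad_t, collapse = ", ")))
  invisible(TRUE)
}

write_msap_track <- function(track, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  h <- config_hash(track$config)
  s <- track$config$sim$seed
  write_result_csv(track$condition_phipt,
                   file.path(out_dir, "condition_phipt.csv"), h, s)
  write_result_csv(track$tissue_phipt,
                   file.path(out_dir, "tissue_phipt.csv"), h, s)
  write_result_csv(track$tissue_averages,
                   file.path(out_dir, "tissue_averages.csv"), h, s)
  for (v in names(track$pcoa))
    write_result_csv(as.data.frame(track$pcoa[[v]]$coordinates),
                     file.path(out_dir, sprintf("pcoa_%s.csv", v)), h, s)
  invisible(out_dir)
}

#' Run the msGBS analysis track
#'
#' Demultiplexes reads (or restarts from a prebuilt count matrix), applies
#' the negative-control and prevalence filters, runs the per-variety NB
#' tests, calls phase-conserved consensus DMRs and, when a genome and gene
#' models are supplied, locates and annotates the consensus tags.
#'
#' @param config a [pipeline_config()].
#' @param fastq,barcodes read FASTQ and barcode TSV paths (or in-memory
#'   read sequences / barcode `data.frame`); ignored when `counts` is
#'   given.
#' @param counts optional prebuilt tag x sample matrix (restart mid
#'   pipeline, skipping demultiplexing).
#' @param metadata sample metadata; defaults to parsing sample ids of the
#'   form `variety_condition_tissue_rN`.
#' @param genome,gff optional genome FASTA / gene models for annotation.
#' @param tag_seqs optional named map tag id -> sequence when `counts` rows
#'   are ids rather than sequences.
#' @param out_dir optional output directory for result CSVs.
#' @return list of class `gbs_track`: `demux_log`, `matrix_raw` dims,
#'   `matrix` (filtered), `tests`, `summary`, `dmrs`, `consensus_tags`,
#'   `annotation` (or NULL), `report`.
#' @export
run_gbs_track <- function(config = pipeline_config(), fastq = NULL,
                          barcodes = NULL, counts = NULL, metadata = NULL,
                          genome = NULL, gff = NULL, tag_seqs = NULL,
                          out_dir = NULL) {
  demux_log <- NULL
  raw_dim <- NULL
  if (is.null(counts)) {
    if (is.null(fastq) || is.null(barcodes))
      stop("either counts or fastq + barcodes must be supplied")
    dm <- demultiplex(fastq, barcodes, tag_len = config$tag_len)
    demux_log <- dm$log
    counts <- build_matrix(dm$tags)
    raw_dim <- dim(counts)
    counts <- filter_matrix(counts, "water_control",
                            min_samples = config$min_samples)
  }
  if (is.null(metadata))
    metadata <- parse_sample_ids(colnames(counts), config$sim$conditions)
  tests <- per_variety_tests(counts, metadata,
                             pair = config$sim$conditions,
                             prior_n = config$prior_n, fdr = config$fdr)
  dmrs <- consensus_dmrs(tests, fdr = config$fdr,
                         min_varieties = config$min_varieties)
  summ <- summarize_differential(tests, fdr = config$fdr)
  cons <- dmrs$tag[dmrs$consensus]
  cons_seq <- if (!is.null(tag_seqs)) unname(tag_seqs[cons]) else cons
  annotation <- NULL
  if (!is.null(genome) && !is.null(gff) && length(cons) > 0) {
    hits <- locate_tags(setNames(cons_seq, cons), genome)
    annotation <- annotate_hits(hits, gff, window = config$window)
  }
  report <- list(
    demux = demux_log,
    tags_before_filter = if (!is.null(raw_dim)) raw_dim[1] else nrow(counts),
    tags_after_filter = nrow(counts),
    filter_log = attr(counts, "filter_log"),
    n_consensus = length(cons),
    consensus_pct = consensus_fraction(length(cons), nrow(counts))
  )
  out <- structure(list(demux_log = demux_log, matrix = counts,
                        tests = tests, summary = summ, dmrs = dmrs,
                        consensus_tags = setNames(cons_seq, cons),
                        annotation = annotation, report = report,
                        config = config), class = "gbs_track")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    h <- config_hash(config)
    s <- config$sim$seed
    write_result_csv(summ, file.path(out_dir, "differential_summary.csv"),
                     h, s)
    write_result_csv(as.data.frame(dmrs),
                     file.path(out_dir, "consensus_dmrs.csv"), h, s)
    if (length(cons) > 0)
      write_tag_fasta(setNames(cons_seq, cons),
                      file.path(out_dir, "consensus_tags.fasta"))
    if (!is.null(annotation))
      write_result_csv(annotation,
                       file.path(out_dir, "annotation.csv"), h, s)
  }
  out
}

parse_sample_ids <- function(ids, conditions = c("field", "in_vitro")) {
  cond <- rep(NA_character_, length(ids))
  tissue <- rep(NA_character_, length(ids))
  for (cd in conditions) {
    pat <- paste0("^[^_]+_", cd, "_(.+)_r\\d+$")
    hit <- grepl(pat, ids) & is.na(cond)
    cond[hit] <- cd
    tissue[hit] <- sub(pat, "\\1", ids[hit])
  }
  if (anyNA(cond))
    stop("cannot parse sample ids; supply metadata explicitly")
  data.frame(sample_id = ids,
             variety = sub("^([^_]+)_.*$", "\\1", ids),
             condition = cond, tissue = tissue,
             replicate = as.integer(sub("^.*_r(\\d+)$", "\\1", ids)),
             stringsAsFactors = FALSE)
}
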