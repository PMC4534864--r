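#' Simulate multiplexed msGBS reads from a planted genome
#'
#' Emits single-end reads with the anatomy `barcode + CGG + tag body (+
#' downstream filler)`, one multiplexed pool covering all samples plus a
#' negative water control, mirroring a reduced-representation library built
#' with a methylation-sensitive enzyme.  Valid read counts per tag and
#' sample come from [simulate_tag_counts()] run on the same configuration
#' (so tag `i` of the count simulation is tag `i` of the genome).  On top, a
#' configurable fraction of structurally invalid reads is added: a
#' single-substitution barcode (must be rejected under the exact-match
#' rule), a corrupted cut-site remnant, and reads too short to yield a full
#' tag.  A small set of non-DMR tags is also planted into the water control
#' so the control filter has real work.
#'
#' @param config a [sim_config()] object; use modest `n_tags` and
#'   `lib_size_range` for read-level work.
#' @param genome_sim optional result of [simulate_toy_genome()] for the same
#'   config (built on the fly if omitted).
#' @return list with `reads` (`data.frame`: `read_id`, `sequence`),
#'   `barcodes` (`data.frame`: `barcode`, `sample_id`, including
#'   `water_control`), `counts_sim` (the underlying count simulation), and
#'   `truth` (planted per-sample counts, control tag ids, contaminant log,
#'   `n_valid`/`n_contaminant`).
#' @export
simulate_gbs_reads <- function(config, genome_sim = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(genome_sim)) genome_sim <- simulate_toy_genome(config)
  counts_sim <- simulate_tag_counts(config)
  set.seed(child_seed(config$seed, 53))
  meta <- counts_sim$metadata
  counts <- counts_sim$counts
  tag_seq <- setNames(genome_sim$planted$sequence, genome_sim$planted$tag_id)
  stopifnot(all(rownames(counts) %in% names(tag_seq)))

  samples <- c(meta$sample_id, "water_control")
  barcodes <- make_barcodes(length(samples), config$barcode_length)
  bmap <- data.frame(barcode = barcodes, sample_id = samples,
                     stringsAsFactors = FALSE)
  if (anyDuplicated(bmap$barcode)) stop("barcode collisions in map")

  # water-control contamination: a few non-DMR tags seen in the control
  non_dmr <- setdiff(rownames(counts), counts_sim$truth$true_dmr_ids)
  n_ctl <- min(length(non_dmr), max(2L, round(0.01 * config$n_tags)))
  control_tags <- sort(sample(non_dmr, n_ctl))
  control_counts <- setNames(1L + rpois(n_ctl, 2), control_tags)

  bc_of <- setNames(bmap$barcode, bmap$sample_id)
  filler <- function(n) vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 10, replace = TRUE), collapse = ""),
    character(1))

  seqs <- character(0)
  src <- character(0) # bookkeeping label per read
  for (s in meta$sample_id) {
    cs <- counts[, s]
    keep <- cs > 0
    if (!any(keep)) next
    reps <- rep(names(cs)[keep], cs[keep])
    seqs <- c(seqs, paste0(bc_of[[s]], tag_seq[reps], filler(length(reps))))
    src <- c(src, rep("valid", length(reps)))
  }
  reps <- rep(control_tags, control_counts)
  seqs <- c(seqs, paste0(bc_of[["water_control"]], tag_seq[reps],
                         filler(length(reps))))
  src <- c(src, rep("valid", length(reps)))
  n_valid <- length(seqs)

  n_contam <- round(config$contaminant_fraction * n_valid)
  contam_type <- character(0)
  if (n_contam > 0) {
    contam_type <- rep(c("bad_barcode", "bad_cutsite", "too_short"),
                       length.out = n_contam)
    pick_tag <- sample(names(tag_seq), n_contam, replace = TRUE)
    pick_sam <- sample(meta$sample_id, n_contam, replace = TRUE)
    cseqs <- character(n_contam)
    for (i in seq_len(n_contam)) {
      bc <- bc_of[[pick_sam[i]]]
      tg <- tag_seq[[pick_tag[i]]]
      cseqs[i] <- switch(contam_type[i],
        bad_barcode = paste0(corrupt_barcode(bc, bmap$barcode), tg,
                             filler(1)),
        bad_cutsite = paste0(bc, "CGA", substring(tg, 4), filler(1)),
        too_short = paste0(bc, substring(tg, 1, 30))
      )
    }
    seqs <- c(seqs, cseqs)
    src <- c(src, contam_type)
  }

  ord <- sample(length(seqs))
  reads <- data.frame(
    read_id = sprintf("read_%07d", seq_along(seqs)),
    sequence = seqs[ord], stringsAsFactors = FALSE
  )

  truth <- list(
    counts = counts,
    control_tags = control_tags,
    control_counts = control_counts,
    contaminants = table(factor(src[src != "valid"],
                                levels = c("bad_barcode", "bad_cutsite",
                                           "too_short"))),
    n_valid = n_valid,
    n_contaminant = n_contam
  )
  list(reads = reads, barcodes = bmap, counts_sim = counts_sim,
       genome_sim = genome_sim, truth = truth, config = config)
}

make_barcodes <- function(n, len) {
  # fixed length, hence trivially prefix-free; pairwise Hamming >= 2 so a
  # single substitution can never turn one valid barcode into another
  out <- character(0)
  while (length(out) < n) {
    cand <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                  collapse = "")
    if (all(vapply(out, function(b) hamming(b, cand) >= 2, logical(1))))
      out <- c(out, cand)
  }
  out
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

corrupt_barcode <- function(bc, valid) {
  repeat {
    chars <- strsplit(bc, "")[[1]]
    i <- sample(length(chars), 1)
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
    out <- paste(chars, collapse = "")
    if (!(out %in% valid)) return(out)
  }
}

#' Write simulated reads and barcode map to disk
#'
#' Writes a 4-line-record Phred+33 FASTQ (all qualities `I`) and a
#' two-column barcode TSV.
#'
#' @param reads_sim result of [simulate_gbs_reads()].
#' @param dir output directory.
#' @return invisible named paths (`fastq`, `barcodes`).
#' @export
write_gbs_files <- function(reads_sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fq <- file.path(dir, "reads.fastq")
  tsv <- file.path(dir, "barcodes.tsv")
  sr <- Biostrings::DNAStringSet(reads_sim$reads$sequence)
  names(sr) <- reads_sim$reads$read_id
  qual <- Biostrings::BStringSet(strrep("I", Biostrings::width(sr)))
  qs <- Biostrings::QualityScaledDNAStringSet(
    sr, Biostrings::PhredQuality(qual))
  Biostrings::writeQualityScaledXStringSet(qs, fq)
  utils::write.table(reads_sim$barcodes, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(fastq = fq, barcodes = tsv))
}
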