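#' Simulate a toy genome with gene models and planted msGBS tags
#'
#' Builds a random chromosome carrying regularly spaced three-exon genes
#' (alternating strands) and plants one 64-mer tag per genomic compartment
#' around each gene: exon, intron, upstream within 5 kb of the strand-aware
#' TSS, downstream within 5 kb of the TTS, and intergenic (> 5 kb from any
#' gene).  Every tag starts with the CGG MspI cut-site remnant; a subset is
#' planted in reverse-complement orientation.  The layout guarantees
#' placements never overlap and that each tag occurs exactly once.
#'
#' @param config a [sim_config()] object; `n_tags` tags are planted.
#' @return list with `genome` (a [Biostrings::DNAStringSet] of one
#'   chromosome), `gff` (a `GRanges` of gene/mRNA/exon features, 1-based,
#'   exportable as GFF3), `genes` (`data.frame`, 0-based half-open), and
#'   `planted` (`data.frame`: `tag_id`, `sequence`, `chrom`, `start`, `end`
#'   0-based half-open, `strand`, `compartment`, `gene_id`, `distance`).
#' @export
simulate_toy_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seed(config$seed, 37))
  nt <- config$n_tags
  tlen <- config$tag_length
  exon_w <- 400L; intron_w <- 800L
  gene_w <- 3L * exon_w + 2L * intron_w
  spacer <- 12000L
  block <- 2L * spacer + gene_w
  n_blocks <- ceiling(nt / 5)
  chrom_len <- n_blocks * block + spacer
  if (chrom_len < nt * tlen)
    stop(sprintf("cannot place %d tags: placed 0", nt))

  genome <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)

  # unique tag sequences: CGG remnant + random body
  tag_ids <- sprintf("tag_%05d", seq_len(nt))
  body <- replicate(nt, paste(sample(c("A", "C", "G", "T"), tlen - 3,
                                     replace = TRUE), collapse = ""))
  while (anyDuplicated(body)) {
    i <- which(duplicated(body))
    body[i] <- replicate(length(i), paste(sample(c("A", "C", "G", "T"),
                                                 tlen - 3, replace = TRUE),
                                          collapse = ""))
  }
  tag_seq <- paste0("CGG", body)

  compartments <- c("exon", "intron", "upstream_5kb", "downstream_5kb",
                    "intergenic")
  genes <- data.frame(gene_id = sprintf("gene_%03d", seq_len(n_blocks)),
                      start = integer(n_blocks), end = integer(n_blocks),
                      strand = rep(c("+", "-"), length.out = n_blocks),
                      stringsAsFactors = FALSE)
  planted <- vector("list", nt)
  revcomp_chr <- function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }

  for (b in seq_len(n_blocks)) {
    B <- (b - 1L) * block
    gs <- B + spacer          # 0-based gene start
    ge <- gs + gene_w
    genes$start[b] <- gs
    genes$end[b] <- ge
    gstrand <- genes$strand[b]
    for (slot in seq_len(5)) {
      i <- (b - 1L) * 5L + slot
      if (i > nt) break
      comp <- compartments[slot]
      d <- NA_integer_
      if (comp == "exon") {
        hs <- gs + exon_w + intron_w + 100L   # inside exon 2
        d <- 0L
      } else if (comp == "intron") {
        hs <- gs + exon_w + 200L              # inside intron 1
        d <- 0L
      } else if (comp == "upstream_5kb") {
        d <- sample(0:5000, 1)
        hs <- if (gstrand == "+") gs - d - tlen else ge + d
      } else if (comp == "downstream_5kb") {
        d <- sample(0:5000, 1)
        hs <- if (gstrand == "+") ge + d else gs - d - tlen
      } else { # intergenic: > 5 kb from this gene, far from neighbours
        hs <- ge + 5500L + sample(0:500, 1)
        if (gstrand == "-") hs <- gs - 5500L - tlen - sample(0:500, 1)
      }
      orient <- if (i %% 7 == 0) "-" else "+"
      seq_in <- if (orient == "+") tag_seq[i] else revcomp_chr(tag_seq[i])
      genome[(hs + 1L):(hs + tlen)] <- strsplit(seq_in, "")[[1]]
      planted[[i]] <- data.frame(
        tag_id = tag_ids[i], sequence = tag_seq[i], chrom = "chr1",
        start = hs, end = hs + tlen, strand = orient, compartment = comp,
        gene_id = if (comp == "intergenic") NA_character_ else
          genes$gene_id[b],
        distance = if (comp == "intergenic") NA_integer_ else d,
        stringsAsFactors = FALSE
      )
    }
  }
  planted <- do.call(rbind, planted)

  genome_ss <- Biostrings::DNAStringSet(paste(genome, collapse = ""))
  names(genome_ss) <- "chr1"

  gff <- build_gene_gff(genes, exon_w, intron_w, chrom_len)
  list(genome = genome_ss, gff = gff, genes = genes, planted = planted,
       config = config)
}

# gene/mRNA/exon GRanges (1-based inclusive) for a three-exon gene layout
build_gene_gff <- function(genes, exon_w, intron_w, chrom_len) {
  feats <- list()
  for (b in seq_len(nrow(genes))) {
    gs1 <- genes$start[b] + 1L # 1-based
    ge1 <- genes$end[b]
    gid <- genes$gene_id[b]
    ex_starts <- gs1 + (0:2) * (exon_w + intron_w)
    ex_ends <- ex_starts + exon_w - 1L
    feats[[b]] <- data.frame(
      start = c(gs1, gs1, ex_starts), end = c(ge1, ge1, ex_ends),
      type = c("gene", "mRNA", rep("exon", 3)),
      strand = genes$strand[b],
      ID = c(gid, paste0(gid, ".1"), paste0(gid, ".1.exon", 1:3)),
      Parent = c(NA, gid, rep(paste0(gid, ".1"), 3)),
      stringsAsFactors = FALSE
    )
  }
  tab <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(
    seqnames = "chr1",
    ranges = IRanges::IRanges(start = tab$start, end = tab$end),
    strand = tab$strand, type = tab$type, ID = tab$ID, Parent = tab$Parent
  )
  GenomeInfoDb::seqlengths(gr) <- c(chr1 = chrom_len)
  gr
}

#' Write a simulated genome to FASTA and GFF3
#'
#' @param genome_sim result of [simulate_toy_genome()].
#' @param dir output directory (created if needed).
#' @return invisible named paths of the written `genome.fasta` and
#'   `genes.gff3`.
#' @export
write_genome_files <- function(genome_sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fasta")
  gff <- file.path(dir, "genes.gff3")
  Biostrings::writeXStringSet(genome_sim$genome, fa, width = 60)
  rtracklayer::export(genome_sim$gff, gff, format = "gff3")
  invisible(c(fasta = fa, gff3 = gff))
}
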