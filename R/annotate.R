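#' Locate tag sequences on a genome by exact matching
#'
#' Reports every exact occurrence of each tag and of its reverse
#' complement.  At 64 nt an exact search is the dependency-free equivalent
#' of a stringent nucleotide BLAST for perfectly matching tags; users with
#' their own alignment results can feed an equivalent hit table straight
#' into [annotate_hits()].
#'
#' @param tags named character vector, `DNAStringSet`, or FASTA path.
#' @param genome `DNAStringSet` or FASTA path.
#' @return `data.frame` of hits: `tag_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand` (`+` forward, `-` reverse complement),
#'   `match_type`, `multi_hit` flag.  Tags containing ambiguity codes are
#'   skipped with a warning.
#' @export
locate_tags <- function(tags, genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (is.character(tags) && length(tags) == 1 && file.exists(tags))
    tags <- Biostrings::readDNAStringSet(tags)
  tags <- setNames(as.character(tags),
                   names(tags) %||% paste0("tag_", seq_along(tags)))
  names(genome) <- sub("\\s.*$", "", names(genome))
  amb <- grepl("[^ACGT]", tags)
  if (any(amb)) {
    warning(sprintf("%d tag(s) with ambiguity codes skipped", sum(amb)))
    tags <- tags[!amb]
  }
  hits <- list()
  for (ti in seq_along(tags)) {
    pat <- Biostrings::DNAString(tags[[ti]])
    rcp <- Biostrings::reverseComplement(pat)
    for (ch in names(genome)) {
      for (ori in c("+", "-")) {
        mm <- Biostrings::matchPattern(if (ori == "+") pat else rcp,
                                       genome[[ch]])
        if (length(mm) == 0) next
        hits[[length(hits) + 1]] <- data.frame(
          tag_id = names(tags)[ti], chrom = ch,
          start = Biostrings::start(mm) - 1L,
          end = Biostrings::end(mm), strand = ori,
          match_type = if (ori == "+") "exact_forward" else
            "exact_revcomp",
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(hits) == 0)
    return(data.frame(tag_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), match_type = character(0),
                      multi_hit = logical(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out$multi_hit <- out$tag_id %in% out$tag_id[duplicated(out$tag_id)]
  rownames(out) <- NULL
  out
}

# normalize gene models to 0-based half-open tables of genes and exons
read_gene_models <- function(gff) {
  if (is.character(gff) && length(gff) == 1 && file.exists(gff))
    gff <- rtracklayer::import(gff, format = "gff3")
  if (methods::is(gff, "GRanges")) {
    tab <- data.frame(
      seqid = as.character(GenomicRanges::seqnames(gff)),
      start = GenomicRanges::start(gff),
      end = GenomicRanges::end(gff),
      strand = as.character(GenomicRanges::strand(gff)),
      type = as.character(gff$type),
      ID = as.character(gff$ID),
      Parent = vapply(as.list(gff$Parent %||% gff$Parent),
                      function(p) if (length(p)) as.character(p)[1] else
                        NA_character_, character(1)),
      stringsAsFactors = FALSE
    )
  } else tab <- as.data.frame(gff, stringsAsFactors = FALSE)
  bad <- tab$end < tab$start
  if (any(bad)) {
    warning(sprintf("%d malformed record(s) with end < start rejected",
                    sum(bad)))
    tab <- tab[!bad, , drop = FALSE]
  }
  genes <- tab[tab$type == "gene", , drop = FALSE]
  mrna <- tab[tab$type == "mRNA", , drop = FALSE]
  exons <- tab[tab$type == "exon", , drop = FALSE]
  # exon Parent is an mRNA; map through to the gene
  m2g <- setNames(mrna$Parent, mrna$ID)
  exons$gene_id <- ifelse(exons$Parent %in% names(m2g),
                          m2g[exons$Parent], exons$Parent)
  list(
    genes = data.frame(gene_id = genes$ID, chrom = genes$seqid,
                       start = genes$start - 1L, end = genes$end,
                       strand = genes$strand, stringsAsFactors = FALSE),
    exons = data.frame(gene_id = exons$gene_id, chrom = exons$seqid,
                       start = exons$start - 1L, end = exons$end,
                       stringsAsFactors = FALSE)
  )
}

#' Classify tag hits relative to gene models
#'
#' Overlap with an exon gives class `exon`; overlap with the gene body but
#' no exon gives `intron`; otherwise a hit lying within `window` bp
#' upstream of the strand-aware TSS (or downstream of the TTS) is
#' `upstream_5kb` (`downstream_5kb`), boundaries inclusive at exactly
#' `window`; anything else is `intergenic`.  The nearest qualifying gene
#' wins; ties break by smaller distance, then lexicographic gene id.
#' Distance is the gap in bp between the hit and the gene body (0 when
#' overlapping).
#'
#' @param hits hit table from [locate_tags()] (or an external table with
#'   `tag_id`, `chrom`, `start`, `end`, `strand`; 0-based half-open).
#' @param gff gene models: GFF3 path, `GRanges`, or a data.frame with
#'   columns `seqid`, `start`, `end` (1-based inclusive), `strand`,
#'   `type`, `ID`, `Parent`.
#' @param window flank width in bp (default 5000).
#' @return `hits` with added `gene_id`, `feature_class`, `distance`.
#' @export
annotate_hits <- function(hits, gff, window = 5000) {
  gm <- read_gene_models(gff)
  genes <- gm$genes
  exons <- gm$exons
  n <- nrow(hits)
  gene_id <- rep(NA_character_, n)
  fclass <- rep("intergenic", n)
  dist <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    hs <- hits$start[i]; he <- hits$end[i]; ch <- hits$chrom[i]
    g <- genes[genes$chrom == ch, , drop = FALSE]
    if (nrow(g) == 0) next
    ov <- g$start < he & g$end > hs
    if (any(ov)) {
      cand <- g[ov, , drop = FALSE]
      cls <- vapply(cand$gene_id, function(gid) {
        ex <- exons[exons$gene_id == gid & exons$chrom == ch, ,
                    drop = FALSE]
        if (any(ex$start < he & ex$end > hs)) "exon" else "intron"
      }, character(1))
      ord <- order(cls != "exon", cand$gene_id)
      gene_id[i] <- cand$gene_id[ord[1]]
      fclass[i] <- cls[ord[1]]
      dist[i] <- 0L
      next
    }
    # flanks: gap to the gene body, classified by the gene's strand
    up_d <- ifelse(g$strand == "+", g$start - he, hs - g$end)
    dn_d <- ifelse(g$strand == "+", hs - g$end, g$start - he)
    cand <- data.frame(gene_id = g$gene_id, stringsAsFactors = FALSE)
    cand$class <- NA_character_
    cand$d <- NA_integer_
    is_up <- up_d >= 0 & up_d <= window
    is_dn <- dn_d >= 0 & dn_d <= window
    cand$class[is_dn] <- "downstream_5kb"
    cand$d[is_dn] <- dn_d[is_dn]
    cand$class[is_up] <- "upstream_5kb" # a 0-width gene can't be both
    cand$d[is_up] <- up_d[is_up]
    cand <- cand[!is.na(cand$class), , drop = FALSE]
    if (nrow(cand) == 0) next
    cand <- cand[order(cand$d, cand$gene_id), , drop = FALSE]
    gene_id[i] <- cand$gene_id[1]
    fclass[i] <- cand$class[1]
    dist[i] <- cand$d[1]
  }
  hits$gene_id <- gene_id
  hits$feature_class <- fclass
  hits$distance <- dist
  hits
}

#' Write tag hits as BED6
#'
#' 0-based half-open intervals, name = tag id, score 0.
#'
#' @param hits hit table from [locate_tags()].
#' @param path output file.
#' @return invisible `path`.
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(hits$chrom, hits$start, hits$end, hits$tag_id, 0,
                    hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
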