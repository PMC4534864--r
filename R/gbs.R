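#' Load and validate a barcode map
#'
#' @param path two-column TSV (barcode, sample_id), no header.
#' @return `data.frame` with columns `barcode`, `sample_id`.  Duplicate
#'   barcodes or a barcode that is a prefix of another are rejected: under
#'   exact-prefix demultiplexing such maps are ambiguous.
#' @export
read_barcode_map <- function(path) {
  bm <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("barcode", "sample_id"))
  validate_barcode_map(bm)
}

validate_barcode_map <- function(bm) {
  stopifnot(all(c("barcode", "sample_id") %in% names(bm)))
  if (anyDuplicated(bm$barcode)) stop("duplicate barcodes in map")
  if (anyDuplicated(bm$sample_id)) stop("duplicate sample ids in map")
  bc <- bm$barcode
  for (i in seq_along(bc)) {
    pre <- startsWith(bc[-i], bc[i])
    if (any(pre))
      stop(sprintf("barcode '%s' is a prefix of '%s': ambiguous map",
                   bc[i], bc[-i][pre][1]))
  }
  bm
}

#' Demultiplex msGBS reads by exact barcode and MspI cut-site remnant
#'
#' A read is assigned to a sample iff it starts with that sample's exact
#' barcode immediately followed by the `CGG` left by MspI digestion.  The
#' barcode is removed and the remainder truncated to `tag_len` nucleotides
#' (so every tag keeps the leading CGG); reads whose remainder is shorter
#' than `tag_len` are rejected.  No mismatches are tolerated anywhere.
#'
#' @param reads character vector of read sequences, or a path to a FASTQ
#'   file (read via Biostrings; gzip supported).
#' @param barcode_map `data.frame` (`barcode`, `sample_id`) or a TSV path;
#'   validated with [read_barcode_map()] rules.
#' @param tag_len tag length after barcode removal (default 64).
#' @return list with `tags` (per-sample character vectors of tag
#'   sequences), and `log`: counts `n_input`, `n_retained`, and rejected
#'   `bad_barcode`, `bad_cutsite`, `too_short` (these always sum to
#'   `n_input`).
#' @export
demultiplex <- function(reads, barcode_map, tag_len = 64) {
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- as.character(Biostrings::readDNAStringSet(reads,
                                                       format = "fastq"))
  reads <- unname(as.character(reads))
  if (is.character(barcode_map) && length(barcode_map) == 1)
    barcode_map <- read_barcode_map(barcode_map)
  bm <- validate_barcode_map(barcode_map)

  assigned <- rep(NA_integer_, length(reads))
  for (i in seq_len(nrow(bm))) { # prefix-free map: at most one can match
    hit <- is.na(assigned) & startsWith(reads, bm$barcode[i])
    assigned[hit] <- i
  }
  bad_barcode <- sum(is.na(assigned))
  ok <- which(!is.na(assigned))
  blen <- nchar(bm$barcode)[assigned[ok]]
  rest <- substring(reads[ok], blen + 1)
  cut_ok <- startsWith(rest, "CGG")
  bad_cutsite <- sum(!cut_ok)
  ok2 <- ok[cut_ok]
  rest <- rest[cut_ok]
  long_enough <- nchar(rest) >= tag_len
  too_short <- sum(!long_enough)
  tags_seq <- substring(rest[long_enough], 1, tag_len)
  sample <- bm$sample_id[assigned[ok2][long_enough]]
  tags <- split(tags_seq, factor(sample, levels = bm$sample_id))
  log <- list(n_input = length(reads), n_retained = length(tags_seq),
              bad_barcode = bad_barcode, bad_cutsite = bad_cutsite,
              too_short = too_short)
  list(tags = tags, log = log)
}

#' Build the tag x sample abundance matrix
#'
#' @param tag_streams per-sample character vectors of tag sequences (the
#'   `tags` element of [demultiplex()]).
#' @return integer matrix, rows = distinct tag sequences in lexicographic
#'   order, columns = samples, cells = occurrence counts.
#' @export
build_matrix <- function(tag_streams) {
  all_tags <- sort(unique(unlist(tag_streams, use.names = FALSE)))
  m <- matrix(0L, length(all_tags), length(tag_streams),
              dimnames = list(all_tags, names(tag_streams)))
  for (s in names(tag_streams)) {
    tb <- table(tag_streams[[s]])
    if (length(tb) > 0) m[names(tb), s] <- as.integer(tb)
  }
  m
}

#' Apply the negative-control and prevalence filters
#'
#' Drops every tag observed (count > 0) in the negative water control, then
#' every tag present in fewer than `min_samples` distinct non-control
#' samples (>= is inclusive); finally removes the control column.
#'
#' @param m tag x sample count matrix.
#' @param negative_control_sample column name of the water control; if
#'   absent, the control filter is skipped with a warning.
#' @param min_samples minimal number of non-control samples a tag must
#'   appear in (default 3).
#' @param control_first apply the control filter before the prevalence
#'   filter (default) or after.
#' @return filtered matrix without the control column; the number of tags
#'   removed by each filter is in `attr(, "filter_log")`.
#' @export
filter_matrix <- function(m, negative_control_sample = "water_control",
                          min_samples = 3, control_first = TRUE) {
  has_ctl <- negative_control_sample %in% colnames(m)
  if (!has_ctl)
    warning(sprintf("control column '%s' absent: control filter skipped",
                    negative_control_sample))
  drop_control <- function(mm) {
    if (!has_ctl) return(list(m = mm, removed = 0L))
    bad <- mm[, negative_control_sample] > 0
    list(m = mm[!bad, , drop = FALSE], removed = sum(bad))
  }
  drop_rare <- function(mm) {
    cols <- setdiff(colnames(mm), negative_control_sample)
    nsamp <- rowSums(mm[, cols, drop = FALSE] > 0)
    bad <- nsamp < min_samples
    list(m = mm[!bad, , drop = FALSE], removed = sum(bad))
  }
  if (control_first) {
    a <- drop_control(m); b <- drop_rare(a$m)
    out <- b$m; logv <- c(control = a$removed, min_samples = b$removed)
  } else {
    a <- drop_rare(m); b <- drop_control(a$m)
    out <- b$m; logv <- c(min_samples = a$removed, control = b$removed)
  }
  out <- out[, setdiff(colnames(out), negative_control_sample),
             drop = FALSE]
  attr(out, "filter_log") <- logv
  out
}
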