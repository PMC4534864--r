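#' Read and write MSAP peak tables
#'
#' Peak tables are plain CSV with columns `sample_id`, `enzyme`, `size_bp`,
#' `height` (one row per sized peak, the shape of a fragment-analysis
#' export).
#'
#' @param path CSV file.
#' @return `data.frame` of peaks.
#' @export
read_peak_table <- function(path) {
  pk <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "enzyme", "size_bp", "height")
  if (!all(need %in% names(pk)))
    stop("peak table needs columns sample_id, enzyme, size_bp, height")
  if (any(pk$size_bp <= 0) || any(pk$height < 0))
    stop("size_bp must be > 0 and height >= 0")
  pk
}

#' @rdname read_peak_table
#' @param peaks peak `data.frame`.
#' @export
write_peak_table <- function(peaks, path) {
  write.csv(peaks, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an epilocus matrix as CSV with a two-row header
#'
#' Row 1 carries the enzyme per locus, row 2 the bin center (bp); data rows
#' are samples.
#'
#' @param m `epilocus_matrix` or `height_matrix`.
#' @param path output CSV.
#' @export
write_epilocus_matrix <- function(m, path) {
  loci <- attr(m, "loci")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("enzyme", loci$enzyme), collapse = ","), con)
  writeLines(paste(c("size", loci$center), collapse = ","), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i], m[i, ]), collapse = ","), con)
  invisible(path)
}

#' @rdname write_epilocus_matrix
#' @export
read_epilocus_matrix <- function(path) {
  lines <- readLines(path)
  hdr1 <- strsplit(lines[1], ",")[[1]]
  hdr2 <- strsplit(lines[2], ",")[[1]]
  body <- strsplit(lines[-(1:2)], ",")
  samples <- vapply(body, `[[`, character(1), 1)
  vals <- t(vapply(body, function(x) as.numeric(x[-1]),
                   numeric(length(hdr1) - 1)))
  loci <- data.frame(enzyme = hdr1[-1],
                     center = as.numeric(hdr2[-1]),
                     stringsAsFactors = FALSE)
  loci$bin_id <- make.unique(sprintf("%s_%.2f", loci$enzyme, loci$center))
  dimnames(vals) <- list(samples, loci$bin_id)
  structure(vals, loci = loci[, c("enzyme", "bin_id", "center")],
            class = c("epilocus_matrix", class(vals)))
}

#' Write a sparse tag count matrix as MatrixMarket with sidecars
#'
#' Writes `<prefix>.mtx` plus `<prefix>.tags.txt` and
#' `<prefix>.samples.txt` naming the rows and columns.
#'
#' @param m tag x sample count matrix.
#' @param prefix path prefix.
#' @return invisible named paths.
#' @export
write_count_mtx <- function(m, prefix) {
  sm <- methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix")
  mtx <- paste0(prefix, ".mtx")
  Matrix::writeMM(sm, mtx)
  writeLines(rownames(m), paste0(prefix, ".tags.txt"))
  writeLines(colnames(m), paste0(prefix, ".samples.txt"))
  invisible(c(mtx = mtx, tags = paste0(prefix, ".tags.txt"),
              samples = paste0(prefix, ".samples.txt")))
}

#' @rdname write_count_mtx
#' @export
read_count_mtx <- function(prefix) {
  m <- as.matrix(Matrix::readMM(paste0(prefix, ".mtx")))
  dimnames(m) <- list(readLines(paste0(prefix, ".tags.txt")),
                      readLines(paste0(prefix, ".samples.txt")))
  storage.mode(m) <- "integer"
  m
}

#' Write tag sequences as FASTA
#'
#' @param tags named character vector of sequences.
#' @param path output FASTA (60-column wrap).
#' @export
write_tag_fasta <- function(tags, path) {
  ss <- Biostrings::DNAStringSet(unname(tags))
  names(ss) <- names(tags) %||% paste0("tag_", seq_along(tags))
  Biostrings::writeXStringSet(ss, path, width = 60)
  invisible(path)
}

# CSV writer with a reproducibility header (config hash + seed)
write_result_csv <- function(df, path, hash = NULL, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(hash))
    writeLines(sprintf("# config_hash=%s seed=%s", hash,
                       format(seed %||% NA)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}
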