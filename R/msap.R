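#' Build a locus catalog from sized MSAP peaks
#'
#' Clusters fragment sizes per enzyme by single linkage (a new bin starts
#' whenever the gap to the previous size exceeds `tolerance_bp`), then
#' enforces the rule that two peaks of one sample never share a bin: within
#' a cluster, a sample's tallest peak stays in the first bin and the losers
#' spill into the next bin (recursively).  Bin centers are the mean of
#' member sizes; catalog order is by size.
#'
#' @param records `data.frame` of peaks with columns `sample_id`, `enzyme`,
#'   `size_bp`, `height`.
#' @param tolerance_bp single-linkage gap (> 0), default 0.5 bp.
#' @return `data.frame` catalog (`enzyme`, `bin_id`, `center`) with the
#'   tolerance stored in `attr(, "tolerance_bp")`; empty for empty input.
#' @export
bin_peaks <- function(records, tolerance_bp = 0.5) {
  if (tolerance_bp <= 0) stop("tolerance_bp must be > 0")
  if (is.null(records) || nrow(records) == 0) {
    out <- data.frame(enzyme = character(0), bin_id = character(0),
                      center = numeric(0), stringsAsFactors = FALSE)
    attr(out, "tolerance_bp") <- tolerance_bp
    return(out)
  }
  stopifnot(all(records$size_bp > 0), all(records$height >= 0))
  out <- lapply(split(records, records$enzyme), function(r) {
    r <- r[order(r$size_bp, r$sample_id, -r$height), , drop = FALSE]
    gap <- c(Inf, diff(r$size_bp))
    cluster <- cumsum(gap > tolerance_bp)
    centers <- unlist(lapply(split(r, cluster), function(cl) {
      split_same_sample_bins(cl)
    }), use.names = FALSE)
    data.frame(enzyme = r$enzyme[1],
               center = sort(centers), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out$bin_id <- make.unique(sprintf("%s_%.2f", out$enzyme, out$center))
  out <- out[, c("enzyme", "bin_id", "center")]
  attr(out, "tolerance_bp") <- tolerance_bp
  out
}

# split one single-linkage cluster so no sample appears twice in a bin;
# per sample the tallest stays in the earliest bin, the rest cascade
split_same_sample_bins <- function(cl) {
  centers <- numeric(0)
  remaining <- cl[order(-cl$height, cl$size_bp), , drop = FALSE]
  while (nrow(remaining) > 0) {
    take <- !duplicated(remaining$sample_id)
    centers <- c(centers, mean(remaining$size_bp[take]))
    remaining <- remaining[!take, , drop = FALSE]
  }
  centers
}

assign_bins <- function(records, catalog) {
  tol <- attr(catalog, "tolerance_bp") %||% 0.5
  idx <- rep(NA_integer_, nrow(records))
  for (ez in unique(records$enzyme)) {
    cat_e <- which(catalog$enzyme == ez)
    if (length(cat_e) == 0) next
    sel <- which(records$enzyme == ez)
    ctr <- catalog$center[cat_e]
    near <- findInterval(records$size_bp[sel],
                         c(-Inf, ctr[-length(ctr)] + diff(ctr) / 2, Inf))
    ok <- abs(records$size_bp[sel] - ctr[near]) <= tol + 1e-9
    idx[sel[ok]] <- cat_e[near[ok]]
  }
  idx
}

#' Score binary presence/absence epilocus matrices
#'
#' Assigns each peak to its nearest catalog bin, keeps bins whose center
#' lies inside the closed `size_window` (default 100-580 bp, limiting size
#' homoplasy), and scores a cell 1 when the sample has at least one peak in
#' the bin with height above `presence_threshold`.
#'
#' @param records peak `data.frame` (`sample_id`, `enzyme`, `size_bp`,
#'   `height`).
#' @param catalog result of [bin_peaks()].
#' @param metadata optional sample metadata; samples listed there but absent
#'   from `records` get all-zero rows with a warning.
#' @param size_window closed interval of admissible bin centers (bp).
#' @param presence_threshold a peak counts as present when `height >`
#'   this value (default 0).
#' @return an `epilocus_matrix`: integer 0/1 matrix, samples x loci, with a
#'   `loci` attribute (`data.frame` of `enzyme`, `bin_id`, `center`).
#' @export
score_binary <- function(records, catalog, metadata = NULL,
                         size_window = c(100, 580),
                         presence_threshold = 0) {
  keep <- catalog$center >= size_window[1] & catalog$center <= size_window[2]
  cat_w <- catalog[keep, , drop = FALSE]
  attr(cat_w, "tolerance_bp") <- attr(catalog, "tolerance_bp")
  samples <- if (!is.null(metadata)) metadata$sample_id else
    sort(unique(records$sample_id))
  missing <- setdiff(samples, unique(records$sample_id))
  if (length(missing) > 0)
    warning(sprintf("samples without peaks scored all-zero: %s",
                    paste(missing, collapse = ", ")))
  m <- matrix(0L, length(samples), nrow(cat_w),
              dimnames = list(samples, cat_w$bin_id))
  idx <- assign_bins(records, cat_w)
  hit <- !is.na(idx) & records$height > presence_threshold &
    records$sample_id %in% samples
  if (any(hit))
    m[cbind(match(records$sample_id[hit], samples), idx[hit])] <- 1L
  structure(m, loci = cat_w[, c("enzyme", "bin_id", "center")],
            class = c("epilocus_matrix", class(m)))
}

#' Build the quantitative peak-height matrix
#'
#' Sums peak heights per sample and bin (robust to split peaks), keeps bins
#' with centers inside the closed `size_window` (default 50-550 bp), then
#' removes epiloci with excessively low intensity across all samples
#' according to `low_filter`.
#'
#' @inheritParams score_binary
#' @param low_filter list with `type` (`"mean"` or `"total"`) and `min`:
#'   loci whose mean (or total) height across samples is below `min` are
#'   dropped.  Default keeps everything with any signal
#'   (`list(type = "total", min = .Machine$double.eps)`).
#' @return a `height_matrix` (samples x loci, non-negative) with a `loci`
#'   attribute.
#' @export
build_height_matrix <- function(records, catalog, metadata = NULL,
                                size_window = c(50, 550),
                                low_filter = list(type = "total",
                                                  min = .Machine$double.eps)) {
  keep <- catalog$center >= size_window[1] & catalog$center <= size_window[2]
  cat_w <- catalog[keep, , drop = FALSE]
  attr(cat_w, "tolerance_bp") <- attr(catalog, "tolerance_bp")
  samples <- if (!is.null(metadata)) metadata$sample_id else
    sort(unique(records$sample_id))
  m <- matrix(0, length(samples), nrow(cat_w),
              dimnames = list(samples, cat_w$bin_id))
  idx <- assign_bins(records, cat_w)
  ok <- !is.na(idx) & records$sample_id %in% samples
  if (any(ok)) {
    ij <- cbind(match(records$sample_id[ok], samples), idx[ok])
    for (r in which(ok)) # sum ties within a bin
      m[match(records$sample_id[r], samples), idx[r]] <-
        m[match(records$sample_id[r], samples), idx[r]] + records$height[r]
  }
  stat <- switch(low_filter$type,
                 mean = colMeans(m), total = colSums(m),
                 stop("low_filter$type must be 'mean' or 'total'"))
  keep2 <- stat >= low_filter$min
  m <- m[, keep2, drop = FALSE]
  structure(m, loci = cat_w[keep2, c("enzyme", "bin_id", "center")],
            class = c("height_matrix", class(m)))
}

#' Match loci across the two enzyme catalogs
#'
#' Pairs HpaII and MspI bins whose centers agree within `tolerance`
#' (greedy nearest-neighbour on sorted centers, one-to-one).
#'
#' @param hpa,msp `epilocus_matrix` objects for HpaII and MspI.
#' @param tolerance maximal center difference (bp) for a cross-enzyme match;
#'   defaults to the binning tolerance of `hpa`.
#' @return `data.frame` with `hpa_col`, `msp_col` (column indices; `NA` when
#'   unmatched) and `center`.
#' @export
match_loci <- function(hpa, msp, tolerance = NULL) {
  tol <- tolerance %||% attr(attr(hpa, "loci"), "tolerance_bp") %||% 0.5
  ch <- attr(hpa, "loci")$center
  cm <- attr(msp, "loci")$center
  used <- logical(length(cm))
  pair <- rep(NA_integer_, length(ch))
  for (i in order(ch)) {
    cand <- which(!used & abs(cm - ch[i]) <= tol)
    if (length(cand) > 0) {
      j <- cand[which.min(abs(cm[cand] - ch[i]))]
      pair[i] <- j
      used[j] <- TRUE
    }
  }
  shared <- data.frame(hpa_col = seq_along(ch), msp_col = pair,
                       center = ch, stringsAsFactors = FALSE)
  only_msp <- which(!used)
  if (length(only_msp) > 0)
    shared <- rbind(shared,
                    data.frame(hpa_col = NA_integer_, msp_col = only_msp,
                               center = cm[only_msp]))
  shared[order(shared$center), , drop = FALSE]
}

#' Classify matched loci as epigenetic-only or genetic-or-epigenetic
#'
#' A locus polymorphic between the two groups in exactly one enzyme can
#' only reflect a methylation difference; polymorphism in both enzymes may
#' be genetic or epigenetic; no group difference in either enzyme is
#' monomorphic.  "Polymorphic" means the group presence frequencies differ
#' by more than `min_freq_diff`.
#'
#' @inheritParams match_loci
#' @param groups two-level factor/character vector aligned with the rows of
#'   both matrices.
#' @param min_freq_diff minimal group frequency difference to call an
#'   enzyme polymorphic (default 0, i.e. any difference).
#' @return `data.frame` of matched loci with per-enzyme polymorphism flags
#'   and `origin` in `{epigenetic_only, genetic_or_epigenetic, monomorphic}`.
#' @export
classify_marker_origin <- function(hpa, msp, groups, tolerance = NULL,
                                   min_freq_diff = 0) {
  if (!identical(rownames(hpa), rownames(msp)))
    stop("hpa and msp must cover the same samples in the same order")
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2) stop("exactly two groups required")
  pairs <- match_loci(hpa, msp, tolerance)
  pairs <- pairs[!is.na(pairs$hpa_col) & !is.na(pairs$msp_col), ,
                 drop = FALSE]
  poly <- function(m, col) {
    f1 <- mean(m[groups == lv[1], col])
    f2 <- mean(m[groups == lv[2], col])
    abs(f1 - f2) > min_freq_diff
  }
  ph <- vapply(pairs$hpa_col, function(j) poly(hpa, j), logical(1))
  pm <- vapply(pairs$msp_col, function(j) poly(msp, j), logical(1))
  origin <- ifelse(ph & pm, "genetic_or_epigenetic",
                   ifelse(ph | pm, "epigenetic_only", "monomorphic"))
  data.frame(center = pairs$center, hpa_polymorphic = ph,
             msp_polymorphic = pm, origin = origin,
             stringsAsFactors = FALSE)
}

#' Interpret a paired HpaII/MspI presence call as a methylation state
#'
#' Both enzymes cut unmethylated CCGG; MspI alone cuts when the internal
#' cytosine is methylated (CmCGG); HpaII alone cuts hemimethylated external
#' cytosine (mCCGG); absence in both is hypermethylation or a missing
#' fragment and cannot be interpreted further.
#'
#' @param hpa_present,msp_present 0/1 vectors (recycled to common length).
#' @return character vector of states: `unmethylated`, `internal_mC`,
#'   `hemi_external_mC`, `hypermethylated_or_absent`.
#' @export
call_methylation_state <- function(hpa_present, msp_present) {
  key <- paste(as.integer(hpa_present), as.integer(msp_present))
  map <- c("1 1" = "unmethylated", "0 1" = "internal_mC",
           "1 0" = "hemi_external_mC", "0 0" = "hypermethylated_or_absent")
  out <- unname(map[key])
  if (anyNA(out)) stop("presence calls must be 0 or 1")
  out
}

#' Partition loci by enzyme of detection
#'
#' @inheritParams match_loci
#' @return named numeric vector `n_unique_hpa`, `n_unique_msp`, `n_shared`,
#'   `n_total` (the total is the sum of the first three).
#' @export
enzyme_partition <- function(hpa, msp, tolerance = NULL) {
  pairs <- match_loci(hpa, msp, tolerance)
  shared <- sum(!is.na(pairs$hpa_col) & !is.na(pairs$msp_col))
  uh <- sum(!is.na(pairs$hpa_col) & is.na(pairs$msp_col))
  um <- sum(is.na(pairs$hpa_col) & !is.na(pairs$msp_col))
  c(n_unique_hpa = uh, n_unique_msp = um, n_shared = shared,
    n_total = uh + um + shared)
}
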