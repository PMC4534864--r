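#' Squared Euclidean distance between binary profiles
#'
#' For 0/1 marker data the squared Euclidean distance between two samples is
#' the number of loci at which they differ, the convention used for binary
#' AMOVA input.
#'
#' @param m samples x loci 0/1 matrix (an `epilocus_matrix` or plain
#'   matrix).
#' @return symmetric numeric matrix of pairwise squared distances with zero
#'   diagonal, sample names preserved.
#' @export
binary_distance <- function(m) {
  m <- unclass(m)
  d <- as.matrix(dist(m, method = "euclidean"))^2
  round(d, 9)
}

phipt_components <- function(d, groups) {
  n <- nrow(d)
  g <- split(seq_len(n), groups)
  k <- length(g)
  ng <- lengths(g)
  ssd_total <- sum(d[upper.tri(d)]) / n
  ssd_within <- sum(vapply(g, function(i) {
    if (length(i) < 2) return(0)
    di <- d[i, i, drop = FALSE]
    sum(di[upper.tri(di)]) / length(i)
  }, numeric(1)))
  ssd_among <- ssd_total - ssd_within
  df_among <- k - 1
  df_within <- n - k
  msw <- if (df_within > 0) ssd_within / df_within else 0
  msa <- if (df_among > 0) ssd_among / df_among else 0
  n0 <- (n - sum(ng^2) / n) / df_among
  va <- (msa - msw) / n0
  if (!is.finite(va) || va < 0) va <- 0 # GenAlex-style truncation
  vw <- msw
  phipt <- if (va + vw <= 0) 0 else va / (va + vw)
  list(ssd_total = ssd_total, ssd_within = ssd_within,
       ssd_among = ssd_among, df_among = df_among, df_within = df_within,
       sigma2_among = va, sigma2_within = vw, phipt = phipt)
}

#' PhiPT from distance-based AMOVA with a permutation test
#'
#' Partitions the total sum of squared distances into among- and
#' within-group components (unequal group sizes handled through the
#' standard n0 coefficient), truncates a negative among-group component at
#' zero, and reports PhiPT = Va / (Va + Vw).  Significance comes from
#' permuting the group labels: with sampled permutations the p-value uses
#' the add-one correction `(b + 1) / (n_perm + 1)`; for two groups whose
#' distinct label assignments number at most `n_perm`, all assignments are
#' enumerated instead and the p-value is the exact tail fraction.
#'
#' @param d symmetric squared-distance matrix (see [binary_distance()]).
#' @param groups group label per sample (>= 2 groups, each non-empty).
#' @param n_perm number of label permutations (default 999).
#' @param seed optional seed controlling the permutations.
#' @return object of class `amova_result`: variance components, `phipt`,
#'   `p_value`, `n_perm` (actual draws or enumerated assignments),
#'   `exact` flag and degrees of freedom.
#' @export
amova_phipt <- function(d, groups, n_perm = 999, seed = NULL) {
  d <- as.matrix(d)
  stopifnot(nrow(d) == ncol(d), nrow(d) == length(groups))
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2) stop("need >= 2 groups")
  if (any(tab == 0)) stop("a group has no samples")
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  obs <- phipt_components(d, groups)

  n <- nrow(d)
  exact <- FALSE
  if (length(tab) == 2 && choose(n, tab[1]) <= n_perm) {
    # exhaustive enumeration of the distinct two-group assignments
    lv <- names(tab)
    combos <- combn(n, tab[[1]])
    stat <- apply(combos, 2, function(idx) {
      gp <- rep(lv[2], n)
      gp[idx] <- lv[1]
      phipt_components(d, gp)$phipt
    })
    p <- mean(stat >= obs$phipt - 1e-12)
    nper <- ncol(combos)
    exact <- TRUE
  } else {
    stat <- vapply(seq_len(n_perm), function(i)
      phipt_components(d, sample(groups))$phipt, numeric(1))
    p <- (sum(stat >= obs$phipt - 1e-12) + 1) / (n_perm + 1)
    nper <- n_perm
  }
  structure(c(obs, list(p_value = p, n_perm = nper, exact = exact,
                        groups = tab)),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("Distance-based AMOVA (PhiPT)\n")
  cat(sprintf("  groups: %s\n",
              paste(sprintf("%s (n=%d)", names(x$groups), x$groups),
                    collapse = ", ")))
  cat(sprintf("  Va (among) = %.4f, Vw (within) = %.4f\n",
              x$sigma2_among, x$sigma2_within))
  cat(sprintf("  PhiPT = %.4f, p = %.4g (%s, %d permutations)\n",
              x$phipt, x$p_value,
              if (x$exact) "exact enumeration" else "sampled", x$n_perm))
  invisible(x)
}

#' Principal coordinates analysis of a squared-distance matrix
#'
#' Metric embedding by Gower double-centering of -d/2 (the input is already
#' a squared distance) and eigendecomposition.  Coordinates are returned
#' for positive eigenvalues only (eigenvectors scaled by the square root of
#' their eigenvalue); negative eigenvalues are reported but their axes
#' dropped.
#'
#' @param d symmetric squared-distance matrix.
#' @return list with `coordinates` (samples x axes, column-centered),
#'   `eigenvalues` (all, non-increasing), `proportion_explained` (per
#'   positive axis, relative to the positive-eigenvalue total).
#' @export
pcoa <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  fit <- suppressWarnings(cmdscale(sqrt(pmax(d, 0)), k = max(1, n - 1),
                                   eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > 1e-9 * max(abs(eig), 1))
  naxes <- min(length(pos), ncol(fit$points))
  coords <- fit$points[, seq_len(naxes), drop = FALSE]
  if (naxes > 0) {
    colnames(coords) <- paste0("Axis", seq_len(naxes))
    rownames(coords) <- rownames(d)
  }
  prop <- if (length(pos) > 0) eig[pos] / sum(eig[pos]) else numeric(0)
  list(coordinates = coords, eigenvalues = eig,
       proportion_explained = prop)
}

#' Allele frequencies and fixed-difference diagnostic markers
#'
#' Computes the band-presence frequency per group and per locus and flags
#' condition-diagnostic loci: frequency 1 in one group and 0 in the other.
#' With `by` (e.g. cultivar), the diagnosis is made within each stratum and
#' the `all` element intersects the per-stratum diagnostic sets requiring a
#' consistent direction.
#'
#' @param m binary samples x loci matrix.
#' @param groups two-level condition label per sample.
#' @param by optional stratum label (cultivar) per sample.
#' @return list with `frequencies` (per stratum: group x locus), per-stratum
#'   `diagnostic` loci (named direction vectors) and `all` (loci diagnostic
#'   in every stratum with the same direction).
#' @export
diagnostic_markers <- function(m, groups, by = NULL) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2) stop("exactly two groups required")
  if (is.null(colnames(m))) colnames(m) <- as.character(seq_len(ncol(m)))
  strata <- if (is.null(by)) rep("all", nrow(m)) else as.character(by)
  per <- lapply(split(seq_len(nrow(m)), strata), function(idx) {
    f1 <- colMeans(m[idx[groups[idx] == lv[1]], , drop = FALSE])
    f2 <- colMeans(m[idx[groups[idx] == lv[2]], , drop = FALSE])
    freq <- rbind(f1, f2)
    rownames(freq) <- lv
    dir <- ifelse(f1 == 1 & f2 == 0, lv[1],
                  ifelse(f1 == 0 & f2 == 1, lv[2], NA))
    list(frequencies = freq,
         diagnostic = dir[!is.na(dir)])
  })
  dirs <- lapply(per, `[[`, "diagnostic")
  common <- Reduce(intersect, lapply(dirs, names))
  if (length(common) > 0) {
    same <- vapply(common, function(l)
      length(unique(vapply(dirs, `[[`, character(1), l))) == 1, logical(1))
    common <- common[same]
  }
  list(frequencies = lapply(per, `[[`, "frequencies"),
       diagnostic = dirs,
       all = if (length(common)) dirs[[1]][common] else
         setNames(character(0), character(0)))
}

#' Average tissue-pair PhiPT over cultivars
#'
#' Summarizes a table of per-cultivar PhiPT estimates between tissue pairs
#' (per enzyme and growing condition) by the arithmetic mean over
#' non-missing cultivars, the way published per-condition averages are
#' formed.
#'
#' @param phipt_table `data.frame` with columns `tissue_pair`, `enzyme`,
#'   `condition`, `cultivar`, `phipt` (values in \[0, 1\] or `NA` for
#'   missing cells).
#' @param digits rounding applied to the reported average (default 4, the
#'   precision such tables print).
#' @return `data.frame` with one row per (`tissue_pair`, `enzyme`,
#'   `condition`): `n_cultivars` used and the `average` (NA when every
#'   cultivar is missing).
#' @export
tissue_divergence_summary <- function(phipt_table, digits = 4) {
  need <- c("tissue_pair", "enzyme", "condition", "cultivar", "phipt")
  stopifnot(all(need %in% names(phipt_table)))
  v <- phipt_table$phipt
  if (any(!is.na(v) & (v < 0 | v > 1)))
    stop("phipt values must lie in [0, 1] or be NA")
  key <- interaction(phipt_table$tissue_pair, phipt_table$enzyme,
                     phipt_table$condition, drop = TRUE)
  out <- do.call(rbind, lapply(split(phipt_table, key), function(b) {
    ok <- !is.na(b$phipt)
    data.frame(tissue_pair = b$tissue_pair[1], enzyme = b$enzyme[1],
               condition = b$condition[1], n_cultivars = sum(ok),
               average = if (any(ok)) round(mean(b$phipt[ok]), digits)
                         else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
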