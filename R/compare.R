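#' Coverage-weighted percent methylation per region
#'
#' Base-conversion (bisulfite/enzymatic) score: the total proportion of
#' methylated base calls over all CpG positions inside the region, i.e. the
#' coverage-weighted mean of per-position methylation. Regions with no
#' covered position are missing (NA), not 0.
#'
#' @param calls A `data.frame` of per-cytosine calls: `chrom`, `pos`
#'   (0-based), `n_meth`, `n_total`.
#' @param regions Regions acceptable to [as_regions()].
#' @return A `data.table` with `id` and `score` (fraction in `[0,1]` or NA).
#' @export
region_percent_methylation <- function(calls, regions) {
  calls <- data.table::as.data.table(calls)
  if (any(calls$n_meth > calls$n_total) || any(calls$n_meth < 0))
    stop("n_meth must lie in [0, n_total]")
  regions <- as_regions(regions)
  agg <- aggregate_by_region(calls$chrom, calls$pos,
                             cbind(meth = calls$n_meth, tot = calls$n_total),
                             regions)
  score <- ifelse(agg[, "tot"] > 0, agg[, "meth"] / agg[, "tot"], NA_real_)
  data.table::data.table(id = regions$id, score = score)
}

#' Count fragments whose center lies in each region
#'
#' Immunoprecipitation-style scoring: a paired-end fragment is a hit in a
#' region when its center position, `floor((start + end) / 2)` on the
#' half-open interval, lies within the region.
#'
#' @param fragments A `data.frame` with `chrom`, `start`, `end` (0-based
#'   half-open insert spans), e.g. the truth table of
#'   [fragments_to_reads()] restricted to aligned pairs.
#' @param regions Regions acceptable to [as_regions()].
#' @return A `data.table` with `id` and count `c`.
#' @export
fragment_center_counts <- function(fragments, regions) {
  fragments <- data.table::as.data.table(fragments)
  if ("aligned" %in% names(fragments)) {
    n_bad <- sum(!fragments$aligned)
    if (n_bad > 0L)
      warning(n_bad, " unaligned pair(s) skipped")
    fragments <- fragments[fragments$aligned, ]
  }
  center <- (fragments$start + fragments$end) %/% 2L
  res <- count_positions_in_regions(fragments$chrom, center, regions)
  data.table::setnames(res, "m", "c")
  res[]
}

#' Mean probe beta value per region
#'
#' Microarray scoring: the unweighted mean beta of all probes whose measured
#' cytosine lies within the region; regions without probes are missing.
#'
#' @param probes A `data.frame` with `chrom`, `pos` (0-based cytosine
#'   coordinate), `beta` in `[0, 1]`.
#' @param regions Regions acceptable to [as_regions()].
#' @return A `data.table` with `id` and `score`.
#' @export
beta_region_score <- function(probes, regions) {
  probes <- data.table::as.data.table(probes)
  if (any(probes$beta < 0 | probes$beta > 1))
    stop("beta values must lie in [0, 1]")
  regions <- as_regions(regions)
  agg <- aggregate_by_region(probes$chrom, probes$pos,
                             cbind(sum = probes$beta, n = 1), regions)
  score <- ifelse(agg[, "n"] > 0, agg[, "sum"] / agg[, "n"], NA_real_)
  data.table::data.table(id = regions$id, score = score)
}

# sum columns of `values` over positions contained in each region
aggregate_by_region <- function(chroms, pos, values, regions) {
  regions <- as_regions(regions)
  out <- matrix(0, nrow = nrow(regions), ncol = ncol(values),
                dimnames = list(NULL, colnames(values)))
  if (length(pos) == 0L) return(out)
  lev <- union(unique(chroms), unique(regions$chrom))
  gr_pos <- GenomicRanges::GRanges(factor(chroms, levels = lev),
                                   IRanges::IRanges(pos + 1L, width = 1L))
  gr_reg <- GenomicRanges::GRanges(factor(regions$chrom, levels = lev),
                                   IRanges::IRanges(regions$start + 1L, regions$end))
  ov <- GenomicRanges::findOverlaps(gr_reg, gr_pos)
  if (length(ov) > 0L) {
    q <- S4Vectors::queryHits(ov)
    for (j in seq_len(ncol(values))) {
      agg <- tapply(values[S4Vectors::subjectHits(ov), j], q, sum)
      out[as.integer(names(agg)), j] <- as.numeric(agg)
    }
  }
  out
}

#' Select the most variable regions by chi-squared score
#'
#' For each region, builds the two-way table of group (e.g. cell type) by
#' methylated-versus-unmethylated counts, computes the Pearson chi-squared
#' statistic `sum((O - E)^2 / E)`, and returns the `k` highest-scoring region
#' ids. Regions whose table has a zero row or column total score 0. Ties are
#' broken by region order.
#'
#' @param meth,unmeth Numeric matrices (regions x groups) of methylated and
#'   unmethylated counts; `rownames` are region ids.
#' @param k Number of regions to select (default 500).
#' @return Character vector of the selected region ids (length `min(k,
#'   nrow)`), with attribute `"chi2"` holding all scores.
#' @examples
#' m <- rbind(a = c(10, 90)); u <- rbind(a = c(90, 10))
#' attr(chi2_select_top(m, u, k = 1), "chi2")  # 128
#' @export
chi2_select_top <- function(meth, unmeth, k = 500L) {
  meth <- as.matrix(meth); unmeth <- as.matrix(unmeth)
  if (!identical(dim(meth), dim(unmeth)))
    stop("meth and unmeth must have identical dimensions")
  if (ncol(meth) < 2L) stop("need at least 2 groups")
  if (any(meth < 0) || any(unmeth < 0)) stop("counts must be non-negative")
  ids <- rownames(meth)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(meth)))
  if (k > nrow(meth)) {
    warning("k exceeds the number of regions; returning all")
    k <- nrow(meth)
  }
  row_m <- meth + unmeth                 # per-group totals (table rows)
  n <- rowSums(row_m)                    # grand total per region
  col_meth <- rowSums(meth)              # methylated column total
  col_unmeth <- rowSums(unmeth)
  # E[group g, meth] = rowtot_g * coltot_meth / n; vectorized over regions
  e_meth <- row_m * (col_meth / n)
  e_unmeth <- row_m * (col_unmeth / n)
  chi2 <- rowSums(ifelse(e_meth > 0, (meth - e_meth)^2 / e_meth, 0)) +
    rowSums(ifelse(e_unmeth > 0, (unmeth - e_unmeth)^2 / e_unmeth, 0))
  degenerate <- n == 0 | col_meth == 0 | col_unmeth == 0 |
    apply(row_m == 0, 1L, any)
  chi2[degenerate] <- 0
  names(chi2) <- ids
  if (k == 0L) {
    out <- character(0)
  } else {
    ord <- order(-chi2, seq_along(chi2))
    out <- ids[ord[seq_len(k)]]
  }
  attr(out, "chi2") <- chi2
  out
}

#' Linearly scale a matrix to the unit interval
#'
#' Whole-matrix min-max scaling, `(x - min) / (max - min)`, applied per
#' platform before concatenating score matrices for clustering (so the
#' platforms contribute on a common scale). Per-feature scaling is available
#' via `per_feature = TRUE`.
#'
#' @param x Numeric matrix (NAs tolerated and preserved).
#' @param per_feature Scale each row (feature) separately instead of the
#'   whole matrix.
#' @return The scaled matrix.
#' @export
scale_unit_interval <- function(x, per_feature = FALSE) {
  x <- as.matrix(x)
  scale1 <- function(v) {
    rng <- range(v, na.rm = TRUE)
    if (!is.finite(rng[1]) || rng[1] == rng[2])
      stop("cannot scale a constant matrix to (0, 1)")
    (v - rng[1]) / (rng[2] - rng[1])
  }
  if (per_feature) t(apply(x, 1L, scale1)) else {
    out <- scale1(as.vector(x))
    matrix(out, nrow = nrow(x), dimnames = dimnames(x))
  }
}

# Pearson distance 1 - r between sample rows of a samples x features matrix
pearson_distance <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 samples")
  sds <- apply(x, 1L, stats::sd)
  if (any(sds == 0 | is.na(sds))) {
    bad <- rownames(x)[sds == 0 | is.na(sds)]
    if (is.null(bad)) bad <- which(sds == 0 | is.na(sds))
    stop("zero-variance sample(s): ", paste(bad, collapse = ", "))
  }
  1 - stats::cor(t(x))
}

#' UPGMA clustering on Pearson distances
#'
#' Hierarchically clusters samples by average linkage (UPGMA) on the Pearson
#' distance `1 - r` computed across features. Ties are resolved
#' deterministically (lowest-index pair first, the `stats::hclust`
#' convention).
#'
#' @param x Samples x features numeric matrix; columns with any NA are
#'   dropped (complete-feature subset).
#' @return An object of class `hclust`.
#' @export
upgma_pearson <- function(x) {
  x <- as.matrix(x)
  keep <- colSums(is.na(x)) == 0L
  x <- x[, keep, drop = FALSE]
  d <- stats::as.dist(pearson_distance(x))
  stats::hclust(d, method = "average")
}

#' Write a dendrogram as Newick
#'
#' @param hc An `hclust` object, e.g. from [upgma_pearson()].
#' @param path Output file path.
#' @export
write_dendrogram_newick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Ratio silhouette of class separation
#'
#' For each sample, the Pearson distance `1 - r` to the *nearest* member of
#' another class divided by the *mean* distance to members of its own class
#' (excluding itself). Values above 1 indicate the sample sits closer to its
#' own class than to any other; note this ratio form is not the classical
#' silhouette width.
#'
#' @param x Samples x features numeric matrix (complete features used).
#' @param labels Class label per sample; every class needs >= 2 members.
#' @return Named numeric vector of per-sample scores.
#' @export
silhouette_ratio <- function(x, labels) {
  x <- as.matrix(x)
  keep <- colSums(is.na(x)) == 0L
  x <- x[, keep, drop = FALSE]
  labels <- as.character(labels)
  if (length(labels) != nrow(x))
    stop("labels must match the number of samples")
  if (any(table(labels) < 2L))
    stop("every class needs at least 2 members (singleton class present)")
  d <- pearson_distance(x)
  out <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    same <- which(labels == labels[i]); same <- setdiff(same, i)
    other <- which(labels != labels[i])
    out[i] <- min(d[i, other]) / mean(d[i, same])
  }
  names(out) <- rownames(x)
  out
}
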