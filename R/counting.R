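#' Classify read pairs by alignability
#'
#' Reproduces the standard read-class accounting for digestion libraries:
#' pairs whose insert is at most `min_insert_dimer` bp are adapter dimers
#' (no genomic insert); longer inserts still below the aligner's minimum
#' seed length `min_seed` are too short to align; aligned pairs are split at
#' `min_mapq` into confidently and poorly aligned; the rest are unaligned.
#' The classes are exhaustive and mutually exclusive.
#'
#' @param insert_len Integer insert lengths (NA when unknown).
#' @param mapq Integer mapping qualities.
#' @param aligned Logical, whether the pair aligned uniquely.
#' @param min_insert_dimer Adapter-dimer insert threshold (default 10 bp).
#' @param min_seed Aligner minimum seed length (default 19 nt).
#' @param min_mapq Minimum MAPQ for confident alignment (default 10, i.e.
#'   posterior probability 0.9 of correct alignment).
#' @return Character vector over `{"adapter_dimer", "too_short",
#'   "unaligned", "poorly_aligned", "confidently_aligned"}`.
#' @examples
#' classify_read_pair(c(4, 15, 32), c(0, 60, 10), c(FALSE, TRUE, TRUE))
#' @export
classify_read_pair <- function(insert_len, mapq, aligned,
                               min_insert_dimer = 10L, min_seed = 19L,
                               min_mapq = 10L) {
  if (any(insert_len < 0, na.rm = TRUE))
    stop("insert lengths must be non-negative")
  n <- max(length(insert_len), length(mapq), length(aligned))
  insert_len <- rep_len(insert_len, n)
  mapq <- rep_len(mapq, n)
  aligned <- rep_len(aligned, n)
  cls <- rep("unaligned", n)
  cls[aligned & !is.na(mapq) & mapq < min_mapq] <- "poorly_aligned"
  cls[aligned & !is.na(mapq) & mapq >= min_mapq] <- "confidently_aligned"
  short <- !is.na(insert_len) & insert_len > min_insert_dimer &
    insert_len < min_seed
  cls[short] <- "too_short"
  cls[!is.na(insert_len) & insert_len <= min_insert_dimer] <- "adapter_dimer"
  cls
}

read_classes <- c("adapter_dimer", "too_short", "unaligned",
                  "poorly_aligned", "confidently_aligned")

#' Derive 5' read-end events from paired truth alignments
#'
#' Each confidently aligned pair contributes two fragment-end events: the
#' forward end at the insert's leftmost coordinate and the reverse end at its
#' rightmost coordinate (the 5' base of read 2 on the top strand).
#'
#' @param truth Truth table from [fragments_to_reads()] or pair table from
#'   [read_alignment_pairs()].
#' @return A `data.table` with `qname`, `chrom`, `five_prime_pos`,
#'   `orientation`, and the originating fragment boundary's site index
#'   (`truth_site`, NA when unknown).
#' @export
aligned_ends_from_pairs <- function(truth) {
  tr <- truth[truth$aligned & !is.na(truth$start), ]
  has_src <- all(c("left_site", "right_site") %in% names(tr))
  data.table::data.table(
    qname = rep(tr$qname, 2L),
    chrom = rep(tr$chrom, 2L),
    five_prime_pos = c(tr$start, tr$end - 1L),
    orientation = rep(c("+", "-"), each = nrow(tr)),
    truth_site = if (has_src) c(tr$left_site, tr$right_site) else
      rep(NA_integer_, 2L * nrow(tr))
  )
}

#' Assign read ends to motif sites by the expected fragment-end offset
#'
#' A read 5' end is a hit at a motif site when it aligns at the enzyme's
#' expected distance from the motif: 10 bp to the right of a forward-strand
#' motif or 10 bp to the left of a reverse-strand motif (equivalently, 13 bp
#' from the methylated C, the coordinate at which the distal side of a cut
#' begins). Matching is exact by default; `tolerance` admits a +/- window.
#' With `credit_proximal = TRUE` the motif-proximal fragment end (overhang
#' side, 16 bp from the methylated C) is also credited — off by default,
#' following the strict one-offset rule.
#'
#' @param ends End table from [aligned_ends_from_pairs()].
#' @param sites Site table from [scan_motifs()] (analysis pattern).
#' @param tolerance Maximum absolute deviation in bp from the expected
#'   coordinate (default 0, exact).
#' @param credit_proximal Also credit proximal (overhang-side) ends.
#' @param enzyme The [enzyme_spec()] used to build `sites` (needed only for
#'   `credit_proximal`).
#' @return The `ends` table with a `site_id` column (row index into `sites`,
#'   NA when no site matches).
#' @export
assign_ends_to_sites <- function(ends, sites, tolerance = 0L,
                                 credit_proximal = FALSE, enzyme = mspji()) {
  ends <- data.table::as.data.table(ends)
  key <- paste(sites$chrom, sites$strand, sites$countable_start)
  lut <- stats::setNames(seq_len(nrow(sites)), key)
  site_id <- rep(NA_integer_, nrow(ends))
  for (off in 0:tolerance) for (sgn in unique(c(1L, -1L))) {
    if (off == 0L && sgn == -1L) next
    qk <- paste(ends$chrom, ends$orientation, ends$five_prime_pos + sgn * off)
    hit <- lut[qk]
    site_id[is.na(site_id) & !is.na(hit)] <-
      hit[is.na(site_id) & !is.na(hit)]
  }
  if (credit_proximal) {
    # proximal 5' coordinates: reverse end at breakpoint + overhang - 1 for a
    # forward site; forward end at breakpoint for a reverse site
    prox_strand <- ifelse(sites$strand == "+", "-", "+")
    prox_pos <- ifelse(sites$strand == "+",
                       sites$breakpoint + enzyme$overhang - 1L,
                       sites$breakpoint)
    lut2 <- stats::setNames(seq_len(nrow(sites)),
                            paste(sites$chrom, prox_strand, prox_pos))
    qk <- paste(ends$chrom, ends$orientation, ends$five_prime_pos)
    hit <- lut2[qk]
    site_id[is.na(site_id) & !is.na(hit)] <-
      hit[is.na(site_id) & !is.na(hit)]
  }
  ends$site_id <- unname(site_id)
  ends[]
}

#' Count hits at motif sites and aggregate over regions
#'
#' Classifies read pairs, takes the two 5' ends of every confidently aligned
#' pair, assigns each end to a motif site at the expected offset, and sums
#' hits per site and per region (a site belongs to a region when the
#' coordinate of its first/methylated C lies within the region). Both mates
#' are counted independently; ends that match no site are ignored.
#'
#' @param alignments Truth table from [fragments_to_reads()], pair table from
#'   [read_alignment_pairs()], or a path to a SAM/BAM file of paired
#'   alignments.
#' @param sites Site table from [scan_motifs()] built with the analysis
#'   pattern (e.g. `CGNR`).
#' @param regions Optional regions acceptable to [as_regions()].
#' @param min_mapq,min_insert_dimer,min_seed Read-class thresholds, see
#'   [classify_read_pair()].
#' @inheritParams assign_ends_to_sites
#' @return A list: `site_hits` (sites with a `hits` column), `region_counts`
#'   (`id`, `c` per region; NULL when no regions given), `class_tally`
#'   (named integer vector over the read classes), `total_assigned` (number
#'   of assigned ends, the library-size denominator for normalization).
#' @export
count_hits <- function(alignments, sites, regions = NULL,
                       min_mapq = 10L, min_insert_dimer = 10L,
                       min_seed = 19L, tolerance = 0L,
                       credit_proximal = FALSE, enzyme = mspji()) {
  if (is.character(alignments) && length(alignments) == 1L)
    alignments <- read_alignment_pairs(alignments)
  pairs <- data.table::as.data.table(alignments)
  known <- attr(sites, "genome_seqnames")
  if (!is.null(known)) {
    bad <- setdiff(unique(pairs$chrom[pairs$aligned]), known)
    if (length(bad) > 0L)
      stop("alignment contig(s) absent from the site registry: ",
           paste(bad, collapse = ", "))
  }
  cls <- classify_read_pair(pairs$insert_len, pairs$mapq, pairs$aligned,
                            min_insert_dimer = min_insert_dimer,
                            min_seed = min_seed, min_mapq = min_mapq)
  tally <- stats::setNames(integer(length(read_classes)), read_classes)
  tab <- table(cls)
  tally[names(tab)] <- as.integer(tab)
  ends <- aligned_ends_from_pairs(pairs[cls == "confidently_aligned", ])
  ends <- assign_ends_to_sites(ends, sites, tolerance = tolerance,
                               credit_proximal = credit_proximal,
                               enzyme = enzyme)
  hits <- integer(nrow(sites))
  assigned <- ends$site_id[!is.na(ends$site_id)]
  if (length(assigned) > 0L) {
    tb <- tabulate(assigned, nbins = nrow(sites))
    hits <- as.integer(tb)
  }
  site_hits <- data.table::copy(sites)
  site_hits$hits <- hits
  region_counts <- NULL
  if (!is.null(regions))
    region_counts <- sum_hits_in_regions(sites, hits, regions)
  list(site_hits = site_hits,
       region_counts = region_counts,
       class_tally = tally,
       total_assigned = length(assigned),
       ends = ends)
}

# per-region c_i: sum of member-site hits, membership by mc_pos containment
sum_hits_in_regions <- function(sites, hits, regions) {
  regions <- as_regions(regions)
  lev <- union(unique(sites$chrom), unique(regions$chrom))
  gr_pos <- GenomicRanges::GRanges(factor(sites$chrom, levels = lev),
                                   IRanges::IRanges(sites$mc_pos + 1L, width = 1L))
  gr_reg <- GenomicRanges::GRanges(factor(regions$chrom, levels = lev),
                                   IRanges::IRanges(regions$start + 1L, regions$end))
  ov <- GenomicRanges::findOverlaps(gr_reg, gr_pos)
  cnt <- integer(nrow(regions))
  if (length(ov) > 0L) {
    agg <- tapply(hits[S4Vectors::subjectHits(ov)],
                  S4Vectors::queryHits(ov), sum)
    cnt[as.integer(names(agg))] <- as.integer(agg)
  }
  data.table::data.table(id = regions$id, c = cnt)
}
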