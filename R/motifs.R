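#' Scan a genome for methylation-dependent enzyme motif sites on both strands
#'
#' Finds every occurrence of an IUPAC motif on the forward strand and every
#' occurrence on the reverse strand (which appears on the top strand as the
#' reverse complement, e.g. `YNCG` for `CGNR`). Each occurrence is a
#' potential cut site of the enzyme; coordinates of the methylated cytosine,
#' the motif span, the expected countable read start, and the scission
#' breakpoint are all reported on the top strand, 0-based, half-open
#' (BED convention).
#'
#' Sites whose scission coordinates fall outside the contig cannot produce a
#' complete overhang; they are retained but flagged `off_contig`. Reference
#' positions containing `N` (or any non-ACGT base) never match.
#'
#' @param genome A named `character` vector or a [Biostrings::DNAStringSet]
#'   of contig sequences.
#' @param enzyme An [enzyme_spec()].
#' @param pattern IUPAC motif to scan for; defaults to the enzyme's
#'   `analysis_pattern`. Its first symbol must be compatible with `C`.
#' @return A `data.table` with one row per site: `chrom`, `mc_pos` (0-based
#'   coordinate of the potentially methylated C on the top strand), `strand`
#'   (`+`/`-`), `motif_start`/`motif_end` (0-based half-open top-strand motif
#'   span), `countable_start` (0-based 5' coordinate of a countable read),
#'   `breakpoint` (top-strand coordinate `t` such that digestion severs the
#'   duplex into a left molecule ending at `t + overhang` and a right
#'   molecule starting at `t`, both carrying the 4-nt 5' overhang), and
#'   `off_contig`.
#' @examples
#' scan_motifs(c(chr = "TTCGAGTT"), mspji())
#' @export
scan_motifs <- function(genome, enzyme = mspji(), pattern = enzyme$analysis_pattern) {
  genome <- as_genome(genome)
  pattern <- toupper(pattern)
  check_iupac(pattern)
  if (!grepl("C", Biostrings::IUPAC_CODE_MAP[[substr(pattern, 1L, 1L)]], fixed = TRUE))
    stop("pattern must be anchored on a (potentially methylated) C")
  k <- nchar(pattern)
  rc <- reverse_complement_pattern(pattern)
  if (length(genome) == 0L) {
    empty <- data.table::data.table(
      chrom = character(0), mc_pos = integer(0), strand = character(0),
      motif_start = integer(0), motif_end = integer(0),
      countable_start = integer(0), breakpoint = integer(0),
      off_contig = logical(0))
    data.table::setattr(empty, "genome_seqnames", character(0))
    data.table::setattr(empty, "contig_lengths", integer(0))
    return(empty)
  }
  out <- vector("list", 2L * length(genome))
  for (i in seq_along(genome)) {
    chrom <- names(genome)[i]
    subj <- genome[[i]]
    L <- length(subj)
    if (L >= k) {
      fwd <- clean_match_starts(pattern, subj)   # 0-based motif starts
      rev <- clean_match_starts(rc, subj)
    } else {
      fwd <- integer(0); rev <- integer(0)
    }
    dt_f <- data.table::data.table(
      chrom = chrom,
      mc_pos = fwd,
      strand = "+",
      motif_start = fwd,
      motif_end = fwd + k,
      countable_start = fwd + enzyme$cut_near,
      breakpoint = fwd + enzyme$cut_near
    )
    dt_r <- data.table::data.table(
      chrom = chrom,
      mc_pos = rev + k - 1L,
      strand = "-",
      motif_start = rev,
      motif_end = rev + k,
      countable_start = rev + k - 1L - enzyme$cut_near,
      breakpoint = rev + k - 1L - enzyme$cut_far + 1L
    )
    dt <- rbind(dt_f, dt_r)
    dt$off_contig <- dt$breakpoint < 0L | dt$breakpoint + enzyme$overhang > L
    out[[i]] <- dt
  }
  sites <- data.table::rbindlist(out)
  data.table::setorder(sites, chrom, mc_pos, strand)
  data.table::setattr(sites, "genome_seqnames", names(genome))
  data.table::setattr(sites, "contig_lengths",
                      stats::setNames(Biostrings::width(genome), names(genome)))
  sites[]
}

# IUPAC match starts (0-based), excluding windows that contain non-ACGT bases
clean_match_starts <- function(pattern, subject) {
  m <- Biostrings::matchPattern(pattern, subject, fixed = FALSE)
  if (length(m) == 0L) return(integer(0))
  windows <- as.character(m)
  keep <- !grepl("[^ACGT]", windows)
  Biostrings::start(m)[keep] - 1L
}

as_genome <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(toupper(genome))
  if (!methods::is(genome, "DNAStringSet"))
    stop("genome must be a named character vector or a DNAStringSet")
  if (length(genome) == 0L) return(genome)
  if (is.null(names(genome)) || anyNA(names(genome)) || any(names(genome) == ""))
    stop("genome contigs must be named")
  genome
}

#' Genomic regions for per-region counting
#'
#' Coerces a `data.frame` (columns `chrom`, `start`, `end`, optional `id`) or
#' a [GenomicRanges::GRanges] into the package's region table: 0-based,
#' half-open, BED-compatible coordinates.
#'
#' @param x Regions as `data.frame` or `GRanges`.
#' @return A `data.table` with `chrom`, `start`, `end`, `id`.
#' @export
as_regions <- function(x) {
  if (methods::is(x, "GRanges")) {
    ids <- names(x)
    if (is.null(ids)) {
      mc <- S4Vectors::mcols(x)
      ids <- if ("name" %in% colnames(mc)) as.character(mc$name) else
        paste0("region_", seq_along(x))
    }
    x <- data.table::data.table(
      chrom = as.character(GenomicRanges::seqnames(x)),
      start = GenomicRanges::start(x) - 1L,
      end = GenomicRanges::end(x),
      id = ids
    )
  } else {
    x <- data.table::as.data.table(x)
    if (!all(c("chrom", "start", "end") %in% names(x)))
      stop("regions need columns chrom, start, end")
    if (!"id" %in% names(x)) x$id <- paste0("region_", seq_len(nrow(x)))
    x <- x[, c("chrom", "start", "end", "id"), with = FALSE]
    x$start <- as.integer(x$start)
    x$end <- as.integer(x$end)
  }
  if (any(x$start >= x$end)) stop("regions must satisfy start < end")
  if (anyDuplicated(x$id)) stop("region ids must be unique")
  x[]
}

#' Count motif sites within regions
#'
#' A site is counted in a region when the coordinate of its potentially
#' methylated cytosine lies within the region (`start <= mc_pos < end`) —
#' the rest of the motif may extend past the boundary. Both orientations of
#' a palindromic context are counted unless the CpG straddles the boundary,
#' so counts are typically even. Regions without any site get a count of 0.
#'
#' @param sites Site table from [scan_motifs()].
#' @param regions Regions acceptable to [as_regions()].
#' @return A `data.table` with `id` and motif count `m` per region, in the
#'   input region order.
#' @export
count_motifs_in_regions <- function(sites, regions) {
  regions <- as_regions(regions)
  known <- attr(sites, "genome_seqnames")
  if (!is.null(known)) {
    bad <- setdiff(unique(regions$chrom), known)
    if (length(bad) > 0L)
      warning("regions on chromosome(s) absent from the scanned genome: ",
              paste(bad, collapse = ", "), "; counted as 0")
  }
  count_positions_in_regions(sites$chrom, sites$mc_pos, regions)
}

#' Count CpG dinucleotides within regions, both strands
#'
#' Each `CG` dinucleotide contributes up to two countable cytosines (one per
#' strand); a cytosine is counted only if its own coordinate lies inside the
#' region, so a CpG straddling the boundary contributes one.
#'
#' @inheritParams count_motifs_in_regions
#' @param genome Named character vector or `DNAStringSet`.
#' @return A `data.table` with `id` and CpG cytosine count `m` per region.
#' @export
count_cpg_in_regions <- function(genome, regions) {
  genome <- as_genome(genome)
  regions <- as_regions(regions)
  chroms <- character(0); pos <- integer(0)
  for (i in seq_along(genome)) {
    s <- Biostrings::start(Biostrings::matchPattern("CG", genome[[i]])) - 1L
    if (length(s) > 0L) {
      chroms <- c(chroms, rep(names(genome)[i], 2L * length(s)))
      pos <- c(pos, as.vector(rbind(s, s + 1L)))  # C on top, C on bottom
    }
  }
  count_positions_in_regions(chroms, pos, regions)
}

count_positions_in_regions <- function(chroms, pos, regions) {
  regions <- as_regions(regions)
  if (length(pos) == 0L)
    return(data.table::data.table(id = regions$id, m = 0L))
  lev <- union(unique(chroms), unique(regions$chrom))
  gr_pos <- GenomicRanges::GRanges(factor(chroms, levels = lev),
                                   IRanges::IRanges(pos + 1L, width = 1L))
  gr_reg <- GenomicRanges::GRanges(factor(regions$chrom, levels = lev),
                                   IRanges::IRanges(regions$start + 1L, regions$end))
  m <- GenomicRanges::countOverlaps(gr_reg, gr_pos)
  data.table::data.table(id = regions$id, m = as.integer(m))
}
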