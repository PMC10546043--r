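#' Read a reference genome from FASTA
#'
#' @param path FASTA file (optionally gzipped).
#' @return A named `DNAStringSet`.
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write a genome to FASTA
#'
#' @param genome Named character vector or `DNAStringSet`.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(as_genome(genome), path)
  invisible(path)
}

#' Read regions from a BED file
#'
#' BED is 0-based half-open, matching the package's coordinate convention.
#'
#' @param path BED file path.
#' @return Region `data.table` (see [as_regions()]).
#' @export
read_regions_bed <- function(path) {
  as_regions(rtracklayer::import(path, format = "BED"))
}

#' Write regions to a BED file
#'
#' @param regions Regions acceptable to [as_regions()].
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, path) {
  regions <- as_regions(regions)
  gr <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start + 1L, regions$end),
                               name = regions$id)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write and read the motif-site registry as BED-like TSV
#'
#' Columns: `chrom`, `mc_pos`, `mc_end` (`mc_pos + 1`), `strand`,
#' `countable_start`, `motif_start`, `motif_end`, `breakpoint`,
#' `off_contig`. Round-trips losslessly.
#'
#' @param sites Site table from [scan_motifs()].
#' @param path Output path.
#' @export
write_site_registry <- function(sites, path) {
  out <- data.table::data.table(
    chrom = sites$chrom, mc_pos = sites$mc_pos, mc_end = sites$mc_pos + 1L,
    strand = sites$strand, countable_start = sites$countable_start,
    motif_start = sites$motif_start, motif_end = sites$motif_end,
    breakpoint = sites$breakpoint, off_contig = sites$off_contig)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' @rdname write_site_registry
#' @return `read_site_registry`: the site `data.table`.
#' @export
read_site_registry <- function(path) {
  x <- data.table::fread(path, sep = "\t")
  data.table::data.table(
    chrom = as.character(x$chrom), mc_pos = as.integer(x$mc_pos),
    strand = as.character(x$strand),
    motif_start = as.integer(x$motif_start),
    motif_end = as.integer(x$motif_end),
    countable_start = as.integer(x$countable_start),
    breakpoint = as.integer(x$breakpoint),
    off_contig = as.logical(x$off_contig))
}

#' Write and read a methylation profile as TSV
#'
#' Columns `chrom`, `mc_pos`, `strand`, `fraction`.
#'
#' @param profile Profile table from [generate_profile()].
#' @param path File path.
#' @export
write_profile_tsv <- function(profile, path) {
  data.table::fwrite(
    profile[, c("chrom", "mc_pos", "strand", "fraction")], path, sep = "\t")
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  x <- data.table::fread(path, sep = "\t")
  data.table::data.table(chrom = as.character(x$chrom),
                         mc_pos = as.integer(x$mc_pos),
                         strand = as.character(x$strand),
                         fraction = as.numeric(x$fraction))
}

#' Write simulated read pairs to FASTQ
#'
#' @param reads Read table from [fragments_to_reads()] (`qname`, `seq1`,
#'   `seq2`).
#' @param path_r1,path_r2 Output FASTQ paths for the two mates.
#' @export
write_reads_fastq <- function(reads, path_r1, path_r2) {
  for (mate in 1:2) {
    seqs <- Biostrings::DNAStringSet(reads[[paste0("seq", mate)]])
    names(seqs) <- reads$qname
    quals <- Biostrings::BStringSet(strrep("I", Biostrings::width(seqs)))
    Biostrings::writeXStringSet(seqs, if (mate == 1) path_r1 else path_r2,
                                format = "fastq", qualities = quals)
  }
  invisible(c(path_r1, path_r2))
}

#' Write simulated pairs as a truth SAM file
#'
#' Emits one primary alignment per mate with M-only CIGARs at the true
#' coordinates (MAPQ 60); adapter-dimer pairs are written as unmapped
#' records. SAM positions are 1-based; the package's 0-based coordinates are
#' converted on write.
#'
#' @param sim The list returned by [fragments_to_reads()].
#' @param contig_lengths Named integer vector of contig lengths (e.g.
#'   `attr(digest(...), "contig_lengths")`).
#' @param path Output `.sam` path.
#' @export
write_truth_sam <- function(sim, contig_lengths, path) {
  reads <- sim$reads; truth <- sim$truth
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  for (i in seq_along(contig_lengths))
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths)[i],
                       contig_lengths[i]), con)
  if (nrow(truth) == 0L) return(invisible(path))
  l1 <- nchar(reads$seq1); l2 <- nchar(reads$seq2)
  aligned <- truth$aligned
  pos1 <- ifelse(aligned, truth$start + 1L, 0L)
  pos2 <- ifelse(aligned, truth$end - l2 + 1L, 0L)
  rname <- ifelse(aligned, truth$chrom, "*")
  flag1 <- ifelse(aligned, 99L, 77L)    # paired,proper,mate-rev,first / both-unmapped,first
  flag2 <- ifelse(aligned, 147L, 141L)
  rec1 <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                  truth$qname, flag1, rname, pos1,
                  ifelse(aligned, truth$mapq, 0L),
                  ifelse(aligned, paste0(l1, "M"), "*"),
                  ifelse(aligned, "=", "*"), pos2,
                  ifelse(aligned, truth$insert_len, 0L),
                  reads$seq1, strrep("I", l1))
  seq2 <- reads$seq2
  rec2 <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                  truth$qname, flag2, rname, pos2,
                  ifelse(aligned, truth$mapq, 0L),
                  ifelse(aligned, paste0(l2, "M"), "*"),
                  ifelse(aligned, "=", "*"), pos1,
                  ifelse(aligned, -truth$insert_len, 0L),
                  seq2, strrep("I", l2))
  writeLines(c(rbind(rec1, rec2)), con)
  invisible(path)
}

#' Read paired alignments from SAM/BAM into a pair table
#'
#' Primary alignments only; secondary and supplementary records are ignored.
#' Pairs are reconstructed by query name. A pair is `aligned` when both
#' mates map to the same contig; its insert is the span from the leftmost to
#' the rightmost aligned base and its MAPQ the minimum of the two mates. For
#' pairs in which both mates are unmapped, the read length stands in for the
#' insert length (simulated reads carry the whole insert when it is shorter
#' than the read length), so adapter dimers remain classifiable.
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @return A `data.table` with `qname`, `chrom`, `start`, `end` (0-based
#'   half-open insert span), `insert_len`, `mapq`, `aligned`.
#' @export
read_alignment_pairs <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path,
                            destination = tempfile(),
                            overwrite = TRUE, indexDestination = FALSE)
  } else bam <- path
  flag <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag,
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "qwidth",
             "seq"))
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  n <- length(rec$qname)
  if (n == 0L) return(empty_truth()[, 1:7])
  # qwidth is derived from the CIGAR and is NA for unmapped records;
  # fall back to the stored sequence length there
  qw_na <- is.na(rec$qwidth)
  if (any(qw_na))
    rec$qwidth[qw_na] <- Biostrings::width(rec$seq)[qw_na]
  mapped <- !is.na(rec$pos)
  ref_width <- rep(NA_integer_, n)
  if (any(mapped))
    ref_width[mapped] <- GenomicAlignments::cigarWidthAlongReferenceSpace(
      rec$cigar[mapped])
  dt <- data.table::data.table(
    qname = rec$qname,
    first = bitwAnd(rec$flag, 64L) > 0L,
    chrom = as.character(rec$rname),
    pos0 = as.numeric(rec$pos - 1L),
    end0 = as.numeric(rec$pos - 1L + ref_width),
    mapq = as.numeric(rec$mapq),
    qwidth = rec$qwidth,
    mapped = mapped
  )
  pairs <- dt[, list(
    chrom = .SD$chrom[1L],
    start = suppressWarnings(min(.SD$pos0, na.rm = TRUE)),
    end = suppressWarnings(max(.SD$end0, na.rm = TRUE)),
    both_mapped = all(.SD$mapped) && .N == 2L &&
      length(unique(.SD$chrom)) == 1L,
    mapq = suppressWarnings(min(.SD$mapq, na.rm = TRUE)),
    qw = .SD$qwidth[1L]
  ), by = "qname"]
  data.table::data.table(
    qname = pairs$qname,
    chrom = ifelse(pairs$both_mapped, pairs$chrom, NA_character_),
    start = as.integer(ifelse(pairs$both_mapped, pairs$start, NA)),
    end = as.integer(ifelse(pairs$both_mapped, pairs$end, NA)),
    insert_len = as.integer(ifelse(pairs$both_mapped,
                                   pairs$end - pairs$start, pairs$qw)),
    mapq = as.integer(ifelse(is.finite(pairs$mapq), pairs$mapq, 0)),
    aligned = pairs$both_mapped
  )
}

#' Write a per-region count or score matrix as TSV
#'
#' Rows are region ids, columns samples.
#'
#' @param mat Matrix with rownames (region ids).
#' @param path Output path.
#' @export
write_matrix_tsv <- function(mat, path) {
  dt <- data.table::data.table(id = rownames(mat))
  for (j in colnames(mat)) dt[[j]] <- mat[, j]
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  x <- data.table::fread(path, sep = "\t")
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- as.character(x[[1]])
  m
}
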