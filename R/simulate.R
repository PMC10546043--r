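#' Generate a synthetic genome with tunable CpG enrichment
#'
#' Samples a first-order Markov sequence over ACGT with human-like base
#' composition. The C-to-G transition probability is boosted by
#' `cpg_enrichment`, so CpG dinucleotide frequency increases monotonically
#' with the factor; at 0 the sequence is i.i.d. and the CpG frequency equals
#' the product of the mononucleotide frequencies. Real promoters are
#' CpG-enriched relative to the genomic background (several-fold), which is
#' what this knob emulates.
#'
#' @param length Sequence length in bp (>= 100).
#' @param cpg_enrichment Non-negative multiplier applied to the C->G
#'   transition before renormalization; 0 = no enrichment.
#' @param seed Optional integer seed for reproducibility.
#' @param gc GC content of the mononucleotide distribution.
#' @param name Contig name.
#' @return A named character vector of length 1 (the contig).
#' @examples
#' g <- generate_genome(500, cpg_enrichment = 4, seed = 1)
#' nchar(g)
#' @export
generate_genome <- function(length, cpg_enrichment = 0, seed = NULL,
                            gc = 0.41, name = "sim_1") {
  length <- as.integer(length)
  if (length < 100L) stop("genome length must be at least 100 bp")
  if (cpg_enrichment < 0) stop("cpg_enrichment must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  trans <- matrix(p, nrow = 4L, ncol = 4L, byrow = TRUE,
                  dimnames = list(bases, bases))
  trans["C", "G"] <- trans["C", "G"] * (1 + cpg_enrichment)
  trans["C", ] <- trans["C", ] / sum(trans["C", ])
  cum <- t(apply(trans, 1L, cumsum))
  u <- stats::runif(length)
  idx <- integer(length)
  idx[1L] <- findInterval(u[1L], cumsum(p)) + 1L
  for (i in 2L:length)
    idx[i] <- findInterval(u[i], cum[idx[i - 1L], ], left.open = TRUE) + 1L
  stats::setNames(paste(bases[idx], collapse = ""), name)
}

#' Assign methylation fractions to motif sites
#'
#' Builds a per-cytosine methylation profile over the sites of a genome.
#' By default the two strands of a CpG receive equal fractions (symmetric
#' CpG methylation, the canonical state maintained by DNMT1); set
#' `symmetric = FALSE` to draw the strands independently (hemimethylation).
#'
#' @param sites Site table from [scan_motifs()].
#' @param mode `"beta"` draws fractions from a Beta distribution (the
#'   classic bimodal-capable model for methylation levels);
#'   `"all_methylated"` / `"all_unmethylated"` set every fraction to 1 / 0;
#'   `"table"` takes fractions from `table`.
#' @param alpha,beta Beta distribution shape parameters (mode `"beta"`).
#' @param table For mode `"table"`: a `data.frame` with `chrom`, `mc_pos`,
#'   `strand`, `fraction`.
#' @param symmetric Give both strands of a CpG the same fraction (ignored
#'   for mode `"table"`).
#' @param seed Optional integer seed.
#' @return A `data.table` with `chrom`, `mc_pos`, `strand`, `fraction`
#'   (fractions in `[0, 1]`).
#' @export
generate_profile <- function(sites,
                             mode = c("beta", "all_methylated",
                                      "all_unmethylated", "table"),
                             alpha = 2, beta = 2, table = NULL,
                             symmetric = TRUE, seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  prof <- data.table::data.table(chrom = sites$chrom, mc_pos = sites$mc_pos,
                                 strand = sites$strand)
  if (mode == "table") {
    table <- data.table::as.data.table(table)
    if (any(table$fraction < 0 | table$fraction > 1))
      stop("methylation fractions must lie in [0, 1]")
    prof <- merge(prof, table[, c("chrom", "mc_pos", "strand", "fraction")],
                  by = c("chrom", "mc_pos", "strand"), all.x = TRUE)
    prof$fraction[is.na(prof$fraction)] <- 0
    return(prof[])
  }
  if (mode == "all_methylated") {
    prof$fraction <- 1
  } else if (mode == "all_unmethylated") {
    prof$fraction <- 0
  } else {
    # anchor each site to its CpG: the reverse-strand C of a CpG sits one
    # base right of the forward C on top-strand coordinates
    key_pos <- prof$mc_pos - (prof$strand == "-")
    if (symmetric) {
      key <- paste(prof$chrom, key_pos)
      uk <- unique(key)
      draws <- stats::setNames(stats::rbeta(length(uk), alpha, beta), uk)
      prof$fraction <- unname(draws[key])
    } else {
      prof$fraction <- stats::rbeta(nrow(prof), alpha, beta)
    }
  }
  prof[]
}

#' Simulation configuration
#'
#' @param n_copies Number of genome copies (alleles) to digest.
#' @param digestion_prob Probability that the enzyme cuts a methylated site
#'   on a given copy (enzymatic efficiency, separate from the biological
#'   methylation fraction).
#' @param read_length Sequencing read length in nt (>= 19, the minimum
#'   aligner seed length).
#' @param adapter_dimer_rate Fraction of read pairs replaced by 4-nt random
#'   inserts, emulating residual adapter dimers.
#' @param insert_min,insert_max Optional insert-size selection bounds.
#' @param seed Optional integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_copies = 100L, digestion_prob = 1, read_length = 150L,
                       adapter_dimer_rate = 0, insert_min = NULL,
                       insert_max = NULL, seed = NULL) {
  if (digestion_prob < 0 || digestion_prob > 1)
    stop("digestion_prob must lie in [0, 1]")
  if (adapter_dimer_rate < 0 || adapter_dimer_rate > 1)
    stop("adapter_dimer_rate must lie in [0, 1]")
  if (read_length < 19L) stop("read_length must be at least 19 nt")
  structure(list(n_copies = as.integer(n_copies),
                 digestion_prob = digestion_prob,
                 read_length = as.integer(read_length),
                 adapter_dimer_rate = adapter_dimer_rate,
                 insert_min = insert_min, insert_max = insert_max,
                 seed = seed),
            class = "sim_config")
}

#' Digest methylated genome copies into fragments
#'
#' Simulates methylation-dependent restriction digestion. For each genome
#' copy, each motif site is methylated by a Bernoulli draw on its profile
#' fraction and, if methylated, cut with probability `digestion_prob`. A cut
#' severs the duplex at the enzyme's near/far scission distances, leaving a
#' 4-nt 5' overhang that, after adapter ligation and fill-in, belongs to both
#' flanking inserts. A site can only cut while its motif and its scission
#' locus are still on the same molecule, so two cuts whose geometries
#' interleave are mutually exclusive (at most one fires per copy, chosen in
#' random order); this reproduces the enzyme's minimum possible insert.
#'
#' Fragments bounded by a contig end lack the enzymatic 5'-phosphate
#' overhang on that side, cannot be adapter-ligated, and are flagged
#' unligatable; an all-unmethylated profile therefore yields zero ligatable
#' fragments, mirroring the no-library negative controls.
#'
#' @param genome Named character vector or `DNAStringSet`.
#' @param profile Methylation profile from [generate_profile()] (or any
#'   `data.frame` with `chrom`, `mc_pos`, `strand`, `fraction`). Sites
#'   absent from the profile are treated as unmethylated.
#' @param enzyme An [enzyme_spec()].
#' @param config A [sim_config()].
#' @param sites Optional precomputed site table from
#'   [scan_motifs()] with the enzyme's recognition pattern.
#' @return A `data.table` of fragments: `copy_id`, `chrom`, `start`, `end`
#'   (0-based half-open filled-in insert span), `left_site`, `right_site`
#'   (row index into `sites`, or `NA` for a contig end), `ligatable`.
#' @export
digest <- function(genome, profile, enzyme = mspji(), config = sim_config(),
                   sites = NULL) {
  genome <- as_genome(genome)
  if (is.null(sites))
    sites <- scan_motifs(genome, enzyme, pattern = enzyme$recognition)
  if (!is.null(config$seed)) set.seed(config$seed)
  ov <- enzyme$overhang
  profile <- data.table::as.data.table(profile)
  if (any(profile$fraction < 0 | profile$fraction > 1))
    stop("methylation fractions must lie in [0, 1]")
  st <- data.table::copy(sites)
  st$site_id <- seq_len(nrow(st))
  st <- merge(st, profile[, c("chrom", "mc_pos", "strand", "fraction")],
              by = c("chrom", "mc_pos", "strand"), all.x = TRUE, sort = FALSE)
  st$fraction[is.na(st$fraction)] <- 0
  lens <- attr(sites, "contig_lengths")

  out <- list()
  for (chrom in names(lens)) {
    L <- unname(lens[chrom])
    cs <- st[st$chrom == chrom & !st$off_contig & st$fraction > 0, ]
    data.table::setorder(cs, breakpoint)
    t_all <- cs$breakpoint
    # connectivity window: an earlier cut with breakpoint inside
    # [win_lo, win_hi] separates this site's motif from its scission locus
    lo <- pmin(cs$motif_start, t_all)
    hi <- pmax(cs$motif_end - 1L, t_all + ov - 1L)
    win_lo <- lo + 1L
    win_hi <- hi - ov
    frag_list <- vector("list", config$n_copies)
    for (copy in seq_len(config$n_copies)) {
      fired <- which(stats::runif(length(t_all)) < cs$fraction &
                     stats::runif(length(t_all)) < config$digestion_prob)
      bp <- resolve_cuts(t_all[fired], win_lo[fired], win_hi[fired])
      src <- cs$site_id[fired][attr(bp, "which")]
      frag_list[[copy]] <- fragments_from_breakpoints(bp, src, L, ov, copy)
    }
    frags <- data.table::rbindlist(frag_list)
    frags$chrom <- chrom
    out[[chrom]] <- frags
  }
  res <- data.table::rbindlist(out)
  data.table::setcolorder(res, c("copy_id", "chrom", "start", "end",
                                 "left_site", "right_site", "ligatable"))
  data.table::setattr(res, "sites", sites)
  data.table::setattr(res, "contig_lengths", lens)
  data.table::setattr(res, "overhang", ov)
  res[]
}

# Sequentially accept cuts in random order; a cut is rejected when an
# already-applied breakpoint lies inside its connectivity window. Cuts more
# than their window width apart cannot interact, so only local clusters need
# the ordered resolution. Returns sorted unique breakpoints with attribute
# "which" giving the index of the accepted cut for each.
resolve_cuts <- function(t, win_lo, win_hi) {
  n <- length(t)
  if (n == 0L) {
    bp <- integer(0); attr(bp, "which") <- integer(0); return(bp)
  }
  ord <- order(t)
  t <- t[ord]; win_lo <- win_lo[ord]; win_hi <- win_hi[ord]
  reach <- max(win_hi - t, t - win_lo, 0L)
  cluster <- cumsum(c(1L, diff(t) > reach))
  accept <- logical(n)
  for (cl in unique(cluster[duplicated(cluster)])) {
    idx <- which(cluster == cl)
    acc_t <- integer(0)
    for (i in sample(idx)) {
      if (!any(acc_t >= win_lo[i] & acc_t <= win_hi[i])) {
        accept[i] <- TRUE
        acc_t <- c(acc_t, t[i])
      }
    }
  }
  accept[!(cluster %in% cluster[duplicated(cluster)])] <- TRUE
  keep <- which(accept)[!duplicated(t[accept])]
  bp <- t[keep]
  o <- order(bp)
  bp <- bp[o]
  attr(bp, "which") <- ord[keep][o]
  bp
}

fragments_from_breakpoints <- function(bp, src, L, ov, copy) {
  k <- length(bp)
  if (k == 0L)
    return(data.table::data.table(copy_id = copy, start = 0L, end = L,
                                  left_site = NA_integer_,
                                  right_site = NA_integer_,
                                  ligatable = FALSE))
  starts <- c(0L, bp)
  ends <- c(bp + ov, L)
  data.table::data.table(
    copy_id = copy,
    start = starts,
    end = ends,
    left_site = c(NA_integer_, src),
    right_site = c(src, NA_integer_),
    ligatable = c(FALSE, rep(TRUE, k - 1L), FALSE)[seq_len(k + 1L)]
  )
}

#' Turn ligatable fragments into paired-end reads with ground truth
#'
#' Read 1 is the top-strand prefix of the insert and read 2 the bottom-strand
#' prefix from the right end, each truncated to the read length. Reads are
#' error-free and pre-trimmed (no adapter sequence). A fraction
#' `adapter_dimer_rate` of pairs is replaced by 4-nt random inserts with no
#' genomic origin; optional insert-size selection bounds are applied first.
#'
#' @param fragments Fragment table from [digest()].
#' @param genome The genome the fragments were digested from.
#' @param config A [sim_config()].
#' @return A list with `reads` (`data.table`: `qname`, `seq1`, `seq2`) and
#'   `truth` (`data.table`: `qname`, `chrom`, `start`, `end`, `insert_len`,
#'   `mapq`, `aligned`, `left_site`, `right_site`; dimer pairs have
#'   `aligned = FALSE` and no genomic coordinates).
#' @export
fragments_to_reads <- function(fragments, genome, config = sim_config()) {
  genome <- as_genome(genome)
  if (!is.null(config$seed)) set.seed(config$seed)
  frags <- fragments[fragments$ligatable, ]
  len <- frags$end - frags$start
  if (!is.null(config$insert_min)) frags <- frags[len >= config$insert_min, ]
  len <- frags$end - frags$start
  if (!is.null(config$insert_max)) frags <- frags[len <= config$insert_max, ]
  n <- nrow(frags)
  if (n == 0L) {
    return(list(reads = data.table::data.table(qname = character(0),
                                               seq1 = character(0),
                                               seq2 = character(0)),
                truth = empty_truth()))
  }
  dimer <- stats::runif(n) < config$adapter_dimer_rate
  qname <- sprintf("frag_%06d", seq_len(n))
  ins <- character(n)
  for (chrom in unique(frags$chrom)) {
    i <- which(frags$chrom == chrom & !dimer)
    if (length(i) > 0L)
      ins[i] <- as.character(Biostrings::extractAt(
        genome[[chrom]],
        IRanges::IRanges(frags$start[i] + 1L, frags$end[i])))
  }
  if (any(dimer))
    ins[dimer] <- vapply(seq_len(sum(dimer)), function(i)
      paste(sample(c("A", "C", "G", "T"), 4L, replace = TRUE), collapse = ""),
      character(1))
  ilen <- nchar(ins)
  r1 <- substr(ins, 1L, pmin(config$read_length, ilen))
  r2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
    substr(ins, pmax(1L, ilen - config$read_length + 1L), ilen))))
  truth <- data.table::data.table(
    qname = qname,
    chrom = ifelse(dimer, NA_character_, frags$chrom),
    start = ifelse(dimer, NA_integer_, frags$start),
    end = ifelse(dimer, NA_integer_, frags$end),
    insert_len = ilen,
    mapq = ifelse(dimer, 0L, 60L),
    aligned = !dimer,
    left_site = ifelse(dimer, NA_integer_, frags$left_site),
    right_site = ifelse(dimer, NA_integer_, frags$right_site)
  )
  list(reads = data.table::data.table(qname = qname, seq1 = r1, seq2 = r2),
       truth = truth)
}

empty_truth <- function() {
  data.table::data.table(qname = character(0), chrom = character(0),
                         start = integer(0), end = integer(0),
                         insert_len = integer(0), mapq = integer(0),
                         aligned = logical(0), left_site = integer(0),
                         right_site = integer(0))
}

#' Insert-length histogram
#'
#' Tabulates the exact multiset of insert lengths from a fragment table
#' (ligatable fragments) or a truth-alignment table.
#'
#' @param x Fragment table from [digest()] or truth table from
#'   [fragments_to_reads()].
#' @return A `data.table` with `length` and `count`, sorted by length;
#'   counts sum to the number of inserts.
#' @export
insert_length_histogram <- function(x) {
  if ("insert_len" %in% names(x)) {
    len <- x$insert_len
  } else {
    x <- x[x$ligatable, ]
    len <- x$end - x$start
  }
  if (length(len) == 0L)
    return(data.table::data.table(length = integer(0), count = integer(0)))
  tab <- table(len)
  data.table::data.table(length = as.integer(names(tab)),
                         count = as.integer(tab))
}

#' Minimum ligatable insert by exhaustive two-site enumeration
#'
#' Enumerates all orientation combinations of two recognition sites in which
#' the second motif immediately flanks the 4-nt overhang left by the first
#' site's cut, digests each configuration to completion (only the two
#' intended sites methylated), and returns the minimum ligatable fragment
#' length observed. Configurations whose two cuts are mutually exclusive
#' (the second cut's scission locus is severed from its motif by the first
#' cut) yield no ligatable fragment and do not contribute. For the MspJI
#' geometry the minimum is 21 bp.
#'
#' @param enzyme An [enzyme_spec()].
#' @return Integer minimum ligatable insert length in bp.
#' @export
min_ligatable_insert <- function(enzyme = mspji()) {
  lens <- integer(0)
  for (o1 in c("+", "-")) for (o2 in c("+", "-")) {
    cfg <- two_site_configuration(enzyme, o1, o2)
    frags <- digest(cfg$genome, cfg$profile, enzyme,
                    sim_config(n_copies = 1L, digestion_prob = 1, seed = 1L))
    lig <- frags[frags$ligatable, ]
    if (nrow(lig) > 0L) lens <- c(lens, lig$end - lig$start)
  }
  if (length(lens) == 0L) stop("no configuration produced a ligatable fragment")
  min(lens)
}

# Build a ~160-bp sequence holding exactly two intended recognition sites:
# site 1 at a fixed anchor, site 2's motif abutting the overhang left by
# site 1's cut. Only the two intended sites are methylated in the profile.
two_site_configuration <- function(enzyme, orient1, orient2) {
  k <- nchar(enzyme$recognition)
  motif_fwd <- concrete_motif(enzyme$recognition)
  motif_rev <- reverse_complement_pattern(motif_fwd)
  L <- 160L
  seq <- rep("T", L)
  p1 <- 70L  # anchor coordinate of site 1's methylated C (top strand)
  if (orient1 == "+") {
    m1 <- p1                             # motif span [p1, p1 + k)
    flank_start <- p1 + enzyme$cut_far   # first base after the overhang
  } else {
    m1 <- p1 - (k - 1L)
    flank_start <- p1 - enzyme$cut_far - k + 1L  # motif ends at overhang start
  }
  m2 <- flank_start
  place <- function(seq, start0, motif) {
    bases <- strsplit(motif, "")[[1]]
    seq[(start0 + 1L):(start0 + length(bases))] <- bases
    seq
  }
  seq <- place(seq, m1, if (orient1 == "+") motif_fwd else motif_rev)
  seq <- place(seq, m2, if (orient2 == "+") motif_fwd else motif_rev)
  genome <- stats::setNames(paste(seq, collapse = ""), "cfg")
  mc1 <- if (orient1 == "+") m1 else m1 + k - 1L
  mc2 <- if (orient2 == "+") m2 else m2 + k - 1L
  profile <- data.table::data.table(
    chrom = "cfg",
    mc_pos = c(mc1, mc2),
    strand = c(orient1, orient2),
    fraction = 1
  )
  list(genome = genome, profile = profile)
}

# a concrete ACGT instantiation of an IUPAC motif
concrete_motif <- function(pattern) {
  paste(vapply(strsplit(pattern, "")[[1]], function(s)
    substr(Biostrings::IUPAC_CODE_MAP[[s]], 1L, 1L), character(1)),
    collapse = "")
}

#' Insert length from symmetric digestion of a fully methylated CpG
#'
#' Places a fully methylated CpG inside a palindromic context (for MspJI,
#' `YNCGNR`, which carries the recognition motif on both strands) at the
#' center of a 200-bp sequence with no other methylated site, digests to
#' completion, and returns the length of the central fragment. Two enzymes
#' cut symmetrically on either side; for the MspJI geometry the insert is
#' 32 bp.
#'
#' @param enzyme An [enzyme_spec()].
#' @return Integer insert length in bp.
#' @export
symmetric_cpg_insert_length <- function(enzyme = mspji()) {
  L <- 200L
  seq <- rep("T", L)
  p <- 100L  # forward-strand mC of the CpG
  ctx <- strsplit("TACGTA", "")[[1]]  # concrete YNCGNR palindromic context
  seq[(p - 2L):(p + 3L) + 1L] <- ctx
  genome <- stats::setNames(paste(seq, collapse = ""), "pal")
  profile <- data.table::data.table(
    chrom = "pal", mc_pos = c(p, p + 1L), strand = c("+", "-"), fraction = 1)
  frags <- digest(genome, profile, enzyme,
                  sim_config(n_copies = 1L, digestion_prob = 1, seed = 1L))
  lig <- frags[frags$ligatable, ]
  if (nrow(lig) != 1L) stop("expected exactly one ligatable central fragment")
  as.integer(lig$end - lig$start)
}
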