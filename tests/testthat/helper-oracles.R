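# Independent oracles used across tests.

# Brute-force motif scan: expand the IUPAC pattern into a regex and find all
# (overlapping) matches of the pattern and of its reverse complement on the
# top strand. Windows containing N never match because N is excluded from
# every character class.
regex_scan_oracle <- function(seq, pattern) {
  expand <- function(p) paste0(vapply(strsplit(p, "")[[1]], function(s)
    paste0("[", Biostrings::IUPAC_CODE_MAP[[s]], "]"), character(1)),
    collapse = "")
  starts <- function(rx, s) {
    m <- gregexpr(paste0("(?=", rx, ")"), s, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m) - 1L
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(pattern)))
  list(fwd = starts(expand(pattern), seq),
       rev = starts(expand(rc), seq))
}

# Naive UPGMA (average linkage from the original distance matrix, exact
# cluster-size weighting) returning the cophenetic distance matrix. Written
# from the definition, independent of stats::hclust.
brute_upgma_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- mean(d[clusters[[i]], clusters[[j]]])
      if (h < best_h) { best_h <- h; best <- c(i, j) }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- best_h; coph[b, a] <- best_h
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}

random_genome_string <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# 200-bp all-T genome carrying one fully methylated CpG in a concrete
# YNCGNR palindromic context centred at forward-strand mC position 100.
palindromic_fixture <- function() {
  seq <- rep("T", 200L)
  seq[99:104] <- strsplit("TACGTA", "")[[1]]  # 0-based 98..103, mC at 100
  genome <- c(pal = paste(seq, collapse = ""))
  profile <- data.frame(chrom = "pal", mc_pos = c(100L, 101L),
                        strand = c("+", "-"), fraction = 1)
  list(genome = genome, profile = profile)
}
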