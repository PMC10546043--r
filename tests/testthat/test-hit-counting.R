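test_that("read-pair classes are exhaustive and follow the insert/MAPQ thresholds", {
  expect_equal(classify_read_pair(4, 0, FALSE), "adapter_dimer")
  expect_equal(classify_read_pair(10, 60, TRUE), "adapter_dimer")  # boundary
  expect_equal(classify_read_pair(15, 60, TRUE), "too_short")
  expect_equal(classify_read_pair(32, 10, TRUE), "confidently_aligned")
  expect_equal(classify_read_pair(32, 9, TRUE), "poorly_aligned")
  expect_equal(classify_read_pair(32, 0, FALSE), "unaligned")
  expect_equal(classify_read_pair(NA, NA, FALSE), "unaligned")
  expect_error(classify_read_pair(-1, 0, FALSE), "non-negative")
})

test_that("end assignment matches the 13-bp mC rule (10 bp from the motif edge)", {
  # forward site with mC at 100 on contig A; reverse site with mC at 100 on B
  gA <- paste0(strrep("T", 100), "CGTA", strrep("T", 96))
  gB <- paste0(strrep("T", 97), "TACG", strrep("T", 99))
  sites <- scan_motifs(c(A = gA, B = gB), mspji())
  ends <- data.frame(
    qname = c("p1", "p2", "p3"),
    chrom = c("A", "B", "A"),
    five_prime_pos = c(113L, 87L, 114L),
    orientation = c("+", "-", "+"))
  res <- assign_ends_to_sites(ends, sites)
  fwd_site <- which(sites$chrom == "A" & sites$mc_pos == 100 &
                      sites$strand == "+")
  rev_site <- which(sites$chrom == "B" & sites$mc_pos == 100 &
                      sites$strand == "-")
  expect_equal(res$site_id[1], fwd_site)   # 113 - 13 = 100
  expect_equal(res$site_id[2], rev_site)   # 87 + 13 = 100
  expect_true(is.na(res$site_id[3]))       # one off: strict matching
  # a +/-1 tolerance window admits the shifted end
  res_tol <- assign_ends_to_sites(ends, sites, tolerance = 1)
  expect_equal(res_tol$site_id[3], fwd_site)
})

test_that("the palindromic fragment's own (proximal) ends score no hits; flanking distal ends do", {
  seq <- rep("T", 200L)
  seq[99:104] <- strsplit("TACGTA", "")[[1]]  # CpG sites at 100 (+) / 101 (-)
  seq[31:34] <- strsplit("CGTA", "")[[1]]     # forward site, mC at 30
  seq[168:171] <- strsplit("TACG", "")[[1]]   # reverse site, mC at 170
  genome <- c(chr = paste(seq, collapse = ""))
  profile <- data.frame(chrom = "chr",
                        mc_pos = c(30L, 100L, 101L, 170L),
                        strand = c("+", "+", "-", "-"), fraction = 1)
  cfg <- sim_config(n_copies = 1, digestion_prob = 1, seed = 1)
  frags <- digest(genome, profile, mspji(), cfg)
  lig <- frags[frags$ligatable, ]
  expect_equal(sort(lig$end - lig$start), c(32L, 45L, 46L))
  sim <- fragments_to_reads(frags, genome, cfg)
  sites <- scan_motifs(genome, mspji())   # CGNR analysis registry
  res <- count_hits(sim$truth, sites)
  hits <- res$site_hits
  intended <- match(paste("chr", profile$mc_pos, profile$strand),
                    paste(hits$chrom, hits$mc_pos, hits$strand))
  expect_equal(hits$hits[intended], rep(1L, 4))
  expect_equal(res$total_assigned, 4L)    # central 32-bp ends unassigned
  expect_equal(sum(hits$hits), 4L)
  # the alternative rule credits the proximal (16-offset) ends too
  res_prox <- count_hits(sim$truth, sites, credit_proximal = TRUE)
  expect_equal(res_prox$total_assigned, 6L)
  expect_equal(res_prox$site_hits$hits[intended], c(1L, 2L, 2L, 1L))
})

test_that("simulator round trip recovers the generating site for distal ends", {
  g <- generate_genome(20000, cpg_enrichment = 6, seed = 21)
  enz <- mspji()
  sites_rec <- scan_motifs(g, enz, pattern = enz$recognition)
  sites_ana <- scan_motifs(g, enz)
  prof <- generate_profile(sites_rec, "beta", seed = 22)
  cfg <- sim_config(n_copies = 30, digestion_prob = 1, seed = 23)
  frags <- digest(g, prof, enz, cfg, sites = sites_rec)
  sim <- fragments_to_reads(frags, g, cfg)
  res <- count_hits(sim$truth, sites_ana)
  ends <- res$ends
  src_strand <- sites_rec$strand[ends$truth_site]
  distal <- (ends$orientation == "+" & src_strand == "+") |
    (ends$orientation == "-" & src_strand == "-")
  key_rec <- paste(sites_rec$chrom, sites_rec$mc_pos,
                   sites_rec$strand)[ends$truth_site]
  in_analysis <- key_rec %in% paste(sites_ana$chrom, sites_ana$mc_pos,
                                    sites_ana$strand)
  check <- distal & in_analysis
  key_ana <- paste(sites_ana$chrom, sites_ana$mc_pos,
                   sites_ana$strand)[ends$site_id]
  expect_gte(mean(key_ana[check] == key_rec[check]), 0.99)
  # no end is ever assigned to a different site than its generator
  ok <- is.na(key_ana[check]) | key_ana[check] == key_rec[check]
  expect_true(all(ok))
  # a proximal end is only ever assigned when it happens to coincide with a
  # different site's countable coordinate (same breakpoint, two sites)
  prox <- ends[!distal & !is.na(ends$site_id), ]
  if (nrow(prox) > 0L)
    expect_true(all(
      sites_ana$countable_start[prox$site_id] == prox$five_prime_pos &
        paste(sites_ana$chrom, sites_ana$mc_pos,
              sites_ana$strand)[prox$site_id] !=
          paste(sites_rec$chrom, sites_rec$mc_pos,
                sites_rec$strand)[prox$truth_site]))
  # every assigned end sits exactly 10 bp from its motif's near edge
  a <- ends[!is.na(ends$site_id), ]
  edge <- ifelse(sites_ana$strand[a$site_id] == "+",
                 sites_ana$motif_end[a$site_id] - 1L,
                 sites_ana$motif_start[a$site_id])
  expect_true(all(abs(a$five_prime_pos - edge) == 10L))
})

test_that("unmethylated libraries produce zero hits and region sums never exceed site sums", {
  g <- generate_genome(10000, cpg_enrichment = 6, seed = 31)
  enz <- mspji()
  sites_rec <- scan_motifs(g, enz, pattern = enz$recognition)
  sites_ana <- scan_motifs(g, enz)
  un <- generate_profile(sites_rec, "all_unmethylated")
  cfg <- sim_config(n_copies = 10, seed = 32)
  sim <- fragments_to_reads(digest(g, un, enz, cfg, sites = sites_rec), g, cfg)
  res0 <- count_hits(sim$truth, sites_ana)
  expect_equal(sum(res0$site_hits$hits), 0L)

  prof <- generate_profile(sites_rec, "beta", seed = 33)
  sim2 <- fragments_to_reads(digest(g, prof, enz, cfg, sites = sites_rec),
                             g, cfg)
  half <- tile_regions(g, 500)
  half <- half[seq_len(nrow(half) %/% 2), ]   # regions do not tile the genome
  res <- count_hits(sim2$truth, sites_ana, half)
  expect_lte(sum(res$region_counts$c), sum(res$site_hits$hits))
  expect_lte(sum(res$site_hits$hits),
             2L * res$class_tally[["confidently_aligned"]])
  # class tally covers every pair exactly once
  expect_equal(sum(res$class_tally), nrow(sim2$truth))
})

test_that("alignments on contigs missing from the registry are a hard error", {
  g <- c(A = paste0(strrep("T", 100), "CGTA", strrep("T", 96)))
  sites <- scan_motifs(g, mspji())
  truth <- data.frame(qname = "p", chrom = "B", start = 10L, end = 50L,
                      insert_len = 40L, mapq = 60L, aligned = TRUE)
  expect_error(count_hits(truth, sites), "absent from the site registry")
})
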