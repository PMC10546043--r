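test_that("genome generation is seeded, sized, and ACGT-only", {
  g1 <- generate_genome(1000, seed = 7)
  g2 <- generate_genome(1000, seed = 7)
  expect_identical(g1, g2)
  expect_equal(nchar(generate_genome(100, seed = 1)[[1]]), 100L)
  expect_false(grepl("[^ACGT]", g1[[1]]))
  expect_error(generate_genome(99), "at least 100")
  expect_error(generate_genome(1000, cpg_enrichment = -1), "non-negative")
})

test_that("CpG frequency is independent at enrichment 0 and rises with it", {
  g0 <- generate_genome(200000, cpg_enrichment = 0, seed = 3)[[1]]
  cpg <- function(s) length(gregexpr("(?=CG)", s, perl = TRUE)[[1]])
  base_freq <- function(s, b) lengths(regmatches(s, gregexpr(b, s)))
  n <- nchar(g0)
  fC <- base_freq(g0, "C") / n
  fG <- base_freq(g0, "G") / n
  obs <- cpg(g0) / (n - 1)
  # binomial SE of the dinucleotide frequency at independence
  se <- sqrt(fC * fG * (1 - fC * fG) / (n - 1))
  expect_lt(abs(obs - fC * fG), 3 * se)
  freqs <- vapply(c(0, 2, 6), function(e)
    cpg(generate_genome(50000, cpg_enrichment = e, seed = 4)[[1]]) / 49999,
    numeric(1))
  expect_true(all(diff(freqs) > 0))
})

test_that("methylation profiles honor their modes and validate fractions", {
  g <- generate_genome(5000, cpg_enrichment = 5, seed = 5)
  sites <- scan_motifs(g, mspji(), pattern = "CNNR")
  expect_true(all(generate_profile(sites, "all_methylated")$fraction == 1))
  expect_true(all(generate_profile(sites, "all_unmethylated")$fraction == 0))
  p1 <- generate_profile(sites, "beta", seed = 9)
  p2 <- generate_profile(sites, "beta", seed = 9)
  expect_identical(p1, p2)
  # Beta(2,2) mean 0.5, sd 1/sqrt(20); symmetric profile halves the
  # effective n (one draw per CpG)
  n_eff <- length(unique(paste(p1$chrom, p1$mc_pos - (p1$strand == "-"))))
  expect_lt(abs(mean(p1$fraction) - 0.5), 3 * sqrt(1 / 20) / sqrt(n_eff))
  # symmetric CpG methylation: the two strands of a CpG share the fraction
  cg <- scan_motifs(g, mspji(), pattern = "CGNR")
  pcg <- generate_profile(cg, "beta", seed = 10)
  key <- paste(pcg$chrom, pcg$mc_pos - (pcg$strand == "-"))
  expect_true(all(tapply(pcg$fraction, key, function(v)
    length(unique(v)) == 1L)))
  expect_error(generate_profile(sites, "table",
                                table = data.frame(chrom = "x", mc_pos = 1,
                                                   strand = "+",
                                                   fraction = 1.5)),
               "\\[0, 1\\]")
})

test_that("symmetric digestion of a fully methylated palindromic CpG yields the 32-bp insert", {
  fx <- palindromic_fixture()
  frags <- digest(fx$genome, fx$profile, mspji(),
                  sim_config(n_copies = 1, digestion_prob = 1, seed = 1))
  lig <- frags[frags$ligatable, ]
  expect_equal(nrow(lig), 1L)
  expect_equal(lig$start, 85L)   # reverse site at 101 cuts 16 bp upstream
  expect_equal(lig$end, 117L)    # forward site at 100 cuts 17 bp downstream
  expect_equal(lig$end - lig$start, 32L)
  expect_equal(symmetric_cpg_insert_length(mspji()), 32L)
})

test_that("exhaustive two-site enumeration reproduces the 21-bp minimum insert", {
  expect_equal(min_ligatable_insert(mspji()), 21L)
})

test_that("unmethylated or undigested genomes produce no ligatable fragments", {
  g <- generate_genome(5000, cpg_enrichment = 5, seed = 6)
  sites <- scan_motifs(g, mspji(), pattern = "CNNR")
  un <- generate_profile(sites, "all_unmethylated")
  frags <- digest(g, un, mspji(), sim_config(n_copies = 5, seed = 2))
  expect_equal(sum(frags$ligatable), 0L)
  me <- generate_profile(sites, "all_methylated")
  frags0 <- digest(g, me, mspji(),
                   sim_config(n_copies = 5, digestion_prob = 0, seed = 2))
  expect_equal(sum(frags0$ligatable), 0L)
})

test_that("fragment lengths conserve the contig: sum = length + overhang per cut", {
  g <- generate_genome(8000, cpg_enrichment = 5, seed = 8)
  sites <- scan_motifs(g, mspji(), pattern = "CNNR")
  prof <- generate_profile(sites, "beta", seed = 8)
  frags <- digest(g, prof, mspji(),
                  sim_config(n_copies = 10, digestion_prob = 0.7, seed = 3))
  L <- nchar(g[[1]])
  for (cp in unique(frags$copy_id)) {
    f <- frags[frags$copy_id == cp, ]
    n_cuts <- nrow(f) - 1L   # internal breakpoints, each filled in twice
    expect_equal(sum(f$end - f$start), L + 4L * n_cuts)
    # boundaries tile: consecutive fragments overlap by exactly the overhang
    o <- order(f$start)
    if (nrow(f) > 1L)
      expect_true(all(f$end[o][-nrow(f)] - f$start[o][-1L] == 4L))
  }
})

test_that("expected ligatable fragment count rises with digestion probability", {
  g <- generate_genome(6000, cpg_enrichment = 5, seed = 12)
  sites <- scan_motifs(g, mspji(), pattern = "CNNR")
  prof <- generate_profile(sites, "beta", seed = 12)
  n_lig <- vapply(c(0.2, 0.5, 0.9), function(p)
    sum(digest(g, prof, mspji(),
               sim_config(n_copies = 30, digestion_prob = p, seed = 13))$ligatable),
    numeric(1))
  expect_true(all(diff(n_lig) > 0))
})

test_that("read pairs carry the correct coordinates, sequences, and filters", {
  fx <- palindromic_fixture()
  cfg <- sim_config(n_copies = 1, digestion_prob = 1, read_length = 150,
                    seed = 4)
  frags <- digest(fx$genome, fx$profile, mspji(), cfg)
  sim <- fragments_to_reads(frags, fx$genome, cfg)
  expect_equal(nrow(sim$truth), 1L)
  expect_equal(sim$truth$start, 85L)
  expect_equal(sim$truth$end, 117L)      # read 2's rightmost base is 116
  expect_equal(sim$truth$insert_len, 32L)
  insert <- substr(fx$genome[[1]], 86, 117)
  expect_equal(sim$reads$seq1, insert)
  expect_equal(sim$reads$seq2, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(insert))))

  # adapter dimers: every pair becomes a 4-nt random insert
  cfg_d <- sim_config(n_copies = 1, digestion_prob = 1,
                      adapter_dimer_rate = 1, seed = 5)
  sim_d <- fragments_to_reads(frags, fx$genome, cfg_d)
  expect_true(all(sim_d$truth$insert_len == 4L))
  expect_false(any(sim_d$truth$aligned))

  # insert-size selection
  g <- generate_genome(8000, cpg_enrichment = 5, seed = 14)
  pr <- generate_profile(scan_motifs(g, mspji(), pattern = "CNNR"),
                         "beta", seed = 14)
  fr <- digest(g, pr, mspji(), sim_config(n_copies = 5, seed = 15))
  cfg_f <- sim_config(n_copies = 5, insert_min = 30, insert_max = 100,
                      seed = 16)
  sim_f <- fragments_to_reads(fr, g, cfg_f)
  expect_true(all(sim_f$truth$insert_len >= 30 & sim_f$truth$insert_len <= 100))
})

test_that("insert-length histogram is the exact multiset of lengths", {
  fx <- palindromic_fixture()
  frags <- digest(fx$genome, fx$profile, mspji(),
                  sim_config(n_copies = 1, digestion_prob = 1, seed = 1))
  h <- insert_length_histogram(frags)
  expect_equal(h$length, 32L)
  expect_equal(h$count, 1L)
  h25 <- insert_length_histogram(digest(fx$genome, fx$profile, mspji(),
    sim_config(n_copies = 25, digestion_prob = 1, seed = 2)))
  expect_equal(h25$length[which.max(h25$count)], 32L)
  expect_equal(sum(h25$count), 25L)
  expect_equal(nrow(insert_length_histogram(empty <- digest(
    fx$genome, transform(fx$profile, fraction = 0), mspji(),
    sim_config(n_copies = 1, seed = 1)))), 0L)
})

test_that("sim_config validates probabilities and read length", {
  expect_error(sim_config(digestion_prob = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(adapter_dimer_rate = -0.1), "\\[0, 1\\]")
  expect_error(sim_config(read_length = 18), "19")
})
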