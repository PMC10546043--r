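# fmlseq

Computational toolkit for **FML-seq** (fragmentation at methylated loci
and sequencing): methylation profiling by methylation-dependent
restriction digestion.

## The method

MspJI is a methylation-*dependent* restriction endonuclease: it binds a
methylated cytosine in `mCNNR` context (R = A/G) and cleaves both
strands downstream — 13 nt on the top strand, 17 nt on the bottom —
leaving a 4-nt 5′ overhang. Digesting genomic DNA with MspJI and
sequencing the fragments therefore produces reads whose 5′ ends sit at a
fixed, known offset from methylated cytosines: the distal fragment end
lies 13 bp from the methylated C, which is exactly **10 bp** from the
near edge of the 4-bp recognition motif. Counting read starts at those
expected coordinates converts an alignment file directly into a
per-site methylation signal — no bisulfite conversion, no
immunoprecipitation. Analysis is restricted to CpG-context sites
(`CGNR` on either strand), the biologically dominant methylation
context in mammals.

In field notation, with 0-based half-open coordinates throughout: a
top-strand site with methylated C at position *p* cuts at breakpoint
*t = p + 13*; fill-in of the overhang duplicates 4 nt into both
flanking inserts. For region *i* with hit count *c<sub>i</sub>* and
motif count *m<sub>i</sub>*, the normalized score is

    RPMPM_i = 1e6 * (c_i / m_i) / sum_j c_j

with a library-wide denominator, so that when regions tile the site
registry, `sum(RPMPM * m) == 1e6` exactly. Scores are compared as
`log10(RPMPM + 1)`, variable regions are selected by a per-region χ²
on {methylated, unmethylated} counts across groups, samples are
clustered by UPGMA on Pearson distance `1 − r`, and class separation is
summarized by a **ratio silhouette** (nearest other-class distance ÷
mean within-class distance; > 1 = separated).

## What the package provides

| Module | Entry points |
|---|---|
| Enzyme geometry | `enzyme_spec()`, `mspji()`, `scan_motifs()` |
| Digestion simulator | `generate_genome()`, `generate_profile()`, `digest()`, `fragments_to_reads()`, `min_ligatable_insert()`, `symmetric_cpg_insert_length()` |
| Hit counting | `classify_read_pair()`, `assign_ends_to_sites()`, `count_hits()` |
| Quantification | `rpmpm()`, `log_score()`, `mapq_to_posterior()`, `subsample_counts()` |
| Cross-platform comparison | `region_percent_methylation()`, `fragment_center_counts()`, `beta_region_score()`, `chi2_select_top()`, `scale_unit_interval()`, `upgma_pearson()`, `silhouette_ratio()` |
| I/O, pipeline, CLI | FASTA/BED/FASTQ/SAM/TSV/Newick readers and writers, `run_pipeline()`, `inst/cli/fml` |

The simulator is a generative model with ground truth: per-copy
Bernoulli methylation and digestion, mechanical cut interference (a cut
can only fire while its motif and scission locus share a molecule —
this produces the enzyme's 21-bp minimum flanking insert),
unligatable contig-edge fragments, adapter dimers, and error-free
paired-end reads with a truth SAM. See the vignette
(`vignettes/fmlseq-methods.Rmd`) for the full model.

## Worked example

Simulate a CpG-enriched 20-kb genome, digest 50 copies, count hits at
CpG-context sites, and normalize:

```r
library(fmlseq)

mspji()
#> <enzyme_spec> MspJI
#>   recognition: CNNR (analysis: CGNR)
#>   cuts at 13/17 bp from mC; 5' overhang 4 nt; countable offset 10 bp

g     <- generate_genome(20000, cpg_enrichment = 6, seed = 11)
enz   <- mspji()
sites <- scan_motifs(g, enz)                  # analysis pattern CGNR
nrow(sites)
#> [1] 2386

prof <- generate_profile(scan_motifs(g, enz, pattern = enz$recognition),
                         "beta", seed = 12)
cfg  <- sim_config(n_copies = 50, digestion_prob = 0.9,
                   adapter_dimer_rate = 0.02, seed = 13)
sim  <- fragments_to_reads(digest(g, prof, enz, cfg), g, cfg)
nrow(sim$truth)
#> [1] 63272

regions <- tile_regions(g, 500)
res <- count_hits(sim$truth, sites, regions)
res$class_tally
#>       adapter_dimer           too_short           unaligned
#>               14067               17852                   0
#>      poorly_aligned confidently_aligned
#>                   0               31353

m <- count_motifs_in_regions(sites, regions)$m
r <- rpmpm(res$region_counts$c, m, denominator = res$total_assigned)
round(head(cbind(c = res$region_counts$c, m = m,
                 rpmpm = as.numeric(r),
                 log = log_score(as.numeric(r))), 4), 2)
#>        c  m  rpmpm  log
#> [1,] 465 57 582.33 2.77
#> [2,] 421 66 455.33 2.66
#> [3,] 299 59 361.75 2.56
#> [4,] 365 51 510.88 2.71
```

(The dimer/too-short classes include genuine sub-19-bp genomic inserts
from convergent cuts, which dense methylation makes common; only
confidently aligned pairs contribute hits.)

The full simulate → count → quantify → cluster pipeline, with all
artifacts written to disk, is one call (or `fml run` on the command
line):

```r
res <- run_pipeline(default_run_config(seed = 1), out_dir = "out")
res$silhouette   # ratio silhouettes per sample; > 1 = types separate
```

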