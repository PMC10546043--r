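---
title: "fmlseq: model, geometry, and analysis methods"
author: "Package Author"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fmlseq: model, geometry, and analysis methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmlseq)
```

# Overview

FML-seq (fragmentation at methylated loci and sequencing) profiles DNA
methylation by digesting genomic DNA with a methylation-*dependent*
restriction endonuclease and sequencing the resulting fragments. Because
the enzyme cuts only next to methylated cytosines, every sequenced
fragment end marks a methylation event at a fixed, known distance from
the methylated base. Counting read ends at those expected coordinates
turns an alignment file directly into a per-site methylation signal — no
bisulfite conversion and no enrichment step.

`fmlseq` implements the complete computational side of this design:

1. **Enzyme geometry** — a declarative description of where a
   methylation-dependent enzyme binds and cuts (`enzyme_spec()`,
   `mspji()`).
2. **Digestion simulation** — a generative model turning a genome plus a
   per-cytosine methylation profile into fragments, paired-end reads,
   and ground-truth alignments (`digest()`, `fragments_to_reads()`).
3. **Hit counting** — classification of read pairs and exact assignment
   of read 5′ ends to motif sites by the offset rule (`count_hits()`).
4. **Quantification** — reads per million per motif (RPMPM) region
   normalization and log scoring (`rpmpm()`, `log_score()`).
5. **Cross-platform comparison** — the statistics used to compare
   methylation assays region-by-region: percent methylation,
   fragment-center counts, probe β means, χ² selection of variable
   regions, unit scaling, UPGMA/Pearson clustering, and a ratio
   silhouette (`chi2_select_top()`, `upgma_pearson()`,
   `silhouette_ratio()`).
6. **I/O and a CLI** — FASTA/BED/FASTQ/SAM/TSV/Newick round-trips and an
   `fml` command-line tool (`inst/cli/fml`).

All genomic coordinates in the package are **0-based, half-open**
(BED convention); the SAM writer/reader converts to and from 1-based
positions at the file boundary.

# Enzyme geometry

MspJI recognizes a methylated cytosine in `mCNNR` context (R = A/G) and
cleaves both strands downstream, 13 nt away on the top strand and 17 nt
on the bottom, leaving a 4-nt 5′ overhang:

```
5'  m C N N R  ·  ·  ·  N N N N N N N N N / N N N N  ·  3'
3'    G N N Y  ·  ·  ·  N N N N N N N N N   N N N N \ ·  5'
                                          ^13       ^17
```

`enzyme_spec()` captures this as `cut_near = 13`, `cut_far = 17`,
`overhang = cut_far − cut_near = 4`. For a top-strand site with its
methylated C at 0-based position *p*, the duplex separates at breakpoint
*t = p + 13*: the downstream molecule begins at *t* and the upstream
molecule ends at *t + 4*. After adapter ligation, polymerase fill-in of
the 5′ overhang duplicates those 4 nt into **both** flanking inserts, so
summed insert lengths exceed the contig length by 4 nt per cut. For a
bottom-strand site (methylated C pairing with top-strand position *q*)
the geometry mirrors: *t = q − 16*, and the upstream insert ends at
*q − 12*.

Two derived constants characterize the geometry and are computed — not
hard-coded — by the package:

* `min_ligatable_insert()` = **21 bp**: the shortest insert any two-cut
  configuration can produce, found by exhaustively enumerating both
  orientations of a second recognition site placed immediately after the
  first cut's overhang and digesting each configuration to completion.
* `symmetric_cpg_insert_length()` = **32 bp**: a fully methylated CpG
  inside the palindromic context `YNCGNR` carries the recognition motif
  on both strands; two enzymes cut symmetrically around it and excise a
  central 32-bp insert.

```{r geometry}
mspji()
min_ligatable_insert()
symmetric_cpg_insert_length()
```

## CpG-context analysis motif

The enzyme's *recognition* pattern `CNNR` includes non-CpG cytosines. In
mammalian methylomes the signal of interest is CpG methylation, so all
counting and quantification use the *analysis* pattern `CGNR` — a CpG
whose +3 base is a purine — scanned on both strands (a bottom-strand
`CGNR` appears on the top strand as `YNCG`). `scan_motifs()` handles
IUPAC-degenerate patterns on both strands and never lets an ambiguous
reference base (`N`) satisfy a degenerate pattern position.

# The digestion simulator

`digest()` models a library preparation on `n_copies` independent
molecules of the genome:

* Each motif site carries a methylation fraction from the profile. On
  each copy, the site is methylated by a Bernoulli draw on that
  fraction, and a methylated site cuts with probability
  `digestion_prob` (enzymatic efficiency).
* **Cut interference.** An enzyme can only cleave while its recognition
  motif and its scission locus sit on the same molecule. If an earlier
  cut on that copy severs the DNA between a site's motif and its
  breakpoint, the later cut cannot fire. `digest()` resolves each local
  cluster of conflicting cuts in random order, accepting a cut only if
  no already-accepted breakpoint lies in its connectivity window. This
  one mechanical rule is what produces the 21-bp minimum insert: closer
  configurations are mutually exclusive, not merely rare.
* Fragments bounded by a contig end lack the enzymatic 5′-phosphate end
  on that side, cannot be adapter-ligated, and are dropped as
  unligatable. An all-unmethylated profile therefore yields zero
  ligatable fragments — the simulator's negative control is structural,
  not statistical.

`fragments_to_reads()` converts ligatable fragments into error-free,
pre-trimmed paired-end reads (read 1 = top-strand prefix, read 2 =
bottom-strand prefix from the right end) plus a ground-truth table, and
optionally replaces a fraction of pairs with 4-nt random inserts to
emulate residual adapter dimers. `write_truth_sam()` emits the truth as
a SAM file so the counting code can be exercised through a standard
alignment-file path (`read_alignment_pairs()` via Rsamtools).

# The offset rule and hit counting

Each cut produces two fragment ends at unequal distances from the
methylated C:

* the **distal** end — 13 bp from the mC, on the fragment *not*
  containing the motif; its read 5′ start lies exactly **10 bp** from
  the near edge of the 4-nt motif; and
* the **proximal** end — overhang-inclusive, 16 bp from the mC, on the
  motif-containing fragment.

`count_hits()` classifies read pairs (adapter dimer ≤ 10 bp insert; too
short < 19 bp, the minimum aligner seed; unaligned; MAPQ < 10 poorly
aligned; the rest confidently aligned — insert-based classes take
precedence), takes both 5′ ends of every confidently aligned pair, and
assigns an end to a site only when it falls **exactly** at the site's
countable coordinate (`tolerance` widens the window; `credit_proximal`
additionally credits overhang-side ends — both off by default,
implementing the strict one-offset rule). MAPQ thresholds translate to
alignment posteriors via `mapq_to_posterior()` (MAPQ 10 ⇒ 0.9).

# Quantification: RPMPM

Raw per-region hit counts confound methylation level with motif density
and sequencing depth. For region *i* with hit count *c~i~* and motif
count *m~i~*,

$$\mathrm{RPMPM}_i = 10^6 \cdot \frac{c_i / m_i}{\sum_j c_j},$$

where the denominator is the **library-wide** total of assigned ends
(not the sum over the supplied regions). Consequences: RPMPM is
invariant to uniform count scaling, and when regions tile the site
registry, \(\sum_i \mathrm{RPMPM}_i \, m_i = 10^6\) exactly — a
conservation identity the test suite asserts. Scores are compared on the
`log_score()` scale, \(\log_{10}(x + 1)\). Regions with hits but no
motifs are an error; motif-free regions are flagged. `subsample_counts()`
provides exact-depth multivariate hypergeometric rarefaction.

# Cross-platform comparison

To compare methylation assays region-by-region the package implements
one score per platform family: coverage-weighted percent methylation
(`region_percent_methylation()`, bisulfite-style calls),
fragment-center counts (`fragment_center_counts()`,
enrichment-style libraries), and unweighted probe β means
(`beta_region_score()`, arrays). The selection-and-clustering pipeline
is:

1. `chi2_select_top()` — per region, a 2 × groups Pearson χ² on
   {methylated, unmethylated} counts pooled over replicates; the top *k*
   regions by statistic are retained (the canonical
   `[[10, 90], [90, 10]]` table gives χ² = 128; degenerate tables score
   0).
2. `scale_unit_interval()` — min–max scaling to [0, 1], whole-matrix by
   default so between-sample contrasts survive (per-feature is opt-in).
3. `upgma_pearson()` — average-linkage (UPGMA) hierarchical clustering
   on the Pearson distance \(1 - r\); `stats::hclust` is the engine and
   the test suite checks it against an independent brute-force
   average-linkage oracle.
4. `silhouette_ratio()` — per sample, nearest other-class Pearson
   distance divided by mean within-class distance; every value > 1
   means each sample is closer to all its replicates than to any other
   class.

Regions with missing scores are dropped listwise before clustering
(Pearson *r* needs complete vectors), and zero-variance samples are a
hard error rather than a silent NA.

# The end-to-end pipeline and CLI

`run_pipeline()` chains simulate → count → quantify → compare for a
configurable population (default: 50-kb CpG-enriched genome, 2 cell
types × 2 replicates, 50 copies, digestion 0.9, dimer rate 0.02,
thresholds 10 bp / 19 nt / MAPQ 10). Cell types share a Beta(2, 2)
baseline profile with a `var_fraction` of CpGs redrawn from the bimodal
Beta(0.5, 0.5) per type — conserved methylome, differential loci. All
randomness derives from one master seed (per-sample substreams
`seed + 100 + i`), and all artifacts (FASTA, BED, FASTQ, truth SAM,
count/score TSVs, Newick dendrogram, run log) are byte-identical across
runs. The same pipeline is scriptable via the bundled CLI:

```sh
fml=$(Rscript -e 'cat(system.file("cli", "fml", package = "fmlseq"))')
Rscript "$fml" run --config run.yaml --out out_dir
Rscript "$fml" scan-motifs --fasta genome.fa --out sites.tsv
```

# What the simulator does and does not emulate

Modeled: per-copy Bernoulli methylation and digestion; cut
interference and the resulting minimum insert; overhang fill-in
duplication; unligatable contig-edge fragments; adapter dimers;
insert-size selection; strand-symmetric CpG methylation
(hemimethylation available via `symmetric = FALSE`).

Not modeled: sequencing errors and quality decay (reads are
error-free, so MAPQ thresholds are exercised by classification rather
than by a real aligner); PCR duplication and amplification bias;
enzyme off-target activity; non-CpG methylation beyond what `CNNR`
digestion implies; diploid genotypes. These are deliberate: the
package's claims are about geometry, counting, and normalization, which
error-free truth alignments test more sharply than a full sequencing
emulator would.

# Design decisions

* **Digest with `CNNR`, analyze with `CGNR`.** The physical enzyme cuts
  at any methylated `CNNR`; restricting the *counting* to CpG-context
  sites reflects how the assay is read out. The simulator therefore
  digests with the recognition pattern while `count_hits()` defaults to
  analysis-pattern sites.
* **Strict exact-offset assignment.** Tolerance 0 and no proximal
  credit by default; both are parameters, not policy baked into the
  counting code.
* **Library-wide RPMPM denominator.** Using all assigned ends — not the
  in-region subset — keeps scores comparable across region sets and
  yields the conservation identity above.
* **Whole-matrix unit scaling.** Per-feature scaling erases the
  magnitude differences between regions that the χ² selection just
  found; it remains available via `per_feature = TRUE`.
* **Two independent Bernoulli draws** (methylation, then digestion) per
  site per copy rather than one draw on the product, so the two
  parameters remain separately interpretable and testable.

# Reproducibility notes

Every stochastic entry point takes an explicit `seed`; `run_pipeline()`
derives all per-sample streams from one master seed. The problem sizes
used in the test suite (10–100-kb genomes, tens to 1000 copies) were
chosen so the full suite runs in minutes on a laptop while still giving
binomial standard errors tight enough for 3-SE parameter-recovery
checks.
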