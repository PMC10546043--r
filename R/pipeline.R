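#' Default pipeline configuration
#'
#' Desk-scale defaults: a 50-kb CpG-enriched synthetic genome, two cell
#' types with two replicates each, 50 genome copies per sample, and the
#' field-standard read thresholds (adapter-dimer insert <= 10 bp, minimum
#' seed 19 nt, minimum MAPQ 10).
#'
#' @param seed Master seed; per-sample substreams are derived from it.
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    genome = list(length = 50000L, cpg_enrichment = 6, gc = 0.41),
    regions = list(width = 500L),
    enzyme = list(),
    population = list(n_types = 2L, replicates = 2L, var_fraction = 0.3,
                      alpha = 2, beta = 2),
    sim = list(n_copies = 50L, digestion_prob = 0.9, read_length = 150L,
               adapter_dimer_rate = 0.02),
    thresholds = list(min_mapq = 10L, min_seed = 19L,
                      min_insert_dimer = 10L)
  ), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Fields omitted from the file keep the [default_run_config()] values.
#'
#' @param path YAML file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- unclass(default_run_config())
  for (nm in names(user)) {
    if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
      for (k in names(user[[nm]])) cfg[[nm]][[k]] <- user[[nm]][[k]]
    } else cfg[[nm]] <- user[[nm]]
  }
  structure(cfg, class = "run_config")
}

#' Tile a genome into fixed-width regions
#'
#' Convenience region set (e.g. promoter-sized windows) when no annotation
#' BED is supplied; the last partial window is kept.
#'
#' @param genome Named character vector or `DNAStringSet`.
#' @param width Window width in bp.
#' @return Region `data.table`.
#' @export
tile_regions <- function(genome, width = 500L) {
  genome <- as_genome(genome)
  out <- list()
  for (i in seq_along(genome)) {
    L <- Biostrings::width(genome)[i]
    starts <- seq.int(0L, L - 1L, by = width)
    out[[i]] <- data.table::data.table(
      chrom = names(genome)[i], start = starts,
      end = pmin(starts + width, L),
      id = sprintf("%s_%06d", names(genome)[i], starts))
  }
  data.table::rbindlist(out)
}

#' Simulate methylation profiles for several cell types
#'
#' Draws a shared baseline profile (symmetric CpG methylation, Beta
#' distributed) and, for a fraction of CpGs, type-specific levels redrawn
#' from a bimodal Beta(0.5, 0.5) — emulating differentially methylated loci
#' that distinguish cell types while most of the methylome is conserved.
#'
#' @param sites Site table from [scan_motifs()] with the enzyme's
#'   recognition pattern.
#' @param n_types Number of cell types.
#' @param var_fraction Fraction of CpGs with type-specific methylation.
#' @param alpha,beta Baseline Beta parameters.
#' @param seed Optional integer seed.
#' @return A list of profile `data.table`s, one per type, named
#'   `type_1 ...`.
#' @export
simulate_type_profiles <- function(sites, n_types = 2L, var_fraction = 0.3,
                                   alpha = 2, beta = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- generate_profile(sites, mode = "beta", alpha = alpha, beta = beta)
  key_pos <- base$mc_pos - (base$strand == "-")
  key <- paste(base$chrom, key_pos)
  uk <- unique(key)
  var_keys <- sample(uk, size = round(var_fraction * length(uk)))
  lapply(stats::setNames(seq_len(n_types), paste0("type_", seq_len(n_types))),
         function(ty) {
    prof <- data.table::copy(base)
    draws <- stats::setNames(stats::rbeta(length(var_keys), 0.5, 0.5), var_keys)
    idx <- key %in% var_keys
    prof$fraction[idx] <- unname(draws[key[idx]])
    prof
  })
}

#' Run the full simulation-to-clustering pipeline
#'
#' Executes simulate -> count -> quantify -> compare with a single master
#' seed: generates (or loads) a genome, scans motif sites, simulates
#' digestion libraries for each cell-type replicate, counts hits at
#' analysis-pattern sites, aggregates per region, normalizes to RPMPM and
#' log scores, and clusters the samples by UPGMA on Pearson distances.
#' When `out_dir` is given, all artifacts are written there (FASTA, BED,
#' FASTQ, truth SAM, TSV tables, Newick dendrogram, run log); outputs are
#' byte-identical across runs with the same configuration.
#'
#' @param config A `run_config` from [default_run_config()] or
#'   [read_run_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return Invisibly, a list with `genome`, `sites_analysis`, `regions`,
#'   `motif_counts`, `counts` (regions x samples), `rpmpm`, `log_scores`,
#'   `class_tally`, `hclust`, `silhouette`, `labels`, `profiles`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config") || is.list(config))
  seed <- as.integer(config$seed)
  enzyme <- do.call(enzyme_spec, config$enzyme)
  set.seed(seed)
  log_lines <- c(sprintf("fmlseq pipeline, seed %d", seed),
                 utils::capture.output(print(enzyme)))

  # --- genome and regions -------------------------------------------------
  if (!is.null(config$genome$fasta)) {
    genome <- read_genome_fasta(config$genome$fasta)
  } else {
    genome <- generate_genome(config$genome$length,
                              cpg_enrichment = config$genome$cpg_enrichment,
                              seed = seed,
                              gc = config$genome$gc %||% 0.41)
  }
  if (!is.null(config$regions$bed)) {
    regions <- read_regions_bed(config$regions$bed)
  } else {
    regions <- tile_regions(genome, config$regions$width %||% 500L)
  }
  sites_rec <- scan_motifs(genome, enzyme, pattern = enzyme$recognition)
  sites_ana <- scan_motifs(genome, enzyme, pattern = enzyme$analysis_pattern)
  motif_counts <- count_motifs_in_regions(sites_ana, regions)
  log_lines <- c(log_lines,
                 sprintf("genome: %d contig(s), %d bp", length(genome),
                         sum(Biostrings::width(genome))),
                 sprintf("sites: %d recognition (%s), %d analysis (%s)",
                         nrow(sites_rec), enzyme$recognition,
                         nrow(sites_ana), enzyme$analysis_pattern),
                 sprintf("regions: %d", nrow(regions)))

  # --- per-sample simulation and counting ---------------------------------
  pop <- config$population
  profiles <- simulate_type_profiles(sites_rec, n_types = pop$n_types,
                                     var_fraction = pop$var_fraction,
                                     alpha = pop$alpha, beta = pop$beta,
                                     seed = seed + 1L)
  samples <- expand.grid(rep = seq_len(pop$replicates),
                         type = seq_len(pop$n_types))
  sample_names <- sprintf("type%d_rep%d", samples$type, samples$rep)
  labels <- paste0("type_", samples$type)
  counts <- matrix(0L, nrow = nrow(regions), ncol = length(sample_names),
                   dimnames = list(regions$id, sample_names))
  denominators <- integer(length(sample_names))
  tallies <- list()
  sims <- list()
  for (i in seq_along(sample_names)) {
    cfg <- sim_config(n_copies = config$sim$n_copies,
                      digestion_prob = config$sim$digestion_prob,
                      read_length = config$sim$read_length,
                      adapter_dimer_rate = config$sim$adapter_dimer_rate,
                      insert_min = config$sim$insert_min,
                      insert_max = config$sim$insert_max,
                      seed = seed + 100L + i)
    frags <- digest(genome, profiles[[labels[i]]], enzyme, cfg, sites = sites_rec)
    sim <- fragments_to_reads(frags, genome, cfg)
    hits <- count_hits(sim$truth, sites_ana, regions,
                       min_mapq = config$thresholds$min_mapq,
                       min_insert_dimer = config$thresholds$min_insert_dimer,
                       min_seed = config$thresholds$min_seed,
                       enzyme = enzyme)
    counts[, i] <- hits$region_counts$c
    denominators[i] <- hits$total_assigned
    tallies[[sample_names[i]]] <- hits$class_tally
    sims[[sample_names[i]]] <- sim
    log_lines <- c(log_lines, sprintf(
      "%s: %d pairs, %d assigned ends [%s]",
      sample_names[i], nrow(sim$truth), hits$total_assigned,
      paste(names(hits$class_tally), hits$class_tally,
            sep = "=", collapse = ", ")))
  }

  # --- quantification and clustering --------------------------------------
  rp <- vapply(seq_along(sample_names), function(i)
    rpmpm(counts[, i], motif_counts$m, denominator = denominators[i]),
    numeric(nrow(regions)))
  dimnames(rp) <- dimnames(counts)
  logs <- log_score(rp)
  informative <- apply(logs, 1L, stats::sd) > 0
  scaled <- scale_unit_interval(logs[informative, , drop = FALSE])
  hc <- upgma_pearson(t(scaled))
  sil <- silhouette_ratio(t(scaled), labels)
  class_tally <- do.call(rbind, tallies)

  res <- list(genome = genome, sites_analysis = sites_ana, regions = regions,
              motif_counts = motif_counts, counts = counts, rpmpm = rp,
              log_scores = logs, class_tally = class_tally, hclust = hc,
              silhouette = sil, labels = labels, profiles = profiles,
              sims = sims, denominators = denominators)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(...) file.path(out_dir, ...)
    write_genome_fasta(genome, p("genome.fa"))
    write_regions_bed(regions, p("regions.bed"))
    write_site_registry(sites_ana, p("sites_analysis.tsv"))
    data.table::fwrite(motif_counts, p("motif_counts.tsv"), sep = "\t")
    lens <- stats::setNames(Biostrings::width(genome), names(genome))
    for (nm in names(sims)) {
      write_reads_fastq(sims[[nm]]$reads, p(paste0(nm, "_R1.fastq")),
                        p(paste0(nm, "_R2.fastq")))
      write_truth_sam(sims[[nm]], lens, p(paste0(nm, ".sam")))
      write_profile_tsv(profiles[[sub("_rep.*", "", sub("type", "type_", nm))]],
                        p(paste0(sub("_rep.*", "", nm), "_profile.tsv")))
    }
    write_matrix_tsv(counts, p("region_counts.tsv"))
    write_matrix_tsv(rp, p("rpmpm.tsv"))
    write_matrix_tsv(logs, p("log_scores.tsv"))
    write_matrix_tsv(class_tally, p("class_tally.tsv"))
    write_dendrogram_newick(hc, p("dendrogram.nwk"))
    data.table::fwrite(data.table::data.table(sample = names(sil),
                                              label = labels,
                                              silhouette = sil),
                       p("silhouette.tsv"), sep = "\t")
    writeLines(log_lines, p("run_log.txt"))
  }
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
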