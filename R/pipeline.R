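# End-to-end composition: trim -> screen -> filter chain -> mitochondrial
# analysis -> breed affinity (-> ZooMS), with a seeded-run manifest.

#' Default end-to-end configuration
#'
#' One global seed fans out to per-module streams by stable names. Sizes are
#' desk-scale; every element can be overridden via `...`.
#'
#' @param seed integer global seed.
#' @param ... named overrides for `genome_cfg`, `read_cfg`, `panel_cfg`,
#'   `mito` (list with `rho`, `n_reads`, `n_reference`), `adapter`,
#'   `min_len`, `missing_rate`, `zooms` (list with `peaks`, `markers`),
#'   `bootstrap_replicates`.
#' @return configuration list for [run_all()].
#' @export
default_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    genome_cfg = sim_genome_config(seed = derive_seed(seed, "genomes")),
    read_cfg = sim_read_config(seed = derive_seed(seed, "reads"),
                               n_reads = 20000L),
    panel_cfg = sim_panel_config(seed = derive_seed(seed, "panel")),
    mito = list(rho = 0.05, n_reads = 12000L, n_reference = 10L),
    adapter = "AGATCGGAAGAGC",
    min_len = 30L,
    missing_rate = 0.6,
    bootstrap_replicates = 100L,
    zooms = NULL
  )
  utils::modifyList(cfg, list(...))
}

#' Run the full pipeline on simulated data
#'
#' Executes read preparation, multi-genome screening with a species call,
#' the endogenous filter chain with sex determination, mitochondrial
#' contamination estimation and haplogroup placement, breed allele-sharing,
#' and (when peak data are configured) the ZooMS species call. Returns one
#' bundle whose fields mirror the standard per-sample summary table, plus a
#' manifest. Byte-identical across runs with the same configuration.
#'
#' @param config a [default_config()] list.
#' @return a `run_bundle` list.
#' @export
run_all <- function(config = default_config()) {
  seed <- config$seed
  sim <- simulate_genomes(config$genome_cfg)
  target <- sim$species[1]
  contaminant <- sim$species[length(sim$species)]

  simr <- simulate_reads(sim, config$read_cfg)
  trim <- run_trim(simr$reads, config$adapter, min_len = config$min_len)

  index <- build_index(sim$db)
  screen_report <- screen(trim$reads, index)
  species <- call_species(screen_report)

  cont_db <- genome_db(stats::setNames(
    list(genome_contigs(sim$db, contaminant)), contaminant))
  cont_index <- build_index(cont_db)
  chain <- filter_chain(trim$reads, sim$db, target,
                        contaminant_index = cont_index)
  sex <- call_sex(chain$hits, trim$reads, sim$db, target)

  mito <- run_mito_module(sim, config)

  affinity <- run_affinity_module(config)

  zooms <- if (!is.null(config$zooms)) {
    sc <- match_peaks(config$zooms$peaks, config$zooms$markers)
    call_species_pmf(sc)
  } else NULL

  bundle <- list(
    schema = "vellum-bundle/1",
    trim_report = trim$report,
    screen_report = screen_report,
    species_call = species,
    filter_report = chain$report,
    sex_call = sex,
    mito = mito,
    affinity = affinity,
    zooms = zooms,
    manifest = list(
      seed = seed,
      tool_version = as.character(utils::packageVersion("vellum")),
      config_hash = config_hash(config),
      stage_counts = list(
        reads_in = trim$report$reads_in,
        reads_after_trim = trim$report$reads_out,
        chain = as.list(chain$report$stage_counts),
        mito_reads = mito$n_reads
      )
    )
  )
  class(bundle) <- "run_bundle"
  bundle
}

run_mito_module <- function(sim, config) {
  seed <- config$seed
  target <- sim$species[1]
  mito_contig <- names(genome_classes(sim$db, target))[
    genome_classes(sim$db, target) == "mito"]
  if (length(mito_contig) != 1) return(NULL)
  tseq <- genome_contigs(sim$db, target)[[mito_contig]]

  # the "modern reference" the pipeline aligns against: a transversion-
  # mutated derivative of the sample haplotype, so diagnostic sites exist
  motif <- sim$truth$mito_motif_interval
  ref <- mutate_sequence(tseq, n = 25L, seed = derive_seed(seed, "mito-ref"),
                         transversions_only = TRUE,
                         avoid = seq.int(motif[1], motif[2] - 1L))
  haps <- c(sample_hap = tseq, reference = ref$seq)
  rcfg <- sim_read_config(seed = derive_seed(seed, "mito-reads"),
                          n_reads = config$mito$n_reads,
                          delta5 = 0, seq_error = 0.001)
  mr <- simulate_mito_reads(haps, "sample_hap", "reference",
                            rho = config$mito$rho, cfg = rcfg)
  mreads <- run_trim(mr$reads, config$adapter, min_len = config$min_len)$reads

  rdb <- genome_db(list(mito_ref = c(chrM = ref$seq)))
  ridx <- build_index(rdb)
  hits <- assign_mapq(align_reads(mreads, ridx, max_mismatch = 3L))
  hits <- hits[hits$mapq >= 30L, , drop = FALSE]
  hits <- remove_duplicates(hits, mreads)
  pl <- pileup_and_consensus(hits, mreads, ref$seq)
  ds <- diagnostic_sites(pl, excluded = list(motif))
  est <- estimate_contamination(pl, ds)

  refs <- simulate_haplotype_alignment(ref$seq, n_clades = 2,
                                       n_per_clade = config$mito$n_reference %/% 2,
                                       seed = derive_seed(seed, "mito-panel"))
  placement <- place_sample(pl$consensus, refs)
  boots <- bootstrap_support(c(stats::setNames(pl$consensus, "sample"), refs),
                             replicates = config$bootstrap_replicates,
                             seed = derive_seed(seed, "boot"))
  list(n_reads = nrow(hits), mean_depth = pl$mean_depth,
       n_diagnostic_sites = length(ds$positions),
       contamination = est, placement = placement,
       tree_newick = write_newick(boots$tree),
       clades = attr(refs, "clade"))
}

run_affinity_module <- function(config) {
  seed <- config$seed
  sp <- simulate_panel(config$panel_cfg)
  calls <- pseudo_haploidize(sp$panel$sites, sp$target,
                             missing_rate = config$missing_rate,
                             seed = derive_seed(seed, "pseudohap"))
  mg <- merge_with_panel(calls, sp$panel)
  sharing <- breed_sharing(mg$merged, sp$panel)
  grid <- if (nrow(sharing$per_breed) >= 3) {
    interpolate_grid(sharing$per_breed)
  } else NULL
  list(sharing = sharing, excluded = mg$excluded, grid = grid,
       true_breed = sp$target_breed,
       top_breed = sharing$per_breed$breed[1])
}

#' Write a report object as JSON
#'
#' Serialises any of the package's report objects (trim report, screen
#' report, filter report, contamination estimate, sharing result, or a full
#' `run_all()` bundle) to pretty-printed JSON, dropping classes.
#'
#' @param x report object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(unclass_recursive(x), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE,
                       na = "null")
  invisible(path)
}

unclass_recursive <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(x))
  if (is.list(x)) return(lapply(unclass(x), unclass_recursive))
  x
}

config_hash <- function(config) {
  raw <- serialize(config, NULL, version = 2)
  h <- 0
  for (b in as.integer(raw)) h <- (h * 257 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' @export
print.run_bundle <- function(x, ...) {
  cat("<run_bundle>\n")
  cat(sprintf("  species call: %s (margin %.1f points)\n",
              x$species_call$species, x$species_call$margin))
  cat(sprintf("  aligned raw %.1f%%, high quality %.1f%%, retrieval %.1f%%\n",
              x$filter_report$aligned_raw_pct, x$filter_report$high_quality_pct,
              x$filter_report$genome_retrieval_pct))
  cat(sprintf("  sex: %s (X/autosome %.2f)\n", x$sex_call$call, x$sex_call$ratio))
  if (!is.null(x$mito)) {
    cat(sprintf("  mtDNA: %d reads, %.0fx, consensus support %d%%, max contamination %d%%\n",
                x$mito$n_reads, x$mito$mean_depth,
                x$mito$contamination$consensus_support_pct,
                x$mito$contamination$max_contamination_pct))
  }
  if (!is.null(x$affinity)) {
    cat(sprintf("  top breed by sharing: %s (true: %s)\n",
                x$affinity$top_breed, x$affinity$true_breed))
  }
  if (!is.null(x$zooms)) {
    cat(sprintf("  ZooMS call: %s\n", x$zooms$species))
  }
  invisible(x)
}
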