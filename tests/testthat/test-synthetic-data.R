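# Generator correctness: determinism, divergence calibration, admixture
# proportions, damage model, fragment/adapter behaviour, panel structure.

test_that("genome simulation is deterministic and respects zero divergence", {
  cfg <- sim_genome_config(seed = 42, species = c("a", "b"),
                           divergence = c(a = 0, b = 0),
                           contig_spec = data.frame(
                             name = "chr1", length = 5000L, class = "autosome",
                             stringsAsFactors = FALSE),
                           shared_repeat = c(length = 0L, copies = 0L))
  s1 <- simulate_genomes(cfg)
  s2 <- simulate_genomes(cfg)
  expect_identical(s1$db, s2$db)
  expect_identical(genome_contigs(s1$db, "a"), genome_contigs(s1$db, "b"))
})

test_that("pairwise mismatch fraction matches the substitution model", {
  # both species diverge independently from the ancestor; a site matches if
  # neither substituted or both substituted to the same of 3 other bases
  d <- c(a = 0.1, b = 0.1)
  cfg <- sim_genome_config(seed = 7, species = c("a", "b"), divergence = d,
                           contig_spec = data.frame(
                             name = "chr1", length = 10000L, class = "autosome",
                             stringsAsFactors = FALSE),
                           shared_repeat = c(length = 0L, copies = 0L))
  sim <- simulate_genomes(cfg)
  va <- strsplit(genome_contigs(sim$db, "a")[["chr1"]], "")[[1]]
  vb <- strsplit(genome_contigs(sim$db, "b")[["chr1"]], "")[[1]]
  p_expect <- 1 - ((1 - d[1]) * (1 - d[2]) + d[1] * d[2] / 3)
  p_obs <- mean(va != vb)
  se <- sqrt(p_expect * (1 - p_expect) / 10000)
  expect_lt(abs(p_obs - p_expect), 3 * se)
})

test_that("shared repeats are planted verbatim in every genome", {
  cfg <- sim_genome_config(seed = 3, shared_repeat = c(length = 100L, copies = 5L))
  sim <- simulate_genomes(cfg)
  rep_seq <- sim$truth$repeat_seq
  for (sp in sim$species) {
    contigs <- genome_contigs(sim$db, sp)
    n_occ <- sum(vapply(contigs, function(s) {
      m <- gregexpr(rep_seq, s, fixed = TRUE)[[1]]
      sum(m > 0)
    }, numeric(1)))
    expect_gte(n_occ, 5)
  }
  # mito tandem motif: two identical adjacent copies
  iv <- sim$truth$mito_motif_interval
  mito <- genome_contigs(sim$db, sim$species[1])[["chrM"]]
  c1 <- substr(mito, iv[1] + 1, iv[1] + 75)
  c2 <- substr(mito, iv[1] + 76, iv[1] + 150)
  expect_identical(c1, c2)
})

test_that("noise-free reads are exact substrings of their source", {
  sim <- simulate_genomes(sim_genome_config(seed = 5))
  cfg <- sim_read_config(seed = 5, n_reads = 400L, delta5 = 0, seq_error = 0,
                         mix = c(target = 0.6, individual2 = 0.1,
                                 cow = 0.1, goat = 0.1, human = 0.1))
  out <- simulate_reads(sim, cfg)
  expect_equal(nrow(out$reads), 400)
  expect_identical(out$reads$id, out$truth$id)
  sources <- list(target = genome_contigs(sim$db, "sheep"),
                  individual2 = sim$individual2,
                  cow = genome_contigs(sim$db, "cow"),
                  goat = genome_contigs(sim$db, "goat"),
                  human = genome_contigs(sim$db, "human"))
  for (i in seq_len(nrow(out$truth))) {
    tr <- out$truth[i, ]
    frag <- substr(sources[[tr$source]][[tr$contig]], tr$start + 1,
                   tr$start + tr$frag_len)
    if (tr$strand == "-") frag <- revcomp(frag)
    expect_identical(substr(out$reads$seq[i], 1, min(tr$frag_len, 49)),
                     substr(frag, 1, 49))
  }
})

test_that("admixture proportions follow the configured mix", {
  sim <- simulate_genomes(sim_genome_config(seed = 2))
  cfg <- sim_read_config(seed = 2, n_reads = 10000L,
                         mix = c(target = 0.95, human = 0.05))
  out <- simulate_reads(sim, cfg)
  counts <- table(out$truth$source)
  expect_equal(sum(counts), 10000) # source-label conservation
  expected <- 10000 * 0.05
  sd3 <- 3 * sqrt(10000 * 0.05 * 0.95)
  expect_lt(abs(counts[["human"]] - expected), sd3)
})

test_that("short fragments carry the adapter and full deamination converts 5' C", {
  sim <- simulate_genomes(sim_genome_config(seed = 9))
  cfg <- sim_read_config(seed = 9, n_reads = 300L, fragment_mean = 30,
                         fragment_sd = 5, delta5 = 0, seq_error = 0,
                         mix = c(target = 1))
  out <- simulate_reads(sim, cfg)
  short <- out$truth$frag_len < 49
  expect_true(any(short))
  for (i in which(short)) {
    tail_len <- nchar(out$reads$seq[i]) - out$truth$frag_len[i]
    expect_identical(substr(out$reads$seq[i], out$truth$frag_len[i] + 1,
                            nchar(out$reads$seq[i])),
                     substr(cfg$adapter, 1, tail_len))
  }

  # delta5 = 1, lambda = 0: every C in the fragment is read as T
  cfg2 <- sim_read_config(seed = 9, n_reads = 200L, delta5 = 1, lambda = 0,
                          seq_error = 0, mix = c(target = 1))
  out2 <- simulate_reads(sim, cfg2)
  expect_false(any(grepl("C", substr(out2$reads$seq, 1, 1), fixed = TRUE)))
})

test_that("empirical 5' C->T rate decays geometrically with position", {
  sim <- simulate_genomes(sim_genome_config(
    seed = 21, species = c("a", "b"), divergence = c(a = 0, b = 0.1),
    contig_spec = data.frame(name = "chr1", length = 20000L,
                             class = "autosome", stringsAsFactors = FALSE),
    shared_repeat = c(length = 0L, copies = 0L)))
  delta5 <- 0.3; lambda <- 0.3
  cfg <- sim_read_config(seed = 21, n_reads = 100000L, delta5 = delta5,
                         lambda = lambda, seq_error = 0, mix = c(target = 1))
  out <- simulate_reads(sim, cfg)
  src <- genome_contigs(sim$db, "a")[["chr1"]]
  frag <- substr(rep(src, nrow(out$truth)), out$truth$start + 1,
                 out$truth$start + out$truth$frag_len)
  minus <- out$truth$strand == "-"
  frag[minus] <- revcomp(frag[minus])
  for (k in 1:4) {
    ref_b <- substr(frag, k, k)
    obs_b <- substr(out$reads$seq, k, k)
    is_c <- ref_b == "C"
    rate <- mean(obs_b[is_c] == "T")
    p <- delta5 * (1 - lambda)^(k - 1)
    se <- sqrt(p * (1 - p) / sum(is_c))
    expect_lt(abs(rate - p), 4 * se)
  }
})

test_that("mito read mixture hits the requested contamination fraction", {
  ref <- random_dna_str(16565, seed = 31)
  tgt <- mutate_sequence(ref, n = 20, seed = 32, transversions_only = TRUE)
  haps <- c(s = tgt$seq, r = ref)
  cfg <- sim_read_config(seed = 33, n_reads = 5000L, delta5 = 0, seq_error = 0)
  out <- simulate_mito_reads(haps, "s", "r", rho = 0.05, cfg = cfg)
  expect_setequal(out$diagnostic_sites, tgt$sites)
  n_cont <- sum(out$truth$source == "contaminant")
  expect_lt(abs(n_cont - 250), 3 * sqrt(5000 * 0.05 * 0.95))

  out0 <- simulate_mito_reads(haps, "s", "r", rho = 0,
                              cfg = sim_read_config(seed = 34, n_reads = 200L,
                                                    delta5 = 0, seq_error = 0))
  expect_true(all(out0$truth$source == "target"))

  # identical haplotypes: no diagnostic sites
  out_id <- simulate_mito_reads(c(a = ref, b = ref), "a", "b", rho = 0.1,
                                cfg = sim_read_config(seed = 35, n_reads = 50L))
  expect_length(out_id$diagnostic_sites, 0)
  expect_error(simulate_mito_reads(haps, "s", "r", rho = 1.2), "rho")
  expect_error(simulate_mito_reads(haps, "s", "s", rho = 0.1), "differ")
})

test_that("panel breed frequencies contract as fst goes to zero", {
  cfg <- sim_panel_config(seed = 8, n_breeds = 2, n_sites = 5000L,
                          fst = 0.001, n_per_breed = 2L)
  sp <- simulate_panel(cfg)
  f <- sp$truth$breed_freq
  obs <- mean(abs(f[, 1] - f[, 2]))
  # half-normal expectation for |X-Y|, X,Y indep with Var = F p(1-p)
  p <- sp$truth$p_ancestral
  expected <- mean(sqrt(2 * 0.001 * p * (1 - p)) * sqrt(2 / pi))
  expect_lt(obs, 2 * expected)
  expect_gt(obs, 0.5 * expected)
})

test_that("panel genotypes are valid and the target comes from its breed", {
  sp <- simulate_panel(sim_panel_config(seed = 4, n_breeds = 3,
                                        n_sites = 500L, n_per_breed = 4L))
  geno <- sp$panel$geno
  a <- sp$panel$sites$allele_a
  b <- sp$panel$sites$allele_b
  for (j in seq_len(ncol(geno))) {
    ok <- geno[, j] %in% c(paste0(a, a), paste0(a, b), paste0(b, b))
    expect_true(all(ok))
  }
  expect_identical(sp$target_breed, "breed01")
  expect_length(sp$target, 500)
})

test_that("read simulation is deterministic under a fixed seed", {
  sim <- simulate_genomes(sim_genome_config(seed = 6))
  cfg <- sim_read_config(seed = 6, n_reads = 500L)
  r1 <- simulate_reads(sim, cfg)
  r2 <- simulate_reads(sim, cfg)
  expect_identical(r1, r2)
})

test_that("configuration validation rejects out-of-range parameters", {
  expect_error(sim_genome_config(divergence = c(sheep = 0.6, cow = 0.05,
                                                goat = 0.08, human = 0.15)),
               "divergence")
  expect_error(sim_read_config(delta5 = 1.5), "probabilities")
  expect_error(sim_read_config(mix = c(target = 0.5, human = 0.2)), "sum to 1")
  expect_error(sim_panel_config(fst = 0), "fst")
  sim <- simulate_genomes(sim_genome_config(seed = 1))
  expect_error(simulate_reads(sim, sim_read_config(mix = c(armadillo = 1))),
               "unknown source")
})
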