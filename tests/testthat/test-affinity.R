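# Pseudo-haploid calling, panel merging with strand reconciliation,
# IBS allele sharing, breed summaries and the IDW surface.

sites_fixture <- function() {
  data.frame(site_id = c("s1", "s2", "s3", "s4"),
             contig = "chr1",
             pos = c(5L, 15L, 25L, 35L),
             allele_a = c("A", "C", "A", "G"),
             allele_b = c("C", "T", "C", "T"),
             stringsAsFactors = FALSE)
}

test_that("pseudo-haploid calling doubles one eligible base per site", {
  sites <- sites_fixture()
  # two reads of A covering s1 (pos 5); one read with G covering s3 (pos 25)
  reads <- read_set(c("r1", "r2", "r3"),
                    c(strrep("A", 10), strrep("A", 10),
                      paste0(strrep("G", 10))),
                    c(strrep("I", 10), strrep("I", 10), strrep("I", 10)))
  hits <- make_hits(c("r1", "r2", "r3"), start = c(0L, 2L, 20L))
  calls <- call_pseudo_haploid(hits, reads, sites, seed = 1)
  # transition site s2 (C/T) is excluded a priori
  expect_identical(calls$site_id, c("s1", "s3", "s4"))
  expect_equal(unname(attr(calls, "excluded")["transition"]), 1L)
  expect_identical(calls$call[calls$site_id == "s1"], "AA")
  # chosen base G is outside s3's A/C pair: missing
  expect_true(is.na(calls$call[calls$site_id == "s3"]))
  # uncovered s4: missing
  expect_true(is.na(calls$call[calls$site_id == "s4"]))
})

test_that("base and mapping quality thresholds gate eligibility", {
  sites <- sites_fixture()[1, , drop = FALSE]
  reads <- read_set(c("lowq", "lowmapq"),
                    c(strrep("A", 10), strrep("C", 10)),
                    c(strrep("!", 10), strrep("I", 10))) # '!' is Q0
  hits <- make_hits(c("lowq", "lowmapq"), start = 0L, mapq = c(37L, 0L))
  calls <- call_pseudo_haploid(hits, reads, sites, seed = 1)
  expect_true(is.na(calls$call[1])) # neither read eligible
  # drop the thresholds and the low-quality A becomes callable
  calls2 <- call_pseudo_haploid(hits, reads, sites, min_bq = 0, min_mapq = 0,
                                seed = 1)
  expect_false(is.na(calls2$call[1]))
})

test_that("minus-strand hits contribute reference-oriented bases at sites", {
  sites <- data.frame(site_id = "s1", contig = "chr1", pos = 2L,
                      allele_a = "A", allele_b = "C", stringsAsFactors = FALSE)
  # reference-oriented segment AACCG at 0..4; stored read is its revcomp
  reads <- read_set("rm", revcomp("AACCG"))
  hits <- make_hits("rm", start = 0L, strand = "-")
  calls <- call_pseudo_haploid(hits, reads, sites, seed = 1)
  expect_identical(calls$call, "CC")
})

test_that("random read picks are seeded per site and order-independent", {
  sites <- sites_fixture()
  withr::with_seed(5, {
    reads <- read_set(sprintf("r%02d", 1:20),
                      replicate(20, paste(sample(c("A", "C"), 40, TRUE),
                                          collapse = "")))
  })
  hits <- make_hits(reads$id, start = 0L)
  c1 <- call_pseudo_haploid(hits, reads, sites, seed = 9)
  c2 <- call_pseudo_haploid(hits[sample(nrow(hits)), ], reads,
                            sites[c(3, 1, 2, 4), ], seed = 9)
  m <- merge(as.data.frame(c1), as.data.frame(c2), by = "site_id")
  expect_identical(m$call.x, m$call.y)
  # a different seed may choose different reads
  expect_identical(call_pseudo_haploid(hits, reads, sites, seed = 9)$call,
                   c1$call)
})

test_that("panel merging flips strands and removes ambiguous pairs", {
  panel_sites <- data.frame(
    site_id = c("p1", "p2", "p3", "p4"),
    contig = "chr1", pos = c(1L, 2L, 3L, 4L),
    allele_a = c("A", "A", "A", "G"),
    allele_b = c("C", "T", "C", "T"), stringsAsFactors = FALSE)
  geno <- matrix("AC", 4, 1, dimnames = list(panel_sites$site_id, "i1"))
  geno[4, 1] <- "GT"
  geno[2, 1] <- "AT"
  panel <- snp_panel(panel_sites, geno,
                     data.frame(individual = "i1", breed = "b", lon = 0,
                                lat = 0, stringsAsFactors = FALSE))
  calls <- pseudo_calls(
    site_id = c("p1", "p2", "p3", "p4"),
    allele_a = c("T", "A", "A", "G"),   # p1 reported on the opposite strand
    allele_b = c("G", "T", "C", "T"),
    call = c("TT", "AA", "GG", "GG"))
  out <- merge_with_panel(calls, panel)
  # p1: complemented TT -> AA; p2: A/T ambiguous, dropped;
  # p3: GG impossible for an A/C site -> irreconcilable, dropped; p4 kept
  expect_identical(out$merged$call[out$merged$site_id == "p1"], "AA")
  expect_false("p2" %in% out$merged$site_id)
  expect_false("p3" %in% out$merged$site_id)
  expect_identical(out$merged$call[out$merged$site_id == "p4"], "GG")
  expect_equal(unname(out$excluded["ambiguous"]), 1L)
  expect_equal(unname(out$excluded["irreconcilable"]), 1L)
})

test_that("allele sharing follows the IBS definition and is symmetric", {
  expect_equal(allele_sharing(c("AA", "AA"), c("AA", "AA"))$s, 1)
  expect_equal(allele_sharing("AA", "AC")$s, 0.5)
  expect_equal(allele_sharing("AA", "CC")$s, 0)
  expect_equal(allele_sharing(c("AA", NA), c("AA", "CC"))$n_overlap, 1)
  expect_true(is.na(allele_sharing(NA_character_, "AA")$s))
  withr::with_seed(6, {
    gts <- c("AA", "AC", "CC", NA)
    g1 <- sample(gts, 30, TRUE); g2 <- sample(gts, 30, TRUE)
    g3 <- sample(gts, 30, TRUE)
  })
  expect_equal(allele_sharing(g1, g2)$s, allele_sharing(g2, g1)$s)
  # 1 - s is a pseudometric on homozygous vectors: triangle inequality
  hz <- function(g) ifelse(is.na(g), NA,
                           paste0(substr(g, 1, 1), substr(g, 1, 1)))
  d <- function(a, b) allele_sharing(a, b)$distance
  a <- hz(g1); b <- hz(g2); c3 <- hz(g3)
  ok <- !is.na(a) & !is.na(b) & !is.na(c3) # common support for the check
  expect_lte(d(a[ok], b[ok]), d(a[ok], c3[ok]) + d(c3[ok], b[ok]) + 1e-12)
})

test_that("breed summaries average individuals and rank breeds", {
  panel_sites <- data.frame(site_id = c("s1", "s2"), contig = "chr1",
                            pos = c(1L, 2L), allele_a = "A", allele_b = "C",
                            stringsAsFactors = FALSE)
  geno <- matrix(c("AA", "AA", "AA", "AC", "CC", "AA"), nrow = 2,
                 dimnames = list(c("s1", "s2"), c("i1", "i2", "i3")))
  indiv <- data.frame(individual = c("i1", "i2", "i3"),
                      breed = c("b1", "b1", "b2"),
                      lon = c(0, 0, 5), lat = c(0, 0, 5),
                      stringsAsFactors = FALSE)
  panel <- snp_panel(panel_sites, geno, indiv)
  merged <- data.frame(site_id = c("s1", "s2"), call = c("AA", "AA"),
                       stringsAsFactors = FALSE)
  sh <- breed_sharing(merged, panel)
  # i1: s = 1, i2: (2 + 1)/4 = 0.75, i3: (0 + 2)/4 = 0.5
  expect_equal(sh$per_breed$mean_s[sh$per_breed$breed == "b1"], 0.875)
  expect_equal(sh$per_breed$mean_s[sh$per_breed$breed == "b2"], 0.5)
  expect_identical(sh$per_breed$breed[1], "b1")
})

test_that("the IDW surface is exact at breed sites and bounded", {
  pb <- data.frame(breed = c("b1", "b2", "b3"), mean_s = c(0.9, 0.5, 0.7),
                   lon = c(-5, 0, 3), lat = c(51, 57, 53),
                   stringsAsFactors = FALSE)
  grid <- interpolate_grid(pb, resolution = 11)
  at_site <- grid[abs(grid$lon - -5) < 1e-9 & abs(grid$lat - 51) < 1e-9, ]
  expect_equal(at_site$value, 0.9)
  expect_true(all(grid$value <= 0.9 + 1e-12 & grid$value >= 0.5 - 1e-12))
  flat <- interpolate_grid(transform(pb, mean_s = 0.6), resolution = 5)
  expect_true(all(abs(flat$value - 0.6) < 1e-12))
  expect_error(interpolate_grid(pb[1:2, ]), "3 breeds")
})

test_that("deamination cannot flip a surviving transversion genotype", {
  # small version of the damage-robustness property: identical fragments,
  # delta5 0 vs 0.3, calls compared at A/C and G/T sites
  sim <- simulate_genomes(sim_genome_config(
    seed = 18, species = c("a", "b"), divergence = c(a = 0, b = 0.1),
    contig_spec = data.frame(name = "chr1", length = 20000L,
                             class = "autosome", stringsAsFactors = FALSE),
    shared_repeat = c(length = 0L, copies = 0L)))
  src <- genome_contigs(sim$db, "a")[["chr1"]]
  pos <- seq(25L, 19900L, by = 100L)
  ref_base <- substr(rep(src, length(pos)), pos + 1, pos + 1)
  withr::with_seed(19, {
    alt <- vapply(ref_base, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  })
  sites <- data.frame(site_id = sprintf("s%04d", seq_along(pos)),
                      contig = "chr1", pos = pos, allele_a = ref_base,
                      allele_b = unname(alt), stringsAsFactors = FALSE)
  mk_calls <- function(delta5) {
    cfg <- sim_read_config(seed = 20, n_reads = 4000L, delta5 = delta5,
                           seq_error = 0, mix = c(target = 1))
    out <- simulate_reads(sim, cfg)
    hits <- make_hits(out$truth$id, contig = "chr1",
                      start = out$truth$read_start, strand = out$truth$strand)
    reads <- read_set(out$truth$id,
                      substr(out$reads$seq, 1, pmin(out$truth$frag_len, 49L)))
    call_pseudo_haploid(hits, reads, sites, seed = 21)
  }
  c0 <- mk_calls(0)
  c3 <- mk_calls(0.3)
  expect_identical(c0$site_id, c3$site_id)
  surv <- vellum:::pair_key(c0$allele_a, c0$allele_b) %in% c("AC", "GT")
  both <- surv & !is.na(c0$call) & !is.na(c3$call)
  expect_gt(sum(both), 20)
  expect_identical(c0$call[both], c3$call[both])
})
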