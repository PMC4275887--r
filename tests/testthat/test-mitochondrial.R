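# Consensus building, the floor/ceil contamination statistic, Jukes-Cantor
# distances, neighbour joining, bootstrap and sample placement.

test_that("consensus takes the majority base, N on ties and zero depth", {
  ref <- strrep("A", 20)
  # nine reads say A at pos 0-9, one says T (via a mismatching read)
  reads <- read_set(sprintf("r%02d", 1:10),
                    c(rep(strrep("A", 10), 9), paste0("T", strrep("A", 9))))
  hits <- make_hits(reads$id, start = 0L)
  pl <- pileup_and_consensus(hits, reads, ref)
  expect_identical(substr(pl$consensus, 1, 1), "A")
  expect_equal(unname(pl$counts["A", 1]), 9)
  expect_equal(unname(pl$counts["T", 1]), 1)
  expect_equal(unname(pl$depth[1]), 10)
  # tie: 5 vs 5
  reads2 <- read_set(sprintf("r%02d", 1:10),
                     c(rep("AAAA", 5), rep("TAAA", 5)))
  pl2 <- pileup_and_consensus(make_hits(reads2$id, start = 0L), reads2, ref)
  expect_identical(substr(pl2$consensus, 1, 1), "N")
  # no coverage past position 10
  expect_identical(substr(pl$consensus, 15, 15), "N")
  expect_equal(pl$mean_depth, sum(pl$depth) / 20)
})

test_that("minus-strand reads contribute reference-oriented bases", {
  ref <- "ACGTACGT"
  # read stored as the sequenced strand; revcomp("ACGT") = "ACGT" is
  # ambiguous, so use an asymmetric read: reference AACC at 0..3
  ref <- "AACCGGTT"
  reads <- read_set("r1", "GGTT") # revcomp(GGTT) = AACC
  pl <- pileup_and_consensus(make_hits("r1", start = 0L, strand = "-"),
                             reads, ref)
  expect_identical(substr(pl$consensus, 1, 4), "AACC")
})

test_that("clean simulated reads reproduce the source haplotype", {
  ref <- random_dna_str(2000, seed = 61)
  tgt <- mutate_sequence(ref, n = 10, seed = 62, transversions_only = TRUE)
  cfg <- sim_read_config(seed = 63, n_reads = 900L, delta5 = 0, seq_error = 0,
                         fragment_mean = 60, fragment_sd = 5)
  out <- simulate_mito_reads(c(s = tgt$seq, r = ref), "s", "r", rho = 0, cfg)
  len <- pmin(out$truth$frag_len, 49L)
  hits <- make_hits(out$truth$id, contig = "chrM",
                    start = out$truth$read_start, strand = out$truth$strand)
  reads <- read_set(out$truth$id, substr(out$reads$seq, 1, len))
  pl <- pileup_and_consensus(hits, reads, ref)
  covered <- pl$depth > 0
  cons <- strsplit(pl$consensus, "")[[1]]
  src <- strsplit(tgt$seq, "")[[1]]
  expect_true(all(cons[covered] == src[covered]))
  ds <- diagnostic_sites(pl, min_depth = 10)
  expect_true(all(ds$positions %in% tgt$sites))
})

test_that("diagnostic sites respect depth and exclusion intervals", {
  reads <- read_set(sprintf("r%02d", 1:12), rep(strrep("T", 10), 12))
  ref <- strrep("A", 30)
  pl <- pileup_and_consensus(make_hits(reads$id, start = 0L), reads, ref)
  ds <- diagnostic_sites(pl, min_depth = 10)
  expect_identical(ds$positions, 0:9)
  # an exclusion interval swallows the differences inside it
  ds2 <- diagnostic_sites(pl, excluded = list(c(0L, 10L)), min_depth = 10)
  expect_length(ds2$positions, 0)
  # consensus == reference everywhere: empty set
  readsA <- read_set(sprintf("a%02d", 1:12), rep(strrep("A", 10), 12))
  plA <- pileup_and_consensus(make_hits(readsA$id, start = 0L), readsA, ref)
  expect_length(diagnostic_sites(plA, min_depth = 10)$positions, 0)
  expect_error(estimate_contamination(plA, diagnostic_sites(plA)),
               "no diagnostic sites")
})

test_that("the contamination statistic floors support and ceils contamination", {
  est <- contamination_estimate(282, 291)
  expect_equal(est$consensus_support_pct, 96)
  expect_equal(est$max_contamination_pct, 4)
  est2 <- contamination_estimate(381, 398)
  expect_equal(est2$consensus_support_pct, 95)
  expect_equal(est2$max_contamination_pct, 5)
  all_cons <- contamination_estimate(100, 100)
  expect_equal(all_cons$consensus_support_pct, 100)
  expect_equal(all_cons$max_contamination_pct, 0)
  # support + contamination is 100 or 101, contamination 0 iff no discord
  withr::with_seed(71, {
    for (i in 1:50) {
      tot <- sample(50:500, 1)
      con <- sample(0:tot, 1)
      e <- contamination_estimate(con, tot)
      expect_true((e$consensus_support_pct + e$max_contamination_pct) %in%
                    c(100L, 101L))
      expect_identical(e$max_contamination_pct == 0L, con == tot)
    }
  })
  expect_error(contamination_estimate(5, 0), "total_reads")
})

test_that("Jukes-Cantor distance matches its closed form and ape's", {
  expect_equal(jc_distance("ACGT", "ACGT"), 0)
  # p = 0.1 over 10 retained columns
  a <- "AAAAAAAAAA"; b <- "CAAAAAAAAA"
  expect_equal(jc_distance(a, b), -0.75 * log(1 - 0.4 / 3))
  expect_equal(jc_distance(a, b), 0.1073256, tolerance = 1e-6)
  # gapped columns are excluded before p
  expect_equal(jc_distance("A-CGAAAAAA", "AGCGAAAAAA"), 0)
  # cross-check against ape on a random pair
  s1 <- random_dna_str(600, seed = 81)
  s2 <- mutate_sequence(s1, n = 60, seed = 82)$seq
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(c(a = s1, b = s2), "")))
  d_ape <- as.numeric(ape::dist.dna(bin, model = "JC69"))
  expect_equal(jc_distance(s1, s2), d_ape, tolerance = 1e-12)
  expect_error(jc_distance("AAAA", "CCCC"), "saturated")
  expect_error(jc_distance("AAAA", "AA"), "equal")
  expect_error(jc_distance("----", "AAAA"), "ungapped")
})

test_that("neighbour joining solves the 3-taxon closed form exactly", {
  D <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tree <- neighbour_joining(D)
  # v_x = (D(xy) + D(xz) - D(yz)) / 2
  lens <- stats::setNames(tree$edge.length[match(1:3, tree$edge[, 2])],
                          tree$tip.label)
  expect_equal(lens[["a"]], 0.5, tolerance = 1e-12)
  expect_equal(lens[["b"]], 1.5, tolerance = 1e-12)
  expect_equal(lens[["c"]], 2.5, tolerance = 1e-12)
  expect_error(neighbour_joining(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa")
  bad <- D; bad[1, 2] <- 99
  expect_error(neighbour_joining(bad), "symmetric")
})

test_that("neighbour joining recovers additive trees exactly", {
  # fixed 4-taxon tree ((a:1,b:2):1,(c:3,d:4))
  true <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:4):0);")
  D <- ape::cophenetic.phylo(true)
  tree <- neighbour_joining(D[letters[1:4], letters[1:4]])
  expect_equal(ape::cophenetic.phylo(tree)[letters[1:4], letters[1:4]],
               D[letters[1:4], letters[1:4]], tolerance = 1e-10)
  # topology: a,b vs c,d split present
  splits <- ape::prop.part(tree)
  expect_true(any(vapply(splits, function(s) {
    setequal(tree$tip.label[s], c("a", "b")) ||
      setequal(tree$tip.label[s], c("c", "d"))
  }, logical(1))))
  # ultrametric equidistant 3 taxa: equal leaf branches
  De <- matrix(2, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  diag(De) <- 0
  te <- neighbour_joining(De)
  expect_true(all(abs(te$edge.length[match(1:3, te$edge[, 2])] - 1) < 1e-12))
})

test_that("bootstrap strongly supports a 20-difference clade split", {
  ref <- random_dna_str(1200, seed = 91)
  aln <- simulate_haplotype_alignment(ref, n_clades = 2, n_per_clade = 4,
                                      n_clade_sites = 20, n_private_sites = 2,
                                      seed = 92)
  bs <- bootstrap_support(aln, replicates = 100, seed = 93)
  clade_a <- names(attr(aln, "clade"))[attr(aln, "clade") == "A"]
  node <- ape::getMRCA(bs$tree, clade_a)
  supp <- as.integer(bs$tree$node.label[node - length(bs$tree$tip.label)])
  expect_gte(supp, 95)
  # no supports when replicates = 0
  expect_null(bootstrap_support(aln, replicates = 0)$supports)
  # permuting taxon order leaves the split support unchanged
  perm <- aln[rev(seq_along(aln))]
  attr(perm, "clade") <- attr(aln, "clade")
  bs2 <- bootstrap_support(perm, replicates = 100, seed = 93)
  node2 <- ape::getMRCA(bs2$tree, clade_a)
  supp2 <- as.integer(bs2$tree$node.label[node2 - length(bs2$tree$tip.label)])
  expect_identical(supp2, supp)
})

test_that("sample placement lands in the matching clade", {
  ref <- random_dna_str(1500, seed = 95)
  aln <- simulate_haplotype_alignment(ref, n_clades = 2, n_per_clade = 5,
                                      n_clade_sites = 25, n_private_sites = 2,
                                      seed = 96)
  clades <- attr(aln, "clade")
  b_members <- names(clades)[clades == "B"]
  # sample: a further mutated member of clade B
  samp <- mutate_sequence(aln[[b_members[1]]], n = 2, seed = 97)$seq
  pl <- place_sample(samp, aln)
  expect_true(pl$nearest$taxon[1] %in% b_members)
  expect_true(all(pl$sister %in% b_members))
  # identical to one reference: zero distance
  pl2 <- place_sample(aln[[b_members[2]]], aln)
  expect_identical(pl2$nearest$taxon[1], b_members[2])
  expect_equal(pl2$nearest$distance[1], 0)
  expect_error(place_sample(substr(samp, 1, 100), aln), "length")
  expect_error(place_sample(strrep("-", 1500), aln), "ungapped")
})
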