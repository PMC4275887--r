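# Synthetic-data generator: multi-species toy genomes with controlled
# homology, damaged short single-end reads with controlled admixture,
# mitochondrial haplotype mixtures, and structured multi-breed SNP panels.
# Every generator returns a truth record so parameter recovery can be tested.
#
# All randomness flows from a single integer seed; independent stages draw
# from named streams derived with derive_seed(), so e.g. changing the damage
# rate does not change which fragments are drawn.

# ---- configurations ----------------------------------------------------------

#' Configuration for the toy genome generator
#'
#' The defaults emulate a four-species screening setup (a sheep-like source
#' plus cow-, goat- and human-like candidates) at desk scale: every species
#' shares the same contig structure (two autosomes, an X and a mitochondrial
#' contig) so coordinates are comparable, with per-species divergence from a
#' common ancestral sequence chosen so pairwise divergences fall in the
#' 8-25% range typical of the ruminant/human comparisons the screen must
#' separate.
#'
#' @param seed integer seed.
#' @param species character vector of genome names; the first is the target.
#' @param divergence named per-species substitution fraction from the common
#'   ancestor, each in `[0, 0.5]`.
#' @param contig_spec `data.frame` with columns `name`, `length`, `class`
#'   (`autosome`/`X`/`mito`), shared by all species.
#' @param shared_repeat `c(length =, copies =)`: a repeat planted verbatim in
#'   every genome to create cross-mapping homology.
#' @param gc target GC fraction of the ancestral sequence.
#' @param indiv_divergence substitution fraction between the target
#'   individual and a second individual of the same species.
#' @return a `sim_genome_config` list.
#' @export
sim_genome_config <- function(seed = 1L,
                              species = c("sheep", "cow", "goat", "human"),
                              divergence = c(sheep = 0.04, cow = 0.05,
                                             goat = 0.08, human = 0.15),
                              contig_spec = data.frame(
                                name = c("chr1", "chr2", "chrX", "chrM"),
                                length = c(30000L, 30000L, 15000L, 16565L),
                                class = c("autosome", "autosome", "X", "mito"),
                                stringsAsFactors = FALSE),
                              shared_repeat = c(length = 100L, copies = 5L),
                              gc = 0.42,
                              indiv_divergence = 0.002) {
  if (length(species) < 2) stop("need at least two species", call. = FALSE)
  divergence <- divergence[species]
  if (any(is.na(divergence)) || any(divergence < 0) || any(divergence > 0.5)) {
    stop("divergence must be given for every species and lie in [0, 0.5]",
         call. = FALSE)
  }
  if (any(contig_spec$length <= 0)) stop("contig lengths must be > 0", call. = FALSE)
  if (gc <= 0 || gc >= 1) stop("gc must be in (0, 1)", call. = FALSE)
  structure(list(seed = as.integer(seed), species = species,
                 divergence = divergence, contig_spec = contig_spec,
                 shared_repeat = shared_repeat, gc = gc,
                 indiv_divergence = indiv_divergence),
            class = "sim_genome_config")
}

#' Configuration for the ancient-read simulator
#'
#' Defaults follow a short single-end ancient library: 49 bp reads from
#' lognormal fragments truncated to 18-150 bp, a double-stranded deamination
#' model (5' C->T, mirrored 3' G->A) with geometric decay into the read, a
#' small per-base error rate, constant Q35 base qualities and a universal
#' adapter appended when the fragment is shorter than the read.
#'
#' @param seed integer seed.
#' @param read_length sequencing read length in bp.
#' @param n_reads number of reads.
#' @param fragment_mean,fragment_sd mean/sd (bp) of the lognormal fragment
#'   length distribution before truncation to `[18, 150]`.
#' @param delta5 5' C->T deamination probability at the terminal position.
#' @param lambda per-position geometric decay of deamination moving inward.
#' @param seq_error per-base sequencing error probability.
#' @param adapter adapter sequence entering reads that sequence through the
#'   fragment.
#' @param mix named proportions over sources; valid names are `target`,
#'   `individual2` and the non-target species of the genome set.
#' @param dup_fraction fraction of reads that are PCR duplicates of an
#'   earlier fragment.
#' @param x_depth_factor relative sampling weight of X contigs (1 emulates a
#'   female, 0.5 a male).
#' @return a `sim_read_config` list.
#' @export
sim_read_config <- function(seed = 1L, read_length = 49L, n_reads = 10000L,
                            fragment_mean = 45, fragment_sd = 12,
                            delta5 = 0.1, lambda = 0.3, seq_error = 0.001,
                            adapter = "AGATCGGAAGAGC",
                            mix = c(target = 0.95, individual2 = 0.01,
                                    cow = 0.015, goat = 0.015, human = 0.01),
                            dup_fraction = 0, x_depth_factor = 1) {
  for (p in list(delta5 = delta5, lambda = lambda, seq_error = seq_error,
                 dup_fraction = dup_fraction)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(mix) - 1) > 1e-8) stop("mix proportions must sum to 1", call. = FALSE)
  if (is.null(names(mix)) || any(!nzchar(names(mix)))) {
    stop("mix must be a named vector", call. = FALSE)
  }
  structure(list(seed = as.integer(seed), read_length = as.integer(read_length),
                 n_reads = as.integer(n_reads), fragment_mean = fragment_mean,
                 fragment_sd = fragment_sd, delta5 = delta5, lambda = lambda,
                 seq_error = seq_error, adapter = toupper(adapter), mix = mix,
                 dup_fraction = dup_fraction, x_depth_factor = x_depth_factor),
            class = "sim_read_config")
}

#' Configuration for the structured SNP panel generator
#'
#' Breed allele frequencies follow the Balding-Nichols model around a shared
#' ancestral frequency; genotypes are Hardy-Weinberg within breed. Default
#' breed coordinates spread over a British-Isles-like bounding box, matching
#' the geographic framing of breed-affinity maps.
#'
#' @param seed integer seed.
#' @param n_breeds number of breeds.
#' @param n_sites number of biallelic sites (allele pairs drawn uniformly
#'   from all six unordered base pairs, so downstream transition and
#'   strand-ambiguity filters are exercised).
#' @param fst Balding-Nichols differentiation parameter, in (0, 1).
#' @param n_per_breed individuals per breed.
#' @param coords optional `data.frame` with columns `breed`, `lon`, `lat`.
#' @param target_breed breed the simulated artefact individual is drawn
#'   from; defaults to the first breed.
#' @return a `sim_panel_config` list.
#' @export
sim_panel_config <- function(seed = 1L, n_breeds = 8L, n_sites = 6000L,
                             fst = 0.15, n_per_breed = 12L, coords = NULL,
                             target_breed = NULL) {
  if (fst <= 0 || fst >= 1) stop("fst must lie in (0, 1)", call. = FALSE)
  if (n_sites < 1) stop("n_sites must be >= 1", call. = FALSE)
  breeds <- sprintf("breed%02d", seq_len(n_breeds))
  if (is.null(coords)) {
    lon <- seq(-10, 2, length.out = n_breeds)
    lat <- rep(c(51, 54, 57), length.out = n_breeds)
    coords <- data.frame(breed = breeds, lon = lon, lat = lat,
                         stringsAsFactors = FALSE)
  }
  if (anyDuplicated(coords[, c("lon", "lat")])) {
    stop("breed coordinates must be unique", call. = FALSE)
  }
  target_breed <- target_breed %||% breeds[1]
  if (!target_breed %in% breeds) stop("unknown target breed", call. = FALSE)
  structure(list(seed = as.integer(seed), n_breeds = as.integer(n_breeds),
                 n_sites = as.integer(n_sites), fst = fst,
                 n_per_breed = as.integer(n_per_breed), coords = coords,
                 breeds = breeds, target_breed = target_breed),
            class = "sim_panel_config")
}

# ---- genomes -----------------------------------------------------------------

random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# substitute a fraction of positions, each to a uniformly chosen other base;
# returns list(seq, sites) with 0-based substituted positions
substitute_seq <- function(seq, rate) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- which(runif(length(v)) < rate)
  if (length(idx)) {
    bases <- c("A", "C", "G", "T")
    shift <- sample.int(3, length(idx), replace = TRUE)
    v[idx] <- bases[(match(v[idx], bases) - 1L + shift) %% 4L + 1L]
  }
  list(seq = paste(v, collapse = ""), sites = idx - 1L)
}

splice_in <- function(seq, start0, insert) {
  # overwrite (not insert) so coordinates stay fixed
  paste0(substr(seq, 1, start0), insert,
         substr(seq, start0 + nchar(insert) + 1, nchar(seq)))
}

#' Simulate a set of homologous toy genomes
#'
#' Every species descends from one ancestral sequence by independent random
#' substitution, so the expected pairwise identity between species i and j is
#' `(1-di)(1-dj) + di*dj/3`. A shared repeat is planted verbatim at the same
#' coordinates in every genome to create cross-mapping homology, and a
#' tandem duplicated motif (75 bp x 2) is planted in each mitochondrial
#' contig to emulate the ambiguously aligning control-region repeat. A second
#' individual of the target species is generated at `indiv_divergence`.
#'
#' @param cfg a [sim_genome_config()].
#' @return an object of class `sim_genomes`: list with elements `db` (a
#'   [genome_db()] over the species), `individual2` (contig vector for the
#'   second target-species individual), `species`, `cfg` and `truth`
#'   (repeat coordinates, mito motif interval, per-species substituted
#'   sites, second-individual sites).
#' @export
simulate_genomes <- function(cfg = sim_genome_config()) {
  stopifnot(inherits(cfg, "sim_genome_config"))
  withr::with_seed(derive_seed(cfg$seed, "genomes"), {
    spec <- cfg$contig_spec
    anc <- stats::setNames(
      vapply(spec$length, random_dna, character(1), gc = cfg$gc), spec$name)

    rep_len <- as.integer(cfg$shared_repeat[["length"]])
    rep_copies <- as.integer(cfg$shared_repeat[["copies"]])
    repeat_seq <- if (rep_len > 0 && rep_copies > 0) random_dna(rep_len, cfg$gc) else ""

    # repeat placement: spread copies over autosome contigs, identical
    # coordinates in every species
    rep_pos <- NULL
    if (nzchar(repeat_seq)) {
      auto <- spec$name[spec$class == "autosome"]
      tgt_contig <- rep(auto, length.out = rep_copies)
      rep_pos <- do.call(rbind, lapply(seq_len(rep_copies), function(i) {
        clen <- spec$length[spec$name == tgt_contig[i]]
        k <- sum(tgt_contig[seq_len(i)] == tgt_contig[i])
        n_on <- sum(tgt_contig == tgt_contig[i])
        start <- floor(clen * k / (n_on + 1))
        data.frame(contig = tgt_contig[i], start = as.integer(start),
                   stringsAsFactors = FALSE)
      }))
    }

    mito_name <- spec$name[spec$class == "mito"]
    mito_motif_interval <- NULL

    genomes <- list()
    subs <- list()
    for (sp in cfg$species) {
      mut <- lapply(anc, substitute_seq, rate = cfg$divergence[[sp]])
      contigs <- vapply(mut, `[[`, character(1), "seq")
      subs[[sp]] <- lapply(mut, `[[`, "sites")
      if (!is.null(rep_pos)) {
        for (i in seq_len(nrow(rep_pos))) {
          cn <- rep_pos$contig[i]
          contigs[[cn]] <- splice_in(contigs[[cn]], rep_pos$start[i], repeat_seq)
        }
      }
      # tandem control-region-like motif: duplicate a species-specific 75 bp
      # window so the two copies are identical within each genome
      if (length(mito_name) == 1) {
        mlen <- nchar(contigs[[mito_name]])
        mstart <- mlen - 400L
        motif <- substr(contigs[[mito_name]], mstart + 1L, mstart + 75L)
        contigs[[mito_name]] <- splice_in(contigs[[mito_name]], mstart + 75L, motif)
        mito_motif_interval <- c(mstart, mstart + 150L)
      }
      genomes[[sp]] <- contigs
    }

    classes <- stats::setNames(rep(list(stats::setNames(spec$class, spec$name)),
                                   length(cfg$species)), cfg$species)
    db <- genome_db(genomes, classes = classes)

    ind2 <- lapply(genomes[[cfg$species[1]]], substitute_seq,
                   rate = cfg$indiv_divergence)
    individual2 <- vapply(ind2, `[[`, character(1), "seq")

    structure(list(
      db = db, individual2 = individual2, species = cfg$species, cfg = cfg,
      truth = list(repeat_seq = repeat_seq, repeat_positions = rep_pos,
                   mito_motif_interval = mito_motif_interval,
                   substituted_sites = subs,
                   individual2_sites = lapply(ind2, `[[`, "sites"))),
      class = "sim_genomes")
  })
}

# ---- reads -------------------------------------------------------------------

# truncated lognormal fragment lengths (rejection sampling)
draw_fragment_lengths <- function(n, mean, sd, lo = 18L, hi = 150L) {
  s2 <- log(1 + (sd / mean)^2)
  mu <- log(mean) - s2 / 2
  out <- integer(0)
  while (length(out) < n) {
    x <- as.integer(round(stats::rlnorm(n, mu, sqrt(s2))))
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

# the shared fragment/damage/error engine behind simulate_reads() and
# simulate_mito_reads(); sources is a named list of contig vectors
sim_reads_engine <- function(sources, mix, cfg, id_prefix = "read") {
  n <- cfg$n_reads
  if (n < 1) stop("n_reads must be >= 1", call. = FALSE)
  for (s in names(sources)) {
    if (length(sources[[s]]) == 0 || any(!nzchar(sources[[s]]))) {
      stop("empty genome for source ", s, call. = FALSE)
    }
  }
  bad <- setdiff(names(mix), names(sources))
  if (length(bad)) {
    stop("mix names unknown source(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }

  layout <- withr::with_seed(derive_seed(cfg$seed, "layout"), {
    src <- sample(names(mix), n, replace = TRUE, prob = mix)
    dup <- runif(n) < cfg$dup_fraction
    dup[1] <- FALSE
    nd <- which(!dup)
    flen <- draw_fragment_lengths(length(nd), cfg$fragment_mean, cfg$fragment_sd)
    contig <- character(length(nd))
    for (s in unique(src[nd])) {
      rows <- which(src[nd] == s)
      ctg <- sources[[s]]
      w <- nchar(ctg)
      cls <- contig_class_heuristic(names(ctg))
      w[cls == "X"] <- w[cls == "X"] * cfg$x_depth_factor
      contig[rows] <- sample(names(ctg), length(rows), replace = TRUE,
                             prob = w / sum(w))
    }
    clen <- nchar(mapply(function(s, cn) sources[[s]][[cn]], src[nd], contig))
    flen <- pmin(flen, clen)
    start <- as.integer(floor(runif(length(nd)) * (clen - flen + 1)))
    strand <- sample(c("+", "-"), length(nd), replace = TRUE)
    tpl <- seq_len(n)
    tpl[dup] <- sample(nd, sum(dup), replace = TRUE)
    list(src = src, dup = dup, nd = nd, flen = flen, contig = contig,
         start = start, strand = strand, tpl = tpl)
  })

  nd <- layout$nd
  frag <- substring(
    mapply(function(s, cn) sources[[s]][[cn]], layout$src[nd], layout$contig),
    layout$start + 1L, layout$start + layout$flen)
  frag[layout$strand == "-"] <- revcomp(frag[layout$strand == "-"])

  # damage on distinct fragments, read (5'->3') orientation
  lmax <- max(layout$flen)
  codes <- utf8ToInt("ACGTN")
  M <- t(vapply(frag, function(s) {
    v <- utf8ToInt(s)
    c(v, rep(0L, lmax - length(v)))
  }, integer(lmax), USE.NAMES = FALSE))
  C <- utf8ToInt("C"); G <- utf8ToInt("G")
  Tt <- utf8ToInt("T"); A <- utf8ToInt("A")
  lens <- layout$flen
  dmg_row <- integer(0); dmg_pos <- integer(0)
  withr::with_seed(derive_seed(cfg$seed, "damage"), {
    for (k in seq_len(lmax)) {
      valid <- lens >= k
      u5 <- runif(nrow(M))
      p5 <- cfg$delta5 * (1 - cfg$lambda)^(k - 1)
      hit5 <- valid & M[, k] == C & u5 < p5
      u3 <- runif(nrow(M))
      p3 <- cfg$delta5 * (1 - cfg$lambda)^(lens - k)
      hit3 <- valid & M[, k] == G & u3 < p3
      if (any(hit5)) M[hit5, k] <- Tt
      if (any(hit3)) M[hit3, k] <- A
      hits <- which(hit5 | hit3)
      dmg_row <- c(dmg_row, hits)
      dmg_pos <- c(dmg_pos, rep.int(k, length(hits)))
    }
  })

  # expand distinct fragments to reads (duplicates copy the damaged template)
  nd_of <- integer(n); nd_of[nd] <- seq_along(nd)
  tpl_nd <- nd_of[layout$tpl]
  Mx <- M[tpl_nd, , drop = FALSE]
  lens_x <- lens[tpl_nd]

  withr::with_seed(derive_seed(cfg$seed, "error"), {
    if (cfg$seq_error > 0) {
      for (k in seq_len(lmax)) {
        u <- runif(n)
        shift <- sample.int(3, n, replace = TRUE)
        hit <- lens_x >= k & u < cfg$seq_error
        if (any(hit)) {
          cur <- match(Mx[hit, k], codes[1:4])
          keep <- !is.na(cur)
          rows <- which(hit)[keep]
          Mx[rows, k] <- codes[(cur[keep] - 1L + shift[rows]) %% 4L + 1L]
        }
      }
    }
  })

  rl <- cfg$read_length
  seqs <- vapply(seq_len(n), function(i) {
    intToUtf8(Mx[i, seq_len(min(lens_x[i], rl))])
  }, character(1))
  short <- lens_x < rl
  seqs[short] <- paste0(seqs[short], substr(cfg$adapter, 1, rl - lens_x[short]))

  ids <- sprintf("%s%06d", id_prefix, seq_len(n))
  reads <- read_set(ids, seqs)

  dmg_str <- rep("", length(nd))
  if (length(dmg_row)) {
    agg <- split(dmg_pos, dmg_row)
    dmg_str[as.integer(names(agg))] <-
      vapply(agg, function(p) paste(sort(p), collapse = ","), character(1))
  }
  frag_start <- layout$start[tpl_nd]
  strand_x <- layout$strand[tpl_nd]
  truth <- data.frame(
    id = ids,
    source = layout$src,
    contig = layout$contig[tpl_nd],
    start = frag_start,
    # reference start of the sequenced read: minus-strand reads sequence the
    # fragment from its 3' reference end inward
    read_start = ifelse(strand_x == "+", frag_start,
                        frag_start + lens_x - pmin(lens_x, rl)),
    strand = strand_x,
    frag_len = lens_x,
    is_duplicate = layout$dup,
    template_id = ids[layout$tpl],
    damage_positions = dmg_str[tpl_nd],
    n_damage = vapply(strsplit(dmg_str[tpl_nd], ","),
                      function(x) sum(nzchar(x)), integer(1)),
    stringsAsFactors = FALSE
  )
  list(reads = reads, truth = truth)
}

#' Simulate an ancient single-end read set
#'
#' Draws reads from a mixture of sources (the target individual, a second
#' individual of the same species, and the other species in the genome set),
#' applies the double-stranded deamination model and per-base sequencing
#' error, and appends adapter sequence to reads that sequence through their
#' fragment. Deterministic given the seed; the fragment layout, damage and
#' error stages draw from independent derived streams.
#'
#' @param sim a `sim_genomes` object from [simulate_genomes()].
#' @param cfg a [sim_read_config()].
#' @return list with elements `reads` (a read set) and `truth` (per-read
#'   source, origin coordinates, fragment length, duplicate template and
#'   damage positions).
#' @export
simulate_reads <- function(sim, cfg = sim_read_config()) {
  stopifnot(inherits(sim, "sim_genomes"), inherits(cfg, "sim_read_config"))
  sources <- list(target = genome_contigs(sim$db, sim$species[1]),
                  individual2 = sim$individual2)
  for (sp in sim$species[-1]) sources[[sp]] <- genome_contigs(sim$db, sp)
  sim_reads_engine(sources, cfg$mix, cfg)
}

#' Simulate mitochondrial reads from a target/contaminant haplotype mixture
#'
#' @param haplotypes named character vector of equal-length ungapped
#'   haplotype sequences.
#' @param target,contaminant haplotype names; must differ.
#' @param rho contaminant fraction in `[0, 1]`.
#' @param cfg a [sim_read_config()]; its `mix` field is ignored.
#' @return list with `reads`, `truth` (per-read source and coordinates) and
#'   `diagnostic_sites` (0-based positions where target and contaminant
#'   differ).
#' @export
simulate_mito_reads <- function(haplotypes, target, contaminant, rho,
                                cfg = sim_read_config()) {
  if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]", call. = FALSE)
  stopifnot(target %in% names(haplotypes), contaminant %in% names(haplotypes))
  if (identical(target, contaminant)) {
    stop("target and contaminant must differ", call. = FALSE)
  }
  tseq <- toupper(haplotypes[[target]])
  cseq <- toupper(haplotypes[[contaminant]])
  if (nchar(tseq) != nchar(cseq)) {
    stop("haplotypes must have equal length", call. = FALSE)
  }
  if (grepl("-", tseq, fixed = TRUE) || grepl("-", cseq, fixed = TRUE)) {
    stop("read simulation requires ungapped haplotypes", call. = FALSE)
  }
  tv <- strsplit(tseq, "")[[1]]
  cv <- strsplit(cseq, "")[[1]]
  diag_sites <- which(tv != cv) - 1L
  sources <- list(target = c(chrM = tseq), contaminant = c(chrM = cseq))
  mix <- c(target = 1 - rho, contaminant = rho)
  out <- sim_reads_engine(sources, mix, cfg, id_prefix = "mt")
  out$diagnostic_sites <- diag_sites
  out
}

#' Derive a mutated haplotype from a sequence
#'
#' Utility for building haplotype panels: substitutes `n` positions (or a
#' per-position `rate`), optionally restricted to transversions so the
#' variants survive the ancient-DNA transition filters.
#'
#' @param seq a DNA string.
#' @param n number of substitutions (exclusive with `rate`).
#' @param rate per-position substitution probability.
#' @param seed integer seed.
#' @param transversions_only restrict substitutions to transversions.
#' @param avoid 0-based positions that must not be touched.
#' @return list with `seq` (mutated string) and `sites` (0-based positions).
#' @export
mutate_sequence <- function(seq, n = NULL, rate = NULL, seed = 1L,
                            transversions_only = FALSE, avoid = integer(0)) {
  stopifnot(xor(is.null(n), is.null(rate)))
  withr::with_seed(derive_seed(seed, "mutate"), {
    v <- strsplit(toupper(seq), "")[[1]]
    ok <- setdiff(which(v %in% c("A", "C", "G", "T")), avoid + 1L)
    idx <- if (!is.null(n)) sort(sample(ok, n)) else sort(ok[runif(length(ok)) < rate])
    # transversion partners: purines -> pyrimidines and vice versa
    tv <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G"))
    for (i in idx) {
      choices <- if (transversions_only) tv[[v[i]]] else setdiff(c("A", "C", "G", "T"), v[i])
      v[i] <- sample(choices, 1)
    }
    list(seq = paste(v, collapse = ""), sites = idx - 1L)
  })
}

#' Simulate an aligned haplotype panel with clade structure
#'
#' Builds `n_clades` clades from a reference sequence: each clade carries a
#' block of shared (fixed) differences, each member a few private ones.
#' Sequences are ungapped and equal length, i.e. already aligned.
#'
#' @param ref reference DNA string.
#' @param n_clades number of clades.
#' @param n_per_clade members per clade.
#' @param n_clade_sites fixed differences defining each clade.
#' @param n_private_sites private differences per member.
#' @param seed integer seed.
#' @return named character vector of haplotypes with a `clade` attribute
#'   (named character vector member -> clade label).
#' @export
simulate_haplotype_alignment <- function(ref, n_clades = 2, n_per_clade = 5,
                                         n_clade_sites = 20, n_private_sites = 3,
                                         seed = 1L) {
  out <- character(0)
  clade <- character(0)
  for (ci in seq_len(n_clades)) {
    base <- mutate_sequence(ref, n = n_clade_sites,
                            seed = derive_seed(seed, paste0("clade", ci)),
                            transversions_only = TRUE)
    for (mi in seq_len(n_per_clade)) {
      m <- mutate_sequence(base$seq, n = n_private_sites,
                           seed = derive_seed(seed, sprintf("c%dm%d", ci, mi)),
                           transversions_only = TRUE, avoid = base$sites)
      nm <- sprintf("hap%s%02d", LETTERS[ci], mi)
      out[nm] <- m$seq
      clade[nm] <- LETTERS[ci]
    }
  }
  attr(out, "clade") <- clade
  out
}

# ---- SNP panel ---------------------------------------------------------------

#' Simulate a structured multi-breed SNP panel
#'
#' Per-site ancestral frequencies are uniform on `[0.1, 0.9]`; per-breed
#' frequencies follow Balding-Nichols
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`; genotypes are Hardy-Weinberg within
#' breed. A target individual is drawn from `target_breed` and returned with
#' the truth record.
#'
#' @param cfg a [sim_panel_config()].
#' @return an object of class `sim_panel`: list with `panel` (an
#'   [snp_panel()]), `target` (true diploid genotypes of the artefact
#'   individual), `target_breed` and `truth` (ancestral and per-breed
#'   frequencies).
#' @export
simulate_panel <- function(cfg = sim_panel_config()) {
  stopifnot(inherits(cfg, "sim_panel_config"))
  withr::with_seed(derive_seed(cfg$seed, "panel"), {
    ns <- cfg$n_sites
    pairs <- c("AC", "AG", "AT", "CG", "CT", "GT")
    pair <- sample(pairs, ns, replace = TRUE)
    sites <- data.frame(
      site_id = sprintf("snp%05d", seq_len(ns)),
      contig = "chr1",
      pos = seq_len(ns) * 10L,
      allele_a = substr(pair, 1, 1),
      allele_b = substr(pair, 2, 2),
      stringsAsFactors = FALSE
    )
    p_anc <- runif(ns, 0.1, 0.9)
    f <- cfg$fst
    breed_freq <- vapply(cfg$breeds, function(b) {
      stats::rbeta(ns, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
    }, numeric(ns))

    geno_of <- function(p) {
      k <- stats::rbinom(length(p), 2L, p) # copies of allele_a
      a <- sites$allele_a; b <- sites$allele_b
      g <- character(length(p))
      g[k == 2] <- paste0(a, a)[k == 2]
      g[k == 1] <- paste0(a, b)[k == 1] # alleles are stored in sorted order
      g[k == 0] <- paste0(b, b)[k == 0]
      g
    }

    geno <- matrix(NA_character_, ns, cfg$n_breeds * cfg$n_per_breed)
    indiv <- data.frame(individual = character(0), breed = character(0),
                        stringsAsFactors = FALSE)
    col <- 0L
    for (bi in seq_len(cfg$n_breeds)) {
      for (ii in seq_len(cfg$n_per_breed)) {
        col <- col + 1L
        geno[, col] <- geno_of(breed_freq[, bi])
        indiv <- rbind(indiv, data.frame(
          individual = sprintf("%s_i%02d", cfg$breeds[bi], ii),
          breed = cfg$breeds[bi], stringsAsFactors = FALSE))
      }
    }
    indiv <- merge(indiv, cfg$coords, by = "breed", sort = FALSE)
    indiv <- indiv[, c("individual", "breed", "lon", "lat")]

    target <- geno_of(breed_freq[, match(cfg$target_breed, cfg$breeds)])

    structure(list(
      panel = snp_panel(sites, geno, indiv),
      target = target,
      target_breed = cfg$target_breed,
      cfg = cfg,
      truth = list(p_ancestral = p_anc, breed_freq = breed_freq)),
      class = "sim_panel")
  })
}
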