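# Small fixture builders shared across test files. Everything is generated
# in code; no stored data.

random_dna_str <- function(n, seed = 1) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = ""))
}

# hits data.frame in the shape align_reads()/assign_mapq() produce
make_hits <- function(read_id, contig = "chr1", start = 0L, strand = "+",
                      mismatches = 0L, mapq = 37L, genome = "g1") {
  data.frame(read_id = read_id, genome = genome, contig = contig,
             start = start, strand = strand, mismatches = mismatches,
             mapq = mapq, stringsAsFactors = FALSE)
}

# brute-force alignment oracle built on Biostrings::matchPattern, kept
# independent of the package's seeded aligner
oracle_align <- function(read_seq, contigs, max_mismatch) {
  out <- list()
  for (cn in names(contigs)) {
    subject <- Biostrings::DNAString(contigs[[cn]])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") read_seq else as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(read_seq)))
      m <- Biostrings::matchPattern(pat, subject, max.mismatch = max_mismatch,
                                    with.indels = FALSE, fixed = TRUE)
      if (length(m) == 0) next
      mm <- Biostrings::neditStartingAt(Biostrings::DNAString(pat), subject,
                                        starting.at = BiocGenerics::start(m),
                                        fixed = TRUE)
      out[[length(out) + 1]] <- data.frame(
        contig = cn, start = BiocGenerics::start(m) - 1L, strand = strand,
        mismatches = mm, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(contig = character(0), start = integer(0),
                      strand = character(0), mismatches = integer(0)))
  }
  do.call(rbind, out)
}

hit_key <- function(df) {
  sort(paste(df$contig, df$start, df$strand, df$mismatches, sep = ":"))
}

# tiny two-genome database with engineered unique/shared/repeated segments
tiny_screen_db <- function() {
  shared <- random_dna_str(60, seed = 11)
  uniq1 <- random_dna_str(60, seed = 12)
  uniq2 <- random_dna_str(60, seed = 13)
  dup <- random_dna_str(40, seed = 14)
  pad1 <- random_dna_str(40, seed = 15)
  pad2 <- random_dna_str(40, seed = 16)
  g1 <- paste0(uniq1, pad1, shared, pad2, dup, pad1, dup)
  g2 <- paste0(uniq2, pad2, shared, pad1, random_dna_str(120, seed = 17))
  genome_db(list(g1 = c(chr1 = g1), g2 = c(chr1 = g2)))
}
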