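# Desk-scale ungapped multi-genome aligner plus the four-category screening
# classifier and the species call.
#
# The aligner is seeded and end-to-end: a read is split into m+1
# non-overlapping blocks and a seed of length seed_len is taken from the
# start of each; any placement with at most m mismatches must match one
# block exactly (pigeonhole), so the search is complete whenever
# seed_len <= floor(read_length / (m+1)). With the default seed_len 7 this
# holds for reads of at least 28 bp at m <= 3, which covers everything the
# 30 bp length filter lets through. Larger seeds (e.g. 12) are accepted for
# speed with a documented loss of completeness on shorter reads.

#' Build a k-mer seed index over a genome database
#'
#' Indexes every genomic position of every seed; both strands are served by
#' reverse-complementing the read at query time.
#'
#' @param db a [genome_db()].
#' @param seed_len seed length in bp, at least 4.
#' @return an object of class `genome_index`.
#' @export
build_index <- function(db, seed_len = 7L) {
  stopifnot(inherits(db, "genome_db"))
  seed_len <- as.integer(seed_len)
  if (seed_len < 4L) stop("seed_len must be at least 4", call. = FALSE)
  for (g in names(db$genomes)) {
    if (any(nchar(db$genomes[[g]]$contigs) < seed_len)) {
      stop("every contig must be at least seed_len long", call. = FALSE)
    }
  }
  ptrs <- lapply(names(db$genomes), function(g) {
    contigs <- db$genomes[[g]]$contigs
    cpp_index_build(names(contigs), unname(contigs), seed_len)
  })
  names(ptrs) <- names(db$genomes)
  structure(list(ptrs = ptrs, seed_len = seed_len, db = db,
                 genomes = names(db$genomes)),
            class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat(sprintf("<genome_index> seed_len=%d over %s\n", x$seed_len,
              paste(x$genomes, collapse = ", ")))
  invisible(x)
}

#' Look up all positions of a seed in one indexed genome
#'
#' @param index a [build_index()] result.
#' @param genome genome name.
#' @param seed sequence of exactly `seed_len` bases.
#' @return `data.frame` with columns `contig` and `pos` (0-based); empty if
#'   the seed is absent.
#' @export
seed_positions <- function(index, genome, seed) {
  stopifnot(inherits(index, "genome_index"))
  if (nchar(seed) != index$seed_len) {
    stop("seed must have length seed_len", call. = FALSE)
  }
  hit <- cpp_index_query(index$ptrs[[genome]], toupper(seed))
  contigs <- cpp_index_contigs(index$ptrs[[genome]])
  data.frame(contig = contigs[hit$contig], pos = hit$pos,
             stringsAsFactors = FALSE)
}

#' Align reads end-to-end against every genome in an index
#'
#' Returns all placements (both strands, all genomes) with at most
#' `max_mismatch` mismatches; an N in the read or the reference counts as a
#' mismatch. Ungapped only.
#'
#' @param reads read set `data.frame`.
#' @param index a [build_index()] result.
#' @param max_mismatch maximum mismatches per placement (0-3 is the
#'   screening range).
#' @return hits `data.frame` with columns `read_id`, `genome`, `contig`,
#'   `start` (0-based), `strand`, `mismatches`.
#' @export
align_reads <- function(reads, index, max_mismatch = 3L) {
  stopifnot(inherits(index, "genome_index"))
  if (any(nchar(reads$seq) < index$seed_len)) {
    stop("all reads must be at least seed_len long; length-filter first",
         call. = FALSE)
  }
  out <- lapply(index$genomes, function(g) {
    h <- cpp_align(index$ptrs[[g]], reads$seq, as.integer(max_mismatch))
    contigs <- cpp_index_contigs(index$ptrs[[g]])
    data.frame(read_id = reads$id[h$read], genome = rep(g, nrow(h)),
               contig = contigs[h$contig], start = h$start,
               strand = ifelse(h$fwd == 1L, "+", "-"),
               mismatches = h$mismatches, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Align a single read
#'
#' @param read a sequence string or a one-row read set.
#' @inheritParams align_reads
#' @return hits `data.frame` as in [align_reads()].
#' @export
align_read <- function(read, index, max_mismatch = 3L) {
  if (is.character(read)) read <- read_set("read1", read)
  align_reads(read, index, max_mismatch)
}

#' Assign a mapping-quality surrogate to hits
#'
#' Per read and genome: a unique best hit with no alternative within 2
#' mismatches of it scores 37; a best hit tied with another location scores
#' 0; a unique best hit with a close alternative scores 25. Non-best hits
#' score 0. The scheme is a deliberate simplification of aligner mapping
#' quality: thresholding at 30 retains exactly the confidently unique tier.
#'
#' @param hits hits `data.frame` from [align_reads()].
#' @return `hits` with a `mapq` column added.
#' @export
assign_mapq <- function(hits) {
  if (nrow(hits) == 0) {
    hits$mapq <- integer(0)
    return(hits)
  }
  dt <- as.data.table(hits)
  dt[, best_mm := min(mismatches), by = .(read_id, genome)]
  dt[, n_best := sum(mismatches == best_mm), by = .(read_id, genome)]
  dt[, n_hits := .N, by = .(read_id, genome)]
  dt[, mapq := 0L]
  dt[mismatches == best_mm & n_best == 1L, mapq := 25L]
  # 37 when no *other* hit lies within best_mm + 2
  dt[, second_mm := {
    s <- sort(mismatches)
    if (.N == 1L) NA_integer_ else s[2]
  }, by = .(read_id, genome)]
  dt[mismatches == best_mm & n_best == 1L &
       (is.na(second_mm) | second_mm - best_mm > 2L), mapq := 37L]
  out <- as.data.frame(dt[, .(read_id, genome, contig, start, strand,
                              mismatches, mapq)])
  out
}

SCREEN_CATEGORIES <- c("unique_one_genome", "multi_one_genome",
                       "unique_multi_genome", "multi_multi_genome")

#' Screen reads against multiple genomes
#'
#' Re-creates multi-genome contamination screening: at each mismatch
#' tolerance every read is classified as aligning uniquely to a single
#' genome, to multiple places in the same genome, uniquely in more than one
#' genome, or to multiple places in multiple genomes (or no hit). Fractions
#' are reported per genome (a read in a multi-genome category counts for
#' every genome it hits), with all reads as the denominator. All reads are
#' screened (no subsampling).
#'
#' @param reads read set `data.frame` (adapter-trimmed, length-filtered).
#' @param index a [build_index()] over the candidate genomes.
#' @param tolerances mismatch tolerances to report (hits are computed once
#'   at the maximum).
#' @return an object of class `screen_report`: list with `per_genome`
#'   (`data.frame` of genome x tolerance x category fractions), `no_hit`
#'   (per-tolerance fraction), `n_reads` and `tolerances`.
#' @export
screen <- function(reads, index, tolerances = 0:3) {
  hits <- align_reads(reads, index, max_mismatch = max(tolerances))
  n_reads <- nrow(reads)
  dt <- as.data.table(hits)
  per_genome <- list()
  no_hit <- numeric(0)
  for (m in sort(tolerances)) {
    sub <- dt[mismatches <= m]
    if (nrow(sub)) {
      per_rg <- sub[, .(n_hits = .N), by = .(read_id, genome)]
      per_read <- per_rg[, .(n_genomes = .N, max_hits = max(n_hits)),
                         by = read_id]
      per_rg <- per_rg[per_read, on = "read_id"]
      per_rg[, category := fifelse(
        n_genomes == 1L & max_hits == 1L, "unique_one_genome", fifelse(
          n_genomes == 1L, "multi_one_genome", fifelse(
            max_hits == 1L, "unique_multi_genome", "multi_multi_genome")))]
      counts <- per_rg[, .(n = .N), by = .(genome, category)]
      n_aligned <- nrow(per_read)
    } else {
      counts <- data.table(genome = character(0), category = character(0),
                           n = integer(0))
      n_aligned <- 0L
    }
    grid <- data.table(expand.grid(genome = index$genomes,
                                   category = SCREEN_CATEGORIES,
                                   stringsAsFactors = FALSE))
    counts <- counts[grid, on = c("genome", "category")]
    counts[is.na(n), n := 0L]
    counts[, `:=`(tolerance = m, fraction = n / n_reads)]
    per_genome[[as.character(m)]] <- as.data.frame(counts)
    no_hit[as.character(m)] <- (n_reads - n_aligned) / n_reads
  }
  structure(list(per_genome = do.call(rbind, per_genome),
                 no_hit = data.frame(tolerance = sort(tolerances),
                                     fraction = unname(no_hit)),
                 n_reads = n_reads, tolerances = sort(tolerances)),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat(sprintf("<screen_report> %d reads\n", x$n_reads))
  u <- x$per_genome[x$per_genome$category == "unique_one_genome" &
                      x$per_genome$tolerance == min(x$tolerances), ]
  for (i in seq_len(nrow(u))) {
    cat(sprintf("  m=%d unique to %s: %.2f%%\n", u$tolerance[i], u$genome[i],
                100 * u$fraction[i]))
  }
  cat(sprintf("  m=%d no hit: %.2f%%\n", min(x$tolerances),
              100 * x$no_hit$fraction[x$no_hit$tolerance == min(x$tolerances)]))
  invisible(x)
}

#' Call the source species from a screen report
#'
#' The species is the genome with the highest fraction of reads aligning
#' uniquely to it (and nowhere else) at the given tolerance. If the margin
#' to the runner-up is below `margin_threshold` percentage points the call
#' is refused as `"ambiguous"`.
#'
#' @param report a [screen()] result.
#' @param tolerance mismatch tolerance at which to call (default 0).
#' @param margin_threshold minimum winning margin in percentage points.
#' @return list with `species`, `margin` (percentage points), and the
#'   per-genome `unique_pct` table.
#' @export
call_species <- function(report, tolerance = 0L, margin_threshold = 2) {
  stopifnot(inherits(report, "screen_report"))
  u <- report$per_genome[report$per_genome$category == "unique_one_genome" &
                           report$per_genome$tolerance == tolerance, ]
  if (nrow(u) == 0) stop("empty screen report", call. = FALSE)
  u <- u[order(-u$fraction), ]
  pct <- 100 * u$fraction
  margin <- if (nrow(u) >= 2) pct[1] - pct[2] else pct[1]
  species <- if (margin < margin_threshold) "ambiguous" else u$genome[1]
  list(species = species, margin = margin,
       unique_pct = data.frame(genome = u$genome, unique_pct = pct,
                               stringsAsFactors = FALSE))
}
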