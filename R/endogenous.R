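# High-quality filtering chain for endogenous reads: mapping-quality filter,
# clonal duplicate removal, contaminant subtraction, uniqueness filter,
# summary percentages, genome retrieval and sex determination.
#
# The source never fixes an order for these filters; here it is fixed as
# mapq -> dedup -> contaminant subtraction -> uniqueness and exposed through
# the `order` argument because deduplicating before or after the
# mapping-quality filter changes the counts.

#' Keep hits at or above a mapping-quality threshold
#'
#' @param hits hits `data.frame` with a `mapq` column (see [assign_mapq()]).
#' @param threshold minimum mapping quality (default 30, which in the
#'   surrogate scheme retains exactly the mapq-37 unique tier).
#' @return filtered hits.
#' @export
filter_mapq <- function(hits, threshold = 30L) {
  hits[hits$mapq >= threshold, , drop = FALSE]
}

#' Remove clonal PCR duplicates
#'
#' Among hits sharing (contig, strand, 5' start) exactly one survives: the
#' read with the greatest base-quality sum, ties broken by read id in
#' lexicographic order. The 5' start of a minus-strand hit is its rightmost
#' reference coordinate. Deterministic and total, unlike version-dependent
#' external tools.
#'
#' @param hits single-genome hits `data.frame` (one row per read).
#' @param reads the read set, used for lengths and quality sums.
#' @return deduplicated hits.
#' @export
remove_duplicates <- function(hits, reads) {
  if (nrow(hits) == 0) return(hits)
  idx <- match(hits$read_id, reads$id)
  len <- nchar(reads$seq[idx])
  start5 <- ifelse(hits$strand == "+", hits$start, hits$start + len - 1L)
  qs <- qual_sum(reads$qual[idx])
  key <- paste(hits$contig, hits$strand, start5, sep = "\r")
  ord <- order(key, -qs, hits$read_id)
  keep_first <- !duplicated(key[ord])
  hits[sort(ord[keep_first]), , drop = FALSE]
}

#' Remove reads that also align to a contaminant genome
#'
#' Any read with at least one placement in the contaminant genome at up to
#' `max_mismatch` mismatches is removed from the target hit set,
#' irrespective of its mapping quality on either genome.
#'
#' @param hits target-genome hits `data.frame`.
#' @param reads the read set behind the hits.
#' @param contaminant_index a [build_index()] over the contaminant genome.
#' @param max_mismatch mismatch tolerance for contaminant matching.
#' @return filtered hits.
#' @export
subtract_contaminant <- function(hits, reads, contaminant_index,
                                 max_mismatch = 3L) {
  if (nrow(hits) == 0) return(hits)
  sub <- reads[reads$id %in% hits$read_id, , drop = FALSE]
  chits <- align_reads(sub, contaminant_index, max_mismatch)
  hits[!hits$read_id %in% chits$read_id, , drop = FALSE]
}

#' Keep only confidently unique alignments
#'
#' A read survives when its best hit is its sole hit at the best mismatch
#' count, with no alternative placement within 2 mismatches — the analogue
#' of an aligner's unique tag with zero suboptimal hits. In the surrogate
#' mapping-quality scheme this is exactly the mapq-37 tier.
#'
#' @param hits hits `data.frame` with `mapq` assigned.
#' @return filtered hits.
#' @export
keep_unique <- function(hits) {
  hits[hits$mapq == 37L, , drop = FALSE]
}

#' Summarise a filter chain into the standard report
#'
#' Percentages use the central half-up 1-decimal formatter; genome retrieval
#' is the fraction of target-genome bases covered at least once by the
#' surviving hits.
#'
#' @param raw_reads total raw reads entering alignment.
#' @param stage_counts named integer vector of reads surviving each stage,
#'   in order (must be non-increasing), starting with `aligned_raw`.
#' @param covered_bases bases of the target genome covered >= 1x.
#' @param genome_length total target (nuclear) genome length.
#' @return an object of class `filter_report`.
#' @export
summarize_chain <- function(raw_reads, stage_counts, covered_bases,
                            genome_length) {
  if (raw_reads <= 0) stop("raw_reads must be positive", call. = FALSE)
  if (any(diff(unname(stage_counts)) > 0)) {
    stop("stage counts must be non-increasing", call. = FALSE)
  }
  final <- stage_counts[[length(stage_counts)]]
  structure(list(
    raw_reads = raw_reads,
    stage_counts = stage_counts,
    removed = c(raw_reads - stage_counts[[1]], -diff(unname(stage_counts))),
    aligned_raw = stage_counts[[1]],
    aligned_raw_pct = pct_round(stage_counts[[1]], raw_reads),
    high_quality = final,
    high_quality_pct = pct_round(final, raw_reads),
    covered_bases = covered_bases,
    genome_length = genome_length,
    genome_retrieval_pct = pct_round(covered_bases, genome_length)
  ), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  cat(sprintf("  raw reads: %d\n", x$raw_reads))
  for (s in names(x$stage_counts)) {
    cat(sprintf("  %s: %d\n", s, x$stage_counts[[s]]))
  }
  cat(sprintf("  aligned raw: %.1f%%  high quality: %.1f%%  retrieval: %.1f%%\n",
              x$aligned_raw_pct, x$high_quality_pct, x$genome_retrieval_pct))
  invisible(x)
}

# bases covered >= 1x, per contig, via IRanges
covered_bases <- function(hits, reads) {
  if (nrow(hits) == 0) return(0L)
  len <- nchar(reads$seq[match(hits$read_id, reads$id)])
  total <- 0L
  for (cn in unique(hits$contig)) {
    i <- hits$contig == cn
    ir <- IRanges::IRanges(start = hits$start[i] + 1L, width = len[i])
    total <- total + sum(IRanges::width(IRanges::reduce(ir)))
  }
  total
}

#' Run the full endogenous filter chain
#'
#' Aligns reads to the target genome's nuclear contigs (the mitochondrial
#' contig is excluded from the nuclear chain), assigns the mapping-quality
#' surrogate, then applies the filters in `order`:
#' `mapq` (>= threshold), `dedup` (clonal duplicates), `contaminant`
#' (subtraction of reads that also align to the contaminant genome) and
#' `unique` (confidently unique placements).
#'
#' @param reads trimmed, length-filtered read set.
#' @param db a [genome_db()] containing the target genome.
#' @param target target genome name.
#' @param contaminant_index optional [build_index()] over the contaminant
#'   genome (skipped if `NULL`).
#' @param mapq_threshold minimum mapping quality.
#' @param max_mismatch alignment tolerance.
#' @param seed_len aligner seed length.
#' @param order permutation of `c("mapq", "dedup", "contaminant", "unique")`.
#' @return list with `hits` (surviving nuclear best hits), `report`
#'   (a `filter_report`), and `index` (the nuclear target index, reusable).
#' @export
filter_chain <- function(reads, db, target, contaminant_index = NULL,
                         mapq_threshold = 30L, max_mismatch = 3L,
                         seed_len = 7L,
                         order = c("mapq", "dedup", "contaminant", "unique")) {
  stopifnot(setequal(order, c("mapq", "dedup", "contaminant", "unique")))
  contigs <- genome_contigs(db, target)
  cls <- genome_classes(db, target)
  nuclear <- contigs[cls != "mito"]
  ndb <- genome_db(stats::setNames(list(nuclear), target),
                   classes = stats::setNames(list(cls[cls != "mito"]), target))
  index <- build_index(ndb, seed_len)
  hits <- assign_mapq(align_reads(reads, index, max_mismatch))

  # collapse to one row per read: its best hit (highest mapq, then fewest
  # mismatches); uniqueness information is already encoded in mapq
  dt <- as.data.table(hits)
  dt <- dt[order(read_id, -mapq, mismatches)]
  best <- as.data.frame(dt[!duplicated(read_id)])

  counts <- c(aligned_raw = nrow(best))
  cur <- best
  for (op in order) {
    cur <- switch(op,
      mapq = filter_mapq(cur, mapq_threshold),
      dedup = remove_duplicates(cur, reads),
      contaminant = if (is.null(contaminant_index)) cur else
        subtract_contaminant(cur, reads, contaminant_index, max_mismatch),
      unique = keep_unique(cur))
    counts[[paste0("after_", op)]] <- nrow(cur)
  }
  cov <- covered_bases(cur, reads)
  report <- summarize_chain(nrow(reads), counts, cov, sum(nchar(nuclear)))
  list(hits = cur, report = report, index = index)
}

#' Determine genetic sex from X-to-autosome coverage
#'
#' Compares mean per-base depth on X contigs to autosomal contigs. A ratio
#' near 1 indicates two X copies (XX), near 0.5 one copy (XY). Thresholds
#' (>= 0.8 XX, <= 0.6 XY, otherwise indeterminate) separate the two
#' expectations with a refusal band.
#'
#' @param hits surviving hits `data.frame`.
#' @param reads the read set behind the hits.
#' @param db a [genome_db()].
#' @param target target genome name.
#' @return an object of class `sex_call` with fields `x_coverage`,
#'   `autosome_coverage`, `ratio`, `call`.
#' @export
call_sex <- function(hits, reads, db, target) {
  contigs <- genome_contigs(db, target)
  cls <- genome_classes(db, target)
  len <- nchar(reads$seq[match(hits$read_id, reads$id)])
  depth_of <- function(class_name) {
    cc <- names(contigs)[cls == class_name]
    if (length(cc) == 0) return(NA_real_)
    sum(len[hits$contig %in% cc]) / sum(nchar(contigs[cc]))
  }
  x_cov <- depth_of("X")
  a_cov <- depth_of("autosome")
  if (is.na(a_cov) || a_cov == 0) {
    stop("no autosome coverage; cannot determine sex", call. = FALSE)
  }
  ratio <- x_cov / a_cov
  call <- if (is.na(ratio)) "indeterminate"
  else if (ratio >= 0.8) "XX"
  else if (ratio <= 0.6) "XY"
  else "indeterminate"
  structure(list(x_coverage = x_cov, autosome_coverage = a_cov,
                 ratio = ratio, call = call), class = "sex_call")
}

#' @export
print.sex_call <- function(x, ...) {
  cat(sprintf("<sex_call> X/autosome depth ratio %.3f -> %s\n", x$ratio, x$call))
  invisible(x)
}

#' Aggregate per-sample summary reports
#'
#' Sums the numeric fields shared by a list of per-sample reports (e.g.
#' mitochondrial read counts across samples) and keeps per-sample values
#' alongside.
#'
#' @param reports named list of per-sample lists with numeric fields.
#' @return list with `per_sample` and `total` (field-wise sums over the
#'   fields present in every sample).
#' @export
combine_sample_reports <- function(reports) {
  stopifnot(length(reports) >= 1)
  fields <- Reduce(intersect, lapply(reports, names))
  numf <- fields[vapply(fields, function(f)
    is.numeric(reports[[1]][[f]]) && length(reports[[1]][[f]]) == 1, logical(1))]
  total <- lapply(numf, function(f) sum(vapply(reports, `[[`, numeric(1), f)))
  names(total) <- numf
  list(per_sample = reports, total = total)
}
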