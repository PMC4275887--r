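# Adapter trimming and length filtering.
#
# The trimmer reproduces a deliberately conservative configuration: any
# read-suffix / adapter-prefix overlap of at least min_overlap bases (default
# a single base) is removed. This causes spurious trimming of reads whose
# last base happens to match the adapter's first base — by design, to guard
# against adapter poisoning of downstream alignment — so it is reproduced
# here rather than "improved".

# longest admissible overlap length per read; 0 = no trim
trim_overlap_len <- function(seqs, adapter, min_overlap, max_error_rate) {
  n <- length(seqs)
  lens <- nchar(seqs)
  alen <- nchar(adapter)
  maxo <- min(alen, max(lens, 0L))
  best <- integer(n)
  if (n == 0 || maxo < min_overlap) return(best)
  avec <- utf8ToInt(adapter)
  # suffix matrix: column j = j-th-from-last character
  smat <- matrix(0L, n, maxo)
  for (j in seq_len(maxo)) {
    has <- lens >= j
    ch <- substr(seqs[has], lens[has] - j + 1L, lens[has] - j + 1L)
    smat[has, j] <- utf8ToInt(paste(ch, collapse = ""))
  }
  for (o in maxo:min_overlap) {
    todo <- best == 0L & lens >= o
    if (!any(todo)) next
    # suffix of length o occupies columns o..1 (from-last indexing)
    mism <- integer(sum(todo))
    rows <- which(todo)
    for (j in seq_len(o)) {
      mism <- mism + (smat[rows, o - j + 1L] != avec[j])
    }
    ok <- mism <= o * max_error_rate
    best[rows[ok]] <- o
  }
  best
}

#' Trim adapter sequence from the 3' end of reads
#'
#' Removes the longest read-suffix / adapter-prefix overlap of length at
#' least `min_overlap` whose mismatch fraction does not exceed
#' `max_error_rate`; qualities are trimmed in lockstep. With the default
#' `min_overlap = 1` a single terminal base matching the adapter's first
#' base is trimmed.
#'
#' @param reads read set `data.frame` (or a single sequence string).
#' @param adapter adapter sequence (non-empty).
#' @param min_overlap minimum overlap in bp.
#' @param max_error_rate maximum mismatch fraction within the overlap.
#' @return trimmed read set (or string, matching the input form).
#' @export
#' @examples
#' trim_adapter("ACGTACGTAGATCGGAAG", "AGATCGGAAG") # "ACGTACGT"
trim_adapter <- function(reads, adapter, min_overlap = 1L, max_error_rate = 0.1) {
  adapter <- toupper(adapter)
  if (!nzchar(adapter)) stop("adapter must be non-empty", call. = FALSE)
  if (is.character(reads)) {
    o <- trim_overlap_len(toupper(reads), adapter, min_overlap, max_error_rate)
    return(substr(reads, 1L, nchar(reads) - o))
  }
  o <- trim_overlap_len(reads$seq, adapter, min_overlap, max_error_rate)
  keep_len <- nchar(reads$seq) - o
  reads$seq <- substr(reads$seq, 1L, keep_len)
  reads$qual <- substr(reads$qual, 1L, keep_len)
  reads
}

#' Remove reads shorter than a minimum length
#'
#' @param reads read set `data.frame`.
#' @param min_len minimum surviving length in bp (a read of exactly
#'   `min_len` is kept).
#' @return list with `reads` (the survivors) and `report`, a `trim_report`
#'   with fields `reads_in`, `reads_discarded_short`, `reads_out`.
#' @export
length_filter <- function(reads, min_len = 30L) {
  keep <- nchar(reads$seq) >= min_len
  report <- structure(list(reads_in = nrow(reads),
                           reads_discarded_short = sum(!keep),
                           reads_out = sum(keep)),
                      class = "trim_report")
  list(reads = reads[keep, , drop = FALSE], report = report)
}

#' Adapter-trim then length-filter a read set
#'
#' The standard preparation applied before screening and alignment.
#'
#' @inheritParams trim_adapter
#' @inheritParams length_filter
#' @return list with `reads` and a `trim_report` (fields `reads_in`,
#'   `reads_trimmed`, `reads_discarded_short`, `reads_out`).
#' @export
run_trim <- function(reads, adapter, min_overlap = 1L, max_error_rate = 0.1,
                     min_len = 30L) {
  n_in <- nrow(reads)
  before <- nchar(reads$seq)
  trimmed <- trim_adapter(reads, adapter, min_overlap, max_error_rate)
  n_trimmed <- sum(nchar(trimmed$seq) < before)
  lf <- length_filter(trimmed, min_len)
  report <- structure(list(reads_in = n_in, reads_trimmed = n_trimmed,
                           reads_discarded_short = lf$report$reads_discarded_short,
                           reads_out = lf$report$reads_out),
                      class = "trim_report")
  list(reads = lf$reads, report = report)
}

#' @export
print.trim_report <- function(x, ...) {
  cat("<trim_report>\n")
  for (f in names(x)) cat(sprintf("  %s: %s\n", f, x[[f]]))
  invisible(x)
}
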