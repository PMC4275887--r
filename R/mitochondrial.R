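# Mitochondrial consensus, the consensus-support / maximum-contamination
# statistic, and haplogroup placement via Jukes-Cantor distances and
# neighbour joining with bootstrap support.

# ---- pileup and consensus ----------------------------------------------------

#' Build a pileup and majority consensus over a mitochondrial reference
#'
#' @param hits duplicate-removed hits on the mitochondrial contig (one row
#'   per read).
#' @param reads the read set behind the hits.
#' @param reference the reference sequence the hits are placed on.
#' @return an object of class `pileup`: list with `counts` (5 x L matrix of
#'   A/C/G/T/N counts), `depth`, `consensus` (majority base per position,
#'   ties and zero depth give N), `mean_depth` and `reference`.
#' @export
pileup_and_consensus <- function(hits, reads, reference) {
  reference <- toupper(reference)
  L <- nchar(reference)
  counts <- matrix(0L, 5L, L, dimnames = list(c("A", "C", "G", "T", "N"), NULL))
  if (nrow(hits)) {
    idx <- match(hits$read_id, reads$id)
    seqs <- reads$seq[idx]
    minus <- hits$strand == "-"
    seqs[minus] <- revcomp(seqs[minus]) # reference orientation
    lens <- nchar(seqs)
    pos <- rep(hits$start, lens) + sequence(lens) # 1-based reference position
    base <- match(unlist(strsplit(seqs, "", fixed = TRUE)),
                  c("A", "C", "G", "T"))
    base[is.na(base)] <- 5L
    ok <- pos >= 1L & pos <= L
    tab <- tabulate((pos[ok] - 1L) * 5L + base[ok], nbins = 5L * L)
    counts[] <- matrix(tab, nrow = 5L)
  }
  depth <- colSums(counts)
  acgt <- counts[1:4, , drop = FALSE]
  top <- apply(acgt, 2, max)
  n_top <- colSums(acgt == rep(top, each = 4))
  cons <- rownames(acgt)[apply(acgt, 2, which.max)]
  cons[top == 0 | n_top > 1] <- "N"
  structure(list(counts = counts, depth = depth,
                 consensus = paste(cons, collapse = ""),
                 mean_depth = sum(depth) / L,
                 reference = reference),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %d positions, mean depth %.1fx\n",
              length(x$depth), x$mean_depth))
  invisible(x)
}

#' Identify haplotype-informative (diagnostic) positions
#'
#' Positions where the sample consensus differs from the reference base at
#' depth >= `min_depth`, excluding the supplied intervals (typically the
#' ambiguously aligning tandem repeat in the control region).
#'
#' @param pileup a [pileup_and_consensus()] result.
#' @param excluded list of `c(start, end)` 0-based half-open intervals.
#' @param min_depth minimum depth for a position to be considered.
#' @return an object of class `diagnostic_sites`: list with `positions`
#'   (0-based) and `excluded`.
#' @export
diagnostic_sites <- function(pileup, excluded = list(), min_depth = 10L) {
  stopifnot(inherits(pileup, "pileup"))
  cons <- strsplit(pileup$consensus, "")[[1]]
  ref <- strsplit(pileup$reference, "")[[1]]
  pos <- which(pileup$depth >= min_depth & cons != ref &
                 cons != "N" & ref != "N") - 1L
  for (iv in excluded) {
    pos <- pos[pos < iv[1] | pos >= iv[2]]
  }
  structure(list(positions = pos, excluded = excluded), class = "diagnostic_sites")
}

#' Contamination estimate from consensus support counts
#'
#' The conservative convention floors the consensus-support percentage and
#' ceils the maximum-contamination percentage, so both are rounded in the
#' direction that overstates contamination: support + contamination is 100
#' or 101.
#'
#' @param consensus_reads read-site observations carrying the consensus base.
#' @param total_reads all read-site observations at the diagnostic sites.
#' @return an object of class `contamination_estimate` with integer
#'   `consensus_support_pct` (floored) and `max_contamination_pct` (ceiled).
#' @export
#' @examples
#' contamination_estimate(282, 291) # support 96%, max contamination 4%
contamination_estimate <- function(consensus_reads, total_reads) {
  if (total_reads <= 0 || consensus_reads > total_reads || consensus_reads < 0) {
    stop("need 0 <= consensus_reads <= total_reads, total_reads > 0",
         call. = FALSE)
  }
  structure(list(
    consensus_reads = as.integer(consensus_reads),
    total_reads = as.integer(total_reads),
    consensus_support_pct = as.integer(floor(100 * consensus_reads / total_reads)),
    max_contamination_pct = as.integer(ceiling(
      100 * (total_reads - consensus_reads) / total_reads))
  ), class = "contamination_estimate")
}

#' @export
print.contamination_estimate <- function(x, ...) {
  cat(sprintf(
    "<contamination_estimate> consensus %d/%d: support %d%%, max contamination %d%%\n",
    x$consensus_reads, x$total_reads, x$consensus_support_pct,
    x$max_contamination_pct))
  invisible(x)
}

#' Estimate mitochondrial contamination at diagnostic sites
#'
#' Sums read-site observations over the diagnostic positions: the total is
#' the summed depth, the consensus count is the summed consensus-base count.
#'
#' @param pileup a [pileup_and_consensus()] result.
#' @param sites a [diagnostic_sites()] result; must be non-empty.
#' @return a [contamination_estimate()].
#' @export
estimate_contamination <- function(pileup, sites) {
  stopifnot(inherits(pileup, "pileup"), inherits(sites, "diagnostic_sites"))
  if (length(sites$positions) == 0) {
    stop("no diagnostic sites: contamination cannot be estimated", call. = FALSE)
  }
  cols <- sites$positions + 1L
  cons <- strsplit(pileup$consensus, "")[[1]][cols]
  total <- sum(pileup$depth[cols])
  consensus <- sum(pileup$counts[cbind(match(cons, rownames(pileup$counts)), cols)])
  contamination_estimate(consensus, total)
}

# ---- distances and trees -----------------------------------------------------

#' Jukes-Cantor distance between two aligned sequences
#'
#' Columns with a gap (`-`) or `N` in either sequence are removed before the
#' mismatch fraction p is computed (complete deletion); the distance is
#' `-(3/4) log(1 - 4p/3)`, which saturates at p >= 0.75.
#'
#' @param a,b equal-length aligned sequences.
#' @param gap_policy only `"complete_deletion"` is supported.
#' @return the JC69 distance.
#' @export
jc_distance <- function(a, b, gap_policy = "complete_deletion") {
  gap_policy <- match.arg(gap_policy)
  va <- strsplit(toupper(a), "")[[1]]
  vb <- strsplit(toupper(b), "")[[1]]
  if (length(va) != length(vb)) {
    stop("sequences must have equal aligned length", call. = FALSE)
  }
  keep <- va %in% c("A", "C", "G", "T") & vb %in% c("A", "C", "G", "T")
  if (!any(keep)) stop("no ungapped columns to compare", call. = FALSE)
  p <- mean(va[keep] != vb[keep])
  if (p >= 0.75) stop("distance saturated (p >= 0.75)", call. = FALSE)
  -0.75 * log(1 - 4 * p / 3)
}

#' Jukes-Cantor distance matrix for an aligned set of sequences
#'
#' Complete deletion is applied alignment-wide: every column containing a
#' gap or N in any sequence is dropped before pairwise distances.
#'
#' @param alignment named character vector of equal-length aligned sequences.
#' @return a symmetric distance matrix.
#' @export
jc_matrix <- function(alignment) {
  mat <- alignment_matrix(alignment)
  keep <- colSums(matrix(mat %in% c("A", "C", "G", "T"),
                         nrow(mat))) == nrow(mat)
  jc_from_columns(mat[, keep, drop = FALSE])
}

# pairwise JC distances from a gap-free character matrix (rows = taxa)
jc_from_columns <- function(mat) {
  if (ncol(mat) == 0) stop("no ungapped columns to compare", call. = FALSE)
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) {
    mi <- mat[i, ]
    for (j in (i + 1):n) {
      p <- mean(mi != mat[j, ])
      if (p >= 0.75) stop("distance saturated (p >= 0.75)", call. = FALSE)
      D[i, j] <- D[j, i] <- -0.75 * log(1 - 4 * p / 3)
    }
  }
  D
}

alignment_matrix <- function(alignment) {
  if (is.matrix(alignment)) return(alignment)
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
  rownames(mat) <- names(alignment)
  mat
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q criterion; negative branch
#' lengths are clamped to zero. On an additive matrix the tree's path-length
#' matrix reproduces the input exactly.
#'
#' @param D symmetric distance matrix with zero diagonal, n >= 3 taxa.
#' @return an unrooted `phylo` tree.
#' @export
neighbour_joining <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3) stop("need at least 3 taxa", call. = FALSE)
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)) ||
      any(abs(diag(D)) > 1e-12)) {
    stop("distance matrix must be symmetric with zero diagonal", call. = FALSE)
  }
  tree <- ape::nj(stats::as.dist(D))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Neighbour-joining tree with bootstrap support
#'
#' Resamples alignment columns with replacement, recomputes the JC + NJ tree
#' per replicate, and counts how often each internal bipartition of the
#' original tree is recovered. Replicate random streams are derived from the
#' seed by counter, so supports do not depend on evaluation order and
#' permuting the taxa leaves them unchanged.
#'
#' @param alignment named character vector of aligned sequences (>= 4 taxa).
#' @param replicates bootstrap replicates (0 = no supports).
#' @param seed integer seed.
#' @return list with `tree` (`phylo`, with `node.label` carrying supports
#'   when `replicates > 0`) and `supports` (named numeric, or `NULL`).
#' @export
bootstrap_support <- function(alignment, replicates = 1000L, seed = 1L) {
  mat <- alignment_matrix(alignment)
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  if (nrow(mat) < 4) stop("need at least 4 taxa for bootstrap", call. = FALSE)
  keep <- colSums(matrix(mat %in% c("A", "C", "G", "T"),
                         nrow(mat))) == nrow(mat)
  mat <- mat[, keep, drop = FALSE]
  main <- neighbour_joining(jc_from_columns(mat))
  if (replicates == 0) {
    return(list(tree = main, supports = NULL))
  }
  boots <- vector("list", replicates)
  for (b in seq_len(replicates)) {
    cols <- withr::with_seed(derive_seed(seed, paste0("boot", b)),
                             sample.int(ncol(mat), replace = TRUE))
    boots[[b]] <- tryCatch(
      neighbour_joining(jc_from_columns(mat[, cols, drop = FALSE])),
      error = function(e) NULL)
  }
  boots <- boots[!vapply(boots, is.null, logical(1))]
  supp <- ape::prop.clades(main, boots, rooted = FALSE)
  supp[is.na(supp)] <- 0L
  main$node.label <- as.character(supp)
  list(tree = main, supports = stats::setNames(supp, seq_along(supp)))
}

#' Place a sample consensus among reference mitogenomes
#'
#' Adds the sample to a reference alignment (same aligned length required),
#' builds the JC + NJ tree, and reports the reference taxa ranked by
#' distance to the sample together with the sample's sister group in the
#' tree.
#'
#' @param sample_consensus the sample sequence, aligned to the reference
#'   alignment coordinates.
#' @param reference_alignment named character vector of aligned references.
#' @param sample_name tip label for the sample.
#' @return list with `tree`, `nearest` (`data.frame` of taxon/distance,
#'   ascending) and `sister` (tips of the sample's sister group).
#' @export
place_sample <- function(sample_consensus, reference_alignment,
                         sample_name = "sample") {
  lens <- nchar(reference_alignment)
  if (nchar(sample_consensus) != lens[1]) {
    stop("sample length does not match the reference alignment", call. = FALSE)
  }
  aln <- c(stats::setNames(sample_consensus, sample_name), reference_alignment)
  D <- jc_matrix(aln)
  tree <- neighbour_joining(D)
  d <- D[sample_name, setdiff(colnames(D), sample_name)]
  nearest <- data.frame(taxon = names(sort(d)), distance = unname(sort(d)),
                        stringsAsFactors = FALSE)
  sister <- sister_tips(tree, sample_name)
  list(tree = tree, nearest = nearest, sister = sister)
}

# tips attached to the internal node adjacent to `tip`, excluding the tip
# itself and excluding the subtree on the far side of that node (the larger
# remainder of an unrooted tree): i.e. the sample's local neighbourhood
sister_tips <- function(tree, tip) {
  tipn <- match(tip, tree$tip.label)
  parent <- tree$edge[tree$edge[, 2] == tipn, 1]
  kids <- tree$edge[tree$edge[, 1] == parent & tree$edge[, 2] != tipn, 2]
  out <- character(0)
  for (k in kids) {
    out <- c(out, clade_tips(tree, k))
  }
  setdiff(out, tip)
}

clade_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  out <- character(0)
  for (k in tree$edge[tree$edge[, 1] == node, 2]) {
    out <- c(out, clade_tips(tree, k))
  }
  out
}
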