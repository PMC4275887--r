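# Pseudo-haploid SNP calling at panel sites, pseudo-diploid merging with
# strand flipping and ambiguity filters, identity-by-state allele sharing,
# and per-breed summaries with an optional interpolated surface.
#
# Filter logic: transition pairs (C/T, G/A) are excluded at calling time
# because post-mortem deamination mimics them; strand-ambiguous pairs (A/T,
# C/G) are excluded at merge time because orientation cannot be
# reconciled. Only A/C and G/T pairs can survive both filters.

TRANSITION_PAIRS <- c("CT", "AG")
AMBIGUOUS_PAIRS <- c("AT", "CG")

pair_key <- function(a, b) paste0(pmin(a, b), pmax(a, b))

#' Construct a pseudo-diploid call set
#'
#' @param site_id,allele_a,allele_b site descriptors (the orientation the
#'   calls were made in).
#' @param call homozygous two-letter genotype strings (`"AA"`) or `NA`.
#' @param excluded named integer vector of per-filter exclusion counts.
#' @return a `pseudo_calls` data.frame with an `excluded` attribute.
#' @export
pseudo_calls <- function(site_id, allele_a, allele_b, call,
                         excluded = c(transition = 0L)) {
  ok <- is.na(call) | substr(call, 1, 1) == substr(call, 2, 2)
  if (!all(ok)) stop("pseudo-diploid calls must be homozygous", call. = FALSE)
  out <- data.frame(site_id = site_id, allele_a = allele_a,
                    allele_b = allele_b, call = call, stringsAsFactors = FALSE)
  attr(out, "excluded") <- excluded
  class(out) <- c("pseudo_calls", "data.frame")
  out
}

#' Call pseudo-haploid genotypes from aligned reads at panel sites
#'
#' At each site the eligible observations are bases from hits with mapping
#' quality >= `min_mapq` and base quality >= `min_bq`; one is chosen
#' uniformly at random and doubled to a homozygous call. The random pick is
#' keyed by `(seed, site_id)`, so calls do not depend on site processing
#' order. Sites whose allele pair is a transition (C/T or G/A) are excluded
#' a priori; a chosen base outside the site's allele pair yields a missing
#' call.
#'
#' @param hits hits `data.frame` with `mapq` (filtered per the endogenous
#'   chain or not — the mapq threshold is applied here as well).
#' @param reads the read set behind the hits.
#' @param sites panel site `data.frame` (`site_id`, `contig`, `pos`,
#'   `allele_a`, `allele_b`).
#' @param min_bq minimum base quality.
#' @param min_mapq minimum mapping quality.
#' @param seed integer seed for the per-site random read pick.
#' @return a [pseudo_calls()] set over the non-transition sites.
#' @export
call_pseudo_haploid <- function(hits, reads, sites, min_bq = 15L,
                                min_mapq = 30L, seed = 1L) {
  pk <- pair_key(sites$allele_a, sites$allele_b)
  transition <- pk %in% TRANSITION_PAIRS
  keep_sites <- sites[!transition, , drop = FALSE]
  n_sites <- nrow(keep_sites)
  call <- rep(NA_character_, n_sites)

  hq <- hits[hits$mapq >= min_mapq, , drop = FALSE]
  if (nrow(hq) && n_sites) {
    idx <- match(hq$read_id, reads$id)
    len <- nchar(reads$seq[idx])
    hdt <- data.table(read_id = hq$read_id, contig = hq$contig,
                      start = hq$start, end = hq$start + len,
                      strand = hq$strand, seq = reads$seq[idx],
                      qual = reads$qual[idx], len = len)
    sdt <- data.table(site_id = keep_sites$site_id, contig = keep_sites$contig,
                      pos = keep_sites$pos, row = seq_len(n_sites))
    ov <- hdt[sdt, on = .(contig, start <= pos, end > pos),
              .(site_id = i.site_id, row = i.row, read_id = x.read_id,
                strand = x.strand, seq = x.seq, qual = x.qual,
                len = x.len, hstart = x.start, pos = i.pos),
              nomatch = NULL, allow.cartesian = TRUE]
    if (nrow(ov)) {
      off <- ov$pos - ov$hstart # 0-based offset on the reference
      plus <- ov$strand == "+"
      # reference-oriented base and its quality
      base <- character(nrow(ov))
      bq <- integer(nrow(ov))
      base[plus] <- substr(ov$seq[plus], off[plus] + 1L, off[plus] + 1L)
      bq[plus] <- utf8ToInt(paste(substr(ov$qual[plus], off[plus] + 1L,
                                         off[plus] + 1L), collapse = "")) - 33L
      if (any(!plus)) {
        j <- ov$len[!plus] - off[!plus] # 1-based position in the stored read
        base[!plus] <- unname(
          c(A = "T", C = "G", G = "C", T = "A", N = "N")[
            substr(ov$seq[!plus], j, j)])
        bq[!plus] <- utf8ToInt(paste(substr(ov$qual[!plus], j, j),
                                     collapse = "")) - 33L
      }
      ov$base <- base
      ov$bq <- bq
      ov <- ov[ov$bq >= min_bq & !is.na(ov$base), ]
      if (nrow(ov)) {
        picks <- ov[order(ov$row, ov$read_id), ]
        grp <- split(seq_len(nrow(picks)), picks$row)
        for (g in names(grp)) {
          rows <- grp[[g]]
          row_i <- as.integer(g)
          pick <- if (length(rows) == 1) rows else {
            withr::with_seed(
              derive_seed(seed, paste0("site:", keep_sites$site_id[row_i])),
              rows[sample.int(length(rows), 1L)])
          }
          b <- picks$base[pick]
          if (b %in% c(keep_sites$allele_a[row_i], keep_sites$allele_b[row_i])) {
            call[row_i] <- paste0(b, b)
          }
        }
      }
    }
  }
  pseudo_calls(keep_sites$site_id, keep_sites$allele_a, keep_sites$allele_b,
               call, excluded = c(transition = sum(transition)))
}

#' Pseudo-haploidise known diploid genotypes
#'
#' Emulates single-read sampling directly from true genotypes: per site one
#' of the two alleles is chosen at random and doubled; a fraction of sites
#' is set missing to emulate sparse coverage.
#'
#' @param sites panel site `data.frame`.
#' @param genotypes character vector of true diploid genotypes parallel to
#'   `sites`.
#' @param missing_rate fraction of sites set to missing.
#' @param seed integer seed.
#' @return a [pseudo_calls()] set over the non-transition sites.
#' @export
pseudo_haploidize <- function(sites, genotypes, missing_rate = 0, seed = 1L) {
  stopifnot(nrow(sites) == length(genotypes))
  pk <- pair_key(sites$allele_a, sites$allele_b)
  transition <- pk %in% TRANSITION_PAIRS
  keep <- !transition
  g <- genotypes[keep]
  withr::with_seed(derive_seed(seed, "pseudohap"), {
    picks <- ifelse(runif(length(g)) < 0.5, substr(g, 1, 1), substr(g, 2, 2))
    call <- paste0(picks, picks)
    call[is.na(g)] <- NA_character_
    call[runif(length(g)) < missing_rate] <- NA_character_
  })
  pseudo_calls(sites$site_id[keep], sites$allele_a[keep], sites$allele_b[keep],
               call, excluded = c(transition = sum(transition)))
}

#' Merge pseudo-diploid calls with a reference panel
#'
#' Reconciles strand orientation with the panel: a call whose allele pair is
#' the reverse complement of the panel's is complemented; panel sites with
#' strand-ambiguous pairs (A/T, C/G) are removed, as are sites whose allele
#' pairs cannot be reconciled by complementation. After both filter stages
#' only A/C and G/T allele pairs survive.
#'
#' @param calls a [pseudo_calls()] set.
#' @param panel an [snp_panel()].
#' @return list with `merged` (`data.frame` of `site_id`, `call` in panel
#'   orientation) and `excluded` (named counts per filter).
#' @export
merge_with_panel <- function(calls, panel) {
  stopifnot(inherits(panel, "snp_panel"))
  m <- merge(as.data.frame(calls), panel$sites, by = "site_id",
             suffixes = c("_call", "_panel"))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  pk_panel <- pair_key(m$allele_a_panel, m$allele_b_panel)
  pk_call <- pair_key(m$allele_a_call, m$allele_b_call)
  pk_call_rc <- pair_key(comp[m$allele_a_call], comp[m$allele_b_call])

  ambiguous <- pk_panel %in% AMBIGUOUS_PAIRS
  same <- !ambiguous & pk_call == pk_panel
  flipped <- !ambiguous & !same & pk_call_rc == pk_panel
  irreconcilable <- !ambiguous & !same & !flipped

  call <- m$call
  flip_idx <- flipped & !is.na(call)
  call[flip_idx] <- vapply(strsplit(call[flip_idx], ""), function(x) {
    paste(comp[x], collapse = "")
  }, character(1))
  # a non-missing call must carry one of the panel's alleles
  bad_base <- !is.na(call) &
    !(substr(call, 1, 1) == m$allele_a_panel |
        substr(call, 1, 1) == m$allele_b_panel)
  irreconcilable <- irreconcilable | ((same | flipped) & bad_base)
  keep <- (same | flipped) & !bad_base
  merged <- data.frame(site_id = m$site_id[keep], call = call[keep],
                       stringsAsFactors = FALSE)
  surviving_pairs <- unique(pk_panel[keep])
  stopifnot(all(surviving_pairs %in% c("AC", "GT")))
  list(merged = merged,
       excluded = c(attr(calls, "excluded"),
                    ambiguous = sum(ambiguous),
                    irreconcilable = sum(irreconcilable)))
}

#' Mean identity-by-state allele sharing between two genotype vectors
#'
#' Per overlapping non-missing locus the IBS count (0-2) between the two
#' diploid genotypes; sharing `s` is the summed IBS over twice the overlap,
#' and `1 - s` is the allele-sharing distance.
#'
#' @param g1,g2 character vectors of two-letter genotypes (`NA` = missing).
#' @return list with `s`, `n_overlap` and `distance`; `s` is `NA` when the
#'   overlap is empty.
#' @export
allele_sharing <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  ok <- !is.na(g1) & !is.na(g2)
  n <- sum(ok)
  if (n == 0) {
    return(list(s = NA_real_, n_overlap = 0L, distance = NA_real_))
  }
  a1 <- substr(g1[ok], 1, 1); a2 <- substr(g1[ok], 2, 2)
  b1 <- substr(g2[ok], 1, 1); b2 <- substr(g2[ok], 2, 2)
  ibs <- pmax((a1 == b1) + (a2 == b2), (a1 == b2) + (a2 == b1))
  list(s = sum(ibs) / (2 * n), n_overlap = n,
       distance = 1 - sum(ibs) / (2 * n))
}

#' Per-individual and per-breed allele sharing against a panel
#'
#' Compares the merged sample calls with every reference individual
#' (pairwise deletion: each comparison uses its own overlap) and averages
#' the per-individual sharing within breeds.
#'
#' @param merged merged calls `data.frame` from [merge_with_panel()].
#' @param panel the [snp_panel()].
#' @return an object of class `sharing_result`: list with `per_individual`,
#'   `per_breed` (ranked by mean sharing, with coordinates) and `n_sites`.
#' @export
breed_sharing <- function(merged, panel) {
  stopifnot(inherits(panel, "snp_panel"))
  rows <- match(merged$site_id, rownames(panel$geno))
  sample_g <- merged$call
  per_ind <- lapply(seq_len(ncol(panel$geno)), function(j) {
    sh <- allele_sharing(sample_g, panel$geno[rows, j])
    data.frame(individual = colnames(panel$geno)[j], s = sh$s,
               n_overlap = sh$n_overlap, stringsAsFactors = FALSE)
  })
  per_ind <- do.call(rbind, per_ind)
  per_ind <- merge(per_ind, panel$indiv, by = "individual", sort = FALSE)

  usable <- per_ind[!is.na(per_ind$s), , drop = FALSE]
  dropped <- setdiff(unique(per_ind$breed), unique(usable$breed))
  if (length(dropped)) {
    warning("breeds without usable individuals omitted: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  agg <- stats::aggregate(s ~ breed, data = usable, FUN = mean)
  names(agg)[2] <- "mean_s"
  nn <- stats::aggregate(individual ~ breed, data = usable, FUN = length)
  names(nn)[2] <- "n_individuals"
  coords <- unique(panel$indiv[, c("breed", "lon", "lat")])
  per_breed <- merge(merge(agg, nn, by = "breed"), coords, by = "breed")
  per_breed <- per_breed[order(-per_breed$mean_s), ]
  rownames(per_breed) <- NULL
  structure(list(per_individual = per_ind, per_breed = per_breed,
                 n_sites = nrow(merged)), class = "sharing_result")
}

#' @export
print.sharing_result <- function(x, ...) {
  cat(sprintf("<sharing_result> %d merged sites\n", x$n_sites))
  print(utils::head(x$per_breed, 5))
  invisible(x)
}

#' Inverse-distance-weighted surface of breed means
#'
#' Interpolates the per-breed mean sharing over a regular longitude/latitude
#' grid; values at breed coordinates are exact and the surface is bounded by
#' the input range.
#'
#' @param per_breed `data.frame` with `breed`, `mean_s`, `lon`, `lat` (e.g.
#'   from [breed_sharing()]).
#' @param power IDW power.
#' @param resolution grid points per axis.
#' @param bbox optional `c(lon_min, lon_max, lat_min, lat_max)`.
#' @return `data.frame` with `lon`, `lat`, `value`.
#' @export
interpolate_grid <- function(per_breed, power = 2, resolution = 25L,
                             bbox = NULL) {
  if (nrow(per_breed) < 3) {
    stop("need at least 3 breeds to interpolate", call. = FALSE)
  }
  if (is.null(bbox)) {
    bbox <- c(range(per_breed$lon), range(per_breed$lat))
  }
  lon <- seq(bbox[1], bbox[2], length.out = resolution)
  lat <- seq(bbox[3], bbox[4], length.out = resolution)
  grid <- expand.grid(lon = lon, lat = lat)
  val <- vapply(seq_len(nrow(grid)), function(i) {
    d2 <- (per_breed$lon - grid$lon[i])^2 + (per_breed$lat - grid$lat[i])^2
    hit <- d2 < 1e-12
    if (any(hit)) return(per_breed$mean_s[which(hit)[1]])
    w <- 1 / d2^(power / 2)
    sum(w * per_breed$mean_s) / sum(w)
  }, numeric(1))
  grid$value <- val
  grid
}
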