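# Collagen peptide-mass-fingerprint species identification: in-silico
# tryptic digestion, monoisotopic [M+H]+ masses with hydroxyproline
# modification, and tolerance matching of MALDI peak lists against species
# marker tables.

# monoisotopic residue masses (Da)
RESIDUE_MASS <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764, V = 99.068414,
  T = 101.047678, C = 103.009184, L = 113.084064, I = 113.084064,
  N = 114.042927, D = 115.026943, Q = 128.058578, K = 128.094963,
  E = 129.042593, M = 131.040485, H = 137.058912, F = 147.068414,
  R = 156.101111, Y = 163.063329, W = 186.079313
)
MASS_WATER <- 18.010565
MASS_PROTON <- 1.007276
MASS_OXYGEN <- 15.994915

#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the next residue is P. Missed cleavages
#' up to `missed` are appended as concatenations of adjacent peptides.
#'
#' @param protein amino-acid sequence over the 20 standard residues.
#' @param missed maximum missed cleavages (0-2).
#' @return character vector of peptides (fully cleaved first, then the
#'   missed-cleavage products).
#' @export
#' @examples
#' digest("GPKGRAP") # "GPK" "GR" "AP"
digest <- function(protein, missed = 0L) {
  protein <- toupper(protein)
  res <- strsplit(protein, "")[[1]]
  if (!all(res %in% names(RESIDUE_MASS))) {
    stop("invalid residue in protein sequence", call. = FALSE)
  }
  if (missed < 0 || missed > 2) stop("missed must be 0-2", call. = FALSE)
  n <- length(res)
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after == n | res[pmin(cut_after + 1L, n)] != "P"]
  bounds <- c(0L, cut_after, if (!(n %in% cut_after)) n)
  base <- character(length(bounds) - 1L)
  for (i in seq_along(base)) {
    base[i] <- substr(protein, bounds[i] + 1L, bounds[i + 1L])
  }
  out <- base
  if (missed > 0 && length(base) > 1) {
    for (mc in seq_len(missed)) {
      if (length(base) <= mc) break
      for (i in seq_len(length(base) - mc)) {
        out <- c(out, paste(base[i:(i + mc)], collapse = ""))
      }
    }
  }
  out
}

#' Monoisotopic [M+H]+ mass of a peptide
#'
#' Sum of residue masses plus water and one proton (singly protonated,
#' MALDI-TOF convention), plus one oxygen per hydroxylation — the
#' characteristic hydroxyproline modification of collagen.
#'
#' @param peptide amino-acid sequence (non-empty).
#' @param n_hydroxylations number of hydroxylations; may not exceed the
#'   count of P residues.
#' @return the [M+H]+ mass in Da.
#' @export
#' @examples
#' peptide_mass("GR") # 232.140416
peptide_mass <- function(peptide, n_hydroxylations = 0L) {
  peptide <- toupper(peptide)
  if (!nzchar(peptide)) stop("empty peptide", call. = FALSE)
  res <- strsplit(peptide, "")[[1]]
  if (!all(res %in% names(RESIDUE_MASS))) {
    stop("invalid residue in peptide", call. = FALSE)
  }
  n_p <- sum(res == "P")
  if (n_hydroxylations > n_p) {
    stop("more hydroxylations than proline residues", call. = FALSE)
  }
  sum(RESIDUE_MASS[res]) + MASS_WATER + MASS_PROTON +
    MASS_OXYGEN * n_hydroxylations
}

#' Read a MALDI peak list
#'
#' Two-column TSV (`mz`, optional `intensity`); masses are sorted ascending.
#'
#' @param path peak list path.
#' @return an object of class `peak_list`: `data.frame` with `mz` and
#'   `intensity`.
#' @export
read_peaks <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  if (!"mz" %in% names(tab)) names(tab)[1] <- "mz"
  if (!"intensity" %in% names(tab)) tab$intensity <- NA_real_
  peak_list(tab$mz, tab$intensity)
}

#' Construct a peak list
#'
#' @param mz m/z values (Da, singly protonated assumed), all positive.
#' @param intensity optional intensities.
#' @return a `peak_list` data.frame sorted by mass.
#' @export
peak_list <- function(mz, intensity = NULL) {
  if (any(mz <= 0)) stop("masses must be positive", call. = FALSE)
  if (is.null(intensity)) intensity <- rep(NA_real_, length(mz))
  o <- order(mz)
  structure(data.frame(mz = mz[o], intensity = intensity[o]),
            class = c("peak_list", "data.frame"))
}

#' Read a species marker table
#'
#' TSV with columns `species`, `marker`, and either `mass` or `peptide`
#' (with optional `n_hydroxylations` giving the maximum modification count
#' to consider), plus a logical `diagnostic` column.
#'
#' @param path marker table path.
#' @return `data.frame` marker table.
#' @export
read_markers <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "marker", "diagnostic") %in% names(tab)))
  if (!"mass" %in% names(tab)) tab$mass <- NA_real_
  if (!"peptide" %in% names(tab)) tab$peptide <- NA_character_
  if (!"n_hydroxylations" %in% names(tab)) tab$n_hydroxylations <- 0L
  tab$diagnostic <- as.logical(tab$diagnostic)
  tab
}

marker_masses <- function(row) {
  if (!is.na(row$mass)) return(row$mass)
  if (is.na(row$peptide) || !nzchar(row$peptide)) {
    stop("marker resolvable to no mass: ", row$marker, call. = FALSE)
  }
  vapply(0:row$n_hydroxylations, function(h) peptide_mass(row$peptide, h),
         numeric(1))
}

#' Match a peak list against species marker tables
#'
#' A marker is matched when some peak lies within the tolerance of any of
#' its masses; a peak may satisfy several markers. The species score is the
#' fraction of its diagnostic markers matched.
#'
#' @param peaks a [peak_list()].
#' @param markers marker table (see [read_markers()]).
#' @param tolerance matching tolerance.
#' @param unit `"Da"` or `"ppm"`.
#' @return `data.frame` with per-species `score`, `n_matched`,
#'   `n_diagnostic` and the matched marker names.
#' @export
match_peaks <- function(peaks, markers, tolerance = 0.2, unit = c("Da", "ppm")) {
  unit <- match.arg(unit)
  if (tolerance <= 0) stop("tolerance must be positive", call. = FALSE)
  if (nrow(markers) == 0) stop("empty marker table", call. = FALSE)
  matched <- vapply(seq_len(nrow(markers)), function(i) {
    mm <- marker_masses(markers[i, ])
    if (nrow(peaks) == 0) return(FALSE)
    any(vapply(mm, function(m) {
      tol <- if (unit == "Da") tolerance else m * tolerance / 1e6
      any(abs(peaks$mz - m) <= tol)
    }, logical(1)))
  }, logical(1))
  out <- lapply(split(seq_len(nrow(markers)), markers$species), function(rows) {
    diag_rows <- rows[markers$diagnostic[rows]]
    data.frame(
      species = markers$species[rows[1]],
      score = if (length(diag_rows)) mean(matched[diag_rows]) else 0,
      n_matched = sum(matched[diag_rows]),
      n_diagnostic = length(diag_rows),
      matched_markers = paste(markers$marker[rows][matched[rows]],
                              collapse = ","),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(-out$score), ]
}

#' Call the species from peptide-mass-fingerprint scores
#'
#' @param scores a [match_peaks()] result (>= 2 species).
#' @param margin minimum score gap to the runner-up; below it the call is
#'   `"ambiguous"`.
#' @return list with `species`, `margin` and the score table.
#' @export
call_species_pmf <- function(scores, margin = 0.2) {
  if (nrow(scores) < 2) stop("need scores for at least 2 species", call. = FALSE)
  scores <- scores[order(-scores$score), ]
  gap <- scores$score[1] - scores$score[2]
  list(species = if (gap < margin) "ambiguous" else scores$species[1],
       margin = gap, scores = scores)
}
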