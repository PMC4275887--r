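# Readers and writers for the external formats the pipeline touches, plus the
# in-memory containers shared by all modules.
#
# Conventions: all coordinates are 0-based half-open internally; 1-based
# coordinates appear only in user-facing exports (SAM). Sequences are stored
# uppercase.

# ---- read sets ---------------------------------------------------------------

#' Construct a read set
#'
#' A read set is a plain `data.frame` with columns `id`, `seq` and `qual`
#' (Phred+33 encoded quality string, same length as the sequence).
#'
#' @param id character vector of read identifiers (non-empty, unique).
#' @param seq character vector of sequences over A/C/G/T/N.
#' @param qual character vector of Phred+33 quality strings; if omitted, a
#'   constant Q35 string is generated.
#' @return a `data.frame` with columns `id`, `seq`, `qual`.
#' @export
read_set <- function(id, seq, qual = NULL) {
  seq <- toupper(as.character(seq))
  if (is.null(qual)) qual <- strrep("D", nchar(seq)) # Q35
  if (any(!nzchar(id))) stop("read ids must be non-empty", call. = FALSE)
  if (any(nchar(seq) != nchar(qual))) {
    stop("sequence and quality lengths differ", call. = FALSE)
  }
  data.frame(id = as.character(id), seq = seq, qual = as.character(qual),
             stringsAsFactors = FALSE)
}

#' Read a FASTQ file
#'
#' Phred+33 qualities are kept as encoded strings in the `qual` column.
#' Malformed records (truncated record, missing `@`/`+` markers, quality
#' length different from sequence length) raise an error reporting the
#' offending line number.
#'
#' @param path path to an uncompressed FASTQ file.
#' @return read set `data.frame` (see [read_set()]).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  n <- length(lines)
  if (n %% 4 != 0) {
    stop(sprintf("malformed FASTQ '%s': truncated record at line %d",
                 path, n + 1), call. = FALSE)
  }
  if (n == 0) return(read_set(character(), character(), character()))
  at <- seq(1, n, by = 4)
  bad <- at[substr(lines[at], 1, 1) != "@"]
  if (length(bad)) {
    stop(sprintf("malformed FASTQ '%s': expected '@' at line %d",
                 path, bad[1]), call. = FALSE)
  }
  bad <- (at + 2)[substr(lines[at + 2], 1, 1) != "+"]
  if (length(bad)) {
    stop(sprintf("malformed FASTQ '%s': expected '+' at line %d",
                 path, bad[1]), call. = FALSE)
  }
  seq <- toupper(lines[at + 1])
  qual <- lines[at + 3]
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad)) {
    stop(sprintf(
      "malformed FASTQ '%s': quality length != sequence length at line %d",
      path, at[bad[1]] + 3), call. = FALSE)
  }
  id <- sub("^@", "", sub("\\s.*$", "", lines[at]))
  read_set(id, seq, qual)
}

#' Write a read set as FASTQ
#'
#' @param reads read set `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  out <- character(4 * nrow(reads))
  out[seq(1, length(out), 4)] <- paste0("@", reads$id)
  out[seq(2, length(out), 4)] <- reads$seq
  out[seq(3, length(out), 4)] <- "+"
  out[seq(4, length(out), 4)] <- reads$qual
  writeLines(out, path)
  invisible(path)
}

# ---- FASTA -------------------------------------------------------------------

#' Read a FASTA file into a named character vector
#'
#' @param path path to an uncompressed FASTA file.
#' @return named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write named sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# ---- genome database ---------------------------------------------------------

#' Construct a genome database
#'
#' Named genomes, each a set of contigs tagged as autosome, X or mito. Contig
#' classes default to a name heuristic: contigs matching `X$` are X, contigs
#' matching `M(T)?$` or containing "mito" are mitochondrial, everything else
#' is autosomal.
#'
#' @param genomes named list; each element a named character vector of contig
#'   sequences (uppercase enforced).
#' @param classes optional named list parallel to `genomes`, each element a
#'   named character vector over `c("autosome", "X", "mito")`.
#' @return an object of class `genome_db`.
#' @export
genome_db <- function(genomes, classes = NULL) {
  stopifnot(is.list(genomes), length(genomes) >= 1, !is.null(names(genomes)))
  out <- lapply(names(genomes), function(g) {
    contigs <- toupper(unlist(genomes[[g]]))
    if (is.null(names(contigs)) || anyDuplicated(names(contigs))) {
      stop("contig names must be unique within a genome", call. = FALSE)
    }
    cls <- if (!is.null(classes)) classes[[g]] else contig_class_heuristic(names(contigs))
    cls <- cls[names(contigs)]
    if (any(is.na(cls)) || !all(cls %in% c("autosome", "X", "mito"))) {
      stop("contig classes must cover every contig with autosome/X/mito",
           call. = FALSE)
    }
    list(contigs = contigs, class = cls)
  })
  names(out) <- names(genomes)
  structure(list(genomes = out), class = "genome_db")
}

contig_class_heuristic <- function(contig_names) {
  cls <- rep("autosome", length(contig_names))
  cls[grepl("X$", contig_names)] <- "X"
  cls[grepl("M(T)?$", contig_names) | grepl("mito", contig_names, ignore.case = TRUE)] <- "mito"
  stats::setNames(cls, contig_names)
}

#' @export
print.genome_db <- function(x, ...) {
  cat("<genome_db> ", length(x$genomes), " genome(s)\n", sep = "")
  for (g in names(x$genomes)) {
    gg <- x$genomes[[g]]
    cat(sprintf("  %s: %d contig(s), %s bp (%s)\n", g, length(gg$contigs),
                format(sum(nchar(gg$contigs)), big.mark = ","),
                paste(sprintf("%s=%s", names(gg$contigs), gg$class), collapse = ", ")))
  }
  invisible(x)
}

#' Load a genome database from FASTA files
#'
#' @param paths named character vector, genome name -> FASTA path.
#' @param classes optional classes list as in [genome_db()].
#' @return a `genome_db`.
#' @export
read_genome_db <- function(paths, classes = NULL) {
  genome_db(lapply(paths, read_fasta), classes = classes)
}

genome_contigs <- function(db, genome) {
  stopifnot(inherits(db, "genome_db"))
  if (!genome %in% names(db$genomes)) {
    stop(sprintf("unknown genome '%s'", genome), call. = FALSE)
  }
  db$genomes[[genome]]$contigs
}

genome_classes <- function(db, genome) {
  db$genomes[[genome]]$class
}

# ---- SNP panel ---------------------------------------------------------------

#' Construct a SNP panel
#'
#' A panel couples biallelic sites with diploid genotypes for a set of
#' reference individuals, plus per-individual breed labels and per-breed
#' geographic coordinates.
#'
#' @param sites `data.frame` with columns `site_id`, `contig`, `pos`
#'   (0-based), `allele_a`, `allele_b` (distinct single bases).
#' @param genotypes character matrix (sites x individuals) of two-letter
#'   genotype strings such as `"AC"` (alphabetically ordered), `NA` for
#'   missing. Row order matches `sites`.
#' @param individuals `data.frame` with columns `individual`, `breed`, `lon`,
#'   `lat`; rows match the columns of `genotypes`.
#' @return an object of class `snp_panel`.
#' @export
snp_panel <- function(sites, genotypes, individuals) {
  need <- c("site_id", "contig", "pos", "allele_a", "allele_b")
  stopifnot(all(need %in% names(sites)))
  if (any(sites$allele_a == sites$allele_b)) {
    stop("allele_a and allele_b must differ at every site", call. = FALSE)
  }
  if (anyDuplicated(sites$site_id)) stop("duplicate site ids", call. = FALSE)
  genotypes <- as.matrix(genotypes)
  if (nrow(genotypes) != nrow(sites)) {
    stop("genotype matrix rows must match sites", call. = FALSE)
  }
  stopifnot(all(c("individual", "breed") %in% names(individuals)))
  if (ncol(genotypes) != nrow(individuals)) {
    stop("genotype matrix columns must match individuals", call. = FALSE)
  }
  rownames(genotypes) <- sites$site_id
  colnames(genotypes) <- individuals$individual
  ok <- is.na(genotypes) |
    (substr(genotypes, 1, 1) %in% c(sites$allele_a, sites$allele_b) &
       nchar(genotypes) == 2L)
  if (!all(ok)) stop("genotypes must be two-letter strings or NA", call. = FALSE)
  structure(list(sites = sites, geno = genotypes, indiv = individuals),
            class = "snp_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("<snp_panel> %d sites x %d individuals, %d breed(s)\n",
              nrow(x$sites), nrow(x$indiv), length(unique(x$indiv$breed))))
  invisible(x)
}

#' Write a SNP panel as TSV (sites x individuals) plus a metadata sidecar
#'
#' @param panel an `snp_panel`.
#' @param sites_path path for the genotype table.
#' @param meta_path path for the individual/breed/coordinate table.
#' @return `sites_path`, invisibly.
#' @export
write_panel <- function(panel, sites_path, meta_path) {
  stopifnot(inherits(panel, "snp_panel"))
  geno <- as.data.frame(panel$geno, stringsAsFactors = FALSE)
  geno[is.na(geno)] <- "NN"
  tab <- cbind(panel$sites, geno)
  write.table(tab, sites_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(panel$indiv, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sites_path)
}

#' Read a SNP panel written by [write_panel()]
#'
#' @param sites_path,meta_path paths written by [write_panel()].
#' @return an `snp_panel`.
#' @export
read_panel <- function(sites_path, meta_path) {
  tab <- read.delim(sites_path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- read.delim(meta_path, stringsAsFactors = FALSE)
  for (col in intersect(c("lon", "lat"), names(meta))) {
    meta[[col]] <- as.numeric(meta[[col]])
  }
  site_cols <- c("site_id", "contig", "pos", "allele_a", "allele_b")
  geno <- as.matrix(tab[, setdiff(names(tab), site_cols), drop = FALSE])
  geno[geno == "NN"] <- NA_character_
  snp_panel(tab[, site_cols], geno, meta)
}

#' Convert PLINK ped/map text files to a SNP panel
#'
#' Accepts the classic whitespace-delimited ped/map pair. The family id
#' column is taken as the breed label; coordinates can be supplied through
#' `meta`, a `data.frame` with columns `breed`, `lon`, `lat`.
#'
#' @param ped_path,map_path PLINK text files.
#' @param meta optional per-breed coordinate table.
#' @return an `snp_panel`.
#' @export
read_plink <- function(ped_path, map_path, meta = NULL) {
  map <- read.table(map_path, stringsAsFactors = FALSE)
  names(map)[1:4] <- c("contig", "site_id", "cm", "pos1")
  ped <- read.table(ped_path, stringsAsFactors = FALSE)
  n_sites <- nrow(map)
  if (ncol(ped) != 6 + 2 * n_sites) {
    stop("ped/map column count mismatch", call. = FALSE)
  }
  a1 <- as.matrix(ped[, 6 + 2 * seq_len(n_sites) - 1, drop = FALSE])
  a2 <- as.matrix(ped[, 6 + 2 * seq_len(n_sites), drop = FALSE])
  a1[a1 == "0"] <- NA
  a2[a2 == "0"] <- NA
  geno <- matrix(NA_character_, n_sites, nrow(ped))
  for (j in seq_len(nrow(ped))) {
    x <- a1[j, ]; y <- a2[j, ]
    g <- ifelse(is.na(x) | is.na(y), NA_character_,
                paste0(pmin(x, y), pmax(x, y)))
    geno[, j] <- g
  }
  alleles <- t(vapply(seq_len(n_sites), function(i) {
    obs <- sort(unique(c(a1[, i], a2[, i])))
    obs <- obs[!is.na(obs)]
    if (length(obs) == 0) obs <- c("A", "C")
    if (length(obs) == 1) obs <- c(obs, setdiff(c("A", "C", "G", "T"), obs)[1])
    obs[1:2]
  }, character(2)))
  sites <- data.frame(site_id = map$site_id, contig = as.character(map$contig),
                      pos = map$pos1 - 1L, allele_a = alleles[, 1],
                      allele_b = alleles[, 2], stringsAsFactors = FALSE)
  indiv <- data.frame(individual = as.character(ped[, 2]),
                      breed = as.character(ped[, 1]),
                      stringsAsFactors = FALSE)
  if (!is.null(meta)) {
    indiv <- merge(indiv, meta, by = "breed", all.x = TRUE, sort = FALSE)
    indiv <- indiv[, c("individual", "breed", "lon", "lat")]
  } else {
    indiv$lon <- NA_real_; indiv$lat <- NA_real_
  }
  snp_panel(sites, geno, indiv)
}

# ---- newick ------------------------------------------------------------------

#' Serialise a phylogenetic tree as newick text
#'
#' Thin wrapper over [ape::write.tree()]; node labels (bootstrap supports)
#' are preserved.
#'
#' @param tree a `phylo` object.
#' @param path optional output path; if `NULL` the newick string is returned.
#' @return newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

# ---- SAM export --------------------------------------------------------------

#' Export alignment hits as a minimal SAM file
#'
#' Writes the mandatory columns only (single-end, ungapped `<L>M` CIGAR).
#' Minus-strand hits are written reference-oriented with reversed qualities,
#' following SAM convention.
#'
#' @param hits alignment hits `data.frame` (see [align_reads()]).
#' @param reads the read set the hits refer to.
#' @param db the `genome_db` used for alignment.
#' @param genome genome name the hits belong to.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(hits, reads, db, genome, path) {
  contigs <- genome_contigs(db, genome)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), nchar(contigs)), con)
  if (nrow(hits)) {
    idx <- match(hits$read_id, reads$id)
    seq <- reads$seq[idx]
    qual <- reads$qual[idx]
    minus <- hits$strand == "-"
    seq[minus] <- revcomp(seq[minus])
    qual[minus] <- vapply(qual[minus], function(q) {
      intToUtf8(rev(utf8ToInt(q)))
    }, character(1), USE.NAMES = FALSE)
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
                       hits$read_id, ifelse(minus, 16L, 0L), hits$contig,
                       hits$start + 1L, hits$mapq, nchar(seq), seq, qual), con)
  }
  invisible(path)
}
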