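# Genetic-code helpers and the reference ubiquitin sequences shipped with
# the package.

#' Amino-acid row order used by fitness matrices
#'
#' Twenty amino acids in single-letter alphabetical order followed by the
#' stop symbol `*`. This is the row order of every 21 x 76 fitness matrix
#' produced by the package.
#'
#' @format Character vector of length 21.
#' @export
AA_ORDER <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "*")

#' Translate DNA codons to amino acids
#'
#' Uses the standard genetic code; stop codons translate to `*`.
#'
#' @param codons Character vector of 3-nt DNA codons.
#' @return Character vector of single-letter amino acids.
#' @export
translate_codons <- function(codons) {
  if (length(codons) == 0L) return(character(0))
  stopifnot(all(nchar(codons) == 3L))
  unname(Biostrings::GENETIC_CODE[toupper(codons)])
}

#' Split an ORF into codons
#'
#' @param orf DNA string whose length is a multiple of 3.
#' @return Character vector of codons.
#' @export
orf_codons <- function(orf) {
  stopifnot(length(orf) == 1L, nchar(orf) %% 3L == 0L)
  n <- nchar(orf) %/% 3L
  substring(orf, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Translate an ORF
#'
#' @param orf DNA string whose length is a multiple of 3.
#' @return Single-letter amino-acid string (stops as `*`).
#' @export
translate_orf <- function(orf) {
  paste(translate_codons(orf_codons(orf)), collapse = "")
}

#' Reference ubiquitin sequences
#'
#' `ub_wt_orf()` returns the 228-nt representative coding sequence for
#' S. cerevisiae ubiquitin shipped with the package (codon choices are a
#' synthetic construct following common yeast usage; the amino-acid sequence
#' is the canonical 76-residue yeast ubiquitin). `ub_protein()` returns the
#' yeast or human 76-aa protein sequence.
#'
#' @param species `"yeast"` or `"human"` (protein only).
#' @return A single DNA or protein string.
#' @export
ub_wt_orf <- function() {
  path <- system.file("extdata", "ub_yeast_orf_synthetic.fasta", package = "bcfitness")
  as.character(Biostrings::readDNAStringSet(path)[[1L]])
}

#' @rdname ub_wt_orf
#' @export
ub_protein <- function(species = c("yeast", "human")) {
  species <- match.arg(species)
  path <- system.file(
    "extdata",
    sprintf("ub_%s_protein.fasta", species),
    package = "bcfitness"
  )
  as.character(Biostrings::readAAStringSet(path)[[1L]])
}

#' Percent identity between two equal-length sequences
#'
#' Ungapped position-wise identity, as used for fixed-length protein
#' comparisons (e.g. yeast vs human ubiquitin, both 76 aa).
#'
#' @param a,b Sequences of equal length.
#' @return Percent identity in `[0, 100]`.
#' @examples
#' seq_identity_pct("AAAA", "AAAT")  # 75
#' @export
seq_identity_pct <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  100 * (1 - hamming_dist(a, b) / nchar(a))
}

#' Parse a Rosetta resfile
#'
#' Reads the body of a fixed-backbone design resfile (the lines after
#' `start`) into a data frame. Only `PIKAA` commands are interpreted; other
#' commands are retained verbatim.
#'
#' @param path Path to the resfile.
#' @return Data frame with columns `position`, `chain`, `command`, `aa`
#'   (target amino acid for PIKAA rows, `NA` otherwise).
#' @export
parse_resfile <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  start <- match("start", tolower(lines))
  if (is.na(start)) stop("resfile has no 'start' line")
  body <- lines[-seq_len(start)]
  if (length(body) == 0L) {
    return(data.frame(position = integer(0), chain = character(0),
                      command = character(0), aa = character(0),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(body, "\\s+")
  data.frame(
    position = vapply(fields, function(f) as.integer(f[[1L]]), integer(1)),
    chain = vapply(fields, function(f) f[[2L]], character(1)),
    command = vapply(fields, function(f) f[[3L]], character(1)),
    aa = vapply(fields, function(f) if (length(f) >= 4L) f[[4L]] else NA_character_,
                character(1)),
    stringsAsFactors = FALSE
  )
}
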