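# Shared fixture builders. Everything is generated in code under pinned
# seeds; no binary fixtures.

# A small ground-truthed library: `n_variants` amino-acid variants over the
# packaged ubiquitin ORF, a handful of WT barcodes, fixed barcodes/allele.
tiny_truth <- function(n_variants = 30, barcodes_per_allele = 3,
                       n_wt_barcodes = 5, seed = 42, jitter = 0,
                       s_true_fun = default_s_true) {
  lib <- build_mutant_library(ub_wt_orf(), n_variants = n_variants,
                              seed = seed)
  assign_barcodes(
    lib, n_wt_barcodes = n_wt_barcodes,
    barcodes_per_allele = function(n) rep(barcodes_per_allele, n),
    s_true_fun = s_true_fun, barcode_jitter = jitter, seed = seed + 1
  )
}

# Build a fitness_matrix directly from a named list position -> named
# vector of aa scores (everything else masked).
manual_fm <- function(cells, wt_orf = ub_wt_orf()) {
  wt_aa <- translate_codons(orf_codons(wt_orf))
  score <- matrix(NA_real_, length(AA_ORDER), length(wt_aa))
  for (pos in names(cells)) {
    v <- cells[[pos]]
    score[match(names(v), AA_ORDER), as.integer(pos)] <- v
  }
  n <- matrix(0L, nrow(score), ncol(score))
  n[!is.na(score)] <- 1L
  fitness_matrix(score, matrix(NA_real_, nrow(score), ncol(score)), n, wt_aa)
}

# Full-grid fitness matrix filled from a function of (aa index, position),
# WT cells masked.
grid_fm <- function(fill, wt_orf = ub_wt_orf()) {
  wt_aa <- translate_codons(orf_codons(wt_orf))
  score <- outer(seq_along(AA_ORDER), seq_along(wt_aa), fill)
  score[cbind(match(wt_aa, AA_ORDER), seq_along(wt_aa))] <- NA_real_
  n <- matrix(0L, nrow(score), ncol(score))
  n[!is.na(score)] <- 1L
  fitness_matrix(score, matrix(NA_real_, nrow(score), ncol(score)), n, wt_aa)
}

# Simple independent Hamming distance: character-by-character comparison.
naive_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

read_df <- function(id, seq, qual = strrep("I", nchar(seq[1])),
                    comment = NULL) {
  df <- data.frame(id = id, seq = seq, qual = rep_len(qual, length(seq)),
                   stringsAsFactors = FALSE)
  if (!is.null(comment)) df$comment <- comment
  df
}
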