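# Subassembly: link each N18 barcode to its full-length allele from
# paired-end reads, by vector-sequence filtering, mate pairing, grouping on
# the barcode and plurality consensus calling.

#' Filter barcode reads on the expected vector sequence
#'
#' Retains reads whose bases immediately after the first `barcode_length`
#' nucleotides match the expected vector sequence within a Hamming cutoff.
#' Reads too short to contain barcode plus vector are dropped and counted.
#'
#' @param reads Data frame of reads (`id`, `seq`, `qual`).
#' @param expected_vector_seq Non-empty constant vector sequence.
#' @param max_mismatch Maximum Hamming mismatches tolerated (default 2).
#' @param barcode_length Barcode width (default 18).
#' @param log_path Optional path; a kept/dropped summary line is appended.
#' @return List with `reads` (the kept subset) and `stats` (named counts:
#'   `kept`, `dropped_mismatch`, `dropped_short`).
#' @export
filter_barcode_reads <- function(reads, expected_vector_seq, max_mismatch = 2L,
                                 barcode_length = 18L, log_path = NULL) {
  stopifnot(nzchar(expected_vector_seq), max_mismatch >= 0L)
  need <- barcode_length + nchar(expected_vector_seq)
  long_enough <- nchar(reads$seq) >= need
  short <- sum(!long_enough)
  candidate <- reads[long_enough, , drop = FALSE]
  if (nrow(candidate) > 0L) {
    region <- substr(candidate$seq, barcode_length + 1L, need)
    ok <- hamming_dist(region, expected_vector_seq) <= max_mismatch
  } else {
    ok <- logical(0)
  }
  kept <- candidate[ok, , drop = FALSE]
  stats <- c(kept = nrow(kept), dropped_mismatch = sum(!ok),
             dropped_short = short)
  if (!is.null(log_path)) {
    cat(sprintf("filter_barcode_reads: kept %d / %d (mismatch %d, short %d)\n",
                stats[["kept"]], nrow(reads), stats[["dropped_mismatch"]],
                stats[["dropped_short"]]),
        file = log_path, append = TRUE)
  }
  list(reads = kept, stats = stats)
}

#' Pair barcode reads with ORF reads by identifier
#'
#' Emits one record per read id present in both inputs; duplicated ids
#' within a file keep the first occurrence (with a warning count), and
#' unpaired ids are tallied.
#'
#' @param barcode_reads,orf_reads Read data frames (`id`, `seq`, `qual`).
#' @return List with `pairs` (data frame: `id`, `barcode_seq`,
#'   `barcode_qual`, `orf_seq`, `orf_qual`) and `stats`.
#' @export
pair_reads <- function(barcode_reads, orf_reads) {
  dedup <- function(df) {
    dup <- duplicated(df$id)
    list(df = df[!dup, , drop = FALSE], n_dup = sum(dup))
  }
  b <- dedup(barcode_reads)
  o <- dedup(orf_reads)
  if (b$n_dup + o$n_dup > 0L) {
    warning(sprintf("dropped %d duplicate read ids (kept first occurrence)",
                    b$n_dup + o$n_dup))
  }
  common <- intersect(b$df$id, o$df$id)
  bi <- b$df[match(common, b$df$id), , drop = FALSE]
  oi <- o$df[match(common, o$df$id), , drop = FALSE]
  pairs <- data.frame(
    id = common,
    barcode_seq = bi$seq, barcode_qual = bi$qual,
    orf_seq = oi$seq, orf_qual = oi$qual,
    stringsAsFactors = FALSE
  )
  stats <- c(paired = length(common),
             unpaired_barcode = nrow(b$df) - length(common),
             unpaired_orf = nrow(o$df) - length(common),
             duplicates = b$n_dup + o$n_dup)
  list(pairs = pairs, stats = stats)
}

#' Group paired reads by barcode
#'
#' The grouping key is the first `barcode_length` nucleotides of the
#' barcode read; group sizes sum to the number of input pairs.
#'
#' @param pairs Data frame from [pair_reads()].
#' @param barcode_length Barcode width (default 18).
#' @return Named list mapping each barcode to the character vector of its
#'   associated ORF read sequences.
#' @export
group_by_barcode <- function(pairs, barcode_length = 18L) {
  key <- substr(pairs$barcode_seq, 1L, barcode_length)
  split(pairs$orf_seq, key)
}

# Plurality consensus of equal-length sequences; NA on a positional tie.
consensus_seq <- function(seqs) {
  if (length(unique(seqs)) == 1L) return(seqs[[1L]])
  m <- seq_matrix(seqs)
  cons <- m[1L, ]
  diff_cols <- which(colSums(m != rep(m[1L, ], each = nrow(m))) > 0L)
  for (j in diff_cols) {
    tab <- table(m[, j])
    top <- max(tab)
    winners <- as.integer(names(tab)[tab == top])
    if (length(winners) > 1L) return(NA_character_)
    cons[j] <- winners
  }
  intToUtf8(cons)
}

#' Call per-barcode consensus alleles
#'
#' For each barcode observed at least `min_reads` times, builds a
#' per-position plurality consensus over its ORF reads and compares it to
#' the WT ORF at the codon level. Barcodes whose consensus differs from WT
#' at exactly one codon become map entries; identical consensus yields a
#' WT-flagged entry; two or more differing codons, positional consensus
#' ties, or mixed read lengths exclude the barcode (all tallied).
#'
#' @param groups Named list from [group_by_barcode()].
#' @param wt_orf WT ORF (length a multiple of 3; 228 nt for ubiquitin).
#' @param min_reads Minimum reads per barcode (default 3).
#' @return A `barcode_map` data frame (`barcode`, `position`,
#'   `mutant_codon`, `aa`, `is_wt`, `n_reads`) with a `stats` attribute.
#' @export
call_consensus <- function(groups, wt_orf, min_reads = 3L) {
  wt_orf <- toupper(wt_orf)
  stopifnot(nchar(wt_orf) %% 3L == 0L)
  wt_codons <- orf_codons(wt_orf)
  n_pos <- length(wt_codons)

  barcodes <- names(groups)
  sizes <- lengths(groups)
  stats <- c(too_few_reads = 0L, length_mismatch = 0L, consensus_tie = 0L,
             multi_mutant = 0L, kept = 0L)
  rows <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    seqs <- groups[[i]]
    if (length(seqs) < min_reads) {
      stats[["too_few_reads"]] <- stats[["too_few_reads"]] + 1L
      next
    }
    if (length(unique(nchar(seqs))) != 1L || nchar(seqs[[1L]]) != nchar(wt_orf)) {
      stats[["length_mismatch"]] <- stats[["length_mismatch"]] + 1L
      next
    }
    cons <- consensus_seq(seqs)
    if (is.na(cons)) {
      stats[["consensus_tie"]] <- stats[["consensus_tie"]] + 1L
      next
    }
    cons_codons <- orf_codons(cons)
    diff <- which(cons_codons != wt_codons)
    if (length(diff) > 1L) {
      stats[["multi_mutant"]] <- stats[["multi_mutant"]] + 1L
      next
    }
    stats[["kept"]] <- stats[["kept"]] + 1L
    if (length(diff) == 0L) {
      rows[[i]] <- data.frame(
        barcode = barcodes[[i]], position = NA_integer_,
        mutant_codon = NA_character_, aa = NA_character_, is_wt = TRUE,
        n_reads = sizes[[i]], stringsAsFactors = FALSE
      )
    } else {
      codon <- cons_codons[[diff]]
      rows[[i]] <- data.frame(
        barcode = barcodes[[i]], position = diff,
        mutant_codon = codon, aa = translate_codons(codon), is_wt = FALSE,
        n_reads = sizes[[i]], stringsAsFactors = FALSE
      )
    }
  }
  map <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(map)) {
    map <- data.frame(barcode = character(0), position = integer(0),
                      mutant_codon = character(0), aa = character(0),
                      is_wt = logical(0), n_reads = integer(0),
                      stringsAsFactors = FALSE)
  }
  rownames(map) <- NULL
  class(map) <- c("barcode_map", "data.frame")
  attr(map, "stats") <- stats
  map
}

#' Run the full subassembly stage
#'
#' Chains vector-sequence filtering, mate pairing, barcode grouping and
#' consensus calling.
#'
#' @param read1,read2 Read data frames (barcode reads and ORF reads).
#' @param wt_orf WT ORF sequence.
#' @param vector_seq Expected constant vector sequence after the barcode.
#' @param max_mismatch Hamming cutoff for the vector match (default 2).
#' @param min_reads Minimum reads per barcode (default 3).
#' @param log_path Optional log file.
#' @return A `barcode_map` with combined `stats` attribute.
#' @export
subassemble <- function(read1, read2, wt_orf, vector_seq = "GGCGCGCC",
                        max_mismatch = 2L, min_reads = 3L, log_path = NULL) {
  filt <- filter_barcode_reads(read1, vector_seq, max_mismatch,
                               log_path = log_path)
  paired <- pair_reads(filt$reads, read2)
  groups <- group_by_barcode(paired$pairs)
  map <- call_consensus(groups, wt_orf, min_reads = min_reads)
  attr(map, "stats") <- c(filter = filt$stats, pairing = paired$stats,
                          consensus = attr(map, "stats"))
  map
}

#' Read or write a barcode-to-allele map as TSV
#'
#' @param map A `barcode_map` data frame.
#' @param path File path.
#' @return `write_barcode_map()` the path invisibly; `read_barcode_map()`
#'   the map.
#' @export
write_barcode_map <- function(map, path) {
  write_tsv(as.data.frame(map), path)
}

#' @rdname write_barcode_map
#' @export
read_barcode_map <- function(path) {
  map <- read_tsv(path)
  map$is_wt <- as.logical(map$is_wt)
  class(map) <- c("barcode_map", "data.frame")
  map
}
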