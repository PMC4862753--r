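# Demultiplexing by sample index and barcode counting with Hamming-distance
# error correction against the subassembly map.

#' Read and validate a sample index table
#'
#' Loads a two-column (name, sequence) index table and checks that all
#' pairwise Hamming distances exceed `index_cutoff`, the condition under
#' which index error correction at that cutoff is unambiguous. With no path,
#' returns the packaged TruSeq-style trio (TS1 CGTGAT, TS2 ACATCG,
#' TS3 GCCTAA).
#'
#' @param path Optional path to a headerless 2-column TSV.
#' @param index_cutoff Demultiplexing Hamming cutoff to validate against.
#' @return Data frame with columns `name`, `sequence`.
#' @export
read_index_table <- function(path = NULL, index_cutoff = 2L) {
  if (is.null(path)) {
    path <- system.file("extdata", "truseq_indices.tsv", package = "bcfitness")
  }
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("name", "sequence"))
  tab$sequence <- toupper(tab$sequence)
  validate_index_table(tab, index_cutoff)
  tab
}

validate_index_table <- function(tab, index_cutoff = 2L) {
  if (length(unique(nchar(tab$sequence))) != 1L) {
    stop("index sequences must share one length")
  }
  if (nrow(tab) > 1L) {
    pairs <- utils::combn(nrow(tab), 2L)
    d <- hamming_dist(tab$sequence[pairs[1L, ]], tab$sequence[pairs[2L, ]])
    if (any(d <= index_cutoff)) {
      stop(sprintf("index pair within Hamming %d: %s / %s", index_cutoff,
                   tab$name[pairs[1L, which.min(d)]],
                   tab$name[pairs[2L, which.min(d)]]))
    }
  }
  invisible(tab)
}

# Pull the sample index out of an Illumina-style header comment
# ("1:N:0:CGTGAT"); falls back to the whole comment when it has no colons.
extract_index <- function(comment) {
  sub("^.*:", "", comment)
}

#' Demultiplex competition reads by sample index
#'
#' Assigns each read to the unique index within `index_cutoff` Hamming
#' distance of its observed index (carried in the header comment). Reads
#' matching no index, or several, are discarded; so are reads whose 8-nt
#' constant region (immediately after the barcode) exceeds `const_cutoff`
#' mismatches, or whose barcode-region mean Phred quality falls below
#' `min_mean_quality`.
#'
#' @param reads Data frame (`id`, `comment`, `seq`, `qual`).
#' @param index_table Data frame (`name`, `sequence`).
#' @param index_cutoff,const_cutoff Hamming cutoffs (defaults 2 and 2).
#' @param min_mean_quality Mean-Phred floor over the barcode bases
#'   (default 20).
#' @param const_seq Expected constant region.
#' @param barcode_length Barcode width (default 18).
#' @return List with `observations` (named list: sample -> character vector
#'   of observed barcodes) and `stats` (assigned, unassigned_index,
#'   ambiguous_index, failed_constant, failed_quality, total).
#' @export
demultiplex <- function(reads, index_table, index_cutoff = 2L,
                        const_cutoff = 2L, min_mean_quality = 20,
                        const_seq = "GGCGCGCC", barcode_length = 18L) {
  validate_index_table(index_table, index_cutoff)
  n <- nrow(reads)
  stats <- c(assigned = 0L, unassigned_index = 0L, ambiguous_index = 0L,
             failed_constant = 0L, failed_quality = 0L, total = n)
  observations <- setNames(
    rep(list(character(0)), nrow(index_table)), index_table$name
  )
  if (n == 0L) return(list(observations = observations, stats = stats))

  obs_index <- extract_index(reads$comment)
  width <- nchar(index_table$sequence[1L])
  valid_len <- nchar(obs_index) == width
  sample_idx <- rep(NA_integer_, n)
  ambiguous <- rep(FALSE, n)
  if (any(valid_len)) {
    im <- seq_matrix(obs_index[valid_len])
    km <- seq_matrix(index_table$sequence)
    d <- matrix(0L, nrow = nrow(im), ncol = nrow(km))
    for (k in seq_len(width)) d <- d + outer(im[, k], km[, k], "!=")
    within <- d <= index_cutoff
    n_within <- rowSums(within)
    hit <- n_within == 1L
    sample_idx[which(valid_len)[hit]] <- max.col(within, ties.method = "first")[hit]
    ambiguous[which(valid_len)[n_within > 1L]] <- TRUE
  }
  if (any(ambiguous)) {
    message(sprintf("%d reads matched multiple indices and were discarded",
                    sum(ambiguous)))
  }
  stats[["ambiguous_index"]] <- sum(ambiguous)
  stats[["unassigned_index"]] <- sum(is.na(sample_idx) & !ambiguous)

  keep <- !is.na(sample_idx)
  const_end <- barcode_length + nchar(const_seq)
  const_ok <- keep & nchar(reads$seq) >= const_end
  if (any(const_ok)) {
    region <- substr(reads$seq[const_ok], barcode_length + 1L, const_end)
    const_ok[const_ok] <- hamming_dist(region, const_seq) <= const_cutoff
  }
  stats[["failed_constant"]] <- sum(keep & !const_ok)

  qual_ok <- const_ok
  if (any(const_ok)) {
    bq <- substr(reads$qual[const_ok], 1L, barcode_length)
    qual_ok[const_ok] <- mean_phred(bq) >= min_mean_quality
  }
  stats[["failed_quality"]] <- sum(const_ok & !qual_ok)
  stats[["assigned"]] <- sum(qual_ok)

  barcodes <- substr(reads$seq[qual_ok], 1L, barcode_length)
  by_sample <- split(barcodes, index_table$name[sample_idx[qual_ok]])
  observations[names(by_sample)] <- by_sample
  list(observations = observations, stats = stats)
}

#' Error-correct observed barcodes and count them
#'
#' Each observed 18-mer increments the count of the unique known barcode
#' within `fuzzy_cutoff` Hamming distance (exact matches shortcut the
#' search). Observations with no known barcode within the cutoff, or with
#' two or more equidistant nearest known barcodes, are discarded and
#' tallied. Results are identical to an exhaustive nearest-neighbour search
#' with tie discard.
#'
#' @param observations Character vector of observed barcodes for one
#'   sample, or a named list of such vectors (as from [demultiplex()]).
#' @param allele_map A `barcode_map`.
#' @param fuzzy_cutoff Maximum Hamming distance considered (default 2).
#' @return For a vector input: list with `counts` (named integer vector
#'   over all map barcodes) and `stats` (exact, corrected, no_match,
#'   ambiguous, bad_length). For a list input: a `barcode_counts` object
#'   (named list of count vectors) with a `stats` attribute.
#' @export
correct_and_count <- function(observations, allele_map, fuzzy_cutoff = 2L) {
  if (nrow(allele_map) == 0L) stop("allele map is empty")
  if (is.list(observations)) {
    per_sample <- lapply(observations, correct_and_count, allele_map,
                         fuzzy_cutoff)
    out <- lapply(per_sample, `[[`, "counts")
    class(out) <- "barcode_counts"
    attr(out, "stats") <- lapply(per_sample, `[[`, "stats")
    return(out)
  }
  known <- allele_map$barcode
  width <- nchar(known[1L])
  counts <- setNames(integer(length(known)), known)
  stats <- c(exact = 0L, corrected = 0L, no_match = 0L, ambiguous = 0L,
             bad_length = 0L)
  if (length(observations) == 0L) return(list(counts = counts, stats = stats))

  ok_len <- nchar(observations) == width
  stats[["bad_length"]] <- sum(!ok_len)
  tab <- table(observations[ok_len])
  uniq <- names(tab)
  mult <- as.integer(tab)
  hit <- match(uniq, known)
  exact <- !is.na(hit)
  stats[["exact"]] <- sum(mult[exact])
  if (any(exact)) {
    add <- tapply(mult[exact], hit[exact], sum)
    counts[as.integer(names(add))] <- counts[as.integer(names(add))] +
      as.integer(add)
  }
  if (any(!exact) && fuzzy_cutoff > 0L) {
    om <- seq_matrix(uniq[!exact])
    km <- seq_matrix(known)
    nn <- nearest_hamming(om, km)
    assignable <- nn$min <= fuzzy_cutoff & !nn$tie
    stats[["corrected"]] <- sum(mult[!exact][assignable])
    stats[["ambiguous"]] <- sum(mult[!exact][nn$min <= fuzzy_cutoff & nn$tie])
    stats[["no_match"]] <- sum(mult[!exact][nn$min > fuzzy_cutoff])
    if (any(assignable)) {
      add <- tapply(mult[!exact][assignable], nn$idx[assignable], sum)
      counts[as.integer(names(add))] <- counts[as.integer(names(add))] +
        as.integer(add)
    }
  } else if (any(!exact)) {
    stats[["no_match"]] <- sum(mult[!exact])
  }
  list(counts = counts, stats = stats)
}

#' Merge barcode counts across sequencing runs
#'
#' Per (sample, barcode), the output count is the sum over the inputs;
#' samples and barcodes are unioned.
#'
#' @param ... `barcode_counts` objects (named lists of named integer
#'   vectors).
#' @return A merged `barcode_counts` object.
#' @export
merge_counts <- function(...) {
  inputs <- list(...)
  stopifnot(length(inputs) > 0L)
  samples <- unique(unlist(lapply(inputs, names)))
  out <- setNames(vector("list", length(samples)), samples)
  for (s in samples) {
    vecs <- lapply(inputs, function(x) x[[s]])
    vecs <- vecs[!vapply(vecs, is.null, logical(1))]
    barcodes <- unique(unlist(lapply(vecs, names)))
    total <- setNames(integer(length(barcodes)), barcodes)
    for (v in vecs) total[names(v)] <- total[names(v)] + v
    out[[s]] <- total
  }
  class(out) <- "barcode_counts"
  out
}

#' Count matrix constructor
#'
#' A `count_matrix` holds per-barcode counts across the ordered timepoints
#' of one (condition, replicate) experiment, with the elapsed WT
#' generations attached.
#'
#' @param counts Numeric matrix (rows = barcodes, columns = timepoints).
#' @param generations Strictly increasing numeric vector, one per column.
#' @param barcodes Optional row names.
#' @return The matrix with class `count_matrix` and a `generations`
#'   attribute.
#' @export
count_matrix <- function(counts, generations, barcodes = NULL) {
  counts <- as.matrix(counts)
  if (length(generations) != ncol(counts)) {
    stop("one generations value per timepoint column required")
  }
  if (any(diff(generations) <= 0)) stop("generations must be strictly increasing")
  if (!is.null(barcodes)) rownames(counts) <- barcodes
  colnames(counts) <- sprintf("t%d", seq_len(ncol(counts)))
  structure(counts, generations = as.numeric(generations),
            class = c("count_matrix", class(counts)))
}

#' Elapsed WT generations of a count matrix
#'
#' @param x A `count_matrix`.
#' @return Numeric vector of generations per timepoint.
#' @export
generations <- function(x) attr(x, "generations")

validate_sample_sheet <- function(sheet) {
  need <- c("sample", "index_name", "index_seq", "condition", "replicate",
            "timepoint", "generations")
  missing <- setdiff(need, names(sheet))
  if (length(missing) > 0L) {
    stop("sample sheet lacks columns: ", paste(missing, collapse = ", "))
  }
  key <- paste(sheet$condition, sheet$replicate, sheet$timepoint)
  if (anyDuplicated(key)) {
    stop("duplicate (condition, replicate, timepoint): ",
         key[duplicated(key)][1L])
  }
  if (grepl("[^ACGT]", paste(sheet$index_seq, collapse = ""))) {
    stop("index sequences must be ACGT")
  }
  for (exp in split(sheet, paste(sheet$condition, sheet$replicate))) {
    exp <- exp[order(exp$timepoint), ]
    if (any(diff(exp$generations) <= 0)) {
      stop("generations must increase with timepoint within an experiment")
    }
  }
  invisible(sheet)
}

#' Assemble per-experiment count matrices from sample counts
#'
#' Joins per-sample barcode counts with the sample sheet into one
#' `count_matrix` per (condition, replicate), columns ordered by
#' generations; barcodes absent from a sample get count 0.
#'
#' @param counts A `barcode_counts` object.
#' @param sample_sheet Sample sheet data frame (see [make_sample_sheet()]).
#' @return Named list of `count_matrix` objects keyed
#'   `<condition>.<replicate>`.
#' @export
assemble_timecourse <- function(counts, sample_sheet) {
  validate_sample_sheet(sample_sheet)
  missing <- setdiff(sample_sheet$sample, names(counts))
  if (length(missing) > 0L) {
    stop("no counts for samples: ", paste(missing, collapse = ", "))
  }
  out <- list()
  for (exp in split(sample_sheet,
                    paste(sample_sheet$condition, sample_sheet$replicate,
                          sep = "."))) {
    exp <- exp[order(exp$generations), ]
    barcodes <- unique(unlist(lapply(counts[exp$sample], names)))
    m <- matrix(0L, nrow = length(barcodes), ncol = nrow(exp),
                dimnames = list(barcodes, NULL))
    for (j in seq_len(nrow(exp))) {
      v <- counts[[exp$sample[j]]]
      m[names(v), j] <- v
    }
    key <- paste(exp$condition[1L], exp$replicate[1L], sep = ".")
    out[[key]] <- count_matrix(m, exp$generations)
  }
  out
}
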