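# Aggregation of clean barcode scores into masked 21 x 76 amino-acid
# fitness matrices with per-cell error estimates, position averages and
# tolerance bins.

#' Fitness matrix constructor
#'
#' A `fitness_matrix` bundles the 21 x 76 (amino acids x positions) mean
#' score matrix, the matching per-cell standard-deviation matrix, the
#' per-cell contributing-barcode counts, and the WT amino acid at each
#' position. Cells with no contributing barcode are `NA` (masked); WT
#' cells carry no mutant score by construction.
#'
#' @param score,error,n 21 x 76 matrices (rows in `AA_ORDER`).
#' @param wt_aa Character vector of WT amino acids (length = columns).
#' @return An object of class `fitness_matrix`.
#' @export
fitness_matrix <- function(score, error, n, wt_aa) {
  stopifnot(nrow(score) == length(AA_ORDER), ncol(score) == length(wt_aa),
            identical(dim(score), dim(error)), identical(dim(score), dim(n)))
  dimnames(score) <- dimnames(error) <- dimnames(n) <-
    list(AA_ORDER, seq_len(ncol(score)))
  structure(list(score = score, error = error, n = n, wt_aa = wt_aa),
            class = "fitness_matrix")
}

#' @export
print.fitness_matrix <- function(x, ...) {
  cat(sprintf("fitness_matrix: %d x %d, %d cells with scores\n",
              nrow(x$score), ncol(x$score), sum(!is.na(x$score))))
  invisible(x)
}

#' Aggregate barcode scores to the amino-acid level
#'
#' Computes, for every (amino acid, position) cell, the mean of all clean
#' barcode scores across synonymous codons (pooling barcodes directly, so
#' cells are weighted by evidence), the sample standard deviation of those
#' contributing scores (NA for single-barcode cells), and the barcode
#' count. Cells with no barcode are masked; WT cells stay masked by
#' construction.
#'
#' @param score_table A filtered `score_table`.
#' @param allele_map A `barcode_map`.
#' @param wt_orf WT ORF (defaults to the packaged ubiquitin ORF); sets the
#'   number of positions and the WT amino acids.
#' @return A `fitness_matrix`.
#' @export
aggregate_fitness <- function(score_table, allele_map, wt_orf = ub_wt_orf()) {
  wt_aa <- translate_codons(orf_codons(wt_orf))
  n_pos <- length(wt_aa)
  scored <- score_table[!score_table$excluded & !is.na(score_table$score), ,
                        drop = FALSE]
  hit <- match(scored$barcode, allele_map$barcode)
  if (anyNA(hit)) stop("score table contains barcodes absent from the map")
  keep <- !allele_map$is_wt[hit]
  pos <- allele_map$position[hit][keep]
  aa <- allele_map$aa[hit][keep]
  s <- scored$score[keep]

  score <- matrix(NA_real_, length(AA_ORDER), n_pos)
  error <- matrix(NA_real_, length(AA_ORDER), n_pos)
  nmat <- matrix(0L, length(AA_ORDER), n_pos)
  if (length(s) > 0L) {
    cell <- paste(match(aa, AA_ORDER), pos)
    means <- tapply(s, cell, mean)
    sds <- tapply(s, cell, function(v) if (length(v) > 1L) sd(v) else NA_real_)
    ns <- tapply(s, cell, length)
    ij <- do.call(rbind, lapply(strsplit(names(means), " "), as.integer))
    score[ij] <- means
    error[ij] <- sds
    nmat[ij] <- ns
  }
  fitness_matrix(score, error, nmat, wt_aa)
}

#' Codon-level score summary
#'
#' Mean, standard deviation and barcode count per (position, mutant codon).
#'
#' @inheritParams aggregate_fitness
#' @return Data frame with columns `position`, `mutant_codon`, `aa`,
#'   `mean`, `sd`, `n`.
#' @export
aggregate_codon <- function(score_table, allele_map) {
  scored <- score_table[!score_table$excluded & !is.na(score_table$score), ,
                        drop = FALSE]
  hit <- match(scored$barcode, allele_map$barcode)
  if (anyNA(hit)) stop("score table contains barcodes absent from the map")
  keep <- !allele_map$is_wt[hit]
  df <- data.frame(position = allele_map$position[hit][keep],
                   mutant_codon = allele_map$mutant_codon[hit][keep],
                   aa = allele_map$aa[hit][keep],
                   score = scored$score[keep], stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    return(data.frame(position = integer(0), mutant_codon = character(0),
                      aa = character(0), mean = numeric(0), sd = numeric(0),
                      n = integer(0)))
  }
  agg <- do.call(rbind, lapply(
    split(df, paste(df$position, df$mutant_codon)),
    function(grp) data.frame(
      position = grp$position[1L], mutant_codon = grp$mutant_codon[1L],
      aa = grp$aa[1L], mean = mean(grp$score),
      sd = if (nrow(grp) > 1L) sd(grp$score) else NA_real_,
      n = nrow(grp), stringsAsFactors = FALSE
    )
  ))
  agg <- agg[order(agg$position, agg$mutant_codon), ]
  rownames(agg) <- NULL
  agg
}

#' Average fitness matrices across biological replicates
#'
#' Cellwise mean over unmasked replicate values; a cell stays masked only
#' where every replicate is masked. Errors combine as the root mean square
#' of the available per-replicate standard deviations, and contributing
#' counts add.
#'
#' @param ... `fitness_matrix` objects of identical shape.
#' @return A `fitness_matrix`.
#' @export
replicate_average <- function(...) {
  mats <- list(...)
  if (length(mats) == 1L && is.list(mats[[1L]]) &&
      !inherits(mats[[1L]], "fitness_matrix")) {
    mats <- mats[[1L]]
  }
  stopifnot(length(mats) >= 1L,
            all(vapply(mats, inherits, logical(1), "fitness_matrix")))
  scores <- lapply(mats, `[[`, "score")
  stack <- simplify2array(scores)
  score <- apply(stack, c(1L, 2L), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  errs <- simplify2array(lapply(mats, `[[`, "error"))
  error <- apply(errs, c(1L, 2L), function(v) {
    if (all(is.na(v))) NA_real_ else sqrt(mean(v^2, na.rm = TRUE))
  })
  n <- Reduce(`+`, lapply(mats, `[[`, "n"))
  fitness_matrix(score, error, n, mats[[1L]]$wt_aa)
}

#' Per-position average fitness
#'
#' Mean over the unmasked, non-WT cells of each position column. The stop
#' row is excluded by default (its uniformly null scores would depress
#' every position mean); set `include_stop = TRUE` to include it.
#'
#' @param fm A `fitness_matrix`.
#' @param include_stop Include the stop row (default FALSE).
#' @return Named numeric vector of length `ncol(fm$score)`; fully masked
#'   columns are `NA`.
#' @export
position_averages <- function(fm, include_stop = FALSE) {
  stopifnot(inherits(fm, "fitness_matrix"))
  m <- fm$score
  if (!include_stop) m <- m[AA_ORDER != "*", , drop = FALSE]
  avg <- colMeans(m, na.rm = TRUE)
  avg[!is.finite(avg)] <- NA_real_
  setNames(avg, seq_along(avg))
}

#' Bin positions by average fitness
#'
#' Positions are categorised as sensitive (average <= `sensitive`,
#' default -0.35), tolerant (average >= `tolerant`, default -0.075) or
#' intermediate (strictly between).
#'
#' @param averages Numeric vector of per-position averages (NA = masked).
#' @param sensitive,tolerant Bin thresholds (must satisfy
#'   `sensitive < tolerant`).
#' @return Data frame with columns `position`, `avg`, `bin` (factor with
#'   levels sensitive/intermediate/tolerant; NA where masked).
#' @export
bin_positions <- function(averages, sensitive = -0.35, tolerant = -0.075) {
  stopifnot(sensitive < tolerant)
  bin <- ifelse(is.na(averages), NA_character_,
                ifelse(averages <= sensitive, "sensitive",
                       ifelse(averages >= tolerant, "tolerant", "intermediate")))
  data.frame(
    position = seq_along(averages),
    avg = unname(averages),
    bin = factor(bin, levels = c("sensitive", "intermediate", "tolerant")),
    stringsAsFactors = FALSE
  )
}

#' Write a fitness matrix (and its error matrix) to TSV
#'
#' Matrices are written as 21 labelled rows by 76 labelled columns with
#' masked cells as `NA`.
#'
#' @param fm A `fitness_matrix`.
#' @param path Output path for the score matrix.
#' @param error_path Optional output path for the error matrix.
#' @export
write_fitness_matrix <- function(fm, path, error_path = NULL) {
  write.table(cbind(aa = rownames(fm$score), as.data.frame(fm$score)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(error_path)) {
    write.table(cbind(aa = rownames(fm$error), as.data.frame(fm$error)),
                error_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a fitness matrix written by [write_fitness_matrix()]
#'
#' @param path Score matrix TSV.
#' @param error_path Optional error matrix TSV.
#' @param wt_orf WT ORF used to restore WT amino-acid annotations.
#' @return A `fitness_matrix` (contributing counts unknown: 1 where
#'   unmasked).
#' @export
read_fitness_matrix <- function(path, error_path = NULL, wt_orf = ub_wt_orf()) {
  df <- read_tsv(path)
  score <- as.matrix(df[, -1L])
  rownames(score) <- df$aa
  score <- score[AA_ORDER, , drop = FALSE]
  error <- matrix(NA_real_, nrow(score), ncol(score))
  if (!is.null(error_path)) {
    ef <- read_tsv(error_path)
    error <- as.matrix(ef[, -1L])
    rownames(error) <- ef$aa
    error <- error[AA_ORDER, , drop = FALSE]
  }
  n <- matrix(0L, nrow(score), ncol(score))
  n[!is.na(score)] <- 1L
  fitness_matrix(score, error, n, translate_codons(orf_codons(wt_orf)))
}
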