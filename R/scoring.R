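# Fitness scoring: per-barcode per-generation log2 selection coefficients
# relative to the aggregated wild-type reference, floored at -0.5.

#' Aggregate wild-type reference counts
#'
#' Column sums of the count matrix over WT-flagged barcodes; the reference
#' trajectory against which every mutant barcode is scored.
#'
#' @param counts A `count_matrix`.
#' @param allele_map A `barcode_map` distinguishing WT-flagged barcodes.
#' @return Numeric vector of per-timepoint WT aggregate counts.
#' @export
wt_reference <- function(counts, allele_map) {
  wt_bc <- allele_map$barcode[allele_map$is_wt]
  rows <- intersect(rownames(counts), wt_bc)
  if (length(rows) == 0L) stop("no WT-flagged barcodes present in counts")
  agg <- colSums(counts[rows, , drop = FALSE])
  if (any(agg <= 0)) {
    stop("WT aggregate count is zero at a timepoint; reference undefined")
  }
  agg
}

# Closed-form OLS slope and R^2 of each row of y against x.
row_ols <- function(y, x) {
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  slope <- as.numeric(y %*% xc) / sxx
  fit_dev <- outer(slope, xc)
  res <- y - rowMeans(y) - fit_dev
  sst <- rowSums((y - rowMeans(y))^2)
  r2 <- ifelse(sst > 0, 1 - rowSums(res^2) / sst, NA_real_)
  list(slope = slope, r2 = r2)
}

#' Score barcodes from a count time course
#'
#' Default method `"log-ratio"`: for each barcode the score is the OLS
#' slope of `log2((c_bt + pseudocount) / (w_t + pseudocount))` against
#' elapsed WT generations — the per-generation log2 selection coefficient
#' relative to wild type. Alternative method `"slope-ratio"`: the slope of
#' depth-normalised counts against generations is computed per barcode and
#' for the WT aggregate, and the score is `log2(slope_b / slope_WT)`
#' (undefined, hence floored, when either slope is non-positive). Raw
#' scores are retained; reported scores are floored at `floor`. Barcodes
#' whose initial count is below `min_initial` are flagged excluded.
#'
#' @param counts A `count_matrix` (rows barcodes, columns timepoints).
#' @param wt_aggregate Per-timepoint WT reference counts, aligned to the
#'   columns of `counts` (see [wt_reference()]).
#' @param generations Elapsed WT generations per timepoint; defaults to the
#'   `generations` attribute of `counts`.
#' @param method `"log-ratio"` (default) or `"slope-ratio"`.
#' @param min_initial Minimum initial count for inclusion (default 4, i.e.
#'   barcodes observed three or fewer times initially are excluded).
#' @param floor Reported-score floor (default -0.5, the stop-codon null
#'   level).
#' @param pseudocount Added to numerator and denominator of the log-ratio
#'   (default 0.5); set to 0 for exact recovery on noiseless trajectories.
#' @return A `score_table` data frame: `barcode`, `score`, `raw_score`,
#'   `r2`, `c0`, `excluded`, `reason`.
#' @export
score_barcodes <- function(counts, wt_aggregate, generations = NULL,
                           method = c("log-ratio", "slope-ratio"),
                           min_initial = 4L, floor = -0.5, pseudocount = 0.5) {
  method <- match.arg(method)
  if (is.null(generations)) generations <- attr(counts, "generations")
  if (is.null(generations)) stop("generations not supplied")
  g <- as.numeric(generations)
  m <- unclass(counts)
  if (length(wt_aggregate) != ncol(m)) {
    stop("wt_aggregate not aligned with count columns")
  }
  n <- nrow(m)
  c0 <- m[, 1L]
  excluded <- c0 < min_initial
  reason <- ifelse(excluded, "low_initial", "")
  raw <- rep(NA_real_, n)
  r2 <- rep(NA_real_, n)

  if (ncol(m) < 2L) {
    excluded[] <- TRUE
    reason[] <- "too_few_timepoints"
  } else if (method == "log-ratio") {
    y <- log2(sweep(m + pseudocount, 2L, wt_aggregate + pseudocount, "/"))
    fit <- row_ols(y, g)
    raw <- fit$slope
    r2 <- fit$r2
  } else {
    totals <- colSums(m)
    if (any(totals <= 0)) stop("zero total counts at a timepoint")
    norm <- sweep(m, 2L, totals, "/")
    wt_norm <- wt_aggregate / totals
    fit <- row_ols(norm, g)
    wt_slope <- row_ols(matrix(wt_norm, nrow = 1L), g)$slope
    raw <- rep(NA_real_, n)
    if (wt_slope > 0) {
      pos <- fit$slope > 0
      raw[pos] <- log2(fit$slope[pos] / wt_slope)
    }
    r2 <- fit$r2
  }
  score <- pmax(raw, floor)
  score[is.na(raw) & !excluded & ncol(m) >= 2L & method == "slope-ratio"] <- floor
  score[excluded] <- NA_real_
  out <- data.frame(
    barcode = rownames(m),
    score = score,
    raw_score = raw,
    r2 = r2,
    c0 = c0,
    excluded = excluded,
    reason = reason,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("score_table", "data.frame")
  attr(out, "generations") <- g
  attr(out, "method") <- method
  attr(out, "floor") <- floor
  out
}

#' Score one experiment end to end
#'
#' Convenience wrapper: builds the WT reference from the allele map and
#' scores every barcode of the count matrix.
#'
#' @inheritParams score_barcodes
#' @param allele_map A `barcode_map`.
#' @param ... Passed to [score_barcodes()].
#' @return A `score_table`.
#' @export
score_experiment <- function(counts, allele_map, ...) {
  wt <- wt_reference(counts, allele_map)
  score_barcodes(counts, wt, ...)
}

#' Read or write a score table as TSV
#'
#' @param scores A `score_table`.
#' @param path File path.
#' @export
write_score_table <- function(scores, path) {
  write_tsv(as.data.frame(scores), path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  out <- read_tsv(path)
  out$excluded <- as.logical(out$excluded)
  class(out) <- c("score_table", "data.frame")
  out
}
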