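#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef lm mad median quantile rbinom rmultinom rnbinom
#'   rnorm runif sd setNames t.test prcomp
#' @importFrom graphics hist
#' @importFrom utils read.delim write.table packageVersion
NULL

# Convert a vector of equal-length sequences to an integer matrix
# (one row per sequence, one column per position). Fast path for
# Hamming arithmetic on fixed-length barcodes and ORFs.
seq_matrix <- function(x, width = NULL) {
  if (length(x) == 0L) {
    return(matrix(integer(0), nrow = 0L, ncol = if (is.null(width)) 0L else width))
  }
  w <- unique(nchar(x))
  if (length(w) != 1L) stop("sequences must share a common length")
  if (!is.null(width) && w != width) {
    stop(sprintf("sequences have length %d, expected %d", w, width))
  }
  matrix(utf8ToInt(paste(x, collapse = "")), ncol = w, byrow = TRUE)
}

#' Hamming distance between equal-length sequences
#'
#' Counts positions at which two strings differ. Vectorised with the usual
#' recycling rules; both arguments must contain strings of one common length.
#'
#' @param a,b Character vectors of equal-length sequences.
#' @return Integer vector of pairwise distances.
#' @examples
#' hamming_dist("CGTGAT", "ACATCG")
#' @export
hamming_dist <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n)
  b <- rep_len(b, n)
  if (n == 0L) return(integer(0))
  if (length(unique(nchar(c(a, b)))) != 1L) {
    stop("Hamming distance requires equal-length sequences")
  }
  ma <- seq_matrix(a)
  mb <- seq_matrix(b)
  as.integer(rowSums(ma != mb))
}

# Distances from every row of obs_mat to every row of known_mat, computed
# position-wise in chunks to bound memory. Returns for each observation the
# minimum distance, its argmin, and whether the minimum is tied.
nearest_hamming <- function(obs_mat, known_mat, chunk = 2000L) {
  n_obs <- nrow(obs_mat)
  out_min <- integer(n_obs)
  out_idx <- integer(n_obs)
  out_tie <- logical(n_obs)
  if (n_obs == 0L) {
    return(list(min = out_min, idx = out_idx, tie = out_tie))
  }
  w <- ncol(obs_mat)
  n_known <- nrow(known_mat)
  for (start in seq(1L, n_obs, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_obs)
    d <- matrix(0L, nrow = length(idx), ncol = n_known)
    for (k in seq_len(w)) {
      d <- d + outer(obs_mat[idx, k], known_mat[, k], "!=")
    }
    mins <- apply(d, 1L, min)
    out_min[idx] <- mins
    out_idx[idx] <- max.col(-d, ties.method = "first")
    out_tie[idx] <- rowSums(d == mins) > 1L
  }
  list(min = out_min, idx = out_idx, tie = out_tie)
}

# Mean Phred quality (Sanger, Phred+33) of a vector of quality strings.
mean_phred <- function(qual) {
  if (length(qual) == 0L) return(numeric(0))
  m <- seq_matrix(qual)
  rowMeans(m - 33)
}

random_dna <- function(n, width) {
  if (n == 0L) return(character(0))
  bases <- c("A", "C", "G", "T")
  m <- matrix(sample(bases, n * width, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Inject substitution sequencing errors
#'
#' Replaces each base independently with probability `eps` by one of the
#' three other bases, preserving read length. The simulator's error model
#' for subassembly and competition reads.
#'
#' @param seqs Character vector of equal-length DNA sequences.
#' @param eps Per-base substitution probability in `[0, 1)`.
#' @return The sequences with errors applied.
#' @export
inject_errors <- function(seqs, eps) {
  stopifnot(eps >= 0, eps < 1)
  if (eps == 0 || length(seqs) == 0L) return(seqs)
  m <- seq_matrix(seqs)
  hit <- which(runif(length(m)) < eps)
  if (length(hit) > 0L) {
    bases <- utf8ToInt("ACGT")
    for (b in bases) {
      sel <- hit[m[hit] == b]
      if (length(sel) > 0L) {
        m[sel] <- sample(setdiff(bases, b), length(sel), replace = TRUE)
      }
    }
  }
  apply(m, 1L, intToUtf8, multiple = FALSE)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, stringsAsFactors = FALSE, ...)
}
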