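# Robust outlier removal among barcodes of the same codon (or amino-acid)
# group: a barcode is flagged when its score lies beyond the Tukey fence,
# `fence` IQRs outside the group quartiles.

#' Flag outlier barcodes within codon groups
#'
#' Scored barcodes are grouped by (position, mutant codon) (or by
#' (position, amino acid) with `level = "aa"`; WT-flagged barcodes form one
#' group). Groups smaller than `min_group` pass through untouched. In
#' larger groups a barcode is flagged dirty when its score lies at least
#' `fence * IQR` outside the group quartiles (the Tukey fence; quartiles
#' use linear interpolation); the rule is suppressed when the IQR is zero,
#' so ties never flag a whole group. The per-group median absolute
#' deviation is also reported, and `criterion = "mad"` switches the fence
#' to `|score - median| >= mad_k * MAD`.
#'
#' @param score_table A `score_table`; only non-excluded barcodes with
#'   defined scores are partitioned.
#' @param allele_map A `barcode_map`; every scored barcode must appear.
#' @param level `"codon"` or `"aa"` grouping.
#' @param min_group Minimum group size for flagging (default 4).
#' @param fence IQR multiplier (default 1.5).
#' @param criterion `"iqr"` (default) or `"mad"`.
#' @param mad_k MAD multiplier for `criterion = "mad"` (default 3).
#' @return An `outlier_partition`: list with `clean` and `dirty` data
#'   frames (`position`, `codon`, `barcode`, `score`) and `group_stats`
#'   (`position`, `codon`, `n`, `median`, `iqr`, `mad`, `n_dirty`).
#' @export
flag_outliers <- function(score_table, allele_map, level = c("codon", "aa"),
                          min_group = 4L, fence = 1.5,
                          criterion = c("iqr", "mad"), mad_k = 3) {
  level <- match.arg(level)
  criterion <- match.arg(criterion)
  stopifnot(fence > 0, mad_k > 0)
  scored <- score_table[!score_table$excluded & !is.na(score_table$score), ,
                        drop = FALSE]
  hit <- match(scored$barcode, allele_map$barcode)
  if (anyNA(hit)) {
    stop("score table contains barcodes absent from the allele map: ",
         scored$barcode[which(is.na(hit))[1L]])
  }
  codon <- if (level == "codon") allele_map$mutant_codon[hit] else allele_map$aa[hit]
  codon[allele_map$is_wt[hit]] <- "WT"
  position <- allele_map$position[hit]
  position[allele_map$is_wt[hit]] <- 0L
  df <- data.frame(position = position, codon = codon,
                   barcode = scored$barcode, score = scored$score,
                   stringsAsFactors = FALSE)
  key <- paste(df$position, df$codon)
  groups <- split(seq_len(nrow(df)), key)

  dirty_flag <- rep(FALSE, nrow(df))
  stats_rows <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    idx <- groups[[i]]
    s <- df$score[idx]
    med <- median(s)
    iqr <- unname(diff(quantile(s, c(0.25, 0.75), type = 7)))
    grp_mad <- mad(s)
    flag <- rep(FALSE, length(idx))
    if (length(idx) >= min_group) {
      if (criterion == "iqr") {
        q <- quantile(s, c(0.25, 0.75), type = 7)
        if (iqr > 0) {
          flag <- s <= q[[1L]] - fence * iqr | s >= q[[2L]] + fence * iqr
        }
      } else {
        if (grp_mad > 0) flag <- abs(s - med) >= mad_k * grp_mad
      }
    }
    dirty_flag[idx] <- flag
    stats_rows[[i]] <- data.frame(
      position = df$position[idx[1L]], codon = df$codon[idx[1L]],
      n = length(idx), median = med, iqr = iqr, mad = grp_mad,
      n_dirty = sum(flag), stringsAsFactors = FALSE
    )
  }
  group_stats <- do.call(rbind, stats_rows)
  ord <- order(group_stats$position, group_stats$codon)
  structure(
    list(clean = df[!dirty_flag, , drop = FALSE],
         dirty = df[dirty_flag, , drop = FALSE],
         group_stats = group_stats[ord, , drop = FALSE]),
    class = "outlier_partition"
  )
}

#' Remove flagged barcodes from a score table
#'
#' @param score_table The `score_table` the partition was built from.
#' @param partition An `outlier_partition` from [flag_outliers()].
#' @return The score table restricted to clean (or unscored) barcodes.
#' @export
apply_filter <- function(score_table, partition) {
  stopifnot(inherits(partition, "outlier_partition"))
  out <- score_table[!(score_table$barcode %in% partition$dirty$barcode), ,
                     drop = FALSE]
  if (nrow(partition$dirty) > 0L && nrow(partition$clean) == 0L) {
    warning("all scored barcodes flagged dirty")
  }
  rownames(out) <- NULL
  out
}
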