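# Comparison of fitness between predicted-destabilizing and
# neutral/stabilizing mutation classes, given an externally computed
# per-mutant stability-change (ddG) table in Rosetta Energy Units.

#' Read a ddG table
#'
#' Expects a TSV with columns `mutant` (e.g. `"T7A"`) and `reu` (stability
#' change in Rosetta Energy Units); any extra columns are preserved.
#'
#' @param path Path to the TSV.
#' @return Data frame with at least `mutant` and `reu`.
#' @export
read_ddg_table <- function(path) {
  df <- read_tsv(path)
  if (!all(c("mutant", "reu") %in% names(df))) {
    stop("ddG table needs columns 'mutant' and 'reu'")
  }
  if (anyDuplicated(df$mutant)) stop("duplicate mutants in ddG table")
  if (any(!is.finite(df$reu))) stop("non-finite ddG values")
  df
}

#' Classify mutations by predicted stability change
#'
#' A mutation is labelled destabilizing when its stability change is at
#' least `threshold` REU, and neutral/stabilizing otherwise.
#'
#' @param ddg Data frame with `mutant` and `reu` (see [read_ddg_table()]).
#' @param threshold REU threshold (default 1.0).
#' @return The input with an added factor column `class` (levels
#'   `"destabilizing"`, `"neutral_stabilizing"`).
#' @export
classify_ddg <- function(ddg, threshold = 1.0) {
  stopifnot(is.finite(threshold))
  ddg$class <- factor(
    ifelse(ddg$reu >= threshold, "destabilizing", "neutral_stabilizing"),
    levels = c("destabilizing", "neutral_stabilizing")
  )
  ddg
}

#' Compare fitness between stability classes
#'
#' Two-sample two-sided t-test (Welch by default; `pooled = TRUE` for the
#' equal-variance form) of unmasked amino-acid fitness values between the
#' predicted-destabilizing and neutral/stabilizing classes. Mutants without
#' a ddG prediction are excluded and counted.
#'
#' @param fm A `fitness_matrix` (or a named list of them, one per
#'   condition).
#' @param labels Classified ddG table from [classify_ddg()].
#' @param pooled Use the pooled-variance t-test instead of Welch.
#' @return Data frame with one row per condition: class means and sizes,
#'   `t`, `p`, and `n_unlabelled`.
#' @export
compare_class_fitness <- function(fm, labels, pooled = FALSE) {
  if (inherits(fm, "fitness_matrix")) fm <- list(condition = fm)
  stopifnot(all(vapply(fm, inherits, logical(1), "fitness_matrix")),
            "class" %in% names(labels))
  rows <- lapply(names(fm), function(cond) {
    tab <- matrix_to_table(fm[[cond]])
    hit <- match(tab$mutant, labels$mutant)
    n_unlab <- sum(is.na(hit))
    tab <- tab[!is.na(hit), , drop = FALSE]
    cls <- labels$class[hit[!is.na(hit)]]
    destab <- tab$score[cls == "destabilizing"]
    neut <- tab$score[cls == "neutral_stabilizing"]
    if (length(destab) < 2L || length(neut) < 2L) {
      stop(sprintf("condition %s: each class needs at least 2 scores", cond))
    }
    if (sd(destab) == 0 && sd(neut) == 0) {
      # degenerate: both classes constant
      tt <- if (mean(destab) == mean(neut)) {
        list(statistic = c(t = 0), p.value = 1)
      } else {
        list(statistic = c(t = sign(mean(destab) - mean(neut)) * Inf),
             p.value = 0)
      }
    } else {
      tt <- t.test(destab, neut, var.equal = pooled)
    }
    data.frame(
      condition = cond,
      mean_destabilizing = mean(destab), mean_neutral = mean(neut),
      n_destabilizing = length(destab), n_neutral = length(neut),
      t = unname(tt$statistic), p = tt$p.value,
      n_unlabelled = n_unlab, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
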