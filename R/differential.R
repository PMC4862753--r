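# Cross-condition comparison of fitness landscapes: difference maps,
# identity-line residual distributions with Lorentzian fits, shared and
# perturbation-specific mutation calls, bin transitions and minimum-fitness
# maps.

#' Flatten a fitness matrix into a per-mutant table
#'
#' @param fm A `fitness_matrix`.
#' @param drop_masked Keep only cells with scores (default TRUE).
#' @return Data frame with `mutant` (e.g. `"T7A"`), `position`, `wt_aa`,
#'   `aa`, `score`, `error`, `n`.
#' @export
matrix_to_table <- function(fm, drop_masked = TRUE) {
  stopifnot(inherits(fm, "fitness_matrix"))
  grid <- expand.grid(aa = AA_ORDER, position = seq_along(fm$wt_aa),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(
    mutant = paste0(fm$wt_aa[grid$position], grid$position, grid$aa),
    position = grid$position,
    wt_aa = fm$wt_aa[grid$position],
    aa = grid$aa,
    score = as.vector(fm$score),
    error = as.vector(fm$error),
    n = as.vector(fm$n),
    stringsAsFactors = FALSE
  )
  if (drop_masked) out <- out[!is.na(out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Difference landscape between two conditions
#'
#' Cellwise `perturbation - reference` difference (sensitisation is
#' negative under this convention, which is printed in output headers);
#' masks are unioned.
#'
#' @param matrix_pert,matrix_ref `fitness_matrix` objects of equal shape.
#' @return A `delta_table`: list with `delta` (21 x 76 matrix) and
#'   `sign_convention`.
#' @export
delta_landscape <- function(matrix_pert, matrix_ref) {
  stopifnot(inherits(matrix_pert, "fitness_matrix"),
            inherits(matrix_ref, "fitness_matrix"))
  if (!identical(dim(matrix_pert$score), dim(matrix_ref$score))) {
    stop("fitness matrices differ in shape")
  }
  structure(
    list(delta = matrix_pert$score - matrix_ref$score,
         wt_aa = matrix_ref$wt_aa,
         sign_convention = "perturbation - reference"),
    class = "delta_table"
  )
}

#' Residuals to the identity line between two landscapes
#'
#' Per shared unmasked cell, the residual `b - a`, plus a histogram on
#' bins centred symmetrically around zero.
#'
#' @param matrix_a,matrix_b `fitness_matrix` objects of equal shape.
#' @param bin_width Histogram bin width (default 0.01).
#' @param range Symmetric histogram half-range (default 1.5, i.e. bins
#'   span about [-1.5, 1.5]); residuals outside it enter the residual
#'   vector but not the histogram.
#' @return List with `residuals`, `mids`, `counts`, `bin_width`.
#' @export
residual_distribution <- function(matrix_a, matrix_b, bin_width = 0.01,
                                  range = 1.5) {
  stopifnot(inherits(matrix_a, "fitness_matrix"),
            inherits(matrix_b, "fitness_matrix"))
  if (!identical(dim(matrix_a$score), dim(matrix_b$score))) {
    stop("fitness matrices differ in shape")
  }
  shared <- !is.na(matrix_a$score) & !is.na(matrix_b$score)
  if (sum(shared) < 10L) stop("fewer than 10 shared unmasked cells")
  r <- matrix_b$score[shared] - matrix_a$score[shared]
  hist <- symmetric_histogram(r, bin_width, range)
  list(residuals = r, mids = hist$mids, counts = hist$counts,
       bin_width = bin_width)
}

# Histogram with bin centres at integer multiples of bin_width (zero is a
# bin centre).
symmetric_histogram <- function(x, bin_width, range) {
  k <- ceiling(range / bin_width)
  breaks <- (seq(-k, k) + 0.5) * bin_width
  breaks <- c(-(k + 0.5) * bin_width, breaks)
  x <- x[x >= breaks[1L] & x <= breaks[length(breaks)]]
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  list(mids = h$mids, counts = h$counts)
}

#' Fit a Lorentzian to a residual distribution
#'
#' Least-squares fit of the peak-height form
#' `A * Gamma^2 / (Gamma^2 + (x - X0)^2)` to histogram bin counts,
#' initialised from the peak bin and the half-width at half-maximum.
#' Degenerate input (residuals with essentially no spread, e.g. a
#' self-comparison) yields a flagged zero-width result instead of an
#' error; non-convergence is flagged with the best iterate's parameters.
#'
#' @param residuals Numeric vector (at least 50 values).
#' @param bin_width Histogram bin width (default 0.001; use a width that
#'   resolves the expected peak).
#' @param range Symmetric histogram half-range; default covers the central
#'   99% of the residuals.
#' @return A `lorentzian_fit`: list with `x0`, `gamma`, `amplitude`,
#'   `bin_width`, `converged`, `degenerate`, `resid_norm`.
#' @export
fit_lorentzian <- function(residuals, bin_width = 0.001, range = NULL) {
  if (length(residuals) < 50L) stop("need at least 50 residuals")
  med <- median(residuals)
  if (is.null(range)) {
    range <- max(quantile(abs(residuals - med), 0.99), 5 * bin_width)
  }
  if (stats::IQR(residuals) < .Machine$double.eps^0.5) {
    return(structure(
      list(x0 = med, gamma = 0, amplitude = Inf, bin_width = bin_width,
           converged = FALSE, degenerate = TRUE, resid_norm = NA_real_),
      class = "lorentzian_fit"
    ))
  }
  h <- symmetric_histogram(residuals - med, bin_width, range)
  x <- h$mids + med
  y <- h$counts
  a0 <- max(y)
  x0_0 <- x[which.max(y)]
  hwhm <- sum(y > a0 / 2) * bin_width / 2
  g0 <- max(hwhm, bin_width / 2)
  resid_fun <- function(p) {
    y - p[["A"]] * p[["g"]]^2 / (p[["g"]]^2 + (x - p[["x0"]])^2)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = list(A = a0, g = g0, x0 = x0_0),
      lower = c(A = .Machine$double.eps, g = .Machine$double.eps, x0 = -Inf),
      fn = resid_fun,
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(structure(
      list(x0 = x0_0, gamma = g0, amplitude = a0, bin_width = bin_width,
           converged = FALSE, degenerate = FALSE,
           resid_norm = NA_real_),
      class = "lorentzian_fit"
    ))
  }
  p <- coef(fit)
  structure(
    list(x0 = unname(p["x0"]), gamma = abs(unname(p["g"])),
         amplitude = unname(p["A"]), bin_width = bin_width,
         converged = fit$info %in% 1:3,
         degenerate = FALSE,
         resid_norm = sqrt(fit$deviance)),
    class = "lorentzian_fit"
  )
}

#' @export
print.lorentzian_fit <- function(x, ...) {
  cat(sprintf("Lorentzian fit: X0 = %.4g, Gamma = %.4g, A = %.4g%s\n",
              x$x0, x$gamma, x$amplitude,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Call shared and perturbation-specific mutations
#'
#' Over mutants unmasked in every perturbation's difference table, fits a
#' total-least-squares line (first principal axis through the centroid) in
#' the k-dimensional difference space and computes each mutant's Euclidean
#' distance to it. Shared sensitising mutations lie close to the line
#' (`distance < shared_dist`) with mean difference at most `shared_mean`;
#' perturbation-specific mutations lie far from it
#' (`distance > specific_dist`), the deviating perturbation being the one
#' with the largest absolute residual component.
#'
#' @param delta_tables Named list of at least 3 `delta_table` objects
#'   sharing one reference condition.
#' @param shared_dist Distance threshold for shared calls (default 0.1).
#' @param shared_mean Mean-difference ceiling for shared calls
#'   (default -0.2).
#' @param specific_dist Distance threshold for specific calls
#'   (default 0.35).
#' @return A `shared_specific_calls`: list with `table` (per-mutant
#'   differences, distance, mean, call, deviating perturbation), `line`
#'   (centroid and direction), and the thresholds.
#' @export
call_shared_specific <- function(delta_tables, shared_dist = 0.1,
                                 shared_mean = -0.2, specific_dist = 0.35) {
  stopifnot(length(delta_tables) >= 3L,
            all(vapply(delta_tables, inherits, logical(1), "delta_table")))
  perts <- names(delta_tables)
  if (is.null(perts)) perts <- paste0("pert", seq_along(delta_tables))
  wt_aa <- delta_tables[[1L]]$wt_aa
  deltas <- lapply(delta_tables, `[[`, "delta")
  shared_cells <- Reduce(`&`, lapply(deltas, function(m) !is.na(m)))
  if (sum(shared_cells) < 3L) stop("too few mutants shared across perturbations")
  grid <- expand.grid(aa = AA_ORDER, position = seq_along(wt_aa),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  keep <- as.vector(shared_cells)
  x <- do.call(cbind, lapply(deltas, as.vector))[keep, , drop = FALSE]
  colnames(x) <- perts
  mutant <- paste0(wt_aa[grid$position], grid$position, grid$aa)[keep]

  if (all(apply(x, 2L, sd) < .Machine$double.eps^0.5)) {
    stop("degenerate difference cloud: no variance to fit a line")
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  center <- pc$center
  direction <- pc$rotation[, 1L]
  centered <- sweep(x, 2L, center)
  proj <- centered %*% direction
  resid <- centered - proj %*% t(direction)
  distance <- sqrt(rowSums(resid^2))
  mean_delta <- rowMeans(x)
  call <- rep("neither", length(distance))
  call[distance < shared_dist & mean_delta <= shared_mean] <- "shared"
  call[distance > specific_dist] <- "specific"
  deviating <- perts[max.col(abs(resid), ties.method = "first")]
  deviating[call != "specific"] <- NA_character_
  tab <- data.frame(mutant = mutant, x, distance = distance,
                    mean_delta = mean_delta, call = call,
                    deviating = deviating, stringsAsFactors = FALSE,
                    check.names = FALSE)
  rownames(tab) <- NULL
  structure(
    list(table = tab, line = list(center = center, direction = direction),
         shared_dist = shared_dist, shared_mean = shared_mean,
         specific_dist = specific_dist),
    class = "shared_specific_calls"
  )
}

#' Position-bin transitions between two conditions
#'
#' Newly-X positions are those categorised X under the perturbation but
#' not under the reference (positions unbinned in either condition are
#' ignored).
#'
#' @param bins_ref,bins_pert Data frames from [bin_positions()] over the
#'   same positions.
#' @return List of integer position vectors: `newly_sensitive`,
#'   `newly_intermediate`, `newly_tolerant`.
#' @export
bin_transitions <- function(bins_ref, bins_pert) {
  stopifnot(identical(bins_ref$position, bins_pert$position))
  ok <- !is.na(bins_ref$bin) & !is.na(bins_pert$bin)
  newly <- function(level) {
    bins_pert$position[ok & bins_pert$bin == level & bins_ref$bin != level]
  }
  list(newly_sensitive = newly("sensitive"),
       newly_intermediate = newly("intermediate"),
       newly_tolerant = newly("tolerant"))
}

#' Overlap of transition sets across perturbations
#'
#' @param sets Named list of integer position vectors (one per
#'   perturbation).
#' @return List with `shared` (intersection), `union`, `n_shared`,
#'   `n_union`.
#' @export
transition_overlap <- function(sets) {
  shared <- Reduce(intersect, sets)
  all_pos <- Reduce(union, sets)
  list(shared = sort(shared), union = sort(all_pos),
       n_shared = length(shared), n_union = length(all_pos))
}

#' Per-position minimum fitness across perturbations
#'
#' Elementwise minimum of per-position average fitness over perturbations,
#' and its difference to the reference condition. Masks propagate: a
#' position is `NA` where every perturbation is masked (or, for the
#' difference, where the reference is).
#'
#' @param averages Named list of per-position average vectors (one per
#'   perturbation).
#' @param reference Per-position averages of the reference condition.
#' @return Data frame with `position`, `min_fitness`, `reference`,
#'   `difference` (`min - reference`).
#' @export
min_fitness_map <- function(averages, reference) {
  stopifnot(length(averages) >= 1L)
  stack <- do.call(cbind, averages)
  min_fit <- apply(stack, 1L, function(v) {
    if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE)
  })
  data.frame(position = seq_along(min_fit),
             min_fitness = min_fit,
             reference = unname(reference),
             difference = min_fit - unname(reference))
}
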