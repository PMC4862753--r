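# The simulator is first-class code: its invariants (variant validity,
# barcode uniqueness, error-injection calibration, the exponential
# frequency law) are what downstream oracle tests lean on.

test_that("mutant libraries respect the variant grid", {
  lib <- build_mutant_library(ub_wt_orf(), seed = 7)
  mut <- lib$mutants
  # every mutant codon differs from WT at its position and encodes its aa
  expect_true(all(mut$mutant_codon != lib$wt_codons[mut$position]))
  expect_identical(translate_codons(mut$mutant_codon), mut$aa)
  expect_true(all(mut$position >= 1 & mut$position <= 76))
  expect_false(anyDuplicated(paste(mut$position, mut$mutant_codon)) > 0)
  # no variant re-creates the WT amino acid
  expect_true(all(mut$aa != lib$wt_aa[mut$position]))
})

test_that("degenerate and full-coverage libraries behave", {
  empty <- build_mutant_library(ub_wt_orf(), n_variants = 0,
                                missing_fraction = 1, seed = 1)
  expect_identical(nrow(empty$mutants), 0L)
  full <- build_mutant_library(ub_wt_orf(), missing_fraction = 0, seed = 1)
  # 76 positions x 20 non-WT amino acids, all covered
  expect_identical(nrow(full$mutants), 76L * 20L)
  cover <- table(full$mutants$position)
  expect_true(all(cover == 20L))
  expect_error(build_mutant_library("ACGTNN"), "non-ACGT|multiple")
  expect_error(build_mutant_library(strrep("ACG", 10)), "228")
})

test_that("missing fraction is realised at ~2.5% across seeds", {
  absent <- vapply(1:100, function(s) {
    lib <- build_mutant_library(ub_wt_orf(), seed = s)
    1 - nrow(lib$mutants) / (76 * 20)
  }, numeric(1))
  expect_equal(mean(absent), 0.025, tolerance = 0.01)
})

test_that("barcode assignment is unique, WT-flagged and median-15", {
  lib <- build_mutant_library(ub_wt_orf(), n_variants = 600, seed = 11)
  truth <- assign_barcodes(lib, seed = 12)
  expect_false(anyDuplicated(truth$map$barcode) > 0)
  expect_identical(sum(truth$map$is_wt), 50L)
  expect_true(all(truth$map$s_true[truth$map$is_wt] == 0))
  expect_equal(median(truth$alleles$n_barcodes), 15)
  # barcodes of one allele share its coefficient when jitter is 0
  per_allele <- tapply(
    truth$map$s_true[!truth$map$is_wt],
    paste(truth$map$position[!truth$map$is_wt],
          truth$map$mutant_codon[!truth$map$is_wt]),
    function(v) diff(range(v))
  )
  expect_true(all(per_allele == 0))
  # stop variants sit at the -0.5 floor by default
  expect_true(all(truth$map$s_true[!is.na(truth$map$aa) &
                                     truth$map$aa == "*"] == -0.5))
})

test_that("barcode uniqueness holds over a large draw", {
  lib <- build_mutant_library(ub_wt_orf(), n_variants = 1000, seed = 3)
  truth <- assign_barcodes(
    lib, barcodes_per_allele = function(n) rep(100L, n), seed = 4
  )
  expect_identical(nrow(truth$map), 1000L * 100L + 50L)
  expect_identical(anyDuplicated(truth$map$barcode), 0L)
})

test_that("single-allele map has expected size", {
  lib <- build_mutant_library(ub_wt_orf(), n_variants = 1, seed = 5)
  truth <- assign_barcodes(lib, n_wt_barcodes = 2,
                           barcodes_per_allele = function(n) rep(1L, n),
                           seed = 6)
  expect_identical(nrow(truth$map), 3L)
  expect_identical(sum(!truth$map$is_wt), 1L)
})

test_that("subassembly reads encode alleles exactly when error-free", {
  truth <- tiny_truth(n_variants = 10, barcodes_per_allele = 1, seed = 20)
  sub <- simulate_subassembly_reads(truth, reads_per_barcode = 3,
                                    error_rate = 0, seed = 21)
  expect_identical(nrow(sub$read1), 3L * nrow(truth$map))
  expect_identical(sub$read1$id, sub$read2$id)
  expect_true(all(nchar(sub$read1$seq) == 30L))
  expect_true(all(nchar(sub$read2$seq) == 228L))
  # each read2 is the barcode's allele ORF verbatim
  bc <- substr(sub$read1$seq, 1, 18)
  hit <- match(bc, truth$map$barcode)
  expect_false(anyNA(hit))
  for (i in seq_len(nrow(sub$read2))) {
    pos <- truth$map$position[hit[i]]
    if (is.na(pos)) {
      expect_identical(sub$read2$seq[i], ub_wt_orf())
    } else {
      codon <- substr(sub$read2$seq[i], 3 * pos - 2, 3 * pos)
      expect_identical(codon, truth$map$mutant_codon[hit[i]])
    }
  }
  none <- simulate_subassembly_reads(truth, reads_per_barcode = 0, seed = 1)
  expect_identical(nrow(none$read1), 0L)
})

test_that("injected substitution errors hit at the configured rate", {
  truth <- tiny_truth(n_variants = 30, barcodes_per_allele = 2, seed = 30)
  clean <- simulate_subassembly_reads(truth, reads_per_barcode = 5,
                                      error_rate = 0, seed = 31)
  noisy <- simulate_subassembly_reads(truth, reads_per_barcode = 5,
                                      error_rate = 0.01, seed = 31)
  expect_identical(clean$read2$id, noisy$read2$id)  # ids untouched
  expect_true(all(nchar(noisy$read2$seq) == 228L))  # length conserved
  mm <- sum(hamming_dist(clean$read2$seq, noisy$read2$seq))
  n_bases <- sum(nchar(clean$read2$seq))
  expect_gt(n_bases, 1e4)
  expect_equal(mm / n_bases, 0.01, tolerance = 0.25)
})

test_that("competition counts follow the exponential frequency law", {
  # one deleterious barcode against WT, expectation only: the ratio to WT
  # halves per generation for s = -1
  lib <- build_mutant_library(ub_wt_orf(), n_variants = 1, seed = 40)
  truth <- assign_barcodes(lib, n_wt_barcodes = 1,
                           barcodes_per_allele = function(n) rep(1L, n),
                           s_true_fun = function(aa) rep(-1, length(aa)),
                           seed = 41)
  cfg <- sim_config(generations = c(0, 1, 2), depth = 1000)
  exp_counts <- expected_competition_counts(truth, cfg,
                                            init_weights = c(1, 1))
  i_mut <- which(!truth$map$is_wt)
  i_wt <- which(truth$map$is_wt)
  ratio <- exp_counts[i_mut, ] / exp_counts[i_wt, ]
  expect_equal(unname(ratio), 2^(-c(0, 1, 2)), tolerance = 1e-12)

  # all-neutral library: expected frequencies constant over time
  truth0 <- assign_barcodes(lib, n_wt_barcodes = 1,
                            barcodes_per_allele = function(n) rep(1L, n),
                            s_true_fun = function(aa) rep(0, length(aa)),
                            seed = 41)
  e0 <- expected_competition_counts(truth0, cfg, init_weights = c(3, 1))
  expect_true(all(abs(e0 - e0[, 1]) < 1e-9))
})

test_that("empirical log-ratio slopes converge to s_true at high depth", {
  truth <- tiny_truth(n_variants = 40, barcodes_per_allele = 2,
                      n_wt_barcodes = 20, seed = 50,
                      s_true_fun = function(aa) runif(length(aa), -0.5, 0.2))
  cfg <- sim_config(generations = c(0, 2.5, 5), depth = 1e6, seed = 51)
  counts <- simulate_competition_counts(truth, cfg)
  wt <- colSums(counts[truth$map$is_wt, ])
  g <- generations(counts)
  sel <- which(!truth$map$is_wt & truth$map$s_true >= -0.5)
  slopes <- vapply(sel, function(i) {
    y <- log2(counts[i, ] / wt)
    unname(coef(lm(y ~ g))[2])
  }, numeric(1))
  expect_true(all(abs(slopes - truth$map$s_true[sel]) < 0.02))
})

test_that("simulation is deterministic for a fixed seed", {
  truth_a <- tiny_truth(seed = 60)
  truth_b <- tiny_truth(seed = 60)
  expect_identical(truth_a$map, truth_b$map)
  sheet <- make_sample_sheet("DMSO", 1, c(0, 2.5, 5), seed = 61)
  cfg <- sim_config(depth = 5000, error_rate = 0.005, seed = 62)
  run_a <- simulate_competition_reads(truth_a, sheet, cfg)
  run_b <- simulate_competition_reads(truth_b, sheet, cfg)
  expect_identical(run_a$reads, run_b$reads)
  expect_identical(run_a$counts, run_b$counts)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(run_a$reads, f1)
  write_fastq(run_b$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("configuration validation rejects bad settings", {
  expect_error(sim_config(generations = c(5, 2.5, 0)), "increasing")
  expect_error(sim_config(generations = 0), "2 timepoints")
  expect_error(sim_config(depth = 0), "positive")
  expect_error(sim_config(error_rate = 0.3), "error_rate")
})
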