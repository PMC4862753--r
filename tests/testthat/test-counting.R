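# Demultiplexing and Hamming error-corrected counting, checked against
# naive brute-force oracles.

ts_indices <- function() read_index_table()

comp_read <- function(barcode, index, const = "GGCGCGCC",
                      qual = strrep("I", nchar(barcode) + nchar(const))) {
  read_df(paste0("r", seq_along(barcode)), paste0(barcode, const),
          qual = qual, comment = paste0("1:N:0:", index))
}

test_that("the packaged index trio is mutually separated beyond Hamming 2", {
  idx <- ts_indices()
  expect_identical(idx$sequence[idx$name == "TS1"], "CGTGAT")
  pairs <- combn(nrow(idx), 2)
  d <- hamming_dist(idx$sequence[pairs[1, ]], idx$sequence[pairs[2, ]])
  expect_true(all(d > 2))
  # loading a table violating the invariant fails
  bad <- data.frame(name = c("A", "B"), sequence = c("CGTGAT", "CGTGAA"))
  expect_error(validate_index_table(bad), "within Hamming")
})

test_that("index assignment follows the Hamming cutoff", {
  idx <- ts_indices()
  bc <- strrep("A", 18)
  reads <- comp_read(rep(bc, 3),
                     c("CGTGAT",   # exact TS1
                       "CGTGCC",   # Hamming 2 from TS1, >= 3 from others
                       "TTTTTT"))  # >= 3 from every index
  expect_identical(naive_hamming("CGTGAT", "CGTGCC"), 2L)
  expect_true(min(hamming_dist(rep("TTTTTT", 3), idx$sequence)) > 2)
  out <- demultiplex(reads, idx)
  expect_identical(length(out$observations$TS1), 2L)
  expect_identical(unname(out$stats["unassigned_index"]), 1L)
  expect_identical(unname(out$stats["assigned"]), 2L)
})

test_that("constant-region and quality filters discard reads", {
  idx <- ts_indices()
  bc <- strrep("A", 18)
  # 3 mismatches in the constant region -> discarded
  bad_const <- read_df("b", paste0(bc, "TTTGCGCC"),
                       comment = "1:N:0:CGTGAT")
  out <- demultiplex(bad_const, idx, const_cutoff = 2)
  expect_identical(unname(out$stats["failed_constant"]), 1L)
  # low barcode-region quality -> discarded
  lowq <- comp_read(bc, "CGTGAT",
                    qual = paste0(strrep("+", 18), strrep("I", 8)))  # Phred 10
  out2 <- demultiplex(lowq, idx, min_mean_quality = 20)
  expect_identical(unname(out2$stats["failed_quality"]), 1L)
  out3 <- demultiplex(lowq, idx, min_mean_quality = 5)
  expect_identical(unname(out3$stats["assigned"]), 1L)
})

test_that("demultiplexing conserves every read in exactly one tally", {
  truth <- tiny_truth(n_variants = 30, barcodes_per_allele = 2, seed = 100)
  sheet <- make_sample_sheet(c("DMSO", "HU"), 1, c(0, 2.5, 5), seed = 101)
  cfg <- sim_config(depth = 3000, error_rate = 0.01, seed = 102)
  run <- simulate_competition_reads(truth, sheet, cfg)
  idx <- unique(sheet[, c("index_name", "index_seq")])
  names(idx) <- c("name", "sequence")
  out <- suppressWarnings(demultiplex(run$reads, idx))
  s <- out$stats
  expect_identical(
    unname(s["assigned"] + s["unassigned_index"] + s["ambiguous_index"] +
             s["failed_constant"] + s["failed_quality"]),
    unname(s["total"]))
  expect_identical(unname(s["total"]), nrow(run$reads))
  expect_identical(sum(lengths(out$observations)),
                   unname(s["assigned"]))
})

test_that("fuzzy counting matches exact, corrects unique neighbours, drops ties", {
  map <- data.frame(
    barcode = c(strrep("A", 18), strrep("C", 18),
                paste0(strrep("A", 16), "CC")),
    position = c(1L, 2L, 3L), mutant_codon = c("TTT", "GGG", "CCC"),
    aa = c("F", "G", "P"), is_wt = FALSE, stringsAsFactors = FALSE
  )
  class(map) <- c("barcode_map", "data.frame")
  obs <- c(
    strrep("A", 18),                      # exact
    paste0(strrep("A", 17), "T"),         # Hamming 1 from barcode 1 only
    paste0(strrep("A", 16), "TG"),        # Hamming 2 from 1 AND 2 from 3 -> tie
    strrep("G", 18)                       # no neighbour within 2
  )
  d <- vapply(map$barcode, naive_hamming, integer(1), a = obs[3])
  expect_identical(sort(unname(d))[1:2], c(2L, 2L))
  out <- correct_and_count(obs, map, fuzzy_cutoff = 2)
  expect_identical(unname(out$counts[map$barcode[1]]), 2L)
  expect_identical(unname(out$stats["exact"]), 1L)
  expect_identical(unname(out$stats["corrected"]), 1L)
  expect_identical(unname(out$stats["ambiguous"]), 1L)
  expect_identical(unname(out$stats["no_match"]), 1L)
})

test_that("fuzzy assignment equals the exhaustive nearest-neighbour oracle", {
  set.seed(123)
  truth <- tiny_truth(n_variants = 180, barcodes_per_allele = 6,
                      n_wt_barcodes = 20, seed = 110)
  known <- truth$map$barcode   # ~1100 barcodes
  n_obs <- 10000
  base <- sample(known, n_obs, replace = TRUE)
  obs <- inject_errors(base, 0.02)
  out <- correct_and_count(obs, truth$map, fuzzy_cutoff = 2)

  # independent oracle: brute-force distance scan with tie discard
  oracle <- setNames(integer(length(known)), known)
  km <- do.call(rbind, strsplit(known, ""))
  for (o in unique(obs)) {
    d <- rowSums(km != matrix(strsplit(o, "")[[1]], nrow(km), 18, byrow = TRUE))
    dmin <- min(d)
    if (dmin <= 2 && sum(d == dmin) == 1) {
      oracle[which.min(d)] <- oracle[which.min(d)] + sum(obs == o)
    }
  }
  expect_identical(out$counts, oracle)
})

test_that("almost all reads with in-map barcodes are recovered at eps = 0.005", {
  set.seed(7)
  truth <- tiny_truth(n_variants = 100, barcodes_per_allele = 5, seed = 120)
  known <- truth$map$barcode
  base <- sample(known, 20000, replace = TRUE)
  obs <- inject_errors(base, 0.005)
  out <- correct_and_count(obs, truth$map, fuzzy_cutoff = 2)
  expect_gte(sum(out$counts) / length(obs), 0.999)
})

test_that("count merging is additive over runs", {
  a <- structure(list(TS1 = c(b1 = 2L, b2 = 1L)), class = "barcode_counts")
  b <- structure(list(TS1 = c(b1 = 3L), TS2 = c(b3 = 7L)),
                 class = "barcode_counts")
  m <- merge_counts(a, b)
  expect_identical(m$TS1[["b1"]], 5L)
  expect_identical(m$TS1[["b2"]], 1L)
  expect_identical(m$TS2[["b3"]], 7L)
  # merging k identical tables scales each count by k
  m3 <- merge_counts(a, a, a)
  expect_identical(m3$TS1, a$TS1 * 3L)
})

test_that("timecourse assembly orders columns and zero-fills", {
  sheet <- data.frame(
    sample = c("TS1", "TS2", "TS3"),
    index_name = c("TS1", "TS2", "TS3"),
    index_seq = c("CGTGAT", "ACATCG", "GCCTAA"),
    condition = "DMSO", replicate = 1L,
    timepoint = c(1L, 2L, 3L), generations = c(0, 2.5, 5),
    stringsAsFactors = FALSE
  )
  counts <- structure(
    list(TS2 = c(b1 = 5L), TS1 = c(b1 = 10L, b2 = 3L), TS3 = c(b1 = 2L)),
    class = "barcode_counts"
  )
  mats <- assemble_timecourse(counts, sheet)
  expect_identical(names(mats), "DMSO.1")
  m <- mats[[1]]
  expect_identical(dim(m), c(2L, 3L))
  expect_identical(generations(m), c(0, 2.5, 5))
  expect_identical(unname(m["b1", ]), c(10L, 5L, 2L))
  expect_identical(unname(m["b2", ]), c(3L, 0L, 0L))  # zero-filled
  # duplicate (condition, replicate, timepoint) is an error naming the dup
  sheet2 <- sheet
  sheet2$timepoint[2] <- 1L
  sheet2$generations[2] <- 0
  expect_error(assemble_timecourse(counts, sheet2), "duplicate.*DMSO 1 1")
})

test_that("counts from an error-free run equal the simulator draws", {
  truth <- tiny_truth(n_variants = 25, barcodes_per_allele = 2,
                      n_wt_barcodes = 5, seed = 130)
  sheet <- make_sample_sheet("DMSO", 1, c(0, 2.5, 5), seed = 131)
  cfg <- sim_config(depth = 5000, error_rate = 0, seed = 132)
  run <- simulate_competition_reads(truth, sheet, cfg)
  idx <- unique(sheet[, c("index_name", "index_seq")])
  names(idx) <- c("name", "sequence")
  demux <- demultiplex(run$reads, idx, min_mean_quality = 0)
  counts <- correct_and_count(demux$observations, truth$map)
  mats <- assemble_timecourse(counts, sheet)
  truth_m <- run$counts[["DMSO.1"]]
  m <- mats[["DMSO.1"]][rownames(truth_m), ]
  expect_identical(as.vector(unclass(m)), as.vector(unclass(truth_m)))
})
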