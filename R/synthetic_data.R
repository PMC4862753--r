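# Ground-truthed simulator for barcoded DMS experiments: single-codon
# mutant libraries over a 76-codon ORF, N18 barcode assignments with known
# per-barcode selection coefficients, paired-end subassembly reads, and
# multinomial count trajectories under exponential growth competition.

# Evaluate expr under a temporary RNG state seeded with `seed` (NULL leaves
# the global stream untouched).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Validates and bundles the knobs of a simulated competition experiment.
#'
#' @param generations Numeric vector of elapsed wild-type generations per
#'   timepoint, strictly increasing, at least two timepoints. Default
#'   `c(0, 2.5, 5)`: three samplings spaced 2-3 WT generations apart.
#' @param depth Sequencing depth (reads) per timepoint; must be positive.
#' @param error_rate Per-base substitution error rate, in `[0, 0.25)`.
#' @param seed Integer RNG seed or `NULL`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(generations = c(0, 2.5, 5), depth = 1e5,
                       error_rate = 0, seed = NULL) {
  if (length(generations) < 2L) stop("need at least 2 timepoints")
  if (any(diff(generations) <= 0)) stop("generations must be strictly increasing")
  if (depth <= 0) stop("depth must be positive")
  if (error_rate < 0 || error_rate >= 0.25) stop("error_rate must lie in [0, 0.25)")
  structure(
    list(generations = as.numeric(generations), depth = depth,
         error_rate = error_rate, seed = seed),
    class = "sim_config"
  )
}

#' Build a single-codon mutant library
#'
#' Samples amino-acid variants over the (positions x 20 non-WT amino acids
#' incl. stop) grid and assigns each a random codon encoding the target
#' amino acid. Every mutant codon necessarily differs from the WT codon at
#' its position, and no (position, codon) pair repeats.
#'
#' @param wt_orf WT DNA ORF; length must be a multiple of 3 (and exactly
#'   228 nt when `strict = TRUE`, matching a 76-codon ORF).
#' @param n_variants Number of amino-acid variants to include; defaults to
#'   `round((1 - missing_fraction) * n_cells)` where `n_cells` is the full
#'   grid size.
#' @param missing_fraction Fraction of possible amino-acid variants left out
#'   of the library (default 0.025, i.e. a 97.5%-complete library).
#' @param seed RNG seed.
#' @param strict Require a 228-nt ACGT ORF.
#' @return An object of class `allele_library`: list with `wt_orf`,
#'   `wt_codons`, `wt_aa`, and `mutants` (data frame: `position`,
#'   `mutant_codon`, `aa`).
#' @export
build_mutant_library <- function(wt_orf, n_variants = NULL,
                                 missing_fraction = 0.025, seed = NULL,
                                 strict = TRUE) {
  wt_orf <- toupper(wt_orf)
  if (grepl("[^ACGT]", wt_orf)) stop("wt_orf contains non-ACGT characters")
  if (nchar(wt_orf) %% 3L != 0L) stop("wt_orf length must be a multiple of 3")
  if (strict && nchar(wt_orf) != 228L) stop("wt_orf must be 228 nt in strict mode")
  wt_codons <- orf_codons(wt_orf)
  wt_aa <- translate_codons(wt_codons)
  n_pos <- length(wt_codons)

  grid <- expand.grid(position = seq_len(n_pos), aa = AA_ORDER,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[grid$aa != wt_aa[grid$position], ]
  n_cells <- nrow(grid)
  if (is.null(n_variants)) {
    if (missing_fraction < 0 || missing_fraction > 1) {
      stop("missing_fraction must lie in [0, 1]")
    }
    n_variants <- round((1 - missing_fraction) * n_cells)
  }
  if (n_variants > n_cells) stop("n_variants exceeds the variant grid")

  aa_codons <- split(names(Biostrings::GENETIC_CODE), unname(Biostrings::GENETIC_CODE))

  mutants <- with_seed(seed, {
    keep <- grid[sample.int(n_cells, n_variants), , drop = FALSE]
    if (nrow(keep) > 0L) {
      keep$mutant_codon <- vapply(seq_len(nrow(keep)), function(i) {
        cands <- setdiff(aa_codons[[keep$aa[i]]], wt_codons[keep$position[i]])
        if (length(cands) == 1L) cands else sample(cands, 1L)
      }, character(1))
    } else {
      keep$mutant_codon <- character(0)
    }
    keep
  })
  mutants <- mutants[order(mutants$position, mutants$mutant_codon),
                     c("position", "mutant_codon", "aa")]
  rownames(mutants) <- NULL
  structure(
    list(wt_orf = wt_orf, wt_codons = wt_codons, wt_aa = wt_aa,
         mutants = mutants, missing_fraction = 1 - n_variants / n_cells),
    class = "allele_library"
  )
}

# Default allele-level selection coefficients: stop variants sit at the
# -0.5 floor; missense variants are a tolerant/deleterious mixture.
default_s_true <- function(aa) {
  s <- ifelse(runif(length(aa)) < 0.7,
              pmin(0.2, pmax(-0.2, rnorm(length(aa), 0, 0.03))),
              runif(length(aa), -0.55, -0.05))
  s[aa == "*"] <- -0.5
  s
}

# Default barcodes-per-allele distribution: shifted negative binomial with
# sample median 15 over libraries of a few hundred alleles.
default_barcodes_per_allele <- function(n) 1L + rnbinom(n, mu = 14.8, size = 10)

generate_unique_barcodes <- function(n, width = 18L) {
  if (n > 4^width) stop("requested barcode count exceeds 4^width")
  bc <- unique(random_dna(n, width))
  while (length(bc) < n) {
    bc <- unique(c(bc, random_dna(n - length(bc), width)))
  }
  bc
}

#' Assign unique N18 barcodes to library alleles
#'
#' Draws a number of barcodes for each allele from a configurable
#' distribution (default: shifted negative binomial with sample median 15),
#' adds a set of WT-flagged barcodes, and attaches ground-truth selection
#' coefficients: stop variants at the -0.5 floor, WT at 0, and missense
#' variants from a tolerant/deleterious mixture (override via `s_true_fun`).
#'
#' @param library An `allele_library`.
#' @param n_wt_barcodes Number of WT-flagged barcodes (default 50).
#' @param barcode_length Barcode width in nt (default 18).
#' @param barcodes_per_allele Function `n -> integer vector` of per-allele
#'   barcode counts (positive).
#' @param s_true_fun Function mapping the allele amino-acid vector to true
#'   per-generation log2 selection coefficients.
#' @param barcode_jitter SD of barcode-level Gaussian jitter around the
#'   allele truth (default 0: barcodes of an allele share its coefficient).
#' @param seed RNG seed.
#' @return An object of class `barcode_truth`: list with `map` (data frame:
#'   `barcode`, `position`, `mutant_codon`, `aa`, `is_wt`, `s_true`),
#'   `alleles` (allele-level truth), and the `library`.
#' @export
assign_barcodes <- function(library, n_wt_barcodes = 50L, barcode_length = 18L,
                            barcodes_per_allele = default_barcodes_per_allele,
                            s_true_fun = default_s_true, barcode_jitter = 0,
                            seed = NULL) {
  stopifnot(inherits(library, "allele_library"), barcode_length >= 1L)
  mut <- library$mutants
  with_seed(seed, {
    k <- if (nrow(mut) > 0L) as.integer(barcodes_per_allele(nrow(mut))) else integer(0)
    if (any(k < 1L)) stop("barcodes_per_allele must yield positive integers")
    alleles <- mut
    alleles$s_true <- if (nrow(mut) > 0L) s_true_fun(mut$aa) else numeric(0)
    alleles$n_barcodes <- k

    n_total <- sum(k) + n_wt_barcodes
    barcodes <- generate_unique_barcodes(n_total, barcode_length)
    idx <- rep.int(seq_len(nrow(mut)), k)
    map <- data.frame(
      barcode = barcodes,
      position = c(alleles$position[idx], rep(NA_integer_, n_wt_barcodes)),
      mutant_codon = c(alleles$mutant_codon[idx], rep(NA_character_, n_wt_barcodes)),
      aa = c(alleles$aa[idx], rep(NA_character_, n_wt_barcodes)),
      is_wt = rep(c(FALSE, TRUE), c(length(idx), n_wt_barcodes)),
      s_true = c(alleles$s_true[idx], rep(0, n_wt_barcodes)),
      stringsAsFactors = FALSE
    )
    if (barcode_jitter > 0) {
      jit <- rnorm(sum(!map$is_wt), 0, barcode_jitter)
      map$s_true[!map$is_wt] <- map$s_true[!map$is_wt] + jit
    }
    structure(list(map = map, alleles = alleles, library = library),
              class = "barcode_truth")
  })
}

# Reconstruct the full mutant ORF for each row of a map-like data frame.
mutant_orfs <- function(truth, position, codon) {
  orf <- truth$library$wt_orf
  out <- rep(orf, length(position))
  mut <- !is.na(position)
  if (any(mut)) {
    starts <- 3L * position[mut] - 2L
    out[mut] <- paste0(
      substr(rep(orf, sum(mut)), 1L, starts - 1L),
      codon[mut],
      substring(rep(orf, sum(mut)), starts + 3L)
    )
  }
  out
}

#' Simulate paired-end subassembly reads
#'
#' Read 1 carries the 18-nt barcode followed by an 8-nt constant vector
#' region and filler up to 30 nt; read 2 carries the allele's full ORF.
#' Mates share read identifiers; substitution errors are injected at a flat
#' per-base rate; qualities are a flat Phred+33 value.
#'
#' @param truth A `barcode_truth`.
#' @param reads_per_barcode Non-negative integer (scalar, recycled) or a
#'   function `n -> integer vector`.
#' @param error_rate Per-base substitution error rate.
#' @param const_seq 8-nt constant vector sequence after the barcode.
#' @param filler Filler sequence padding read 1 to 30 nt.
#' @param phred Flat Phred quality value.
#' @param seed RNG seed.
#' @return List with data frames `read1` and `read2` (columns `id`, `seq`,
#'   `qual`).
#' @export
simulate_subassembly_reads <- function(truth, reads_per_barcode = 5L,
                                       error_rate = 0, const_seq = "GGCGCGCC",
                                       filler = "ACGT", phred = 37L,
                                       seed = NULL) {
  stopifnot(inherits(truth, "barcode_truth"))
  map <- truth$map
  with_seed(seed, {
    k <- if (is.function(reads_per_barcode)) {
      as.integer(reads_per_barcode(nrow(map)))
    } else {
      rep_len(as.integer(reads_per_barcode), nrow(map))
    }
    if (any(k < 0L)) stop("reads_per_barcode must be non-negative")
    idx <- rep.int(seq_len(nrow(map)), k)
    n <- length(idx)
    if (n == 0L) {
      empty <- data.frame(id = character(0), seq = character(0),
                          qual = character(0), stringsAsFactors = FALSE)
      return(list(read1 = empty, read2 = empty))
    }
    id <- sprintf("sub%07d", seq_len(n))
    r1 <- paste0(map$barcode[idx], const_seq, filler)
    r2 <- mutant_orfs(truth, map$position[idx], map$mutant_codon[idx])
    r1 <- inject_errors(r1, error_rate)
    r2 <- inject_errors(r2, error_rate)
    q1 <- strrep(intToUtf8(33L + phred), nchar(r1[1L]))
    q2 <- strrep(intToUtf8(33L + phred), nchar(r2[1L]))
    list(
      read1 = data.frame(id = id, seq = r1, qual = q1, stringsAsFactors = FALSE),
      read2 = data.frame(id = id, seq = r2, qual = q2, stringsAsFactors = FALSE)
    )
  })
}

#' Competition count trajectories
#'
#' Barcode frequencies follow exponential selection,
#' `f_b(g) = f_b(0) 2^(s_b g)` (renormalised), and observed counts at each
#' timepoint are a multinomial draw of the configured depth across all
#' barcodes. `expected_competition_counts()` returns the deterministic
#' expectation `depth * f_b(g)` instead of a draw.
#'
#' @param truth A `barcode_truth`.
#' @param config A `sim_config`.
#' @param init_weights Initial relative abundances per barcode (default:
#'   log-normal, sdlog 0.5).
#' @return A `count_matrix`: integer (or numeric, for expectations) matrix
#'   with one row per barcode and one ordered column per timepoint, with a
#'   `generations` attribute.
#' @export
simulate_competition_counts <- function(truth, config, init_weights = NULL) {
  stopifnot(inherits(truth, "barcode_truth"), inherits(config, "sim_config"))
  with_seed(config$seed, {
    freqs <- competition_frequencies(truth, config$generations, init_weights)
    counts <- apply(freqs, 2L, function(p) rmultinom(1L, config$depth, p))
    count_matrix(counts, config$generations, barcodes = truth$map$barcode)
  })
}

#' @rdname simulate_competition_counts
#' @export
expected_competition_counts <- function(truth, config, init_weights = NULL) {
  freqs <- competition_frequencies(truth, config$generations, init_weights)
  count_matrix(freqs * config$depth, config$generations,
               barcodes = truth$map$barcode)
}

competition_frequencies <- function(truth, generations, init_weights = NULL) {
  n <- nrow(truth$map)
  if (is.null(init_weights)) {
    init_weights <- exp(rnorm(n, 0, 0.5))
  }
  stopifnot(length(init_weights) == n, all(init_weights > 0))
  f <- outer(log2(init_weights), rep(1, length(generations))) +
    outer(truth$map$s_true, generations)
  f <- 2^sweep(f, 2L, apply(f, 2L, max))  # stabilised
  sweep(f, 2L, colSums(f), "/")
}

#' Simulate a multiplexed competition sequencing run
#'
#' For each (condition, replicate) in the sample sheet a count trajectory is
#' drawn with `simulate_competition_counts()`; each (sample, barcode) count
#' is then expanded into reads whose sequence is the barcode followed by the
#' constant vector region, with the sample's index carried in the header
#' comment (Illumina `1:N:0:<index>` convention). Substitution errors are
#' injected into barcode, constant region and index alike.
#'
#' @param truth A `barcode_truth`.
#' @param sample_sheet Data frame from [make_sample_sheet()].
#' @param config A `sim_config` (depth is per sample/timepoint).
#' @param const_seq Constant vector region following the barcode.
#' @param phred Flat Phred quality.
#' @return List with `reads` (data frame: `id`, `comment`, `seq`, `qual`,
#'   shuffled across samples) and `counts` (list of true `count_matrix`
#'   objects keyed `<condition>.<replicate>`).
#' @export
simulate_competition_reads <- function(truth, sample_sheet, config,
                                       const_seq = "GGCGCGCC", phred = 37L) {
  stopifnot(inherits(truth, "barcode_truth"), inherits(config, "sim_config"))
  validate_sample_sheet(sample_sheet)
  with_seed(config$seed, {
    experiments <- split(
      sample_sheet,
      paste(sample_sheet$condition, sample_sheet$replicate, sep = ".")
    )
    all_reads <- list()
    counts_out <- list()
    for (exp_name in names(experiments)) {
      sheet <- experiments[[exp_name]]
      sheet <- sheet[order(sheet$generations), ]
      if (!isTRUE(all.equal(sort(config$generations), sheet$generations))) {
        stop(sprintf("sample sheet generations for %s do not match config",
                     exp_name))
      }
      cfg <- config
      cfg$seed <- NULL  # already inside the seeded stream
      counts <- simulate_competition_counts(truth, cfg)
      counts_out[[exp_name]] <- counts
      for (j in seq_len(ncol(counts))) {
        n_reads <- counts[, j]
        idx <- rep.int(seq_len(nrow(counts)), n_reads)
        if (length(idx) == 0L) next
        seqs <- paste0(truth$map$barcode[idx], const_seq)
        seqs <- inject_errors(seqs, config$error_rate)
        index_obs <- inject_errors(rep(sheet$index_seq[j], length(idx)),
                                   config$error_rate)
        all_reads[[paste(exp_name, j)]] <- data.frame(
          id = paste0("cmp_", exp_name, "_t", j, "_", seq_along(idx)),
          comment = paste0("1:N:0:", index_obs),
          seq = seqs,
          qual = strrep(intToUtf8(33L + phred), nchar(seqs[1L])),
          stringsAsFactors = FALSE
        )
      }
    }
    reads <- do.call(rbind, all_reads)
    if (is.null(reads)) {
      reads <- data.frame(id = character(0), comment = character(0),
                          seq = character(0), qual = character(0),
                          stringsAsFactors = FALSE)
    } else {
      reads <- reads[sample.int(nrow(reads)), ]
      rownames(reads) <- NULL
    }
    list(reads = reads, counts = counts_out)
  })
}

#' Build a sample sheet for simulated competition runs
#'
#' Assigns one sample index per (condition, replicate, timepoint), drawing
#' index sequences from the supplied table (extended with random well-
#' separated 6-mers when more samples than indices are requested).
#'
#' @param conditions Character vector of condition names.
#' @param replicates Number of replicates per condition.
#' @param generations Timepoint generations (shared across experiments).
#' @param index_table Data frame (`name`, `sequence`) of sample indices;
#'   default: the packaged TruSeq-style trio extended as needed.
#' @param seed RNG seed for index extension.
#' @return Data frame with columns `sample`, `index_name`, `index_seq`,
#'   `condition`, `replicate`, `timepoint`, `generations`.
#' @export
make_sample_sheet <- function(conditions, replicates = 1L,
                              generations = c(0, 2.5, 5),
                              index_table = NULL, seed = NULL) {
  grid <- expand.grid(
    timepoint = seq_along(generations),
    replicate = seq_len(replicates),
    condition = conditions,
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  grid$generations <- generations[grid$timepoint]
  n <- nrow(grid)
  if (is.null(index_table)) index_table <- read_index_table()
  idx <- with_seed(seed, extend_index_table(index_table, n))
  grid$index_name <- idx$name[seq_len(n)]
  grid$index_seq <- idx$sequence[seq_len(n)]
  grid$sample <- grid$index_name
  grid[, c("sample", "index_name", "index_seq", "condition", "replicate",
           "timepoint", "generations")]
}

# Extend an index table with random 6-mers keeping all pairwise Hamming
# distances > 2.
extend_index_table <- function(index_table, n_needed, min_dist = 3L) {
  seqs <- index_table$sequence
  names_out <- index_table$name
  width <- unique(nchar(seqs))
  stopifnot(length(width) == 1L)
  tries <- 0L
  while (length(seqs) < n_needed) {
    cand <- random_dna(1L, width)
    if (all(hamming_dist(rep(cand, length(seqs)), seqs) >= min_dist)) {
      seqs <- c(seqs, cand)
      names_out <- c(names_out, sprintf("TS%d", length(seqs)))
    }
    tries <- tries + 1L
    if (tries > 1e5L) stop("could not extend index table")
  }
  data.frame(name = names_out, sequence = seqs, stringsAsFactors = FALSE)
}

#' Write the barcode truth map to TSV
#'
#' @param truth A `barcode_truth`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_truth_map <- function(truth, path) {
  write_tsv(truth$map, path)
}

#' Ground-truth amino-acid fitness matrix
#'
#' Arranges the simulator's allele-level selection coefficients into the
#' same 21 x 76 masked layout the pipeline estimates, for direct
#' comparison. Cells covered by several codons of one amino acid take the
#' codon mean.
#'
#' @param truth A `barcode_truth`.
#' @param floor Apply the reporting floor to the truth (default NULL: no
#'   flooring).
#' @return A `fitness_matrix` whose error matrix is NA and whose `n`
#'   counts codons per cell.
#' @export
truth_fitness_matrix <- function(truth, floor = NULL) {
  stopifnot(inherits(truth, "barcode_truth"))
  wt_aa <- truth$library$wt_aa
  alleles <- truth$alleles
  s <- alleles$s_true
  if (!is.null(floor)) s <- pmax(s, floor)
  score <- matrix(NA_real_, length(AA_ORDER), length(wt_aa))
  n <- matrix(0L, length(AA_ORDER), length(wt_aa))
  if (nrow(alleles) > 0L) {
    cell <- paste(match(alleles$aa, AA_ORDER), alleles$position)
    means <- tapply(s, cell, mean)
    ns <- tapply(s, cell, length)
    ij <- do.call(rbind, lapply(strsplit(names(means), " "), as.integer))
    score[ij] <- means
    n[ij] <- ns
  }
  fitness_matrix(score, matrix(NA_real_, nrow(score), ncol(score)), n, wt_aa)
}
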