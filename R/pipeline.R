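# End-to-end, sample-sheet-driven pipeline over plain-text artifacts:
# simulate -> subassemble -> count -> score -> filter -> aggregate ->
# compare (-> stability), with per-stage manifests for provenance and
# change-driven re-execution.

#' Pipeline configuration
#'
#' Bundles every tunable of an end-to-end synthetic run. Defaults follow
#' the packaged study design: a 97.5%-complete single-mutant library over
#' the 76-codon ubiquitin ORF, a median of 15 barcodes per substitution,
#' three timepoints at 0/2.5/5 WT generations, and the documented filter
#' and threshold settings.
#'
#' @param conditions Condition names; the first is the reference.
#' @param replicates Replicates per condition.
#' @param generations Timepoint generations.
#' @param depth Competition sequencing depth per sample.
#' @param error_rate Per-base substitution error rate (competition run).
#' @param n_variants,missing_fraction Library size controls.
#' @param reads_per_barcode,subassembly_error_rate Subassembly run
#'   controls.
#' @param n_wt_barcodes WT-flagged barcodes in the library.
#' @param seed Master RNG seed.
#' @param vector_seq Constant vector sequence after the barcode.
#' @param min_reads Subassembly consensus minimum reads per barcode.
#' @param max_mismatch Vector-sequence Hamming cutoff.
#' @param index_cutoff,const_cutoff,min_mean_quality,fuzzy_cutoff Counting
#'   cutoffs.
#' @param min_initial,floor,pseudocount,score_method Scoring controls.
#' @param min_group,fence Outlier-filter controls.
#' @param sensitive,tolerant Position-bin thresholds.
#' @param shared_dist,shared_mean,specific_dist Shared/specific call
#'   thresholds.
#' @param ddg_path Optional per-mutant ddG TSV enabling the stability
#'   stage.
#' @param ddg_threshold REU threshold for the stability classes.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(conditions = c("DMSO", "Caffeine"),
                            replicates = 1L,
                            generations = c(0, 2.5, 5),
                            depth = 2e4,
                            error_rate = 0.001,
                            n_variants = NULL,
                            missing_fraction = 0.025,
                            reads_per_barcode = 5L,
                            subassembly_error_rate = 0,
                            n_wt_barcodes = 50L,
                            seed = 1L,
                            vector_seq = "GGCGCGCC",
                            min_reads = 3L,
                            max_mismatch = 2L,
                            index_cutoff = 2L,
                            const_cutoff = 2L,
                            min_mean_quality = 20,
                            fuzzy_cutoff = 2L,
                            min_initial = 4L,
                            floor = -0.5,
                            pseudocount = 0.5,
                            score_method = "log-ratio",
                            min_group = 4L,
                            fence = 1.5,
                            sensitive = -0.35,
                            tolerant = -0.075,
                            shared_dist = 0.1,
                            shared_mean = -0.2,
                            specific_dist = 0.35,
                            ddg_path = NULL,
                            ddg_threshold = 1.0) {
  cfg <- as.list(environment())
  sim_config(generations, depth, error_rate, seed)  # validates shared knobs
  structure(cfg, class = "pipeline_config")
}

stage_manifest_path <- function(dir, stage) {
  file.path(dir, sprintf("%s.manifest.json", stage))
}

stage_signature <- function(inputs, params) {
  list(
    inputs = as.list(tools::md5sum(inputs)),
    params = params,
    package_version = as.character(packageVersion("bcfitness"))
  )
}

stage_up_to_date <- function(dir, stage, inputs, params, outputs) {
  mpath <- stage_manifest_path(dir, stage)
  if (!file.exists(mpath) || !all(file.exists(outputs))) return(FALSE)
  old <- tryCatch(jsonlite::read_json(mpath, simplifyVector = TRUE),
                  error = function(e) NULL)
  new <- jsonlite::toJSON(stage_signature(inputs, params), auto_unbox = TRUE,
                          digits = NA)
  identical(as.character(jsonlite::toJSON(old, auto_unbox = TRUE, digits = NA)),
            as.character(new))
}

write_stage_manifest <- function(dir, stage, inputs, params) {
  jsonlite::write_json(stage_signature(inputs, params),
                       stage_manifest_path(dir, stage),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the full pipeline on synthetic data
#'
#' Executes simulate, subassemble, count, score, filter, aggregate and
#' compare (plus stability when a ddG table is configured), writing every
#' stage's TSV outputs plus per-stage manifests (parameters, input
#' digests, package version) under `out_dir`. A stage is skipped when its
#' manifest matches the current inputs and its outputs exist.
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created if needed).
#' @param force Re-run every stage regardless of manifests.
#' @return Invisibly, a list of the principal file paths and in-memory
#'   results.
#' @export
run_pipeline <- function(config, out_dir, force = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    truth_map = file.path(out_dir, "truth_map.tsv"),
    sample_sheet = file.path(out_dir, "sample_sheet.tsv"),
    index_table = file.path(out_dir, "index_table.tsv"),
    sub_r1 = file.path(out_dir, "subassembly_R1.fastq"),
    sub_r2 = file.path(out_dir, "subassembly_R2.fastq"),
    run_fastq = file.path(out_dir, "competition_run.fastq"),
    map = file.path(out_dir, "barcode_map.tsv"),
    counts = file.path(out_dir, "sample_counts.tsv"),
    demux_report = file.path(out_dir, "demux_report.tsv")
  )
  params_all <- unclass(config)
  params_all$ddg_path <- if (is.null(config$ddg_path)) "" else config$ddg_path

  ## stage: simulate ---------------------------------------------------
  sim_params <- params_all[c("conditions", "replicates", "generations",
                             "depth", "error_rate", "n_variants",
                             "missing_fraction", "reads_per_barcode",
                             "subassembly_error_rate", "n_wt_barcodes",
                             "seed", "vector_seq")]
  sim_outputs <- unlist(paths[c("truth_map", "sample_sheet", "index_table",
                                "sub_r1", "sub_r2", "run_fastq")])
  if (force || !stage_up_to_date(out_dir, "simulate", character(0),
                                 sim_params, sim_outputs)) {
    lib <- build_mutant_library(ub_wt_orf(), n_variants = config$n_variants,
                                missing_fraction = config$missing_fraction,
                                seed = config$seed)
    truth <- assign_barcodes(lib, n_wt_barcodes = config$n_wt_barcodes,
                             seed = config$seed + 1L)
    sheet <- make_sample_sheet(config$conditions, config$replicates,
                               config$generations, seed = config$seed + 2L)
    sub <- simulate_subassembly_reads(
      truth, reads_per_barcode = config$reads_per_barcode,
      error_rate = config$subassembly_error_rate,
      const_seq = config$vector_seq, seed = config$seed + 3L
    )
    cmp <- simulate_competition_reads(
      truth, sheet,
      sim_config(config$generations, config$depth, config$error_rate,
                 seed = config$seed + 4L),
      const_seq = config$vector_seq
    )
    write_truth_map(truth, paths$truth_map)
    write_tsv(sheet, paths$sample_sheet)
    write_tsv(unique(sheet[, c("index_name", "index_seq")]),
              paths$index_table)
    write_fastq(sub$read1, paths$sub_r1)
    write_fastq(sub$read2, paths$sub_r2)
    write_fastq(cmp$reads, paths$run_fastq)
    write_stage_manifest(out_dir, "simulate", character(0), sim_params)
  }

  ## stage: subassemble ------------------------------------------------
  sub_params <- params_all[c("vector_seq", "max_mismatch", "min_reads")]
  sub_inputs <- unlist(paths[c("sub_r1", "sub_r2")])
  if (force || !stage_up_to_date(out_dir, "subassemble", sub_inputs,
                                 sub_params, paths$map)) {
    map <- subassemble(read_fastq(paths$sub_r1), read_fastq(paths$sub_r2),
                       ub_wt_orf(), vector_seq = config$vector_seq,
                       max_mismatch = config$max_mismatch,
                       min_reads = config$min_reads)
    write_barcode_map(map, paths$map)
    write_stage_manifest(out_dir, "subassemble", sub_inputs, sub_params)
  }
  map <- read_barcode_map(paths$map)

  ## stage: count ------------------------------------------------------
  cnt_params <- params_all[c("index_cutoff", "const_cutoff",
                             "min_mean_quality", "fuzzy_cutoff",
                             "vector_seq")]
  cnt_inputs <- unlist(paths[c("run_fastq", "map", "sample_sheet",
                               "index_table")])
  if (force || !stage_up_to_date(out_dir, "count", cnt_inputs, cnt_params,
                                 c(paths$counts, paths$demux_report))) {
    reads <- read_fastq(paths$run_fastq)
    idx <- read_tsv(paths$index_table)
    names(idx) <- c("name", "sequence")
    demux <- demultiplex(reads, idx, index_cutoff = config$index_cutoff,
                         const_cutoff = config$const_cutoff,
                         min_mean_quality = config$min_mean_quality,
                         const_seq = config$vector_seq)
    counts <- correct_and_count(demux$observations, map,
                                fuzzy_cutoff = config$fuzzy_cutoff)
    long <- do.call(rbind, lapply(names(counts), function(s) {
      v <- counts[[s]]
      data.frame(sample = s, barcode = names(v), count = as.integer(v),
                 stringsAsFactors = FALSE)
    }))
    write_tsv(long[long$count > 0L, ], paths$counts)
    write_tsv(data.frame(metric = names(demux$stats),
                         value = as.integer(demux$stats)),
              paths$demux_report)
    write_stage_manifest(out_dir, "count", cnt_inputs, cnt_params)
  }

  ## remaining stages operate per experiment ---------------------------
  sheet <- read_tsv(paths$sample_sheet)
  long <- read_tsv(paths$counts)
  counts <- lapply(split(long, long$sample),
                   function(d) setNames(as.integer(d$count), d$barcode))
  class(counts) <- "barcode_counts"
  matrices <- assemble_timecourse(counts, sheet)

  exp_keys <- names(matrices)
  score_paths <- file.path(out_dir, sprintf("scores_%s.tsv", exp_keys))
  clean_paths <- file.path(out_dir, sprintf("scores_clean_%s.tsv", exp_keys))
  stats_paths <- file.path(out_dir, sprintf("outlier_stats_%s.tsv", exp_keys))
  names(score_paths) <- names(clean_paths) <- names(stats_paths) <- exp_keys

  score_params <- params_all[c("min_initial", "floor", "pseudocount",
                               "score_method", "min_group", "fence")]
  if (force || !stage_up_to_date(out_dir, "score",
                                 c(paths$counts, paths$map), score_params,
                                 c(score_paths, clean_paths, stats_paths))) {
    for (key in exp_keys) {
      scores <- score_experiment(matrices[[key]], map,
                                 method = config$score_method,
                                 min_initial = config$min_initial,
                                 floor = config$floor,
                                 pseudocount = config$pseudocount)
      part <- flag_outliers(scores, map, min_group = config$min_group,
                            fence = config$fence)
      clean <- apply_filter(scores, part)
      write_score_table(scores, score_paths[[key]])
      write_score_table(clean, clean_paths[[key]])
      write_tsv(part$group_stats, stats_paths[[key]])
    }
    write_stage_manifest(out_dir, "score", c(paths$counts, paths$map),
                         score_params)
  }

  ## aggregate ---------------------------------------------------------
  conds <- unique(sheet$condition)
  matrix_paths <- file.path(out_dir, sprintf("fitness_matrix_%s.tsv", conds))
  error_paths <- file.path(out_dir, sprintf("fitness_error_%s.tsv", conds))
  posavg_paths <- file.path(out_dir, sprintf("position_bins_%s.tsv", conds))
  names(matrix_paths) <- names(error_paths) <- names(posavg_paths) <- conds
  agg_params <- params_all[c("sensitive", "tolerant")]
  if (force || !stage_up_to_date(out_dir, "aggregate", clean_paths,
                                 agg_params,
                                 c(matrix_paths, error_paths, posavg_paths))) {
    for (cond in conds) {
      keys <- exp_keys[sub("\\.[^.]*$", "", exp_keys) == cond]
      mats <- lapply(keys, function(key) {
        aggregate_fitness(read_score_table(clean_paths[[key]]), map)
      })
      fm <- replicate_average(mats)
      write_fitness_matrix(fm, matrix_paths[[cond]], error_paths[[cond]])
      avg <- position_averages(fm)
      bins <- bin_positions(avg, config$sensitive, config$tolerant)
      bins$wt_aa <- fm$wt_aa
      write_tsv(bins, posavg_paths[[cond]])
    }
    write_stage_manifest(out_dir, "aggregate", clean_paths, agg_params)
  }

  ## compare -----------------------------------------------------------
  reference <- config$conditions[[1L]]
  perts <- setdiff(conds, reference)
  results <- list()
  if (length(perts) > 0L) {
    cmp_params <- params_all[c("shared_dist", "shared_mean", "specific_dist",
                               "sensitive", "tolerant")]
    delta_paths <- file.path(out_dir, sprintf("delta_%s.tsv", perts))
    names(delta_paths) <- perts
    fit_path <- file.path(out_dir, "lorentzian_fits.tsv")
    calls_path <- file.path(out_dir, "shared_specific_calls.tsv")
    trans_path <- file.path(out_dir, "bin_transitions.tsv")
    minfit_path <- file.path(out_dir, "min_fitness_map.tsv")
    cmp_outputs <- c(delta_paths, fit_path, trans_path, minfit_path,
                     if (length(perts) >= 3L) calls_path)
    if (force || !stage_up_to_date(out_dir, "compare", matrix_paths,
                                   cmp_params, cmp_outputs)) {
      fms <- lapply(conds, function(cond) {
        read_fitness_matrix(matrix_paths[[cond]], error_paths[[cond]])
      })
      names(fms) <- conds
      deltas <- list()
      fit_rows <- list()
      trans_rows <- list()
      for (p in perts) {
        dt <- delta_landscape(fms[[p]], fms[[reference]])
        deltas[[p]] <- dt
        tab <- data.frame(
          mutant = paste0(dt$wt_aa[col(dt$delta)], col(dt$delta),
                          AA_ORDER[row(dt$delta)]),
          delta = as.vector(dt$delta), stringsAsFactors = FALSE
        )
        tab <- tab[!is.na(tab$delta), ]
        con <- file(delta_paths[[p]], "w")
        writeLines(sprintf("# delta = %s fitness - %s fitness (%s)",
                           p, reference, dt$sign_convention), con)
        write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
        close(con)
        res <- residual_distribution(fms[[reference]], fms[[p]])
        fit <- fit_lorentzian(res$residuals, bin_width = 0.01)
        fit_rows[[p]] <- data.frame(
          comparison = sprintf("%s_vs_%s", p, reference),
          x0 = fit$x0, gamma = fit$gamma, amplitude = fit$amplitude,
          degenerate = fit$degenerate, stringsAsFactors = FALSE
        )
        bins_ref <- read_tsv(posavg_paths[[reference]])
        bins_p <- read_tsv(posavg_paths[[p]])
        bins_ref$bin <- factor(bins_ref$bin,
                               c("sensitive", "intermediate", "tolerant"))
        bins_p$bin <- factor(bins_p$bin,
                             c("sensitive", "intermediate", "tolerant"))
        tr <- bin_transitions(bins_ref, bins_p)
        trans_rows[[p]] <- data.frame(
          perturbation = p,
          transition = rep(names(tr), lengths(tr)),
          position = unlist(tr, use.names = FALSE),
          stringsAsFactors = FALSE
        )
      }
      write_tsv(do.call(rbind, fit_rows), fit_path)
      tr_all <- do.call(rbind, trans_rows)
      if (is.null(tr_all)) {
        tr_all <- data.frame(perturbation = character(0),
                             transition = character(0),
                             position = integer(0))
      }
      write_tsv(tr_all, trans_path)
      avgs <- lapply(perts, function(p) {
        b <- read_tsv(posavg_paths[[p]])
        setNames(b$avg, b$position)
      })
      names(avgs) <- perts
      ref_avg <- read_tsv(posavg_paths[[reference]])$avg
      write_tsv(min_fitness_map(avgs, ref_avg), minfit_path)
      if (length(perts) >= 3L) {
        calls <- call_shared_specific(deltas,
                                      shared_dist = config$shared_dist,
                                      shared_mean = config$shared_mean,
                                      specific_dist = config$specific_dist)
        con <- file(calls_path, "w")
        writeLines(sprintf("# delta sign convention: %s",
                           deltas[[1L]]$sign_convention), con)
        write.table(calls$table, con, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        close(con)
      }
      write_stage_manifest(out_dir, "compare", matrix_paths, cmp_params)
    }
  }

  ## stability ---------------------------------------------------------
  if (!is.null(config$ddg_path)) {
    stab_path <- file.path(out_dir, "stability_comparison.tsv")
    stab_params <- params_all["ddg_threshold"]
    if (force || !stage_up_to_date(out_dir, "stability",
                                   c(config$ddg_path, matrix_paths),
                                   stab_params, stab_path)) {
      labels <- classify_ddg(read_ddg_table(config$ddg_path),
                             config$ddg_threshold)
      fms <- lapply(conds, function(cond) {
        read_fitness_matrix(matrix_paths[[cond]], error_paths[[cond]])
      })
      names(fms) <- conds
      write_tsv(compare_class_fitness(fms, labels), stab_path)
      write_stage_manifest(out_dir, "stability",
                           c(config$ddg_path, matrix_paths), stab_params)
    }
  }

  ## run manifest ------------------------------------------------------
  outputs <- list.files(out_dir, pattern = "\\.tsv$|\\.fastq$",
                        full.names = TRUE)
  manifest <- list(
    package_version = as.character(packageVersion("bcfitness")),
    seed = config$seed,
    parameters = params_all,
    outputs = as.list(tools::md5sum(sort(outputs)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(out_dir = out_dir, map = map, matrices = matrices,
                 paths = paths))
}
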