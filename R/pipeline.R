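#' Pipeline configuration
#'
#' Collects the paths and parameters of an analysis run. All parameters are
#' validated here so a misconfigured run fails before any work is done.
#'
#' @param focal_fasta,spike_fasta Paths to the paired transcriptome FASTAs.
#' @param sample_sheet Path to the sample sheet CSV (must contain a `file`
#'   column with per-sample read paths, relative to the sheet's directory or
#'   absolute).
#' @param out_dir Output directory for result tables.
#' @param read_length Read/k-mer length (default 30).
#' @param reference_timepoint Reference condition label; defaults to the
#'   first timepoint in the sheet.
#' @param alpha Significance threshold for differential calls (default
#'   0.01).
#' @param pseudocount TPM pseudocount (default 1).
#' @param tpm_floor Expression floor in TPM (default 1).
#' @param verbose Print a per-sample summary line (unique focal reads,
#'   unique spike reads, ratio, factor).
#'
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(focal_fasta, spike_fasta, sample_sheet, out_dir,
                            read_length = 30L, reference_timepoint = NULL,
                            alpha = 0.01, pseudocount = 1, tpm_floor = 1,
                            verbose = TRUE) {
  for (p in c(focal_fasta, spike_fasta, sample_sheet)) {
    if (!file.exists(p)) abort(sprintf("Input path does not exist: %s", p))
  }
  read_length <- assert_count(read_length, "read_length")
  assert_scalar_number(alpha, "alpha", 0, 1)
  assert_scalar_number(pseudocount, "pseudocount", 0)
  assert_scalar_number(tpm_floor, "tpm_floor", 0)
  structure(
    list(
      focal_fasta = focal_fasta, spike_fasta = spike_fasta,
      sample_sheet = sample_sheet, out_dir = out_dir,
      read_length = read_length,
      reference_timepoint = reference_timepoint,
      alpha = alpha, pseudocount = pseudocount, tpm_floor = tpm_floor,
      verbose = verbose
    ),
    class = "pipeline_config"
  )
}

#' Simulate an experiment to disk
#'
#' Runs [sim_experiment()] and writes everything a pipeline run needs:
#' paired transcriptome FASTAs, one FASTQ per sample, a sample sheet CSV
#' with file paths, the full ground truth as JSON, and a manifest with MD5
#' checksums of every written file. Reruns with the same config are
#' byte-identical.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created; must be writable).
#' @return Invisibly, a list with the `sim_experiment` object, the sample
#'   sheet (with `file` column), and the manifest path.
#' @export
run_simulation <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  probe <- file.path(out_dir, ".write_test")
  ok <- tryCatch(
    {
      writeLines("x", probe)
      TRUE
    },
    error = function(e) FALSE,
    warning = function(e) FALSE
  )
  if (!ok) abort(sprintf("Output directory not writable: %s", out_dir))
  unlink(probe)

  ex <- sim_experiment(config)
  tx_paths <- write_transcriptomes(ex$transcriptomes, out_dir)
  sheet <- ex$sample_sheet |>
    mutate(file = paste0(.data$sample, ".fastq"))
  reads_split <- split(ex$reads, ex$reads$sample)
  for (s in sheet$sample) {
    write_reads_fastq(reads_split[[s]], file.path(out_dir, paste0(s, ".fastq")))
  }
  sheet_path <- file.path(out_dir, "samples.csv")
  write_sample_sheet(sheet, sheet_path)
  truth_path <- file.path(out_dir, "true_state.json")
  truth_to_json(ex$truth, truth_path)
  manifest_path <- write_manifest(
    c(tx_paths, file.path(out_dir, sheet$file), sheet_path, truth_path),
    file.path(out_dir, "manifest.json"),
    seed = config$seed
  )
  invisible(list(
    experiment = ex, sample_sheet = sheet, manifest = manifest_path
  ))
}

#' Run the full spike-in analysis pipeline
#'
#' Executes the stages in order: exact read assignment on the combined
#' two-species k-mer index, unique-read counting, TPM on coding sequences,
#' focal:spike ratios and scale factors (footprint assay), bulk translation
#' levels, the mRNA stability check, per-gene translational efficiency, and
#' differential translation between the reference and the last timepoint.
#' Every stage's table is written to `out_dir` as TSV, plus a manifest with
#' checksums. Identical inputs give byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_result` with all result tibbles
#'   (`factors`, `bulk_translation`, `mrna_stability`, `te`,
#'   `differential`, `counts`, `totals`) and the output paths.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be created with pipeline_config().")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  sheet <- read_sample_sheet(config$sample_sheet)
  if (!"file" %in% names(sheet)) {
    abort("Sample sheet needs a `file` column with per-sample read paths.")
  }
  sheet_dir <- dirname(config$sample_sheet)
  paths <- ifelse(
    file.exists(sheet$file), sheet$file, file.path(sheet_dir, sheet$file)
  )
  missing <- sheet$sample[!file.exists(paths)]
  if (length(missing) > 0L) {
    abort(sprintf(
      "Read file missing for sample(s): %s.", paste(missing, collapse = ", ")
    ))
  }
  ref <- config$reference_timepoint %||% sheet$timepoint[1]

  tx <- read_transcriptomes(config$focal_fasta, config$spike_fasta)
  index <- build_kmer_index(tx, read_length = config$read_length)

  stage <- function(name, sample, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf(
        "Pipeline stage '%s' failed for sample '%s': %s",
        name, sample, conditionMessage(e)
      ))
    })
  }
  assignments <- purrr::map2(sheet$sample, paths, function(s, p) {
    reads <- stage("read", s, read_reads(p))
    stage("assign", s, assign_reads(index, reads)) |>
      mutate(sample = s)
  }) |>
    purrr::list_rbind()

  cm <- count_reads(assignments, sheet)
  fp_totals <- cm$footprint$totals
  mr_totals <- cm$mrna$totals

  factors <- scale_factors(fp_totals, reference_timepoint = ref)
  if (isTRUE(config$verbose)) {
    for (i in seq_len(nrow(factors))) {
      message(sprintf(
        "sample %-24s unique focal %8d  unique spike %6d  ratio %8.3f  factor %6.3f",
        factors$sample[i], factors$focal_total[i], factors$spike_total[i],
        factors$ratio[i], factors$scale_factor[i]
      ))
    }
  }
  bulk <- bulk_translation(factors)
  stability <- mrna_stability_check(mr_totals, reference_timepoint = ref)

  lengths <- setNames(tx$length, tx$gene)
  sheet_tp <- sheet |> select("sample", "timepoint")
  fp_tpm <- compute_tpm(cm$footprint$counts, lengths) |>
    left_join(sheet_tp, by = "sample")
  mr_tpm <- compute_tpm(cm$mrna$counts, lengths) |>
    left_join(sheet_tp, by = "sample")

  te <- translational_efficiency(
    fp_tpm, mr_tpm, factors,
    pseudocount = config$pseudocount, tpm_floor = config$tpm_floor
  )

  # differential translation: last timepoint vs reference, on spike-adjusted
  # replicate-level footprint TPM
  tps <- unique(sheet$timepoint)
  last_tp <- tps[length(tps)]
  adj <- fp_tpm |>
    left_join(
      factors |> as_tibble() |> select("sample", "scale_factor"),
      by = "sample"
    ) |>
    mutate(value = .data$tpm * .data$scale_factor)
  fp_sheet <- sheet |> filter(.data$assay == "footprint")
  group_a <- fp_sheet$sample[fp_sheet$timepoint == ref]
  group_b <- fp_sheet$sample[fp_sheet$timepoint == last_tp]
  differential <- differential_translation(
    adj, group_a, group_b,
    alpha = config$alpha, pseudocount = config$pseudocount
  )

  out <- config$out_dir
  files <- c(
    counts = "counts.tsv", totals = "totals.tsv", factors = "factors.tsv",
    bulk = "bulk_translation.tsv", stability = "mrna_stability.tsv",
    te = "te.tsv", differential = "differential.tsv"
  )
  fp <- function(f) file.path(out, f)
  readr::write_tsv(
    bind_rows(footprint = cm$footprint$counts, mrna = cm$mrna$counts,
      .id = "assay"
    ),
    fp(files["counts"])
  )
  readr::write_tsv(
    bind_rows(footprint = fp_totals, mrna = mr_totals, .id = "assay"),
    fp(files["totals"])
  )
  readr::write_tsv(as_tibble(factors), fp(files["factors"]))
  readr::write_tsv(bulk, fp(files["bulk"]))
  readr::write_tsv(
    stability$conditions |>
      left_join(
        stability$tests |>
          rename(timepoint = "timepoint_a", vs = "timepoint_b"),
        by = "timepoint"
      ),
    fp(files["stability"])
  )
  readr::write_tsv(te, fp(files["te"]))
  readr::write_tsv(as_tibble(differential), fp(files["differential"]))
  manifest <- write_manifest(fp(files), file.path(out, "manifest.json"))

  structure(
    list(
      counts = cm, factors = factors, bulk_translation = bulk,
      mrna_stability = stability, footprint_tpm = fp_tpm, mrna_tpm = mr_tpm,
      te = te, differential = differential,
      reference_timepoint = ref, comparison = c(ref, last_tp),
      out_dir = out, manifest = manifest
    ),
    class = "pipeline_result"
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  reference timepoint: %s\n", x$reference_timepoint))
  cat("  bulk translation:\n")
  print(x$bulk_translation)
  cat(sprintf(
    "  differential (%s vs %s): %d up, %d down of %d genes\n",
    x$comparison[2], x$comparison[1],
    sum(x$differential$class == "up"), sum(x$differential$class == "down"),
    nrow(x$differential)
  ))
  cat(sprintf("  outputs in %s\n", x$out_dir))
  invisible(x)
}
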