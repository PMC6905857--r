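#' Transcripts per million over coding sequences
#'
#' Length-normalizes focal-species counts and rescales each sample to one
#' million: `tpm_g = 1e6 * (count_g / length_g) / sum_j (count_j / length_j)`.
#' Genes in `cds_lengths` absent from a sample's counts receive TPM 0, so
#' every sample covers the same gene universe.
#'
#' @param counts Tidy counts: tibble with `sample`, `gene`, `count`.
#' @param cds_lengths Named numeric vector of coding-sequence lengths (nt),
#'   or a tibble with `gene` and `length` columns; every counted gene must
#'   be present.
#'
#' @return Tibble (`sample`, `gene`, `count`, `tpm`), complete over the
#'   length table's gene universe for every sample.
#' @export
#'
#' @examples
#' counts <- tibble::tibble(
#'   sample = "s1", gene = c("a", "b"), count = c(10, 10)
#' )
#' compute_tpm(counts, c(a = 100, b = 200))
compute_tpm <- function(counts, cds_lengths) {
  if (is.data.frame(cds_lengths)) {
    cds_lengths <- setNames(cds_lengths$length, cds_lengths$gene)
  }
  if (any(cds_lengths <= 0)) {
    abort("All CDS lengths must be positive.")
  }
  missing <- setdiff(unique(counts$gene), names(cds_lengths))
  if (length(missing) > 0L) {
    abort(sprintf(
      "No CDS length for counted gene(s): %s.", paste(missing, collapse = ", ")
    ))
  }
  universe <- tidyr::expand_grid(
    sample = unique(counts$sample),
    gene = names(cds_lengths)
  )
  out <- universe |>
    left_join(counts |> select("sample", "gene", "count"),
      by = c("sample", "gene")
    ) |>
    mutate(
      count = tidyr::replace_na(.data$count, 0L),
      rate = .data$count / cds_lengths[.data$gene]
    ) |>
    group_by(.data$sample) |>
    mutate(
      denom = sum(.data$rate),
      tpm = ifelse(.data$denom > 0, 1e6 * .data$rate / .data$denom, 0)
    ) |>
    ungroup()
  zero <- out |>
    group_by(.data$sample) |>
    summarise(all_zero = all(.data$count == 0)) |>
    filter(.data$all_zero)
  if (nrow(zero) > 0L) {
    warn(sprintf(
      "Sample(s) with zero counts, TPM set to 0: %s.",
      paste(zero$sample, collapse = ", ")
    ))
  }
  out |> select("sample", "gene", "count", "tpm")
}

#' Focal-to-spike read ratio per sample
#'
#' The spike-in is a constant RNA mass per sample, so this ratio is
#' proportional to the absolute focal signal and carries between-sample
#' changes in bulk translation (footprint assay) or total mRNA (mRNA assay).
#'
#' @param totals Tibble with `sample`, `focal_total`, `spike_total` (as
#'   produced by [count_reads()]).
#' @return The input with a `ratio` column (`focal_total / spike_total`).
#' @export
spike_ratio <- function(totals) {
  if (any(totals$spike_total == 0)) {
    bad <- totals$sample[totals$spike_total == 0]
    abort(sprintf(
      "Zero spike reads (spike-in failed) in sample(s): %s.",
      paste(bad, collapse = ", ")
    ))
  }
  totals |> mutate(ratio = .data$focal_total / .data$spike_total)
}

#' Per-sample spike-in scale factors relative to a reference timepoint
#'
#' Each sample's focal:spike read ratio is divided by the arithmetic mean
#' ratio over the reference timepoint's replicates, yielding a scale factor
#' of 1 (on average) at the reference and, e.g., ~0.6 when bulk translation
#' has dropped to 60%. Adjusting footprint TPMs by these factors converts
#' within-sample relative abundances into between-sample absolute levels.
#'
#' @param totals Tibble with `sample`, `focal_total`, `spike_total`, and a
#'   `timepoint` column (join the sample sheet first if needed, or pass
#'   `sample_sheet`).
#' @param sample_sheet Optional tibble with `sample` and `timepoint`, joined
#'   onto `totals` when `totals` lacks a `timepoint` column.
#' @param reference_timepoint Label of the reference condition.
#'
#' @return An object of class `norm_factors`: per-sample tibble (`sample`,
#'   `timepoint`, `replicate` if present, `focal_total`, `spike_total`,
#'   `ratio`, `scale_factor`) with the reference label stored as an
#'   attribute.
#' @export
scale_factors <- function(totals, sample_sheet = NULL, reference_timepoint) {
  if (!"timepoint" %in% names(totals)) {
    if (is.null(sample_sheet)) {
      abort("Provide a `timepoint` column or a `sample_sheet`.")
    }
    totals <- totals |>
      left_join(sample_sheet |> select("sample", "timepoint"), by = "sample")
  }
  if (!reference_timepoint %in% totals$timepoint) {
    abort(sprintf(
      "Reference timepoint '%s' has no samples.", reference_timepoint
    ))
  }
  out <- spike_ratio(totals)
  ref_mean <- mean(out$ratio[out$timepoint == reference_timepoint])
  out <- out |> mutate(scale_factor = .data$ratio / ref_mean)
  structure(out,
    class = c("norm_factors", class(out)),
    reference_timepoint = reference_timepoint,
    reference_ratio = ref_mean
  )
}

#' Per-timepoint relative bulk translation
#'
#' Summarizes footprint-assay scale factors per timepoint: the mean factor is
#' the bulk translation level relative to the reference (1 at the reference;
#' e.g. 0.59 and 0.43 when translation has declined to 59% and 43%).
#'
#' @param factors A [scale_factors()] result computed from footprint totals.
#' @return Tibble (`timepoint`, `bulk_translation`, `sd`, `n_replicates`).
#' @export
bulk_translation <- function(factors) {
  factors |>
    as_tibble() |>
    group_by(.data$timepoint) |>
    summarise(
      bulk_translation = mean(.data$scale_factor),
      sd = sd(.data$scale_factor),
      n_replicates = n()
    )
}

#' Per-gene translational efficiency across conditions
#'
#' Footprint TPMs are first multiplied by their sample's spike-in scale
#' factor (absolute translation); mRNA TPMs stay unadjusted. Replicates are
#' then averaged per timepoint, and translational efficiency is the
#' pseudocount-stabilized ratio
#' `te = (adjusted footprint TPM + pseudocount) / (mRNA TPM + pseudocount)`.
#' Genes whose mRNA TPM stays below `tpm_floor` in every condition are
#' flagged unexpressed (`expressed = FALSE`) so TE summaries can exclude
#' them.
#'
#' @param footprint_tpm,mrna_tpm [compute_tpm()] outputs with a `timepoint`
#'   column (join the sample sheet first, or pass `sample_sheet`).
#' @param factors Footprint-assay [scale_factors()].
#' @param sample_sheet Optional (`sample`, `timepoint`) mapping joined onto
#'   either TPM table when it lacks `timepoint`.
#' @param pseudocount Non-negative TPM pseudocount (default 1).
#' @param tpm_floor Expression floor in mRNA TPM (default 1).
#'
#' @return Tibble (`gene`, `timepoint`, `fp_tpm`, `fp_tpm_adj`, `mrna_tpm`,
#'   `te`, `expressed`), one row per gene and condition.
#' @export
translational_efficiency <- function(footprint_tpm, mrna_tpm, factors,
                                     sample_sheet = NULL,
                                     pseudocount = 1, tpm_floor = 1) {
  assert_scalar_number(pseudocount, "pseudocount", 0)
  assert_scalar_number(tpm_floor, "tpm_floor", 0)
  add_tp <- function(tab) {
    if ("timepoint" %in% names(tab)) return(tab)
    if (is.null(sample_sheet)) {
      abort("TPM tables need a `timepoint` column or a `sample_sheet`.")
    }
    tab |> left_join(sample_sheet |> select("sample", "timepoint"), by = "sample")
  }
  fp <- add_tp(footprint_tpm) |>
    left_join(
      factors |> as_tibble() |> select("sample", "scale_factor"),
      by = "sample"
    ) |>
    mutate(tpm_adj = .data$tpm * .data$scale_factor) |>
    group_by(.data$gene, .data$timepoint) |>
    summarise(
      fp_tpm = mean(.data$tpm), fp_tpm_adj = mean(.data$tpm_adj),
      .groups = "drop"
    )
  mr <- add_tp(mrna_tpm) |>
    group_by(.data$gene, .data$timepoint) |>
    summarise(mrna_tpm = mean(.data$tpm), .groups = "drop")
  shared <- intersect(unique(fp$gene), unique(mr$gene))
  out <- fp |>
    inner_join(mr, by = c("gene", "timepoint")) |>
    filter(.data$gene %in% shared) |>
    mutate(te = (.data$fp_tpm_adj + pseudocount) / (.data$mrna_tpm + pseudocount))
  expressed <- out |>
    group_by(.data$gene) |>
    summarise(expressed = any(.data$mrna_tpm >= tpm_floor))
  out |>
    left_join(expressed, by = "gene") |>
    arrange(.data$gene, .data$timepoint)
}

#' Spike-normalized mRNA stability check across timepoints
#'
#' Computes per-sample spike-normalized total mRNA (focal:spike read ratio
#' relative to the mean reference ratio) and tests every pair of timepoints
#' with a two-sample Student t-test — the control that total mRNA does not
#' change while translation declines.
#'
#' @param totals mRNA-assay totals (`sample`, `timepoint`, `focal_total`,
#'   `spike_total`).
#' @param sample_sheet Optional (`sample`, `timepoint`) mapping.
#' @param reference_timepoint Reference condition label.
#' @param var_equal Pooled-variance Student t (default) or Welch.
#'
#' @return A list of class `mrna_stability`: `samples` (per-sample relative
#'   levels), `conditions` (per-timepoint mean, sd, n), `tests` (pairwise
#'   `timepoint_a`, `timepoint_b`, `p_value`). With fewer than 2 replicates
#'   in a condition the affected tests are `NA` with a warning.
#' @export
mrna_stability_check <- function(totals, sample_sheet = NULL,
                                 reference_timepoint, var_equal = TRUE) {
  fac <- scale_factors(totals, sample_sheet, reference_timepoint)
  samples <- fac |>
    as_tibble() |>
    mutate(relative_level = .data$scale_factor) |>
    select("sample", "timepoint", "focal_total", "spike_total",
      "ratio", "relative_level"
    )
  conditions <- samples |>
    group_by(.data$timepoint) |>
    summarise(
      mean_relative = mean(.data$relative_level),
      sd = sd(.data$relative_level),
      n_replicates = n()
    )
  tps <- unique(samples$timepoint)
  pairs <- utils::combn(tps, 2L)
  too_few <- conditions$timepoint[conditions$n_replicates < 2L]
  if (length(too_few) > 0L) {
    warn(sprintf(
      "Fewer than 2 replicates for %s; pairwise tests involving them are NA.",
      paste(too_few, collapse = ", ")
    ))
  }
  tests <- purrr::map2(pairs[1, ], pairs[2, ], function(a, b) {
    xa <- samples$relative_level[samples$timepoint == a]
    xb <- samples$relative_level[samples$timepoint == b]
    p <- if (length(xa) < 2L || length(xb) < 2L) {
      NA_real_
    } else {
      # constant data make the t statistic 0/0; report NA rather than fail
      tryCatch(
        t.test(xa, xb, var.equal = var_equal)$p.value,
        error = function(e) NA_real_
      )
    }
    tibble(timepoint_a = a, timepoint_b = b, p_value = p)
  }) |>
    purrr::list_rbind()
  structure(
    list(samples = samples, conditions = conditions, tests = tests),
    class = "mrna_stability"
  )
}

#' @export
print.mrna_stability <- function(x, ...) {
  cat("<mrna_stability> spike-normalized total mRNA per timepoint\n")
  print(x$conditions)
  cat("pairwise Student t-tests:\n")
  print(x$tests)
  invisible(x)
}
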