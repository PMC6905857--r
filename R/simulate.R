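#' Simulation configuration for a two-species spike-in experiment
#'
#' Bundles and validates every parameter of the synthetic experiment: the
#' ortholog transcriptomes, the per-timepoint bulk translation factors, the
#' spike-in read mass fraction, and the sequencing depth. The defaults mirror
#' the study design the package targets: stage 14 oocytes sampled in
#' triplicate at three storage timepoints, 30-nt footprints, a spike-in
#' amounting to 2% of read mass in the reference sample (1.6 ug foreign
#' lysate against 80 ug focal RNA), and bulk translation declining to 59.5%
#' and 42.7% of the reference level.
#'
#' @param n_genes Number of ortholog gene pairs.
#' @param length_range Integer pair: minimum and maximum coding-sequence
#'   length in nucleotides.
#' @param divergence Per-site substitution probability between the focal and
#'   spike orthologs, in `[0, 1]`.
#' @param spike_fraction Expected fraction of reads originating from the
#'   spike species in a reference (bulk factor 1) sample, in `[0, 1)`.
#' @param timepoints Character vector of timepoint labels; the first (or the
#'   one whose `bulk_factors` entry is 1) is the reference.
#' @param bulk_factors One positive real per timepoint: the true bulk
#'   translation level relative to the reference (which must be 1).
#' @param n_replicates Replicates per timepoint and assay.
#' @param reads_per_sample Reads simulated per sample.
#' @param read_length Footprint/fragment length in nucleotides (default 30).
#' @param abundance_shape Log-scale SD of the log-normal per-gene abundance
#'   distribution.
#' @param te_profile Per-gene relative translation rates for the footprint
#'   assay: `NULL` (uniform), a numeric vector of length `n_genes`, or a
#'   named list with one such vector per timepoint.
#' @param seed Integer seed; all randomness in the experiment derives from it.
#'
#' @return A validated list of class `sim_config`.
#' @export
#'
#' @examples
#' cfg <- sim_config(n_genes = 20, reads_per_sample = 1000, seed = 1)
#' cfg$bulk_factors
sim_config <- function(n_genes = 200,
                       length_range = c(150L, 300L),
                       divergence = 0.12,
                       spike_fraction = 0.02,
                       timepoints = c("day2", "day8", "day12"),
                       bulk_factors = c(1.0, 0.595, 0.427),
                       n_replicates = 3L,
                       reads_per_sample = 50000L,
                       read_length = 30L,
                       abundance_shape = 1,
                       te_profile = NULL,
                       seed = 1L) {
  n_genes <- assert_count(n_genes, "n_genes")
  n_replicates <- assert_count(n_replicates, "n_replicates")
  reads_per_sample <- assert_count(reads_per_sample, "reads_per_sample")
  read_length <- assert_count(read_length, "read_length")
  seed <- assert_count(seed, "seed", lower = 0L)
  assert_scalar_number(divergence, "divergence", 0, 1)
  assert_scalar_number(spike_fraction, "spike_fraction", 0, 1, open_upper = TRUE)
  assert_scalar_number(abundance_shape, "abundance_shape", 0)
  if (length(length_range) != 2L || any(length_range < read_length)) {
    abort("`length_range` must be two integers, both >= `read_length`.")
  }
  if (length_range[1] > length_range[2]) {
    abort("`length_range` must be increasing.")
  }
  if (length(bulk_factors) != length(timepoints)) {
    abort("`bulk_factors` must have one entry per timepoint.")
  }
  if (any(bulk_factors <= 0)) {
    abort("`bulk_factors` must be positive.")
  }
  if (sum(bulk_factors == 1) != 1L) {
    abort("Exactly one timepoint must have bulk factor 1 (the reference).")
  }
  if (anyDuplicated(timepoints)) {
    abort("`timepoints` must be unique labels.")
  }
  if (!is.null(te_profile)) {
    te_list <- if (is.list(te_profile)) te_profile else list(te_profile)
    ok <- vapply(
      te_list,
      function(v) is.numeric(v) && length(v) == n_genes && all(v >= 0) && any(v > 0),
      logical(1)
    )
    if (!all(ok)) {
      abort("`te_profile` vectors must be non-negative, not all zero, of length `n_genes`.")
    }
    if (is.list(te_profile) && !all(names(te_profile) %in% timepoints)) {
      abort("Names of a per-timepoint `te_profile` list must be timepoint labels.")
    }
  }
  structure(
    list(
      n_genes = n_genes, length_range = as.integer(length_range),
      divergence = divergence, spike_fraction = spike_fraction,
      timepoints = as.character(timepoints), bulk_factors = as.numeric(bulk_factors),
      n_replicates = n_replicates, reads_per_sample = reads_per_sample,
      read_length = read_length, abundance_shape = abundance_shape,
      te_profile = te_profile, seed = seed
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf(
    "  %d genes (%d-%d nt), divergence %.3g, spike fraction %.3g\n",
    x$n_genes, x$length_range[1], x$length_range[2], x$divergence,
    x$spike_fraction
  ))
  cat(sprintf(
    "  timepoints: %s (bulk factors %s)\n",
    paste(x$timepoints, collapse = ", "),
    paste(format(x$bulk_factors), collapse = ", ")
  ))
  cat(sprintf(
    "  %d replicates x 2 assays, %d reads/sample, read length %d, seed %d\n",
    x$n_replicates, x$reads_per_sample, x$read_length, x$seed
  ))
  invisible(x)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a pair of diverged ortholog transcriptomes
#'
#' Builds `n_genes` random focal coding sequences and derives a spike-species
#' ortholog for each by substituting every site independently with probability
#' `divergence` (to a uniformly chosen different base). Orthologs therefore
#' stay length-matched and positionally aligned, and the exact set of
#' substituted positions is recorded, making window distinguishability
#' computable in closed form downstream.
#'
#' @param n_genes Number of gene pairs.
#' @param length_range Integer pair of minimum/maximum sequence length (nt).
#' @param divergence Per-site substitution probability in `[0, 1]`.
#' @param seed Integer seed.
#'
#' @return A tibble with one row per gene: `gene`, `focal_seq`, `spike_seq`,
#'   `length`, and the list-column `substituted_positions` (0-based integer
#'   positions where the two sequences differ).
#' @export
#'
#' @examples
#' tx <- sim_ortholog_transcriptomes(5, c(60, 80), divergence = 0.1, seed = 1)
#' tx$gene
sim_ortholog_transcriptomes <- function(n_genes, length_range,
                                        divergence, seed = 1L) {
  n_genes <- assert_count(n_genes, "n_genes")
  assert_scalar_number(divergence, "divergence", 0, 1)
  if (length(length_range) != 2L || any(length_range < 1) ||
      length_range[1] > length_range[2]) {
    abort("`length_range` must be an increasing pair of positive integers.")
  }
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    len_choices <- seq.int(length_range[1], length_range[2])
    lens <- len_choices[sample.int(length(len_choices), n_genes, replace = TRUE)]
    rows <- lapply(seq_len(n_genes), function(i) {
      focal <- sample(bases, lens[i], replace = TRUE)
      hit <- which(runif(lens[i]) < divergence)
      spike <- focal
      if (length(hit) > 0L) {
        # substitute to a uniformly chosen different base
        offs <- sample.int(3L, length(hit), replace = TRUE)
        spike[hit] <- bases[(match(focal[hit], bases) - 1L + offs) %% 4L + 1L]
      }
      list(
        focal = paste(focal, collapse = ""),
        spike = paste(spike, collapse = ""),
        subs = as.integer(hit - 1L)
      )
    })
    tibble(
      gene = sprintf("g%04d", seq_len(n_genes)),
      focal_seq = vapply(rows, `[[`, character(1), "focal"),
      spike_seq = vapply(rows, `[[`, character(1), "spike"),
      length = as.integer(lens),
      substituted_positions = lapply(rows, `[[`, "subs")
    )
  })
}

#' Simulate the reads of one library
#'
#' Draws `n_reads` error-free reads from the combined focal + spike
#' transcriptome. Each read chooses its species first: the spike RNA mass is
#' held fixed at the amount that yields `spike_fraction` of reads when the
#' focal bulk signal is at its reference level, so the probability of a spike
#' read is `spike_fraction / (bulk_factor * (1 - spike_fraction) +
#' spike_fraction)`. Within the focal species a gene is chosen proportional to
#' `abundance` (times `te_profile` for the footprint assay, since footprint
#' density reflects translation); the spike extract is the same in every
#' sample, so spike reads are drawn proportional to `abundance` alone. The
#' read start is uniform over valid positions and the true labels are
#' recorded.
#'
#' @param transcriptomes Tibble from [sim_ortholog_transcriptomes()].
#' @param abundances Non-negative per-gene mRNA abundances (not all zero).
#' @param te_profile Per-gene relative translation rates (footprint assay
#'   only); `NULL` for uniform.
#' @param bulk_factor Focal bulk translation level relative to the reference
#'   sample (footprint assay) or relative mRNA mass (mRNA assay, normally 1).
#' @param spike_fraction Expected spike read fraction at `bulk_factor = 1`.
#' @param n_reads Number of reads.
#' @param read_length Read length (nt).
#' @param assay `"footprint"` or `"mrna"`.
#' @param seed Integer seed.
#'
#' @return A tibble with one row per read: `read_id`, `sequence`,
#'   `true_species` (`"focal"`/`"spike"`), `true_gene`, `true_start`
#'   (0-based), `assay`.
#' @export
sim_sample_reads <- function(transcriptomes, abundances, te_profile = NULL,
                             bulk_factor = 1, spike_fraction = 0.02,
                             n_reads = 10000L, read_length = 30L,
                             assay = c("footprint", "mrna"), seed = 1L) {
  assay <- match.arg(assay)
  n_reads <- assert_count(n_reads, "n_reads")
  read_length <- assert_count(read_length, "read_length")
  assert_scalar_number(bulk_factor, "bulk_factor", 0, Inf, open_lower = TRUE)
  assert_scalar_number(spike_fraction, "spike_fraction", 0, 1, open_upper = TRUE)
  n_genes <- nrow(transcriptomes)
  if (length(abundances) != n_genes || any(abundances < 0) || !any(abundances > 0)) {
    abort("`abundances` must be non-negative, not all zero, one per gene.")
  }
  te <- te_profile %||% rep(1, n_genes)
  if (length(te) != n_genes || any(te < 0)) {
    abort("`te_profile` must be non-negative, one value per gene.")
  }

  focal_w <- if (assay == "footprint") abundances * te else abundances
  spike_w <- abundances
  if (!any(focal_w > 0)) {
    abort("Footprint gene weights are all zero (abundance x te_profile).")
  }
  sel <- transcriptomes$length[focal_w > 0 | spike_w > 0]
  short <- transcriptomes$gene[(focal_w > 0 | spike_w > 0) &
    transcriptomes$length < read_length]
  if (length(short) > 0L) {
    abort(sprintf(
      "read_length %d exceeds the length of transcript %s.",
      read_length, short[1]
    ))
  }

  # spike mass fixed; focal mass scales with bulk_factor
  p_spike <- spike_fraction /
    (bulk_factor * (1 - spike_fraction) + spike_fraction)

  with_seed(seed, {
    is_spike <- runif(n_reads) < p_spike
    gene_idx <- integer(n_reads)
    n_sp <- sum(is_spike)
    if (n_sp < n_reads) {
      gene_idx[!is_spike] <- sample.int(n_genes, n_reads - n_sp,
        replace = TRUE, prob = focal_w
      )
    }
    if (n_sp > 0L) {
      gene_idx[is_spike] <- sample.int(n_genes, n_sp,
        replace = TRUE, prob = spike_w
      )
    }
    max_start <- transcriptomes$length[gene_idx] - read_length
    start <- floor(runif(n_reads) * (max_start + 1))
    src <- ifelse(is_spike,
      transcriptomes$spike_seq[gene_idx],
      transcriptomes$focal_seq[gene_idx]
    )
    tibble(
      read_id = sprintf("%s_%07d", substr(assay, 1, 2), seq_len(n_reads)),
      sequence = substr(src, start + 1, start + read_length),
      true_species = ifelse(is_spike, "spike", "focal"),
      true_gene = transcriptomes$gene[gene_idx],
      true_start = as.integer(start),
      assay = assay
    )
  })
}

#' Simulate a complete multi-timepoint spike-in experiment
#'
#' Generates ortholog transcriptomes, draws one per-gene abundance vector,
#' and simulates one footprint and one mRNA library per (timepoint,
#' replicate). The per-timepoint `bulk_factors` are applied to the footprint
#' assay only; the mRNA assay runs at bulk factor 1 at every timepoint (total
#' mRNA in stored oocytes does not change). Every latent parameter is
#' returned in `truth` so downstream estimates can be checked against the
#' generating values.
#'
#' @param config A [sim_config()] object.
#'
#' @return A list of class `sim_experiment`:
#'   * `transcriptomes` — ortholog tibble,
#'   * `reads` — one tibble of all reads with `sample`, `assay`, `timepoint`,
#'     `replicate` columns,
#'   * `sample_sheet` — tibble (`sample`, `assay`, `timepoint`, `replicate`),
#'   * `truth` — list of all generating parameters (abundances, te profiles,
#'     bulk factors, per-sample seeds).
#' @export
#'
#' @examples
#' ex <- sim_experiment(sim_config(
#'   n_genes = 10, reads_per_sample = 200,
#'   n_replicates = 1, seed = 42
#' ))
#' ex$sample_sheet
sim_experiment <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be created with sim_config().")
  }
  tx <- sim_ortholog_transcriptomes(
    config$n_genes, config$length_range, config$divergence,
    seed = derive_seed(config$seed, 0L)
  )
  abundances <- with_seed(derive_seed(config$seed, 1L), {
    rlnorm(config$n_genes, meanlog = 0, sdlog = config$abundance_shape)
  })
  te_for <- function(timepoint) {
    tp <- config$te_profile
    if (is.null(tp)) {
      rep(1, config$n_genes)
    } else if (is.list(tp)) {
      tp[[timepoint]] %||% rep(1, config$n_genes)
    } else {
      tp
    }
  }

  sheet <- tidyr::expand_grid(
    assay = c("footprint", "mrna"),
    timepoint = config$timepoints,
    replicate = seq_len(config$n_replicates)
  ) |>
    mutate(sample = sprintf("%s_%s_rep%d", .data$assay, .data$timepoint,
      .data$replicate
    )) |>
    select("sample", "assay", "timepoint", "replicate")

  sample_seeds <- derive_seed(config$seed, seq_len(nrow(sheet)) + 1L)
  bulk <- setNames(config$bulk_factors, config$timepoints)

  reads <- purrr::pmap(
    list(sheet$sample, sheet$assay, sheet$timepoint, sample_seeds),
    function(sample, assay, timepoint, sseed) {
      sim_sample_reads(
        tx,
        abundances = abundances,
        te_profile = if (assay == "footprint") te_for(timepoint) else NULL,
        bulk_factor = if (assay == "footprint") bulk[[timepoint]] else 1,
        spike_fraction = config$spike_fraction,
        n_reads = config$reads_per_sample,
        read_length = config$read_length,
        assay = assay,
        seed = sseed
      ) |>
        mutate(sample = sample, timepoint = timepoint, .before = 1)
    }
  ) |>
    purrr::list_rbind() |>
    left_join(sheet |> select("sample", "replicate"), by = "sample")

  truth <- list(
    config = unclass(config)[setdiff(names(config), "te_profile")],
    abundances = setNames(abundances, tx$gene),
    te_profile = lapply(
      setNames(config$timepoints, config$timepoints), te_for
    ),
    bulk_factors = bulk,
    sample_seeds = setNames(sample_seeds, sheet$sample)
  )

  structure(
    list(
      transcriptomes = tx, reads = reads,
      sample_sheet = sheet, truth = truth
    ),
    class = "sim_experiment"
  )
}

#' Simulate hatch-rate decay data
#'
#' Draws binomial hatch counts from a logistic viability decay: the hatch
#' probability at storage day `t` is `h0 / (1 + exp(slope * (t - t50)))`, an
#' upper plateau `h0` (hatch rate of fresh oocytes) falling to `h0 / 2` at
#' `t50` days.
#'
#' @param h0 Initial hatch plateau, in `(0, 1]`.
#' @param slope Decay steepness per day, positive.
#' @param t50 Day at which hatch probability reaches `h0 / 2`.
#' @param days Numeric vector of assay days (strictly increasing).
#' @param n_eggs Eggs scored per day: a single integer or one per day.
#' @param seed Integer seed.
#'
#' @return A tibble (`day`, `n_eggs`, `n_hatched`, `hatch_rate`).
#' @export
#'
#' @examples
#' sim_hatch_data(0.95, 0.8, 12, days = seq(1, 21, 2), n_eggs = 200, seed = 1)
sim_hatch_data <- function(h0, slope, t50, days, n_eggs, seed = 1L) {
  assert_scalar_number(h0, "h0", 0, 1, open_lower = TRUE)
  assert_scalar_number(slope, "slope", 0, Inf, open_lower = TRUE)
  assert_scalar_number(t50, "t50", 0, Inf, open_lower = TRUE)
  if (any(n_eggs <= 0) || any(n_eggs != floor(n_eggs))) {
    abort("`n_eggs` must be positive integers.")
  }
  if (any(days < 0) || is.unsorted(days, strictly = TRUE)) {
    abort("`days` must be non-negative and strictly increasing.")
  }
  n_eggs <- as.integer(rep_len(n_eggs, length(days)))
  p <- h0 / (1 + exp(slope * (days - t50)))
  hatched <- with_seed(seed, rbinom(length(days), n_eggs, p))
  tibble(
    day = as.numeric(days), n_eggs = n_eggs,
    n_hatched = hatched, hatch_rate = hatched / n_eggs
  )
}
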