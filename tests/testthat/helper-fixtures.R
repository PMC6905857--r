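# Shared fixtures, built once per test run. Sizes are deliberately small;
# the acceptance tests build their own full-size simulations.

fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, fixture_env)) {
    assign(name, builder(), fixture_env)
  }
  get(name, fixture_env)
}

# 30 ortholog pairs at moderate divergence
tiny_transcriptomes <- function() {
  memo("tiny_tx", function() {
    sim_ortholog_transcriptomes(30, c(60, 120), divergence = 0.12, seed = 101)
  })
}

# 3 timepoints x 2 replicates x 2 assays, small read depth
tiny_experiment <- function() {
  memo("tiny_ex", function() {
    sim_experiment(sim_config(
      n_genes = 30, length_range = c(60L, 120L), divergence = 0.12,
      spike_fraction = 0.05, n_replicates = 2L, reads_per_sample = 4000L,
      seed = 202
    ))
  })
}

tiny_counts <- function() {
  memo("tiny_cm", function() {
    ex <- tiny_experiment()
    idx <- build_kmer_index(ex$transcriptomes, read_length = 30L)
    asg <- assign_reads(idx, ex$reads)
    list(
      experiment = ex, index = idx, assignments = asg,
      counts = count_reads(asg, ex$sample_sheet)
    )
  })
}

# Independent oracle: naive all-vs-all substring occurrence search. For each
# query, every transcript of both species is scanned with fixed-string
# matching and occurrences are collapsed to distinct (species, gene) pairs.
naive_assign <- function(transcriptomes, sequences) {
  seqs <- c(
    setNames(transcriptomes$focal_seq, paste0("focal:", transcriptomes$gene)),
    setNames(transcriptomes$spike_seq, paste0("spike:", transcriptomes$gene))
  )
  vapply(sequences, function(q) {
    hits <- names(seqs)[vapply(
      seqs, function(s) grepl(q, s, fixed = TRUE), logical(1)
    )]
    if (length(hits) == 0L) {
      "unmapped"
    } else if (length(hits) == 1L) {
      hits
    } else {
      "multimapped"
    }
  }, character(1), USE.NAMES = FALSE)
}

# Independent oracle for window distinguishability: direct substring
# comparison of every window of the two ortholog sequences.
naive_distinguishable <- function(focal, spike, w = 30L) {
  n <- nchar(focal) - w + 1L
  if (n < 1L) {
    return(c(n_windows = 0L, n_dist = 0L))
  }
  dist <- vapply(seq_len(n), function(i) {
    substr(focal, i, i + w - 1L) != substr(spike, i, i + w - 1L)
  }, logical(1))
  c(n_windows = n, n_dist = sum(dist))
}

# Replicate-level expression table on a lognormal null: log2 values are
# exactly Gaussian, so Student-t p-values must be exactly uniform.
null_expression <- function(n_genes, samples, sdlog = 0.4, mean_log2 = 7) {
  tidyr::expand_grid(gene = sprintf("n%05d", seq_len(n_genes)), sample = samples) |>
    dplyr::mutate(value = 2^stats::rnorm(dplyr::n(), mean_log2, sdlog))
}

# Full-scale study-design simulation shared by the acceptance tests:
# 3 timepoints x 3 replicates x 2 assays at 2e5 reads/sample with the true
# bulk factors (1, 0.595, 0.427) and a 2% spike-in.
acceptance_main <- function() {
  memo("acc_main", function() {
    cfg <- sim_config(
      n_genes = 250, length_range = c(120L, 240L), divergence = 0.12,
      spike_fraction = 0.02, timepoints = c("day2", "day8", "day12"),
      bulk_factors = c(1.0, 0.595, 0.427), n_replicates = 3L,
      reads_per_sample = 200000L, seed = 424242
    )
    ex <- sim_experiment(cfg)
    idx <- build_kmer_index(ex$transcriptomes, read_length = 30L)
    asg <- assign_reads(idx, ex$reads)
    list(
      config = cfg, experiment = ex, index = idx, assignments = asg,
      counts = count_reads(asg, ex$sample_sheet)
    )
  })
}
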