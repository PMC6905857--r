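test_that("ortholog generation handles identity and saturation divergence", {
  tx0 <- sim_ortholog_transcriptomes(10, c(50, 80), divergence = 0, seed = 1)
  expect_identical(tx0$focal_seq, tx0$spike_seq)
  expect_true(all(lengths(tx0$substituted_positions) == 0L))

  tx1 <- sim_ortholog_transcriptomes(10, c(50, 80), divergence = 1, seed = 1)
  expect_true(all(lengths(tx1$substituted_positions) == tx1$length))
  expect_true(all(mapply(
    function(a, b) all(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]),
    tx1$focal_seq, tx1$spike_seq
  )))
})

test_that("substituted_positions are exactly the differing sites", {
  tx <- tiny_transcriptomes()
  recomputed <- purrr::map2(tx$focal_seq, tx$spike_seq, function(a, b) {
    which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]) - 1L
  })
  expect_identical(unname(tx$substituted_positions), unname(recomputed))
})

test_that("total substitutions at divergence 0.1 follow the binomial expectation", {
  tx <- sim_ortholog_transcriptomes(100, c(100, 100), divergence = 0.1, seed = 5)
  total_len <- sum(tx$length)
  expect_equal(total_len, 10000)
  n_subs <- sum(lengths(tx$substituted_positions))
  sd3 <- 3 * sqrt(total_len * 0.1 * 0.9)
  expect_lt(abs(n_subs - 1000), sd3)
})

test_that("every simulated read is an exact substring at its recorded offset", {
  ex <- tiny_experiment()
  tx <- ex$transcriptomes
  src <- ifelse(ex$reads$true_species == "spike",
    tx$spike_seq[match(ex$reads$true_gene, tx$gene)],
    tx$focal_seq[match(ex$reads$true_gene, tx$gene)]
  )
  expect_identical(
    ex$reads$sequence,
    substr(src, ex$reads$true_start + 1L, ex$reads$true_start + 30L)
  )
  expect_true(all(nchar(ex$reads$sequence) == 30L))
})

test_that("degenerate abundance concentrates all focal reads on one gene", {
  tx <- tiny_transcriptomes()
  ab <- rep(0, nrow(tx))
  ab[7] <- 1
  reads <- sim_sample_reads(tx, ab,
    spike_fraction = 0.1, n_reads = 500,
    read_length = 30, assay = "footprint", seed = 3
  )
  focal <- reads[reads$true_species == "focal", ]
  expect_true(all(focal$true_gene == tx$gene[7]))
})

test_that("spike read fraction matches spike_fraction and responds to bulk factor", {
  tx <- tiny_transcriptomes()
  ab <- rep(1, nrow(tx))
  n <- 40000
  r1 <- sim_sample_reads(tx, ab,
    bulk_factor = 1, spike_fraction = 0.05,
    n_reads = n, seed = 11
  )
  p1 <- mean(r1$true_species == "spike")
  expect_lt(abs(p1 - 0.05), 3 * sqrt(0.05 * 0.95 / n))

  # halving the focal bulk (spike mass fixed) halves the focal:spike ratio
  r2 <- sim_sample_reads(tx, ab,
    bulk_factor = 0.5, spike_fraction = 0.05,
    n_reads = n, seed = 12
  )
  p2_expected <- 0.05 / (0.5 * 0.95 + 0.05)
  p2 <- mean(r2$true_species == "spike")
  expect_lt(abs(p2 - p2_expected), 3 * sqrt(p2_expected * (1 - p2_expected) / n))
  ratio1 <- (1 - p1) / p1
  ratio2 <- (1 - p2) / p2
  expect_equal(ratio2 / ratio1, 0.5, tolerance = 0.15)
})

test_that("identical seed and inputs reproduce the read set exactly", {
  tx <- tiny_transcriptomes()
  ab <- seq_len(nrow(tx))
  a <- sim_sample_reads(tx, ab, n_reads = 1000, seed = 77)
  b <- sim_sample_reads(tx, ab, n_reads = 1000, seed = 77)
  expect_identical(a, b)
  c <- sim_sample_reads(tx, ab, n_reads = 1000, seed = 78)
  expect_false(identical(a$sequence, c$sequence))
})

test_that("experiment layout matches the design and truth is complete", {
  ex <- tiny_experiment()
  # 3 timepoints x 2 replicates x 2 assays
  expect_equal(nrow(ex$sample_sheet), 12)
  expect_equal(dplyr::n_distinct(ex$reads$sample), 12)
  expect_setequal(
    names(ex$truth),
    c("config", "abundances", "te_profile", "bulk_factors", "sample_seeds")
  )
  expect_length(ex$truth$abundances, 30)

  ex1 <- sim_experiment(sim_config(
    n_genes = 5, n_replicates = 1, timepoints = "d0", bulk_factors = 1,
    reads_per_sample = 100, length_range = c(40L, 60L), seed = 1
  ))
  expect_equal(nrow(ex1$sample_sheet), 2) # one footprint + one mrna
})

test_that("mRNA assay ignores bulk factors while footprints scale with them", {
  ex <- tiny_experiment()
  frac <- ex$reads |>
    dplyr::group_by(sample, assay, timepoint) |>
    dplyr::summarise(spike = mean(true_species == "spike"), .groups = "drop")
  mr <- frac |> dplyr::filter(assay == "mrna")
  # mrna spike fraction flat across timepoints at ~spike_fraction
  expect_lt(max(abs(mr$spike - 0.05)), 3 * sqrt(0.05 * 0.95 / 4000))
  fp <- frac |>
    dplyr::filter(assay == "footprint") |>
    dplyr::group_by(timepoint) |>
    dplyr::summarise(spike = mean(spike))
  # lower bulk -> higher spike share among footprint reads
  expect_gt(fp$spike[fp$timepoint == "day12"], fp$spike[fp$timepoint == "day2"])
})

test_that("true state survives a JSON round trip", {
  dir <- withr::local_tempdir()
  run_simulation(
    sim_config(
      n_genes = 8, length_range = c(40L, 60L), n_replicates = 1L,
      reads_per_sample = 100L, seed = 5
    ),
    dir
  )
  ex_small <- sim_experiment(sim_config(
    n_genes = 8, length_range = c(40L, 60L), n_replicates = 1L,
    reads_per_sample = 100L, seed = 5
  ))
  back <- jsonlite::read_json(
    file.path(dir, "true_state.json"),
    simplifyVector = TRUE
  )
  expect_equal(unlist(back$abundances), unlist(ex_small$truth$abundances))
  expect_equal(unlist(back$bulk_factors), unlist(ex_small$truth$bulk_factors))
  expect_equal(
    back$config$reads_per_sample,
    ex_small$truth$config$reads_per_sample
  )
})

test_that("hatch data follow the logistic decay law", {
  # midpoint: p(t50) = h0/2 exactly
  p_mid <- 1 / (1 + exp(0.8 * (12 - 12)))
  expect_equal(p_mid, 0.5)

  # plateau: early days with distant t50 hatch at ~h0
  d <- sim_hatch_data(0.9, 1, t50 = 50, days = c(0.5, 1), n_eggs = 50000, seed = 4)
  expect_equal(d$hatch_rate, rep(0.9, 2), tolerance = 0.01)

  # binomial SE at the midpoint
  dm <- sim_hatch_data(1, 0.8, t50 = 12, days = c(1, 5, 12, 20), n_eggs = 10000, seed = 9)
  at12 <- dm$hatch_rate[dm$day == 12]
  expect_lt(abs(at12 - 0.5), 3 * sqrt(0.5 * 0.5 / 10000))
})

test_that("simulation inputs are validated", {
  expect_error(sim_config(divergence = 1.5), "divergence")
  expect_error(sim_config(bulk_factors = c(1, 1, 0.5)), "reference")
  expect_error(sim_config(bulk_factors = c(1, 0.5)), "per timepoint")
  expect_error(
    sim_ortholog_transcriptomes(3, c(100, 50), 0.1),
    "increasing"
  )
  expect_error(sim_hatch_data(0.9, 1, 12, days = 1:5, n_eggs = 0), "n_eggs")
  expect_error(
    sim_hatch_data(0.9, 1, 12, days = c(3, 2, 5), n_eggs = 10),
    "increasing"
  )
  tx <- tiny_transcriptomes()
  expect_error(
    sim_sample_reads(tx, rep(1, nrow(tx)), read_length = 500, n_reads = 10),
    "read_length"
  )
  expect_error(
    sim_sample_reads(tx, rep(0, nrow(tx)), n_reads = 10),
    "abundances"
  )
})
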