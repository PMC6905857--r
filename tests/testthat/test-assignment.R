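test_that("index enumerates every window and flags short transcripts", {
  seq1 <- paste(rep("ACGT", 20), collapse = "") # 80 nt
  idx <- build_kmer_index(c(tx1 = seq1), character(0), read_length = 30)
  # L - k + 1 positions before deduplication
  expect_equal(nrow(idx$occurrences), 80 - 30 + 1)
  expect_error(
    build_kmer_index(c(short = "ACGTACGT"), character(0), read_length = 30),
    "short"
  )
})

test_that("identical orthologs make every k-mer ambiguous across species", {
  s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
  idx <- build_kmer_index(c(g = s), c(g = s), read_length = 30)
  expect_true(all(idx$lookup$n_pairs == 2L))
  asg <- assign_reads(idx, substr(s, 1, 30))
  expect_equal(asg$status, "multimapped")
})

test_that("index lookups agree with naive substring search on random queries", {
  tx <- tiny_transcriptomes()
  idx <- build_kmer_index(tx, read_length = 30)
  set.seed(42)
  # mix of real windows (both species) and random sequences
  real <- sapply(sample(nrow(tx), 40, replace = TRUE), function(i) {
    src <- if (runif(1) < 0.5) tx$focal_seq[i] else tx$spike_seq[i]
    start <- sample(nchar(src) - 29L, 1)
    substr(src, start, start + 29L)
  })
  random <- replicate(10, paste(
    sample(c("A", "C", "G", "T"), 30, replace = TRUE),
    collapse = ""
  ))
  queries <- c(real, random)
  got <- assign_reads(idx, queries)
  want <- naive_assign(tx, queries)
  expect_identical(
    got$status,
    ifelse(want %in% c("unmapped", "multimapped"), want, "unique")
  )
  uniq <- !want %in% c("unmapped", "multimapped")
  expect_identical(
    paste0(got$assigned_species[uniq], ":", got$assigned_gene[uniq]),
    want[uniq]
  )
})

test_that("unique-status assignments never contradict the simulation truth", {
  tc <- tiny_counts()
  u <- dplyr::filter(tc$assignments, status == "unique")
  expect_gt(nrow(u), 0)
  expect_identical(u$assigned_gene, u$true_gene)
  expect_identical(u$assigned_species, u$true_species)
})

test_that("uniqueness granularity distinguishes gene- from position-level hits", {
  # one gene containing the same 30-mer twice: unique at gene granularity,
  # multimapped at position granularity
  core <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE), collapse = "")
  seqs <- c(dup = paste0(core, "AAAAA", core))
  gene_idx <- build_kmer_index(seqs, character(0), read_length = 30)
  pos_idx <- build_kmer_index(seqs, character(0),
    read_length = 30,
    granularity = "position"
  )
  expect_equal(assign_reads(gene_idx, core)$status, "unique")
  expect_equal(assign_reads(pos_idx, core)$status, "multimapped")
})

test_that("length-mismatched reads get a per-read error status unless strict", {
  tx <- tiny_transcriptomes()
  idx <- build_kmer_index(tx, read_length = 30)
  bad <- c(substr(tx$focal_seq[1], 1, 30), "ACGT")
  res <- assign_reads(idx, bad)
  expect_equal(res$status[2], "length_error")
  expect_error(assign_reads(idx, bad, strict = TRUE), "length")
})

test_that("counting conserves unique reads and matches ground truth", {
  tc <- tiny_counts()
  cm <- tc$counts
  asg <- tc$assignments
  # totals equal the number of unique-status reads per sample
  per_sample <- asg |>
    dplyr::filter(status == "unique") |>
    dplyr::count(sample)
  totals <- dplyr::bind_rows(cm$footprint$totals, cm$mrna$totals) |>
    dplyr::mutate(n = focal_total + spike_total)
  merged <- dplyr::left_join(per_sample, totals, by = "sample")
  expect_equal(merged$n.x, merged$n.y)
  # focal totals equal the column sums of the gene matrix
  colsums <- cm$footprint$counts |>
    dplyr::group_by(sample) |>
    dplyr::summarise(total = sum(count))
  merged2 <- dplyr::left_join(colsums, cm$footprint$totals, by = "sample")
  expect_equal(merged2$total, merged2$focal_total)
  # per-gene counts equal ground-truth tallies of unique focal reads
  truth_counts <- asg |>
    dplyr::filter(status == "unique", true_species == "focal") |>
    dplyr::count(sample, gene = true_gene, name = "count") |>
    dplyr::arrange(sample, gene)
  expect_equal(
    as.data.frame(cm$footprint$counts |>
      dplyr::filter(sample %in% truth_counts$sample[
        grepl("^footprint", truth_counts$sample)
      ])),
    as.data.frame(truth_counts |> dplyr::filter(grepl("^footprint", sample)))
  )
  expect_error(
    count_reads(
      dplyr::mutate(asg, sample = "mystery"),
      tc$experiment$sample_sheet
    ),
    "sample sheet"
  )
})

test_that("all-ambiguous read sets produce an all-zero count matrix", {
  s <- paste(rep("AC", 40), collapse = "")
  tx_like <- tibble::tibble(
    gene = "g", focal_seq = s, spike_seq = s, length = nchar(s),
    substituted_positions = list(integer(0))
  )
  idx <- build_kmer_index(tx_like, read_length = 30)
  reads <- tibble::tibble(
    read_id = "r1", sequence = substr(s, 1, 30), sample = "s1"
  )
  sheet <- tibble::tibble(
    sample = "s1", assay = "footprint", timepoint = "d0", replicate = 1L
  )
  cm <- count_reads(assign_reads(idx, reads), sheet)
  expect_equal(nrow(cm$footprint$counts), 0)
  expect_equal(cm$footprint$totals$focal_total, 0L)
  expect_equal(cm$footprint$totals$spike_total, 0L)
})

test_that("window distinguishability matches enumeration on hand-built cases", {
  # identical orthologs: nothing distinguishable
  same <- tibble::tibble(
    gene = "id", focal_seq = strrep("A", 50), spike_seq = strrep("A", 50),
    length = 50L, substituted_positions = list(integer(0))
  )
  wd0 <- window_distinguishability(same)
  expect_equal(wd0$fraction, 0)

  # length 59, one substitution at 0-based position 29: every one of the 30
  # windows covers it
  f <- strrep("A", 59)
  s <- paste0(strrep("A", 29), "C", strrep("A", 29))
  one <- tibble::tibble(
    gene = "mid", focal_seq = f, spike_seq = s, length = 59L,
    substituted_positions = list(29L)
  )
  wd1 <- window_distinguishability(one)
  expect_equal(wd1$n_windows, 30)
  expect_equal(wd1$n_distinguishable, 30)
  expect_equal(wd1$fraction, 1)

  # transcript shorter than the window contributes zero windows, flagged
  shorty <- tibble::tibble(
    gene = "tiny", focal_seq = strrep("A", 10), spike_seq = strrep("A", 10),
    length = 10L, substituted_positions = list(integer(0))
  )
  wds <- window_distinguishability(shorty)
  expect_true(wds$too_short)
  expect_equal(wds$n_windows, 0)
})

test_that("window counts agree with the brute-force window oracle", {
  tx <- tiny_transcriptomes()
  wd <- window_distinguishability(tx)
  oracle <- t(mapply(naive_distinguishable, tx$focal_seq, tx$spike_seq))
  expect_equal(wd$n_windows, unname(oracle[, "n_windows"]))
  expect_equal(wd$n_distinguishable, unname(oracle[, "n_dist"]))
})

test_that("distinguishable fraction grows monotonically with nested substitution sets", {
  set.seed(31)
  len <- 150L
  subs_small <- sort(sample(0:(len - 1L), 5))
  subs_big <- sort(union(subs_small, sample(0:(len - 1L), 15)))
  mk <- function(subs) {
    f <- rep("A", len)
    s <- f
    s[subs + 1L] <- "C"
    tibble::tibble(
      gene = "g", focal_seq = paste(f, collapse = ""),
      spike_seq = paste(s, collapse = ""), length = len,
      substituted_positions = list(as.integer(subs))
    )
  }
  fr_small <- window_distinguishability(mk(subs_small))$fraction
  fr_big <- window_distinguishability(mk(subs_big))$fraction
  expect_gte(fr_big, fr_small)
})

test_that("aggregate distinguishability follows the closed form 1-(1-p)^w", {
  p <- 0.12
  tx <- sim_ortholog_transcriptomes(250, c(100, 200), divergence = p, seed = 77)
  wd <- window_distinguishability(tx)
  agg <- distinguishability_summary(wd)
  expected <- 1 - (1 - p)^30
  se <- sd(wd$fraction) / sqrt(nrow(wd))
  expect_lt(abs(mean(wd$fraction) - expected), 3 * se)
  expect_lt(abs(agg$fraction - expected), 3 * se)
})
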