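#' Build a combined two-species k-mer index
#'
#' Enumerates every `read_length`-mer of every transcript of both species and
#' records its occurrences. Exact full-length lookup against this index
#' reproduces the unique-mapping filter of a combined-reference alignment: a
#' read matching exactly one transcript (or, at the default granularity,
#' exactly one (species, gene) pair) is uniquely attributable to one species
#' and gene.
#'
#' @param focal Named character vector of focal-species coding sequences, or
#'   a transcriptome tibble with `gene`, `focal_seq` and `spike_seq` columns
#'   (then `spike` is ignored).
#' @param spike Named character vector of spike-species coding sequences.
#' @param read_length k-mer length; every indexed transcript must be at least
#'   this long.
#' @param granularity `"gene"` (default): occurrences are collapsed to
#'   distinct (species, gene) pairs, so a read hitting one gene at two
#'   positions is still unique — the transcript-level semantics of an
#'   `NH:i:1` filter. `"position"`: every occurrence counts separately.
#' @param revcomp Also index reverse complements (off by default; reads are
#'   simulated sense-strand).
#'
#' @return An object of class `kmer_index` with the per-k-mer lookup table,
#'   the full occurrence list, and the gene universe.
#' @export
#'
#' @examples
#' tx <- sim_ortholog_transcriptomes(3, c(40, 50), 0.2, seed = 1)
#' idx <- build_kmer_index(tx, read_length = 30)
#' idx
build_kmer_index <- function(focal, spike = NULL, read_length = 30L,
                             granularity = c("gene", "position"),
                             revcomp = FALSE) {
  granularity <- match.arg(granularity)
  read_length <- assert_count(read_length, "read_length")
  if (is.data.frame(focal)) {
    tx <- focal
    focal <- setNames(tx$focal_seq, tx$gene)
    spike <- setNames(tx$spike_seq, tx$gene)
  }
  if (is.null(spike)) spike <- character(0)
  for (set in list(focal, spike)) {
    if (length(set) > 0L && is.null(names(set))) {
      abort("Sequence vectors must be named by gene.")
    }
  }
  occ <- purrr::list_rbind(purrr::imap(
    list(focal = focal, spike = spike),
    function(seqs, species) {
      if (length(seqs) == 0L) return(NULL)
      lens <- nchar(seqs)
      short <- which(lens < read_length)
      if (length(short) > 0L) {
        abort(sprintf(
          "Transcript %s (%s, %d nt) is shorter than read_length %d.",
          names(seqs)[short[1]], species, lens[short[1]], read_length
        ))
      }
      n_win <- lens - read_length + 1L
      gene <- rep(names(seqs), n_win)
      start <- unlist(lapply(n_win, seq_len), use.names = FALSE) - 1L
      seq_rep <- rep(unname(seqs), n_win)
      tibble(
        kmer = substr(seq_rep, start + 1L, start + read_length),
        species = species, gene = gene, start = start
      )
    }
  ))
  if (revcomp) {
    rc <- occ |>
      mutate(
        kmer = as.character(
          Biostrings::reverseComplement(Biostrings::DNAStringSet(.data$kmer))
        ),
        strand = "-"
      )
    occ <- bind_rows(mutate(occ, strand = "+"), rc)
  }

  # collapse to per-k-mer hit counts without per-group apply: distinct() and
  # count() are single vectorised passes, which keeps indexing fast for
  # transcriptome-scale inputs
  pairs <- distinct(occ, .data$kmer, .data$species, .data$gene)
  lookup <- count(pairs, .data$kmer, name = "n_pairs") |>
    left_join(count(occ, .data$kmer, name = "n_occ"), by = "kmer") |>
    mutate(n_hits = if (granularity == "gene") .data$n_pairs else .data$n_occ)
  label <- pairs |>
    semi_join(filter(lookup, .data$n_hits == 1L), by = "kmer")
  lookup <- lookup |>
    left_join(label, by = "kmer") |>
    mutate(
      species = ifelse(.data$n_hits == 1L, .data$species, NA_character_),
      gene = ifelse(.data$n_hits == 1L, .data$gene, NA_character_)
    )

  structure(
    list(
      lookup = lookup, occurrences = occ,
      read_length = read_length, granularity = granularity,
      revcomp = revcomp,
      genes = list(focal = names(focal), spike = names(spike))
    ),
    class = "kmer_index"
  )
}

#' @export
print.kmer_index <- function(x, ...) {
  cat(sprintf(
    "<kmer_index> k = %d, %d distinct k-mers over %d focal + %d spike transcripts (%s granularity)\n",
    x$read_length, nrow(x$lookup), length(x$genes$focal),
    length(x$genes$spike), x$granularity
  ))
  invisible(x)
}

#' Assign reads to species and gene by exact k-mer lookup
#'
#' Looks every read up in the combined index. A read whose sequence occurs in
#' exactly one place (at the index's granularity) is `unique` and inherits
#' that species and gene; more than one occurrence is `multimapped`; none is
#' `unmapped`. Only unique reads are attributable, mirroring a
#' uniquely-mapping-reads filter on a combined two-species reference. With
#' error-free reads this assignment admits no mislabeling — ambiguity only
#' ever discards reads.
#'
#' @param index A [build_kmer_index()] object.
#' @param reads A tibble with `sequence` (and any metadata columns, which are
#'   preserved), or a character vector of read sequences.
#' @param strict If `TRUE`, a read whose length differs from the index k
#'   aborts; otherwise it receives status `"length_error"`.
#'
#' @return The input tibble, row order preserved, with `status`
#'   (`unique` / `multimapped` / `unmapped` / `length_error`),
#'   `assigned_species` and `assigned_gene` columns appended.
#' @export
assign_reads <- function(index, reads, strict = FALSE) {
  if (!inherits(index, "kmer_index")) {
    abort("`index` must be a kmer_index.")
  }
  if (is.character(reads)) {
    reads <- tibble(read_id = sprintf("r%06d", seq_along(reads)), sequence = reads)
  }
  if (!"sequence" %in% names(reads)) {
    abort("`reads` must have a `sequence` column.")
  }
  bad_len <- nchar(reads$sequence) != index$read_length
  if (strict && any(bad_len)) {
    abort(sprintf(
      "%d read(s) do not have length %d.", sum(bad_len), index$read_length
    ))
  }
  hits <- tibble(sequence = reads$sequence) |>
    left_join(
      index$lookup |>
        select("kmer", "n_hits", "species", "gene"),
      by = c(sequence = "kmer")
    )
  status <- case_when(
    bad_len ~ "length_error",
    is.na(hits$n_hits) ~ "unmapped",
    hits$n_hits == 1L ~ "unique",
    .default = "multimapped"
  )
  reads |>
    mutate(
      status = status,
      assigned_species = ifelse(status == "unique", hits$species, NA_character_),
      assigned_gene = ifelse(status == "unique", hits$gene, NA_character_)
    )
}

#' Tally unique reads into per-gene counts and per-species totals
#'
#' Keeps only unique-status reads: focal-species reads are counted per gene
#' and per sample, and per-sample totals of unique focal and unique spike
#' reads are recorded — the quantities the spike-in normalization is built
#' from. Multimapped, unmapped and malformed reads are excluded everywhere.
#'
#' @param assignments Output of [assign_reads()] with a `sample` column.
#' @param sample_sheet Tibble with `sample`, `assay`, `timepoint`,
#'   `replicate`; every read's sample must appear here.
#'
#' @return A list of class `count_matrix`, one entry per assay, each with
#'   `counts` (tibble `sample`, `gene`, `count`; focal unique reads only) and
#'   `totals` (tibble `sample`, `timepoint`, `replicate`, `focal_total`,
#'   `spike_total`).
#' @export
count_reads <- function(assignments, sample_sheet) {
  if (!"sample" %in% names(assignments)) {
    abort("`assignments` must carry a `sample` column.")
  }
  unknown <- setdiff(unique(assignments$sample), sample_sheet$sample)
  if (length(unknown) > 0L) {
    abort(sprintf(
      "Sample(s) not in the sample sheet: %s.", paste(unknown, collapse = ", ")
    ))
  }
  uni <- assignments |>
    filter(.data$status == "unique") |>
    left_join(
      sample_sheet |> select("sample", "assay", "timepoint", "replicate"),
      by = "sample",
      suffix = c("", ".sheet")
    )
  if ("assay.sheet" %in% names(uni)) {
    uni$assay <- uni$assay.sheet
  }

  per_assay <- function(sheet_assay) {
    samples <- sample_sheet |> filter(.data$assay == sheet_assay)
    sub <- uni |> filter(.data$sample %in% samples$sample)
    counts <- sub |>
      filter(.data$assigned_species == "focal") |>
      count(.data$sample, gene = .data$assigned_gene, name = "count") |>
      arrange(.data$sample, .data$gene)
    totals <- sub |>
      count(.data$sample, .data$assigned_species) |>
      tidyr::pivot_wider(
        names_from = "assigned_species", values_from = "n", values_fill = 0L
      )
    for (col in c("focal", "spike")) {
      if (!col %in% names(totals)) totals[[col]] <- 0L
    }
    totals <- samples |>
      select("sample", "timepoint", "replicate") |>
      left_join(totals, by = "sample") |>
      mutate(
        focal_total = tidyr::replace_na(.data$focal, 0L),
        spike_total = tidyr::replace_na(.data$spike, 0L),
        .keep = "unused"
      )
    list(counts = counts, totals = totals)
  }

  assays <- unique(sample_sheet$assay)
  structure(
    setNames(lapply(assays, per_assay), assays),
    class = "count_matrix"
  )
}

#' 30-mer distinguishability of ortholog windows
#'
#' For each gene, slides a window of `window_length` along the aligned
#' ortholog pair and asks whether the window covers at least one substituted
#' position — i.e. whether a footprint from that window carries a
#' polymorphism identifying its species. Transcripts shorter than the window
#' contribute zero windows and are flagged.
#'
#' @param transcriptomes Tibble from [sim_ortholog_transcriptomes()] (needs
#'   `gene`, `length`, `substituted_positions`).
#' @param gene_subset Optional character vector restricting the genes.
#' @param window_length Window size in nucleotides (default 30).
#'
#' @return A tibble per gene: `gene`, `n_windows`, `n_distinguishable`,
#'   `fraction`, `too_short`. Aggregate over a gene set with
#'   [distinguishability_summary()].
#' @export
#'
#' @examples
#' tx <- sim_ortholog_transcriptomes(50, c(100, 200), 0.12, seed = 7)
#' wd <- window_distinguishability(tx)
#' distinguishability_summary(wd)
window_distinguishability <- function(transcriptomes, gene_subset = NULL,
                                      window_length = 30L) {
  window_length <- assert_count(window_length, "window_length")
  tx <- transcriptomes
  if (!is.null(gene_subset)) {
    missing <- setdiff(gene_subset, tx$gene)
    if (length(missing) > 0L) {
      abort(sprintf(
        "Genes not in the transcriptome: %s.", paste(missing, collapse = ", ")
      ))
    }
    tx <- tx |> filter(.data$gene %in% gene_subset)
  }
  res <- purrr::pmap(
    list(tx$length, tx$substituted_positions),
    function(len, subs) {
      n_win <- len - window_length + 1L
      if (n_win < 1L) {
        return(c(n_windows = 0L, n_dist = 0L))
      }
      if (length(subs) == 0L) {
        return(c(n_windows = n_win, n_dist = 0L))
      }
      # window starting at i (0-based) covers substitution s iff
      # i in [s - window_length + 1, s]; mark the union of these ranges
      lo <- pmax(subs - window_length + 1L, 0L)
      hi <- pmin(subs, n_win - 1L)
      keep <- lo <= hi
      delta <- integer(n_win + 1L)
      for (j in which(keep)) {
        delta[lo[j] + 1L] <- delta[lo[j] + 1L] + 1L
        delta[hi[j] + 2L] <- delta[hi[j] + 2L] - 1L
      }
      covered <- cumsum(delta[seq_len(n_win)]) > 0L
      c(n_windows = n_win, n_dist = sum(covered))
    }
  )
  tibble(
    gene = tx$gene,
    n_windows = vapply(res, `[[`, numeric(1), "n_windows"),
    n_distinguishable = vapply(res, `[[`, numeric(1), "n_dist")
  ) |>
    mutate(
      fraction = ifelse(.data$n_windows > 0, .data$n_distinguishable / .data$n_windows, NA_real_),
      too_short = .data$n_windows == 0
    )
}

#' Aggregate window distinguishability over a gene set
#'
#' @param per_gene Output of [window_distinguishability()].
#' @return One-row tibble: `n_genes`, `n_windows`, `n_distinguishable`,
#'   `fraction`, `n_too_short`.
#' @export
distinguishability_summary <- function(per_gene) {
  per_gene |>
    summarise(
      n_genes = n(),
      n_windows = sum(.data$n_windows),
      n_distinguishable = sum(.data$n_distinguishable),
      fraction = .data$n_distinguishable / .data$n_windows,
      n_too_short = sum(.data$too_short)
    )
}
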