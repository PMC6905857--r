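# File plumbing: FASTA/FASTQ, sample sheets, TSV tables, JSON manifests.
# Transcriptomes travel as two FASTA files with matching record ids; reads as
# FASTQ with a constant quality string; tables as one-header-line TSV.

#' Write ortholog transcriptomes as paired FASTA files
#'
#' @param transcriptomes Tibble from [sim_ortholog_transcriptomes()].
#' @param dir Output directory (created if missing).
#' @param basenames File names for the focal and spike FASTA.
#' @return Invisibly, the two file paths.
#' @export
write_transcriptomes <- function(transcriptomes, dir,
                                 basenames = c("focal.fa", "spike.fa")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, basenames)
  focal <- Biostrings::DNAStringSet(
    setNames(transcriptomes$focal_seq, transcriptomes$gene)
  )
  spike <- Biostrings::DNAStringSet(
    setNames(transcriptomes$spike_seq, transcriptomes$gene)
  )
  Biostrings::writeXStringSet(focal, paths[1])
  Biostrings::writeXStringSet(spike, paths[2])
  invisible(paths)
}

#' Read paired transcriptome FASTA files back into a tibble
#'
#' Record ids must match between the two files; substituted positions are
#' recomputed by comparing the aligned sequences.
#'
#' @param focal_path,spike_path FASTA paths.
#' @return Tibble with the same shape as [sim_ortholog_transcriptomes()].
#' @export
read_transcriptomes <- function(focal_path, spike_path) {
  focal <- Biostrings::readDNAStringSet(focal_path)
  spike <- Biostrings::readDNAStringSet(spike_path)
  if (!identical(names(focal), names(spike))) {
    abort("Focal and spike FASTA record ids must match in order and name.")
  }
  if (!all(Biostrings::width(focal) == Biostrings::width(spike))) {
    abort("Orthologs must be length-matched.")
  }
  f <- as.character(focal)
  s <- as.character(spike)
  subs <- purrr::map2(f, s, function(a, b) {
    which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]]) - 1L
  })
  tibble(
    gene = names(focal),
    focal_seq = unname(f),
    spike_seq = unname(s),
    length = unname(nchar(f)),
    substituted_positions = unname(subs)
  )
}

#' Write reads as FASTQ with a constant quality string
#'
#' @param reads Tibble with `read_id` and `sequence`.
#' @param path Output `.fastq` path.
#' @param quality_char Single quality character applied to every base.
#' @return Invisibly, `path`.
#' @export
write_reads_fastq <- function(reads, path, quality_char = "I") {
  qual <- strrep(quality_char, nchar(reads$sequence))
  lines <- as.vector(rbind(
    paste0("@", reads$read_id), reads$sequence, "+", qual
  ))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a FASTQ (or FASTA) read file into a tibble
#'
#' @param path FASTQ/FASTA path.
#' @param format `"fastq"` (default) or `"fasta"`.
#' @return Tibble (`read_id`, `sequence`).
#' @export
read_reads <- function(path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  x <- Biostrings::readDNAStringSet(path, format = format)
  tibble(
    read_id = sub("\\s.*$", "", names(x)),
    sequence = unname(as.character(x))
  )
}

#' Read / write a sample sheet CSV
#'
#' Columns: `sample`, `assay`, `timepoint`, `replicate`, and optionally
#' `file` (path to the sample's read file).
#'
#' @param path CSV path.
#' @param sheet Sample sheet tibble.
#' @return The sheet (read) or invisibly the path (write).
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("sample", "assay", "timepoint", "replicate")
  missing <- setdiff(needed, names(sheet))
  if (length(missing) > 0L) {
    abort(sprintf(
      "Sample sheet lacks column(s): %s.", paste(missing, collapse = ", ")
    ))
  }
  sheet
}

#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  readr::write_csv(sheet, path)
  invisible(path)
}

# Named numeric vectors serialize to JSON arrays (names lost); convert them
# to lists so the truth file round-trips with gene/sample names intact.
truth_to_json <- function(truth, path) {
  for (field in c("abundances", "bulk_factors", "sample_seeds")) {
    truth[[field]] <- as.list(truth[[field]])
  }
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

write_manifest <- function(files, path, seed = NULL) {
  files <- files[file.exists(files)]
  manifest <- list(
    package = "ribospike",
    version = as.character(utils::packageVersion("ribospike")),
    seed = seed,
    files = lapply(
      setNames(files, basename(files)),
      function(f) list(md5 = unname(tools::md5sum(f)), bytes = file.size(f))
    )
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
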