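#' Per-gene differential translation between two groups of samples
#'
#' Tests each gene for a change in (spike-adjusted) expression between two
#' sample groups with a two-sided two-sample t-test on log2-transformed
#' replicate values (Student's pooled-variance test by default, as is
#' standard for triplicate designs; Welch via `var_equal = FALSE`). The
#' log2 fold change is taken between pseudocount-stabilized group means
#' (group B over group A) and Benjamini-Hochberg q-values are reported
#' alongside raw p-values.
#'
#' @param values Replicate-level table: tibble with `gene`, `sample`, and a
#'   value column (adjusted TPM or TE).
#' @param group_a,group_b Character vectors of sample names (at least 2
#'   each).
#' @param alpha Significance threshold on the raw p-value for the class
#'   label (default 0.01).
#' @param pseudocount Added before log transform and to group means
#'   (default 1).
#' @param value_col Name of the value column (default `"value"`).
#' @param var_equal Student (`TRUE`, default) or Welch t-test.
#'
#' @return A tibble of class `ribo_differential`: per gene `mean_a`,
#'   `mean_b` (raw group means), `log2_fc`, `statistic`, `p_value`,
#'   `q_value`, `neg_log10_p`, and `class` (`up` / `down` / `unchanged`, by
#'   sign of the fold change at `p_value < alpha`).
#' @export
#'
#' @examples
#' tab <- tidyr::expand_grid(
#'   gene = c("a", "b"), sample = paste0("s", 1:6)
#' ) |> dplyr::mutate(value = c(10, 10, 10, 40, 41, 39, 5, 5, 6, 5, 6, 5))
#' differential_translation(tab, paste0("s", 1:3), paste0("s", 4:6))
differential_translation <- function(values, group_a, group_b, alpha = 0.01,
                                     pseudocount = 1, value_col = "value",
                                     var_equal = TRUE) {
  assert_scalar_number(alpha, "alpha", 0, 1)
  assert_scalar_number(pseudocount, "pseudocount", 0)
  if (length(group_a) < 2L || length(group_b) < 2L) {
    abort("Each group needs at least 2 replicate samples.")
  }
  if (length(intersect(group_a, group_b)) > 0L) {
    abort("Groups must not share samples.")
  }
  mat_a <- values_to_matrix(values, group_a, value_col)
  mat_b <- values_to_matrix(values, group_b, value_col)
  genes <- union(rownames(mat_a), rownames(mat_b))
  pad <- function(m) {
    miss <- setdiff(genes, rownames(m))
    if (length(miss) > 0L) {
      m <- rbind(m, matrix(0, length(miss), ncol(m),
        dimnames = list(miss, colnames(m))
      ))
    }
    m[genes, , drop = FALSE]
  }
  mat_a <- pad(mat_a)
  mat_b <- pad(mat_b)

  tt <- row_t_test(
    log2(mat_a + pseudocount), log2(mat_b + pseudocount),
    var_equal = var_equal
  )
  mean_a <- rowMeans(mat_a)
  mean_b <- rowMeans(mat_b)
  out <- tibble(
    gene = genes,
    mean_a = unname(mean_a),
    mean_b = unname(mean_b),
    log2_fc = log2((mean_b + pseudocount) / (mean_a + pseudocount)),
    statistic = tt$statistic,
    p_value = tt$p_value,
    q_value = p.adjust(tt$p_value, method = "BH"),
    neg_log10_p = -log10(tt$p_value)
  ) |>
    mutate(class = case_when(
      .data$p_value < alpha & .data$log2_fc > 0 ~ "up",
      .data$p_value < alpha & .data$log2_fc < 0 ~ "down",
      .default = "unchanged"
    )) |>
    arrange(.data$gene)
  class(out) <- c("ribo_differential", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' Classify preferentially translated ("pilot light") genes
#'
#' Identifies genes whose spike-adjusted translation is significantly higher
#' in arrested oocytes than in early embryos — candidates for maintaining
#' oocyte viability during storage. Both input tables must already be on a
#' common spike-normalized scale (apply the embryo scale factor upstream).
#' The test is the same two-sided Student t-test as
#' [differential_translation()], with classification on the raw p-value plus
#' a higher-in-oocyte direction filter; BH q-values are reported alongside.
#'
#' @param oocyte_values,embryo_values Replicate-level adjusted tables
#'   (`gene`, `sample`, value column), already on a common scale.
#' @param alpha Raw p-value threshold (default 0.01).
#' @param pseudocount TPM pseudocount (default 1).
#' @param tpm_floor Expression floor: the expressed-gene universe is the set
#'   of genes whose mean oocyte value is at least this (default 1).
#' @param value_col Name of the value column.
#' @param var_equal Student (default) or Welch t-test.
#'
#' @return A list of class `pilot_light`: `genes` (per-gene stats with
#'   `expressed` and `is_pilot_light`), `summary` (one row: `n_pilot_light`,
#'   `n_expressed`, `fraction_of_expressed`).
#' @export
classify_pilot_light <- function(oocyte_values, embryo_values, alpha = 0.01,
                                 pseudocount = 1, tpm_floor = 1,
                                 value_col = "value", var_equal = TRUE) {
  assert_scalar_number(alpha, "alpha", 0, 1)
  oo_samples <- unique(oocyte_values$sample)
  em_samples <- unique(embryo_values$sample)
  combined <- bind_rows(oocyte_values, embryo_values)
  # group A = embryo, group B = oocyte: pilot-light genes come out `up`
  res <- differential_translation(
    combined,
    group_a = em_samples, group_b = oo_samples,
    alpha = alpha, pseudocount = pseudocount,
    value_col = value_col, var_equal = var_equal
  )
  genes <- res |>
    rename(mean_embryo = "mean_a", mean_oocyte = "mean_b") |>
    mutate(
      expressed = .data$mean_oocyte >= tpm_floor,
      is_pilot_light = .data$expressed &
        .data$p_value < alpha &
        .data$mean_oocyte > .data$mean_embryo
    ) |>
    select(-"class")
  n_expressed <- sum(genes$expressed)
  if (n_expressed == 0L) {
    abort("No expressed oocyte genes above `tpm_floor`; cannot classify.")
  }
  summary <- tibble(
    n_pilot_light = sum(genes$is_pilot_light),
    n_expressed = n_expressed,
    fraction_of_expressed = sum(genes$is_pilot_light) / n_expressed
  )
  structure(
    list(genes = genes, summary = summary, alpha = alpha),
    class = "pilot_light"
  )
}

#' @export
print.pilot_light <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<pilot_light> %d of %d expressed oocyte genes (%.1f%%) preferentially translated at p < %g\n",
    s$n_pilot_light, s$n_expressed, 100 * s$fraction_of_expressed, x$alpha
  ))
  invisible(x)
}

#' Per-category translation and mRNA changes between two timepoints
#'
#' For user-supplied gene categories (e.g. functional classes of interest),
#' reports each member gene's log2 change in spike-adjusted translation and
#' in mRNA level between two conditions, plus category medians — the
#' tabular form of a category heat map. Genes listed in a category but
#' absent from the expression table are reported, never dropped silently.
#'
#' @param expression A [translational_efficiency()] result (needs `gene`,
#'   `timepoint`, `fp_tpm_adj`, `mrna_tpm`).
#' @param category_map Tibble with `category` and `gene` columns.
#' @param timepoint_a,timepoint_b Condition labels; changes are
#'   `log2(B / A)`.
#' @param pseudocount TPM pseudocount (default 1).
#'
#' @return A list of class `category_summary`: `members` (per category x
#'   gene, `translation_log2fc`, `mrna_log2fc`, `present`), `summary` (per
#'   category `n_genes`, `n_missing`, `median_translation_log2fc`,
#'   `median_mrna_log2fc`, `empty` flag).
#' @export
category_summary <- function(expression, category_map,
                             timepoint_a, timepoint_b, pseudocount = 1) {
  assert_scalar_number(pseudocount, "pseudocount", 0)
  for (tp in c(timepoint_a, timepoint_b)) {
    if (!tp %in% expression$timepoint) {
      abort(sprintf("Timepoint '%s' not present in the expression table.", tp))
    }
  }
  wide <- expression |>
    filter(.data$timepoint %in% c(timepoint_a, timepoint_b)) |>
    select("gene", "timepoint", "fp_tpm_adj", "mrna_tpm") |>
    tidyr::pivot_wider(
      names_from = "timepoint",
      values_from = c("fp_tpm_adj", "mrna_tpm")
    )
  fa <- paste0("fp_tpm_adj_", timepoint_a)
  fb <- paste0("fp_tpm_adj_", timepoint_b)
  ma <- paste0("mrna_tpm_", timepoint_a)
  mb <- paste0("mrna_tpm_", timepoint_b)
  members <- category_map |>
    select("category", "gene") |>
    left_join(wide, by = "gene") |>
    mutate(
      present = !is.na(.data[[fa]]),
      translation_log2fc = log2((.data[[fb]] + pseudocount) /
        (.data[[fa]] + pseudocount)),
      mrna_log2fc = log2((.data[[mb]] + pseudocount) /
        (.data[[ma]] + pseudocount))
    ) |>
    select("category", "gene", "present",
      "translation_log2fc", "mrna_log2fc"
    )
  summary <- members |>
    group_by(.data$category) |>
    summarise(
      n_genes = sum(.data$present),
      n_missing = sum(!.data$present),
      median_translation_log2fc = median(.data$translation_log2fc, na.rm = TRUE),
      median_mrna_log2fc = median(.data$mrna_log2fc, na.rm = TRUE)
    ) |>
    mutate(empty = .data$n_genes == 0L)
  if (any(summary$empty)) {
    warn(sprintf(
      "Categories with no genes present in the table: %s.",
      paste(summary$category[summary$empty], collapse = ", ")
    ))
  }
  structure(list(members = members, summary = summary),
    class = "category_summary"
  )
}

#' @export
print.category_summary <- function(x, ...) {
  cat("<category_summary>\n")
  print(x$summary)
  invisible(x)
}
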