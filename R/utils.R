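# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

# Scalar validators -----------------------------------------------------------

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must lie in %s%s, %s%s (got %g).", name,
      if (open_lower) "(" else "[", format(lower),
      format(upper), if (open_upper) ")" else "]", x
    ))
  }
  invisible(x)
}

assert_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < lower) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, lower))
  }
  invisible(as.integer(x))
}

# Deterministic per-sample RNG streams: each sample gets its own seed derived
# from the experiment seed and the sample's index, so individual samples are
# reproducible in isolation. Kept strictly below 2^31 - 1.
derive_seed <- function(seed, index) {
  base <- as.double(seed %% 1048576L)
  as.integer((base * 1013L + as.double(index) * 7919) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Vectorised two-sample t-test over the rows of two matrices (one row per
# gene, one column per replicate). Student (pooled variance) by default,
# Welch optional. Returns a tibble with estimate difference (mean_b - mean_a),
# t statistic, df, and two-sided p. Cross-checked against stats::t.test in the
# test suite.
row_t_test <- function(mat_a, mat_b, var_equal = TRUE) {
  stopifnot(nrow(mat_a) == nrow(mat_b))
  na <- ncol(mat_a)
  nb <- ncol(mat_b)
  if (na < 2L || nb < 2L) {
    abort("At least 2 replicates per group are required for the t-test.")
  }
  mean_a <- rowMeans(mat_a)
  mean_b <- rowMeans(mat_b)
  var_a <- rowSums((mat_a - mean_a)^2) / (na - 1L)
  var_b <- rowSums((mat_b - mean_b)^2) / (nb - 1L)
  if (var_equal) {
    pooled <- ((na - 1L) * var_a + (nb - 1L) * var_b) / (na + nb - 2L)
    se <- sqrt(pooled * (1 / na + 1 / nb))
    df <- rep(na + nb - 2L, length(se))
  } else {
    se <- sqrt(var_a / na + var_b / nb)
    df <- (var_a / na + var_b / nb)^2 /
      ((var_a / na)^2 / (na - 1L) + (var_b / nb)^2 / (nb - 1L))
  }
  delta <- mean_b - mean_a
  t_stat <- delta / se
  p <- 2 * pt(abs(t_stat), df = df, lower.tail = FALSE)
  # Degenerate genes: zero variance in both groups. Equal means -> no evidence
  # of change (p = 1); unequal means with zero noise -> certain change.
  degenerate <- se == 0
  p[degenerate & delta == 0] <- 1
  t_stat[degenerate & delta == 0] <- 0
  p[degenerate & delta != 0] <- 0
  tibble(
    mean_a = unname(mean_a), mean_b = unname(mean_b),
    estimate = unname(delta), statistic = unname(t_stat),
    df = unname(df), p_value = unname(p)
  )
}

# Spread a tidy (gene, sample, value) table into a genes x samples matrix with
# a fixed column order; missing combinations become `fill`.
values_to_matrix <- function(data, samples, value_col = "value", fill = 0) {
  missing_samples <- setdiff(samples, unique(data$sample))
  if (length(missing_samples) > 0L) {
    abort(sprintf(
      "Samples not present in the table: %s.",
      paste(missing_samples, collapse = ", ")
    ))
  }
  wide <- data |>
    filter(.data$sample %in% .env$samples) |>
    select("gene", "sample", value = all_of(value_col)) |>
    tidyr::pivot_wider(
      names_from = "sample", values_from = "value", values_fill = fill
    )
  mat <- as.matrix(wide[, samples, drop = FALSE])
  rownames(mat) <- wide$gene
  mat
}
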