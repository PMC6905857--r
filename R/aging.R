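#' Fit the logistic decay of stored-oocyte viability
#'
#' Models the hatch rate of eggs from oocytes stored for `day` days as a
#' three-parameter logistic decay,
#' `hatch(t) = h0 / (1 + exp(slope * (t - t50)))`:
#' an upper plateau `h0` (fresh oocytes hatch at 90-96%, not 100%), a decay
#' steepness `slope` (per day), and the half-life `t50` at which the hatch
#' rate reaches `h0 / 2`. The lower plateau is fixed at 0. Fitting is
#' Levenberg-Marquardt least squares, weighted by `n_eggs` when egg counts
#' are available (binomial variance shrinks as 1/n). Starting values are
#' deterministic — `h0` = maximum observed hatch rate, `t50` = the day whose
#' hatch rate is closest to half of that, `slope` = 0.5/day — so fits are
#' reproducible.
#'
#' @param data Tibble with `day` plus either `n_eggs` and `n_hatched`, or a
#'   `hatch_rate` column (then the fit is unweighted); at least 4 distinct
#'   days.
#' @param weighted Weight residuals by `n_eggs` when counts are present
#'   (default `TRUE`).
#'
#' @return An object of class `hatch_fit` with elements `fit` (the
#'   underlying `nls` object, or `NULL`), `params` (tibble of estimates and
#'   standard errors), `data`, `converged`. Degenerate data (constant hatch
#'   rate, or a fit that does not converge) yields `converged = FALSE` and
#'   `NA` parameters — no fabricated half-life. Use [tidy()], [glance()],
#'   [predict_hatch()] and [autoplot()] on the result.
#' @export
#'
#' @examples
#' d <- sim_hatch_data(0.95, 0.8, 12, days = 1:20, n_eggs = 200, seed = 1)
#' fit <- fit_decay_curve(d)
#' tidy(fit)
fit_decay_curve <- function(data, weighted = TRUE) {
  if (!"day" %in% names(data)) {
    abort("`data` needs a `day` column.")
  }
  if ("n_hatched" %in% names(data) && "n_eggs" %in% names(data)) {
    if (any(data$n_hatched > data$n_eggs) || any(data$n_hatched < 0)) {
      abort("Need 0 <= n_hatched <= n_eggs.")
    }
    data <- data |> mutate(hatch_rate = .data$n_hatched / .data$n_eggs)
  } else if (!"hatch_rate" %in% names(data)) {
    abort("`data` needs either `n_eggs` + `n_hatched` or `hatch_rate`.")
  }
  if (length(unique(data$day)) < 4L) {
    abort("At least 4 distinct days are required to fit 3 parameters.")
  }
  w <- if (weighted && "n_eggs" %in% names(data)) data$n_eggs else rep(1, nrow(data))

  na_params <- tibble(
    term = c("h0", "slope", "t50"),
    estimate = NA_real_, std_error = NA_real_
  )
  degenerate <- sd(data$hatch_rate) == 0
  fit <- NULL
  if (!degenerate) {
    h0_start <- max(data$hatch_rate)
    t50_start <- data$day[which.min(abs(data$hatch_rate - h0_start / 2))]
    fit <- tryCatch(
      minpack.lm::nlsLM(
        hatch_rate ~ h0 / (1 + exp(slope * (day - t50))),
        data = data,
        start = list(h0 = h0_start, slope = 0.5, t50 = t50_start),
        weights = w,
        lower = c(h0 = 1e-6, slope = 1e-6, t50 = -Inf),
        upper = c(h0 = 1, slope = Inf, t50 = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  }
  converged <- !is.null(fit) && isTRUE(fit$convInfo$isConv)
  params <- if (converged) {
    sm <- summary(fit)$coefficients
    tibble(
      term = rownames(sm),
      estimate = unname(sm[, "Estimate"]),
      std_error = unname(sm[, "Std. Error"])
    )
  } else {
    na_params
  }
  structure(
    list(
      fit = if (converged) fit else NULL,
      params = params, data = data,
      converged = converged, weighted = weighted
    ),
    class = "hatch_fit"
  )
}

#' @export
print.hatch_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<hatch_fit> did not converge (degenerate or ill-conditioned data)\n")
    return(invisible(x))
  }
  est <- setNames(x$params$estimate, x$params$term)
  cat(sprintf(
    "<hatch_fit> h0 = %.3f, slope = %.3f /day, t50 = %.2f days (%s, n = %d days)\n",
    est["h0"], est["slope"], est["t50"],
    if (x$weighted) "binomial-weighted" else "unweighted",
    nrow(x$data)
  ))
  invisible(x)
}

#' @describeIn fit_decay_curve Tidy the fitted parameters (broom
#'   convention: `term`, `estimate`, `std.error`, `statistic`, `p.value`).
#' @param x A `hatch_fit`.
#' @param ... Unused.
#' @method tidy hatch_fit
#' @export
tidy.hatch_fit <- function(x, ...) {
  out <- x$params |> rename(std.error = "std_error")
  out |>
    mutate(
      statistic = .data$estimate / .data$std.error,
      p.value = 2 * pt(abs(.data$statistic),
        df = max(nrow(x$data) - 3L, 1L), lower.tail = FALSE
      )
    )
}

#' @describeIn fit_decay_curve One-row model summary (`converged`,
#'   `n_days`, `sigma`, `deviance`, `df.residual`, `t50`).
#' @method glance hatch_fit
#' @export
glance.hatch_fit <- function(x, ...) {
  if (!x$converged) {
    return(tibble(
      converged = FALSE, n_days = nrow(x$data), sigma = NA_real_,
      deviance = NA_real_, df.residual = NA_integer_, t50 = NA_real_
    ))
  }
  tibble(
    converged = TRUE,
    n_days = nrow(x$data),
    sigma = summary(x$fit)$sigma,
    deviance = sum(resid(x$fit)^2),
    df.residual = nrow(x$data) - 3L,
    t50 = x$params$estimate[x$params$term == "t50"]
  )
}

#' @describeIn fit_decay_curve Observed data with fitted hatch rates and
#'   residuals appended.
#' @method augment hatch_fit
#' @export
augment.hatch_fit <- function(x, ...) {
  x$data |>
    mutate(
      .fitted = predict_hatch(x, .data$day),
      .resid = .data$hatch_rate - .data$.fitted
    )
}

#' Predict hatch rates from a fitted decay curve
#'
#' @param fit A converged [fit_decay_curve()] result.
#' @param days Numeric vector of storage days.
#' @return Predicted hatch fractions, monotone non-increasing in `days`.
#' @export
predict_hatch <- function(fit, days) {
  if (!inherits(fit, "hatch_fit")) {
    abort("`fit` must be a hatch_fit.")
  }
  if (!fit$converged) {
    abort("Cannot predict from an unconverged fit.")
  }
  est <- setNames(fit$params$estimate, fit$params$term)
  unname(est["h0"] / (1 + exp(est["slope"] * (days - est["t50"]))))
}

#' @describeIn fit_decay_curve Plot observed hatch rates with the fitted
#'   decay curve.
#' @param object A `hatch_fit`.
#' @method autoplot hatch_fit
#' @export
autoplot.hatch_fit <- function(object, ...) {
  p <- ggplot2::ggplot(
    object$data,
    ggplot2::aes(x = .data$day, y = .data$hatch_rate)
  ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "storage (days)", y = "hatch rate",
      title = "Stored-oocyte viability decay"
    ) +
    ggplot2::ylim(0, 1)
  if (object$converged) {
    grid <- tibble(day = seq(min(object$data$day), max(object$data$day),
      length.out = 200
    ))
    grid$hatch_rate <- predict_hatch(object, grid$day)
    p <- p + ggplot2::geom_line(data = grid, colour = "#2166ac")
  }
  p
}
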