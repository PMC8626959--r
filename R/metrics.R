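#' Coefficient of variation
#'
#' `CV = sd / mean` with the sample (n - 1) standard deviation, the
#' dimensionless variability measure used to score landmarking consistency
#' across a cohort. Set `sample_sd = FALSE` for the population variant.
#'
#' @param xs Numeric vector (>= 2 values).
#' @param sample_sd Use the n - 1 denominator (default) or n.
#' @return The CV (dimensionless, scale-invariant).
#' @examples
#' coefficient_of_variation(c(1, 3))  # sqrt(2)/2
#' @export
coefficient_of_variation <- function(xs, sample_sd = TRUE) {
  if (length(xs) < 2) abort_config("CV needs at least 2 values")
  mu <- mean(xs)
  if (mu == 0) abort_config("CV is undefined for zero mean")
  s <- stats::sd(xs)
  if (!sample_sd) s <- s * sqrt((length(xs) - 1) / length(xs))
  s / mu
}

# Extract one summary metric from a landmark_result. `metric` is one of
# n_bends, total_bend_length, bend_length (k-th bend via `k`), or
# labeled_bend_length (via `label`). NA when the result lacks the bend.
result_metric <- function(result, metric, k = 1L, label = "superior") {
  b <- result$bends
  switch(metric,
    n_bends = nrow(b),
    total_bend_length = sum(b$length),
    bend_length = if (nrow(b) >= k) b$length[k] else NA_real_,
    labeled_bend_length = {
      i <- which(b$label == label)
      if (length(i) && !result$failed) b$length[i[1]] else NA_real_
    },
    abort_config(sprintf("unknown metric: %s", metric))
  )
}

#' Summarize a landmarking metric over a cohort
#'
#' Evaluates one metric per result (`n_bends`, `total_bend_length`,
#' `bend_length` of the k-th bend, or `labeled_bend_length`) and returns its
#' mean, sample SD, and CV. Results lacking the requested bend (e.g. failed
#' four-bend subdivisions in labeled mode) are excluded, with the exclusion
#' count reported.
#'
#' @param results A list of `landmark_result` objects (>= 2).
#' @param metric One of `"n_bends"`, `"total_bend_length"`, `"bend_length"`,
#'   `"labeled_bend_length"`.
#' @param k Bend rank (proximal to distal) for `metric = "bend_length"`.
#' @param label Anatomical label for `metric = "labeled_bend_length"`.
#' @return A one-row tibble: `metric`, `n`, `n_excluded`, `mean`, `sd`, `cv`
#'   (`cv` is `NA` when the mean is 0).
#' @export
cohort_summary <- function(results, metric = "n_bends", k = 1L, label = "superior") {
  if (length(results) < 2) abort_config("a cohort needs at least 2 results")
  xs <- vapply(results, result_metric, numeric(1), metric = metric, k = k, label = label)
  excluded <- sum(is.na(xs))
  xs <- xs[!is.na(xs)]
  if (length(xs) == 0) abort_config("no result in the cohort provides the requested metric")
  mu <- mean(xs)
  s <- if (length(xs) > 1) stats::sd(xs) else 0
  tibble::tibble(
    metric = metric, n = length(xs), n_excluded = excluded,
    mean = mu, sd = s, cv = if (mu != 0) s / mu else NA_real_
  )
}

#' Default sensitivity-sweep grids for the preprocessing parameters
#'
#' The default sweep varies one parameter while keeping the others at their
#' defaults: `r` over 0.10 +/- 0.05 mm, `lam` over 1.2 +/- 0.8, and `n_iter`
#' over 150 +/- 100, each on an evenly spaced grid.
#'
#' @param n_values Number of grid points per parameter.
#' @return A named list of numeric grids for `r`, `lam`, `n_iter`.
#' @export
default_sweep_grids <- function(n_values = 5) {
  list(
    r = seq(0.05, 0.15, length.out = n_values),
    lam = seq(0.4, 2.0, length.out = n_values),
    n_iter = as.integer(round(seq(50, 250, length.out = n_values)))
  )
}

#' Parameter sensitivity sweep over a cohort
#'
#' Re-runs a landmarking algorithm on every centerline of a cohort for each
#' value of one preprocessing parameter (`r`, `lam`, or `n_iter`), keeping the
#' others fixed, and reports the cohort mean, SD, and CV of a summary metric
#' per grid value. Algorithm failures at a grid point are recorded per cell
#' (excluded from the statistics), not fatal. Deterministic given its inputs.
#'
#' @param cohort A list of [centerline()] objects.
#' @param parameter `"r"`, `"lam"`, or `"n_iter"`.
#' @param values Grid of parameter values (default: [default_sweep_grids()]).
#' @param fixed A [preprocess_config()] providing the non-swept parameters.
#' @param algorithm `"piccinelli"` or `"bogunovic"`.
#' @param metric,k,label Metric passed to [cohort_summary()].
#' @param ... Extra arguments for the algorithm's config constructor.
#' @return A `sweep_report` tibble with columns `parameter`, `value`, `n`,
#'   `n_failures`, `mean`, `sd`, `cv`.
#' @export
sensitivity_sweep <- function(cohort, parameter = c("r", "lam", "n_iter"),
                              values = NULL, fixed = preprocess_config(),
                              algorithm = c("piccinelli", "bogunovic"),
                              metric = "n_bends", k = 1L, label = "superior", ...) {
  parameter <- match.arg(parameter)
  algorithm <- match.arg(algorithm)
  if (length(cohort) < 1) abort_config("empty cohort")
  if (is.null(values)) values <- default_sweep_grids()[[parameter]]
  stopifnot(inherits(fixed, "preprocess_config"))

  rows <- purrr::map_dfr(values, function(v) {
    pp <- fixed
    pp[[parameter]] <- if (parameter == "n_iter") as.integer(v) else v
    pp <- preprocess_config(r = pp$r, lam = pp$lam, n_iter = pp$n_iter)
    results <- purrr::map(cohort, function(cl) {
      tryCatch(
        suppressWarnings(run_algorithm(cl, algorithm, pp, ...)),
        error = function(e) NULL
      )
    })
    failed <- vapply(results, is.null, logical(1))
    results <- results[!failed]
    xs <- vapply(results, result_metric, numeric(1), metric = metric, k = k, label = label)
    excluded <- sum(is.na(xs))
    xs <- xs[!is.na(xs)]
    if (length(xs) >= 1) {
      mu <- mean(xs)
      s <- if (length(xs) > 1) stats::sd(xs) else 0
      tibble::tibble(parameter = parameter, value = v,
                     n = length(xs), n_failures = sum(failed) + excluded,
                     mean = mu, sd = s, cv = if (mu != 0) s / mu else NA_real_)
    } else {
      tibble::tibble(parameter = parameter, value = v, n = 0L,
                     n_failures = sum(failed) + excluded, mean = NA_real_,
                     sd = NA_real_, cv = NA_real_)
    }
  })
  structure(rows, class = c("sweep_report", class(rows)))
}

run_algorithm <- function(cl, algorithm, preprocess, ...) {
  if (algorithm == "piccinelli") {
    landmark_piccinelli(cl, piccinelli_config(preprocess = preprocess, ...))
  } else {
    landmark_bogunovic(cl, bogunovic_config(preprocess = preprocess, ...))
  }
}

#' Plot a sensitivity sweep report
#'
#' Mean +/- SD of the swept metric, with the CV on a second panel, versus the
#' parameter value.
#'
#' @param object A `sweep_report` from [sensitivity_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sweep_report
#' @export
autoplot.sweep_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  long <- dplyr::bind_rows(
    dplyr::transmute(df, .data$value, panel = "mean +/- sd",
                     y = .data$mean, ymin = .data$mean - .data$sd,
                     ymax = .data$mean + .data$sd),
    dplyr::transmute(df, .data$value, panel = "CV", y = .data$cv,
                     ymin = NA_real_, ymax = NA_real_)
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$value, .data$y)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ymin, ymax = .data$ymax),
                             na.rm = TRUE) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = unique(df$parameter), y = NULL)
}
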