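empty_bend_table <- function() {
  tibble::tibble(
    bend = integer(), label = character(),
    start_arclength = numeric(), peak_arclength = numeric(),
    end_arclength = numeric(), length = numeric()
  )
}

new_landmark_result <- function(algorithm, parameters, bends, interfaces,
                                centerline, failed = FALSE, extra = list()) {
  bends <- tibble::as_tibble(bends)
  if (nrow(bends) > 0) {
    stopifnot(
      all(bends$start_arclength <= bends$peak_arclength + 1e-9),
      all(bends$peak_arclength <= bends$end_arclength + 1e-9),
      !is.unsorted(bends$start_arclength)
    )
    bends$length <- bends$end_arclength - bends$start_arclength
    bends$bend <- seq_len(nrow(bends))
  } else {
    bends <- empty_bend_table()
  }
  structure(
    c(list(
      algorithm = algorithm, parameters = parameters, bends = bends,
      interfaces = as.numeric(interfaces), failed = isTRUE(failed),
      centerline = centerline
    ), extra),
    class = "landmark_result"
  )
}

#' @export
print.landmark_result <- function(x, ...) {
  cat(sprintf("# Landmarking result (%s)%s\n", x$algorithm,
              if (x$failed) " -- FAILED (partial or empty)" else ""))
  cat(sprintf("#   %d bend(s), total bend length %.2f mm, centerline %.2f mm\n",
              nrow(x$bends), sum(x$bends$length), total_length(x$centerline)))
  if (nrow(x$bends) > 0) print(x$bends, ...)
  invisible(x)
}

#' Tidy a landmarking result into its bend table
#'
#' @param x A `landmark_result`.
#' @param ... Unused.
#' @return A tibble with one row per bend: `bend`, `label`,
#'   `start_arclength`, `peak_arclength`, `end_arclength`, `length` (mm).
#' @method tidy landmark_result
#' @export
tidy.landmark_result <- function(x, ...) {
  x$bends
}

#' One-row summary of a landmarking result
#'
#' @param x A `landmark_result`.
#' @param ... Unused.
#' @return A one-row tibble: `algorithm`, `n_bends`, `total_bend_length`,
#'   `landmarked_fraction`, `failed`.
#' @method glance landmark_result
#' @export
glance.landmark_result <- function(x, ...) {
  tibble::tibble(
    algorithm = x$algorithm,
    n_bends = nrow(x$bends),
    total_bend_length = sum(x$bends$length),
    landmarked_fraction = sum(x$bends$length) / total_length(x$centerline),
    failed = x$failed
  )
}

#' Plot a landmarking result over its curvature profile
#'
#' Shows the curvature (and |torsion|) profile of the preprocessed centerline
#' with detected bends shaded and interfaces marked, the standard way of
#' inspecting a landmarking run.
#'
#' @param object A `landmark_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot landmark_result
#' @export
autoplot.landmark_result <- function(object, ...) {
  geo <- compute_geometry(object$centerline)
  prof <- tidyr::pivot_longer(
    tibble::tibble(arclength = geo$arclength, curvature = geo$curvature,
                   `|torsion|` = abs(geo$torsion)),
    -"arclength", names_to = "profile", values_to = "value"
  )
  gg <- ggplot2::ggplot(prof, ggplot2::aes(.data$arclength, .data$value))
  if (nrow(object$bends) > 0) {
    gg <- gg + ggplot2::geom_rect(
      data = object$bends,
      ggplot2::aes(xmin = .data$start_arclength, xmax = .data$end_arclength,
                   fill = .data$label),
      ymin = -Inf, ymax = Inf, alpha = 0.25, inherit.aes = FALSE
    )
  }
  gg +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$interfaces, linetype = "dashed",
                        linewidth = 0.3) +
    ggplot2::facet_wrap(~profile, ncol = 1, scales = "free_y") +
    ggplot2::labs(
      x = "arc length (mm)", y = "1/mm", fill = "bend",
      title = sprintf("%s landmarking: %d bend(s)", object$algorithm,
                      nrow(object$bends))
    )
}
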