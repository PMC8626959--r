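#' Configuration for geometric (torsion-bounded) bend landmarking
#'
#' @param preprocess A [preprocess_config()].
#' @param curvature_prominence,torsion_prominence Prominence fractions (of the
#'   profile range) a curvature / |torsion| extremum must reach to count as a
#'   peak, in `[0, 1]`.
#' @export
piccinelli_config <- function(preprocess = preprocess_config(),
                              curvature_prominence = 0.05,
                              torsion_prominence = 0.05) {
  stopifnot(inherits(preprocess, "preprocess_config"))
  if (curvature_prominence < 0 || curvature_prominence > 1 ||
      torsion_prominence < 0 || torsion_prominence > 1) {
    abort_config("prominence fractions must be in [0, 1]")
  }
  structure(list(preprocess = preprocess,
                 curvature_prominence = curvature_prominence,
                 torsion_prominence = torsion_prominence),
            class = "piccinelli_config")
}

#' Pair curvature peaks with enclosing torsion peaks
#'
#' Core pairing rule of the geometric landmarking algorithm, exposed at the
#' profile level: each curvature peak that has at least one |torsion| peak
#' strictly proximal and one strictly distal defines a bend spanning from the
#' nearest enclosing proximal |torsion| peak to the nearest enclosing distal
#' one. When several curvature peaks share the same enclosing torsion
#' interval, the boundary between their bends is placed at the curvature
#' minimum between consecutive peaks.
#'
#' @param kappa_peaks Integer indices (into `arclengths`) of curvature peaks,
#'   strictly increasing.
#' @param tau_peaks Integer indices of |torsion| peaks, strictly increasing.
#' @param curvature Curvature signal (same length as `arclengths`), used to
#'   locate inter-peak minima.
#' @param arclengths Arc-length coordinate per point (mm).
#' @return A tibble of bends (possibly empty): `start_arclength`,
#'   `peak_arclength`, `end_arclength`.
#' @export
pair_curvature_bends <- function(kappa_peaks, tau_peaks, curvature, arclengths) {
  stopifnot(!is.unsorted(kappa_peaks, strictly = TRUE),
            !is.unsorted(tau_peaks, strictly = TRUE))
  out <- tibble::tibble(start_arclength = numeric(), peak_arclength = numeric(),
                        end_arclength = numeric())
  if (length(kappa_peaks) == 0 || length(tau_peaks) < 2) return(out)
  # Nearest strictly enclosing torsion peak on each side of each curvature
  # peak (indices are integers, so "strictly proximal" means tau <= k - 1).
  pos_prox <- findInterval(kappa_peaks - 1L, tau_peaks)
  pos_dist <- findInterval(kappa_peaks, tau_peaks) + 1L
  enclosed <- pos_prox >= 1L & pos_dist <= length(tau_peaks)
  k <- kappa_peaks[enclosed]
  if (length(k) == 0) return(out)
  lo <- tau_peaks[pos_prox[enclosed]]
  hi <- tau_peaks[pos_dist[enclosed]]

  start_idx <- lo
  end_idx <- hi
  # Consecutive curvature peaks sharing an enclosing torsion interval (or
  # overlapping enclosures, e.g. when a curvature peak falls exactly on a
  # torsion peak) are separated at the inter-peak curvature minimum.
  if (length(k) > 1) {
    for (i in 1:(length(k) - 1)) {
      if (end_idx[i] > start_idx[i + 1]) {
        between <- (k[i] + 1L):(k[i + 1] - 1L)
        cut <- between[which.min(curvature[between])]
        end_idx[i] <- cut
        start_idx[i + 1] <- cut
      }
    }
  }
  tibble::tibble(
    start_arclength = arclengths[start_idx],
    peak_arclength = arclengths[k],
    end_arclength = arclengths[end_idx]
  )
}

#' Landmark geometric bends bounded by torsion peaks
#'
#' Detects one bend per curvature peak enclosed between a proximal and a
#' distal |torsion| peak (the geometric bend definition of Piccinelli and
#' colleagues). The raw centerline is preprocessed internally (resample,
#' Laplacian smoothing, resample), curvature and torsion profiles are
#' computed, extrema are selected by topographic prominence, and curvature
#' peaks are paired with their nearest enclosing torsion peaks via
#' [pair_curvature_bends()]. The number of bends is unbounded and bends carry
#' no anatomical label. With fewer than two |torsion| peaks an empty result is
#' returned with a warning (not an error).
#'
#' @param c An oriented (proximal-first), raw [centerline()].
#' @param config A [piccinelli_config()].
#' @return A `landmark_result`; see [tidy.landmark_result()].
#' @examples
#' sip <- make_siphon(siphon_spec())
#' res <- landmark_piccinelli(sip$centerline)
#' tidy(res)
#' @export
landmark_piccinelli <- function(c, config = piccinelli_config()) {
  stopifnot(inherits(config, "piccinelli_config"))
  cp <- preprocess_centerline(c, config$preprocess)
  geo <- compute_geometry(cp)
  kp <- find_peaks(geo$curvature, config$curvature_prominence, exclude_ends = 2L)
  tp <- find_peaks(abs(geo$torsion), config$torsion_prominence, exclude_ends = 2L)
  params <- list(
    preprocess = unclass(config$preprocess),
    curvature_prominence = config$curvature_prominence,
    torsion_prominence = config$torsion_prominence
  )
  if (nrow(tp) < 2) {
    rlang::warn("fewer than 2 torsion peaks; no bends can be enclosed")
    return(new_landmark_result("piccinelli", params, empty_bend_table(),
                               numeric(), cp, failed = FALSE))
  }
  bends <- pair_curvature_bends(kp$index, tp$index, geo$curvature, geo$arclength)
  if (nrow(bends) > 0) bends$label <- "unlabeled"
  interfaces <- sort(unique(c(bends$start_arclength, bends$end_arclength)))
  new_landmark_result("piccinelli", params, bends, interfaces, cp)
}
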