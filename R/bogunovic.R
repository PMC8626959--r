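#' Configuration for anatomical four-bend landmarking
#'
#' @param preprocess A [preprocess_config()].
#' @param thresholds_deg Interface threshold angles in degrees, consumed in
#'   order from proximal to distal. The default `c(45, 60, 45, 110)` is the
#'   published ICA-specific set; exactly 4 thresholds are required for
#'   anatomical labeling.
#' @param curvature_prominence Prominence fraction for curvature-peak
#'   acceptance, in `[0, 1]`.
#' @param labels Anatomical labels assigned proximal to distal when all
#'   interfaces are found. Set `labels = NULL` (generic mode) to return
#'   unlabeled bends, e.g. with user thresholds for other vessels.
#' @export
bogunovic_config <- function(preprocess = preprocess_config(),
                             thresholds_deg = c(45, 60, 45, 110),
                             curvature_prominence = 0.05,
                             labels = c("inferior", "posterior", "anterior", "superior")) {
  stopifnot(inherits(preprocess, "preprocess_config"))
  if (any(thresholds_deg <= 0) || any(thresholds_deg > 180)) {
    abort_config("threshold angles must be in (0, 180] degrees")
  }
  if (!is.null(labels) && length(labels) != length(thresholds_deg)) {
    abort_config("need exactly one threshold per anatomical label (4 for the ICA)")
  }
  if (curvature_prominence < 0 || curvature_prominence > 1) {
    abort_config("`curvature_prominence` must be in [0, 1]")
  }
  structure(list(preprocess = preprocess, thresholds_deg = thresholds_deg,
                 curvature_prominence = curvature_prominence, labels = labels),
            class = "bogunovic_config")
}

#' Direction trajectory of the curvature vector
#'
#' Converts a parallel-transport frame trace into the trajectory of the
#' curvature vector in the `(k1, k2)` plane: the direction angle
#' `theta = atan2(k2, k1)` (radians, unwrapped along arc length) and the
#' curvature magnitude. Because `E1`/`E2` are parallel-transported, `theta`
#' only changes when the bend plane actually rotates about the vessel axis;
#' where the curvature magnitude falls below `kappa_min` the direction is
#' ill-defined and the last well-defined angle is carried forward.
#'
#' @param frames Output of [compute_parallel_transport()].
#' @param kappa_min Curvature magnitude below which `theta` is frozen (1/mm).
#' @return A tibble with columns `arclength`, `theta` (radians, unwrapped),
#'   `kmag` (1/mm).
#' @export
curvature_vector_trace <- function(frames, kappa_min = 1e-6) {
  stopifnot(all(c("k1", "k2", "arclength") %in% names(frames)))
  kmag <- sqrt(frames$k1^2 + frames$k2^2)
  theta <- atan2(frames$k2, frames$k1)
  defined <- kmag >= kappa_min
  if (!any(defined)) {
    theta <- rep(0, length(theta))
  } else {
    first_def <- which(defined)[1]
    if (first_def > 1) theta[1:(first_def - 1)] <- theta[first_def]
    for (i in seq_along(theta)[-1]) {
      if (!defined[i]) theta[i] <- theta[i - 1]
    }
    theta <- unwrap_angle(theta)
  }
  tibble::tibble(arclength = frames$arclength, theta = theta, kmag = kmag)
}

# Candidate curved segments: one per accepted curvature peak, separated at the
# curvature minimum between consecutive peaks.
candidate_segments <- function(kmag, theta, arclength, prominence) {
  peaks <- find_peaks(kmag, prominence, exclude_ends = 2L)
  n_pk <- nrow(peaks)
  if (n_pk == 0) return(NULL)
  sep <- integer(0)
  if (n_pk > 1) {
    sep <- vapply(seq_len(n_pk - 1), function(i) {
      between <- (peaks$index[i] + 1L):(peaks$index[i + 1] - 1L)
      between[which.min(kmag[between])]
    }, integer(1))
  }
  tibble::tibble(
    peak_index = peaks$index,   # rightmost peak of the (possibly merged) segment
    dom_index = peaks$index,    # dominant (highest-curvature) peak of the segment
    peak_kappa = peaks$value,
    theta_deg = theta[peaks$index] * 180 / pi
  )
}

#' Landmark the four anatomical bends of the carotid siphon
#'
#' Anatomical landmarking driven by the curvature-vector trajectory in the
#' parallel-transport frame (the four-bend subdivision of Bogunovic and
#' colleagues). The centerline is preprocessed, candidate curved segments are
#' delimited by local curvature minima (one curvature peak each), and each
#' candidate is assigned the direction angle `theta` of its curvature peak.
#' Traversing candidates from proximal to distal, an interface is accepted at
#' the curvature minimum between adjacent candidates whenever the angle
#' between their directions (folded to at most 180 degrees) exceeds the
#' current threshold; thresholds (default 45, 60, 45, 110 degrees) are
#' consumed strictly in order, and a candidate failing the current threshold
#' is merged with its predecessor (the merged segment keeps the direction of
#' its dominant curvature peak). With all four interfaces found, the bends
#' between consecutive interfaces are labeled inferior, posterior, anterior,
#' and superior from proximal to distal; the superior bend ends at the first
#' curvature minimum distal to its peak (or the curve end). The regions
#' proximal to the first interface and distal to that end stay unlandmarked,
#' and at most four bends are ever returned, irrespective of vessel length.
#' If fewer interfaces exist the result is partial and flagged as failed.
#'
#' @param c An oriented, proximal-first, raw [centerline()].
#' @param config A [bogunovic_config()].
#' @return A `landmark_result` with a `failed` flag and per-interface
#'   `delta_theta_deg` angles; see [tidy.landmark_result()].
#' @examples
#' sip <- make_siphon(siphon_spec())
#' res <- landmark_bogunovic(sip$centerline)
#' tidy(res)
#' @export
landmark_bogunovic <- function(c, config = bogunovic_config()) {
  stopifnot(inherits(config, "bogunovic_config"))
  if (!is_proximal_first(c)) {
    rlang::warn("centerline orientation unverified; assuming proximal-first (see orient_centerline)")
  }
  cp <- preprocess_centerline(c, config$preprocess)
  frames <- compute_parallel_transport(cp)
  trace <- curvature_vector_trace(frames)
  params <- list(
    preprocess = unclass(config$preprocess),
    thresholds_deg = config$thresholds_deg,
    curvature_prominence = config$curvature_prominence
  )
  cand <- candidate_segments(trace$kmag, trace$theta, trace$arclength,
                             config$curvature_prominence)
  thresholds <- config$thresholds_deg
  n_ifc <- length(thresholds)
  if (is.null(cand) || nrow(cand) < 2) {
    return(new_landmark_result("bogunovic", params, empty_bend_table(),
                               numeric(), cp, failed = TRUE,
                               extra = list(delta_theta_deg = numeric())))
  }

  # Proximal-to-distal traversal with sequential threshold consumption.
  interfaces_idx <- integer(0)
  delta_acc <- numeric(0)
  seg_peaks <- list()  # peak rows of the accepted segments (post-merging)
  cur <- cand[1, ]
  level <- 1L
  for (j in 2:nrow(cand)) {
    nxt <- cand[j, ]
    dtheta <- fold_angle(nxt$theta_deg - cur$theta_deg)
    if (level <= n_ifc && dtheta > thresholds[level]) {
      # Interface at the curvature minimum between the two peaks.
      between <- (cur$peak_index + 1L):(nxt$peak_index - 1L)
      cut <- between[which.min(trace$kmag[between])]
      interfaces_idx <- c(interfaces_idx, cut)
      delta_acc <- c(delta_acc, dtheta)
      seg_peaks[[length(seg_peaks) + 1L]] <- cur
      cur <- nxt
      level <- level + 1L
      if (level > n_ifc) break
    } else {
      # Merge: keep the direction of the dominant curvature peak.
      if (nxt$peak_kappa > cur$peak_kappa) {
        cur$theta_deg <- nxt$theta_deg
        cur$peak_kappa <- nxt$peak_kappa
        cur$dom_index <- nxt$dom_index
      }
      cur$peak_index <- nxt$peak_index
    }
  }
  seg_peaks[[length(seg_peaks) + 1L]] <- cur
  failed <- length(interfaces_idx) < n_ifc

  if (length(interfaces_idx) == 0) {
    return(new_landmark_result("bogunovic", params, empty_bend_table(),
                               numeric(), cp, failed = TRUE,
                               extra = list(delta_theta_deg = numeric())))
  }

  # Bends lie between consecutive interfaces; the last accepted segment ends
  # at the curvature minimum between its peak and the next detected curvature
  # peak (robust to sub-resolution ripple), or at the curve end.
  last_seg <- seg_peaks[[length(seg_peaks)]]
  end_idx <- distal_minimum(trace$kmag, last_seg$dom_index,
                            next_peak = cand$peak_index[cand$peak_index > last_seg$peak_index][1])
  bounds <- c(interfaces_idx, end_idx)
  labels <- if (is.null(config$labels)) {
    rep("unlabeled", length(bounds) - 1L)
  } else {
    config$labels[seq_len(length(bounds) - 1L)]
  }
  bend_peaks <- vapply(seg_peaks[-1], function(s) s$dom_index, numeric(1))
  bends <- tibble::tibble(
    label = labels,
    start_arclength = trace$arclength[bounds[-length(bounds)]],
    peak_arclength = trace$arclength[bend_peaks],
    end_arclength = trace$arclength[bounds[-1]]
  )
  new_landmark_result("bogunovic", params, bends,
                      interfaces = trace$arclength[bounds], centerline = cp,
                      failed = failed,
                      extra = list(delta_theta_deg = delta_acc))
}

# Curvature minimum distal to index `from`: the argmin between `from` and the
# next detected peak when one exists, otherwise the argmin of the remaining
# tail (falling back to the curve end for degenerate tails). An argmin is
# used rather than the first strict local minimum, which sub-resolution
# ripple on an otherwise monotone descent would trigger prematurely.
distal_minimum <- function(signal, from, next_peak = NA_integer_) {
  n <- length(signal)
  if (from >= n - 1) return(n)
  hi <- if (!is.na(next_peak) && next_peak > from + 1L) next_peak - 1L else n
  window <- (from + 1L):hi
  window[which.min(signal[window])]
}
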