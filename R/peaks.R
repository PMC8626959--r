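#' Local maxima of a 1D signal filtered by topographic prominence
#'
#' Finds interior local maxima (plateaus are collapsed and report their
#' midpoint) and keeps those whose topographic prominence is at least
#' `min_prominence_frac` times the signal range. The prominence of a peak is
#' its height minus the higher of the two minima separating it from the
#' nearest higher ground on each side (or from the signal end). Endpoints are
#' never peaks; a constant signal yields an empty result.
#'
#' @param signal Numeric vector (length >= 3).
#' @param min_prominence_frac Fraction of the signal range (`max - min`) a
#'   peak's prominence must reach, in `[0, 1]`.
#' @param exclude_ends Number of points at each end that are ineligible as
#'   peaks (and excluded from the range used for the prominence threshold).
#'   The derivative stencils are one-sided and noisy there; the landmarking
#'   pipeline uses 2.
#' @return A tibble with columns `index` (1-based position in `signal`),
#'   `value`, and `prominence`, ordered by increasing index.
#' @examples
#' find_peaks(c(0, 1, 0, 2, 0), min_prominence_frac = 0.1)
#' @export
find_peaks <- function(signal, min_prominence_frac = 0.05, exclude_ends = 0L) {
  if (length(signal) < 3) abort_config("`signal` must have at least 3 values")
  if (anyNA(signal)) abort_config("`signal` must not contain NA")
  if (min_prominence_frac < 0 || min_prominence_frac > 1) {
    abort_config("`min_prominence_frac` must be in [0, 1]")
  }
  exclude_ends <- as.integer(exclude_ends)
  n <- length(signal)

  # Collapse plateaus: run-length encode the signal.
  r <- rle(signal)
  vals <- r$values
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mids <- as.integer((starts + ends) %/% 2)
  m <- length(vals)
  empty <- tibble::tibble(index = integer(), value = numeric(), prominence = numeric())
  if (m < 3) return(empty)

  is_max <- c(FALSE, vals[2:(m - 1)] > vals[1:(m - 2)] & vals[2:(m - 1)] > vals[3:m], FALSE)
  peak_runs <- which(is_max)
  if (length(peak_runs) == 0) return(empty)

  prominence <- vapply(peak_runs, function(k) {
    h <- vals[k]
    left <- vals[1:(k - 1)]
    higher_l <- which(left > h)
    lo_l <- min(left[if (length(higher_l)) (max(higher_l) + 1L):(k - 1L) else 1:(k - 1L)])
    right <- vals[(k + 1):m]
    higher_r <- which(right > h)
    lo_r <- min(right[if (length(higher_r)) 1:(min(higher_r) - 1L) else seq_along(right)])
    h - max(lo_l, lo_r)
  }, numeric(1))

  lo <- 1L + exclude_ends
  hi <- n - exclude_ends
  if (hi - lo < 2) return(empty)
  rng <- diff(range(signal[lo:hi]))
  # The resample/differentiate machinery carries O(1e-4..1e-3) relative
  # ripple even on analytically constant profiles; a signal whose total
  # variation sits at that floor is constant for landmarking purposes and
  # has no peaks (real bends vary by order-1 relative amounts).
  if (rng <= 1e-3 * max(abs(signal[lo:hi]))) return(empty)
  keep <- prominence >= min_prominence_frac * rng & rng > 0 &
    mids[peak_runs] > lo & mids[peak_runs] < hi
  tibble::tibble(
    index = mids[peak_runs][keep],
    value = vals[peak_runs][keep],
    prominence = prominence[keep]
  )
}

#' Local minima of a 1D signal
#'
#' Equivalent to [find_peaks()] applied to the negated signal; used for the
#' curvature minima that separate adjacent bends.
#'
#' @inheritParams find_peaks
#' @return A tibble with columns `index`, `value`, `prominence`.
#' @export
find_minima <- function(signal, min_prominence_frac = 0.05, exclude_ends = 0L) {
  res <- find_peaks(-signal, min_prominence_frac, exclude_ends)
  res$value <- -res$value
  res
}

#' Count curvature and torsion peaks across resampling spacings
#'
#' For each spacing `r`, the centerline is preprocessed
#' (resample, smooth, resample) and peaks of the curvature and
#' absolute-torsion profiles are counted. Plotting the counts against `r`
#' (log-log) shows how strongly the centerline resolution drives the number
#' of detected extrema, and hence bends.
#'
#' Unlike the landmarking algorithms (which filter extrema by prominence,
#' default 0.05), this analysis counts all interior profile extrema by
#' default (`min_prominence_frac = 0`): a range-relative prominence threshold
#' would make the counts incomparable across resolutions, because the profile
#' range itself varies by orders of magnitude with `r` on noisy centerlines.
#'
#' @param c A [centerline()].
#' @param r_values Spacings to evaluate (mm, each < total length).
#' @param lam,n_iter Smoothing parameters held fixed across the sweep.
#' @param min_prominence_frac Prominence fraction for peak acceptance.
#' @return A tibble with columns `r`, `n_curvature_peaks`, `n_torsion_peaks`.
#' @export
count_peaks <- function(c, r_values, lam = 1.2, n_iter = 100L,
                        min_prominence_frac = 0) {
  purrr::map_dfr(r_values, function(r) {
    cp <- preprocess_centerline(c, preprocess_config(r = r, lam = lam, n_iter = n_iter))
    geo <- compute_geometry(cp)
    tibble::tibble(
      r = r,
      n_curvature_peaks = nrow(find_peaks(geo$curvature, min_prominence_frac, exclude_ends = 2L)),
      n_torsion_peaks = nrow(find_peaks(abs(geo$torsion), min_prominence_frac, exclude_ends = 2L))
    )
  })
}
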