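# Shared fixtures, built in code and cached across test files (preprocessing
# plus landmarking costs ~0.5 s per siphon).

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

helix_10_3 <- function() cached("helix_10_3", make_helix(a = 10, b = 3, n_turns = 2, spacing = 0.1))

canonical_siphon <- function() cached("canonical_siphon", make_siphon(siphon_spec()))

canonical_bogunovic <- function() {
  cached("canonical_bogunovic", landmark_bogunovic(canonical_siphon()$centerline))
}

canonical_piccinelli <- function() {
  cached("canonical_piccinelli", landmark_piccinelli(canonical_siphon()$centerline))
}

noisy_cohort <- function(seeds = 1:10, sigma = 0.1) {
  cached(paste0("cohort_", sigma, "_", paste(range(seeds), collapse = "_")), {
    lapply(seeds, function(s) {
      add_noise(make_siphon(random_siphon_spec(s))$centerline, sigma, seed = s)
    })
  })
}

# Interior index range (excludes the stencil-affected ends).
interior <- function(c, margin = 10) margin:(nrow(c) - margin)

# Brute-force topographic prominence oracle: enumerate all strict interior
# local maxima of the plateau-collapsed signal, then compute each prominence
# by direct definition (min between the peak and the nearest higher ground on
# each side, or the signal end) and filter. Mirrors find_peaks' documented
# semantics with independent, naive code.
oracle_peaks <- function(signal, frac, exclude_ends = 0L) {
  r <- rle(signal)
  vals <- r$values
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  mids <- as.integer((starts + ends) %/% 2)
  m <- length(vals)
  n <- length(signal)
  lo <- 1L + exclude_ends
  hi <- n - exclude_ends
  out <- data.frame(index = integer(), value = numeric(), prominence = numeric())
  if (m < 3 || hi - lo < 2) return(out)
  rng <- diff(range(signal[lo:hi]))
  if (rng <= 1e-3 * max(abs(signal[lo:hi]))) return(out)
  for (k in 2:(m - 1)) {
    if (!(vals[k] > vals[k - 1] && vals[k] > vals[k + 1])) next
    h <- vals[k]
    i <- k - 1L; lo_l <- h
    while (i >= 1 && vals[i] <= h) { lo_l <- min(lo_l, vals[i]); i <- i - 1L }
    i <- k + 1L; lo_r <- h
    while (i <= m && vals[i] <= h) { lo_r <- min(lo_r, vals[i]); i <- i + 1L }
    prom <- h - max(lo_l, lo_r)
    if (prom >= frac * rng && mids[k] > lo && mids[k] < hi) {
      out <- rbind(out, data.frame(index = mids[k], value = h, prominence = prom))
    }
  }
  out
}

# Exhaustive pairing oracle for the geometric bend definition: for every
# curvature peak enumerate ALL (proximal, distal) torsion-peak pairs, keep
# peaks with at least one enclosing pair, pick the nearest pair, then walk
# consecutive bends and cut any overlap at the inter-peak curvature minimum.
oracle_pairing <- function(kappa_peaks, tau_peaks, curvature, arclengths) {
  rows <- list()
  for (k in kappa_peaks) {
    best <- NULL
    for (ti in tau_peaks) for (tj in tau_peaks) {
      if (ti < k && tj > k) {
        if (is.null(best) ||
            ti > best[1] ||
            (ti == best[1] && tj < best[2])) {
          best <- c(ti, tj)
        }
      }
    }
    if (!is.null(best)) rows[[length(rows) + 1L]] <- c(best[1], k, best[2])
  }
  if (length(rows) == 0) {
    return(data.frame(start = numeric(), peak = numeric(), end = numeric()))
  }
  mat <- do.call(rbind, rows)
  if (nrow(mat) > 1) {
    for (i in 1:(nrow(mat) - 1)) {
      if (mat[i, 3] > mat[i + 1, 1]) {
        between <- (mat[i, 2] + 1L):(mat[i + 1, 2] - 1L)
        cut <- between[which.min(curvature[between])]
        mat[i, 3] <- cut
        mat[i + 1, 1] <- cut
      }
    }
  }
  data.frame(start = arclengths[mat[, 1]], peak = arclengths[mat[, 2]],
             end = arclengths[mat[, 3]])
}

# Random synthetic profile (peak index sets plus a curvature signal) for
# pairing-oracle comparisons.
random_profile <- function(seed, n = 200) {
  set.seed(seed)
  kappa <- abs(stats::rnorm(n)) + 0.05
  k_peaks <- sort(sample(5:(n - 5), sample(1:8, 1)))
  t_peaks <- sort(sample(3:(n - 3), sample(2:10, 1)))
  # Peak index sets must be strictly increasing and distinct within each set.
  list(kappa = kappa, k_peaks = unique(k_peaks), t_peaks = unique(t_peaks),
       arclengths = seq_len(n) * 0.1)
}
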