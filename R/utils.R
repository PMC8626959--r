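# Condition helpers: distinct classes let the command-line wrapper map
# I/O problems and bad configuration to distinct exit codes.

abort_io <- function(msg) rlang::abort(msg, class = "bendmark_io_error")
abort_config <- function(msg) rlang::abort(msg, class = "bendmark_config_error")

# Fold an angle difference (degrees) into [0, 180].
fold_angle <- function(deg) {
  a <- abs(deg) %% 360
  ifelse(a > 180, 360 - a, a)
}

# Unwrap a sequence of angles (radians) so consecutive differences lie in
# (-pi, pi].
unwrap_angle <- function(theta) {
  if (length(theta) < 2) return(theta)
  d <- diff(theta)
  jump <- round(d / (2 * pi))
  theta - c(0, cumsum(jump)) * 2 * pi
}

norm3 <- function(v) sqrt(sum(v * v))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Row-wise cross product of n-by-3 matrices.
cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

row_norms <- function(m) sqrt(rowSums(m * m))
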