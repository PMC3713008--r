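# Internal numeric helpers shared across modules.

# Trapezoidal integral of y sampled at unit spacing (time indices).
trapz_unit <- function(y) {
  n <- length(y)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2)
}

# Cumulative trapezoidal integral at unit spacing; first element is 0.
cumtrapz_unit <- function(y) {
  n <- length(y)
  if (n < 2L) return(rep(0, n))
  c(0, cumsum((y[-1] + y[-n]) / 2))
}

# Sum of m over every w x w window fully inside the image, via a 2D
# summed-area table. Returns an (nr - w + 1) x (nc - w + 1) matrix.
box_sum <- function(m, w) {
  p <- matrix(0, nrow(m) + 1L, ncol(m) + 1L)
  p[-1L, -1L] <- t(apply(apply(m, 2L, cumsum), 1L, cumsum))
  nr <- nrow(m) - w + 1L
  nc <- ncol(m) - w + 1L
  p[(w + 1L):(nrow(m) + 1L), (w + 1L):(ncol(m) + 1L), drop = FALSE] -
    p[1L:nr, (w + 1L):(ncol(m) + 1L), drop = FALSE] -
    p[(w + 1L):(nrow(m) + 1L), 1L:nc, drop = FALSE] +
    p[1L:nr, 1L:nc, drop = FALSE]
}

is_odd <- function(x) (x %% 2L) == 1L

# Format a numeric scalar/vector for the TSV reports: 12 significant digits,
# NA as the literal "NA". Stable under write -> read -> write.
format_report_number <- function(x) {
  out <- ifelse(is.na(x), "NA", sprintf("%.12g", x))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
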