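# Independent oracles used across the suite. These deliberately use naive
# algorithms (explicit loops, full enumeration) so they share no code with
# the implementation they check.

# Naive per-voxel double-loop local moments (population convention).
brute_force_moments <- function(image, w) {
  h <- (w - 1L) %/% 2L
  nr <- nrow(image); nc <- ncol(image)
  mk <- function() matrix(NA_real_, nr, nc)
  out <- list(mean = mk(), m2 = mk(), m3 = mk(), m4 = mk())
  for (i in (h + 1L):(nr - h)) {
    for (j in (h + 1L):(nc - h)) {
      v <- as.vector(image[(i - h):(i + h), (j - h):(j + h)])
      mu <- sum(v) / length(v)
      d <- v - mu
      out$mean[i, j] <- mu
      out$m2[i, j] <- sum(d^2) / length(v)
      out$m3[i, j] <- sum(d^3) / length(v)
      out$m4[i, j] <- sum(d^4) / length(v)
    }
  }
  out
}

# Scalar even-odd ray-casting point-in-polygon with boundary inclusion,
# evaluated one point at a time.
pip_oracle_point <- function(pr, pc, verts) {
  n <- nrow(verts)
  inside <- FALSE
  eps <- 1e-9
  j <- n
  for (i in seq_len(n)) {
    r1 <- verts[j, 1]; c1 <- verts[j, 2]
    r2 <- verts[i, 1]; c2 <- verts[i, 2]
    # boundary check
    dr <- r2 - r1; dc <- c2 - c1
    len2 <- dr^2 + dc^2
    if (len2 > 0) {
      tt <- ((pr - r1) * dr + (pc - c1) * dc) / len2
      if (tt > -eps && tt < 1 + eps) {
        perp <- abs((pr - r1) * dc - (pc - c1) * dr) / sqrt(len2)
        if (perp < eps) return(TRUE)
      }
    } else if (abs(pr - r1) < eps && abs(pc - c1) < eps) {
      return(TRUE)
    }
    if ((r1 > pr) != (r2 > pr)) {
      cx <- c1 + (pr - r1) / (r2 - r1) * (c2 - c1)
      if (pc < cx) inside <- !inside
    }
    j <- i
  }
  inside
}

# Exact two-sided rank-sum p-value by full enumeration of group assignments.
wilcox_enum_oracle <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  na <- length(a)
  w_obs <- sum(r[seq_len(na)])
  combos <- utils::combn(length(pooled), na)
  w_all <- apply(combos, 2L, function(ix) sum(r[ix]))
  tol <- 1e-9
  min(1, 2 * min(mean(w_all <= w_obs + tol), mean(w_all >= w_obs - tol)))
}

# Step-up FDR reference via stats::p.adjust.
bh_oracle <- function(p) stats::p.adjust(p, method = "BH")

# Small phantom configuration for fast unit tests: fewer regions, smaller
# grid, same tissue model.
small_effect_config <- function(seed = 1L, ...) {
  phantom_effect_config(seed = seed, grid = c(1L, 64L, 64L),
                        n_nawm = 5L, n_el = 5L, n_nel = 5L, ...)
}

small_null_config <- function(seed = 1L, ...) {
  phantom_null_config(seed = seed, grid = c(1L, 64L, 64L),
                      n_nawm = 5L, n_el = 5L, n_nel = 5L, ...)
}

# Constant-in-time test series.
constant_series <- function(value = 100, n_time = 8L, slices = 1L,
                            rows = 8L, cols = 8L) {
  dsce_series(array(value, dim = c(n_time, slices, rows, cols)),
              te_ms = 47, tr_ms = 1440)
}

full_mask_toi <- function(label, tissue_class, slices, rows, cols) {
  toi(label, tissue_class, array(TRUE, dim = c(slices, rows, cols)))
}
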