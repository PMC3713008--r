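# Sliding-kernel histogram texture parameter maps (TPMs).
#
# All kernel maps use population (divide-by-n) central moments over a w x w
# in-plane neighbourhood; kernels never cross slice boundaries (slices are
# 5 mm thick, so through-plane neighbourhoods would be strongly anisotropic).
# The border band of half-width (w-1)/2 is marked invalid rather than padded.

#' Local central moments over a sliding square kernel
#'
#' For every voxel whose `w x w` neighbourhood lies fully inside the image,
#' computes the neighbourhood mean and the population central moments
#' `m_r = mean((v - mean)^r)` for orders 2, 3 and 4. Implemented with summed-area
#' tables on globally centred powers, so it is exact up to floating point and
#' fast for any kernel size.
#'
#' @param image Numeric matrix (one slice at one time point).
#' @param w Odd kernel side length, `3 <= w <= min(dim(image))`.
#' @return List of matrices `mean`, `m2`, `m3`, `m4` (same shape as `image`,
#'   `NA` on the invalid border) and the logical `valid` mask.
#' @examples
#' img <- matrix(1:9, 3, 3, byrow = TRUE)
#' local_moments(img, 3)$m2[2, 2]  # 20/3
#' @export
local_moments <- function(image, w) {
  stopifnot(is.matrix(image))
  w <- as.integer(w)
  if (!is_odd(w) || w < 3L) stop("kernel side `w` must be odd and >= 3")
  if (w > min(dim(image))) stop("kernel larger than the image")
  h <- (w - 1L) %/% 2L
  n <- as.numeric(w) * w
  mu0 <- mean(image)
  x <- image - mu0  # global centring keeps the power sums well conditioned
  s1 <- box_sum(x, w) / n
  s2 <- box_sum(x * x, w) / n
  s3 <- box_sum(x * x * x, w) / n
  s4 <- box_sum(x * x * x * x, w) / n
  m2 <- s2 - s1^2
  m3 <- s3 - 3 * s1 * s2 + 2 * s1^3
  m4 <- s4 - 4 * s1 * s3 + 6 * s1^2 * s2 - 3 * s1^4
  m2 <- pmax(m2, 0)
  nr <- nrow(image); nc <- ncol(image)
  embed <- function(core) {
    out <- matrix(NA_real_, nr, nc)
    out[(h + 1L):(nr - h), (h + 1L):(nc - h)] <- core
    out
  }
  valid <- matrix(FALSE, nr, nc)
  valid[(h + 1L):(nr - h), (h + 1L):(nc - h)] <- TRUE
  list(mean = embed(s1 + mu0), m2 = embed(m2), m3 = embed(m3),
       m4 = embed(m4), valid = valid)
}

# Default degeneracy threshold on the local variance below which skewness and
# kurtosis are undefined: 1e-12 * (dynamic range)^2, with a tiny floor.
default_degeneracy_eps <- function(values) {
  rng <- diff(range(values[is.finite(values)]))
  max(1e-12 * rng^2, .Machine$double.eps)
}

# Compute one slice-level 2D map for a kernel-derived TPM type.
kernel_map_2d <- function(image, tpm_type, w, eps, vava_mode = "two_pass") {
  lm <- local_moments(image, w)
  switch(tpm_type,
    AVER = list(map = lm$mean, valid = lm$valid),
    VARI = list(map = lm$m2, valid = lm$valid),
    STDEV = list(map = sqrt(lm$m2), valid = lm$valid),
    SKEW = {
      bad <- !lm$valid | (lm$m2 <= eps)
      map <- ifelse(bad, NA_real_, lm$m3 / lm$m2^1.5)
      list(map = map, valid = !bad)
    },
    KURT = {
      bad <- !lm$valid | (lm$m2 <= eps)
      map <- ifelse(bad, NA_real_, lm$m4 / lm$m2^2 - 3)
      list(map = map, valid = !bad)
    },
    VAVA = {
      if (vava_mode == "closed_form") {
        map <- lm$m4 - lm$m2^2
        list(map = ifelse(lm$valid, map, NA_real_), valid = lm$valid)
      } else {
        # second pass: the local variance of the local-variance map
        h <- (w - 1L) %/% 2L
        nr <- nrow(image); nc <- ncol(image)
        core <- lm$m2[(h + 1L):(nr - h), (h + 1L):(nc - h), drop = FALSE]
        if (min(dim(core)) < w)
          stop("image too small for the two-pass variance-of-variance map")
        lm2 <- local_moments(core, w)
        map <- matrix(NA_real_, nr, nc)
        valid <- matrix(FALSE, nr, nc)
        map[(2L * h + 1L):(nr - 2L * h), (2L * h + 1L):(nc - 2L * h)] <-
          lm2$m2[(h + 1L):(nrow(core) - h), (h + 1L):(ncol(core) - h)]
        valid[(2L * h + 1L):(nr - 2L * h), (2L * h + 1L):(nc - 2L * h)] <- TRUE
        list(map = map, valid = valid)
      }
    },
    stop("unknown TPM type: ", tpm_type))
}

#' Compute one texture parameter map series
#'
#' Derives a time-resolved texture parameter map (TPM) from the difference
#' image series. The eight types are: `ORIG` (coil-normalized raw signal,
#' supplied separately via [compute_all_tpms()]), `DIFF` (the difference
#' series itself), and six kernel maps computed per slice and time point over
#' a sliding `w x w` neighbourhood of the difference image: `AVER` (local
#' mean), `VARI` (local population variance), `STDEV` (its square root),
#' `SKEW` (`m3 / m2^1.5`), `KURT` (excess kurtosis `m4 / m2^2 - 3`, zero for
#' Gaussian intensities), and `VAVA` (variance-of-variance: the local
#' variance of the `VARI` map, computed as a second pass with the same
#' kernel; unlike `VARI` it is not an edge detector).
#'
#' `SKEW` and `KURT` are marked invalid where the local variance falls below
#' `degeneracy_eps` (near-constant neighbourhoods, e.g. noise-free baseline
#' difference images). The two-pass `VAVA` map has an invalid border band of
#' width `w - 1`; the within-kernel closed form `m4 - m2^2` is available via
#' `vava_mode = "closed_form"`.
#'
#' @param diff A `difference_series`.
#' @param tpm_type One of `"DIFF"`, `"AVER"`, `"VARI"`, `"STDEV"`, `"SKEW"`,
#'   `"KURT"`, `"VAVA"`.
#' @param kernel Odd kernel side length in voxels (default 3).
#' @param degeneracy_eps Local-variance threshold below which skewness and
#'   kurtosis are invalid; default `1e-12 * (dynamic range)^2`.
#' @param vava_mode `"two_pass"` (default) or `"closed_form"`.
#' @return A `tpm_series`: list with `tpm_type`, `values` (4D array), `kernel`
#'   and `valid` (4D logical).
#' @export
compute_tpm <- function(diff, tpm_type, kernel = 3L, degeneracy_eps = NULL,
                        vava_mode = c("two_pass", "closed_form")) {
  stopifnot(inherits(diff, "difference_series"))
  vava_mode <- match.arg(vava_mode)
  tpm_type <- match.arg(tpm_type, setdiff(TPM_TYPES, "ORIG"))
  d <- dim(diff$diff)
  if (tpm_type == "DIFF") {
    return(structure(list(tpm_type = "DIFF", values = diff$diff,
                          kernel = NA_integer_,
                          valid = array(TRUE, dim = d)),
                     class = "tpm_series"))
  }
  kernel <- as.integer(kernel)
  eps <- degeneracy_eps %||% default_degeneracy_eps(diff$diff)
  values <- array(NA_real_, dim = d)
  valid <- array(FALSE, dim = d)
  for (k in seq_len(d[1])) {
    for (s in seq_len(d[2])) {
      img <- matrix(diff$diff[k, s, , ], d[3], d[4])
      res <- kernel_map_2d(img, tpm_type, kernel, eps, vava_mode)
      values[k, s, , ] <- res$map
      valid[k, s, , ] <- res$valid
    }
  }
  structure(list(tpm_type = tpm_type, values = values, kernel = kernel,
                 valid = valid),
            class = "tpm_series")
}

#' @export
print.tpm_series <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<tpm_series> %s, kernel %s, %d time points, %d slice(s), %d x %d voxels (%.1f%% valid)\n",
              x$tpm_type, ifelse(is.na(x$kernel), "-", x$kernel),
              d[1], d[2], d[3], d[4], 100 * mean(x$valid)))
  invisible(x)
}

#' Compute all eight texture parameter maps
#'
#' `ORIG` is the coil-normalized raw signal as-is, `DIFF` the (cardiac-
#' normalized) difference series as-is; the six kernel maps are derived from
#' `DIFF` with one shared kernel.
#'
#' @param series The coil-normalized [dsce_series] (source of `ORIG`).
#' @param diff The normalized `difference_series`.
#' @inheritParams compute_tpm
#' @return Named list of eight `tpm_series`, in canonical order
#'   `ORIG, DIFF, AVER, VARI, STDEV, SKEW, KURT, VAVA`.
#' @export
compute_all_tpms <- function(series, diff, kernel = 3L, degeneracy_eps = NULL,
                             vava_mode = c("two_pass", "closed_form")) {
  stopifnot(inherits(series, "dsce_series"))
  if (!identical(dim(series$signal), dim(diff$diff)))
    stop("`series` and `diff` are not aligned")
  vava_mode <- match.arg(vava_mode)
  orig <- structure(list(tpm_type = "ORIG", values = series$signal,
                         kernel = NA_integer_,
                         valid = array(TRUE, dim = dim(series$signal))),
                    class = "tpm_series")
  eps <- degeneracy_eps %||% default_degeneracy_eps(diff$diff)
  kernel <- as.integer(kernel)
  d <- dim(diff$diff)
  derived <- c("AVER", "VARI", "STDEV", "SKEW", "KURT", "VAVA")
  vals <- lapply(derived, function(tt) array(NA_real_, dim = d))
  names(vals) <- derived
  valids <- lapply(derived, function(tt) array(FALSE, dim = d))
  names(valids) <- derived
  # one moments pass per frame feeds all six kernel maps
  for (k in seq_len(d[1])) {
    for (s in seq_len(d[2])) {
      img <- matrix(diff$diff[k, s, , ], d[3], d[4])
      lm <- local_moments(img, kernel)
      bad <- !lm$valid | (lm$m2 <= eps)
      frame <- list(
        AVER = list(map = lm$mean, valid = lm$valid),
        VARI = list(map = lm$m2, valid = lm$valid),
        STDEV = list(map = sqrt(lm$m2), valid = lm$valid),
        SKEW = list(map = ifelse(bad, NA_real_, lm$m3 / lm$m2^1.5), valid = !bad),
        KURT = list(map = ifelse(bad, NA_real_, lm$m4 / lm$m2^2 - 3), valid = !bad),
        VAVA = kernel_map_2d(img, "VAVA", kernel, eps, vava_mode))
      for (tt in derived) {
        vals[[tt]][k, s, , ] <- frame[[tt]]$map
        valids[[tt]][k, s, , ] <- frame[[tt]]$valid
      }
    }
  }
  maps <- lapply(derived, function(tt)
    structure(list(tpm_type = tt, values = vals[[tt]], kernel = kernel,
                   valid = valids[[tt]]),
              class = "tpm_series"))
  names(maps) <- derived
  diff_map <- structure(list(tpm_type = "DIFF", values = diff$diff,
                             kernel = NA_integer_,
                             valid = array(TRUE, dim = d)),
                        class = "tpm_series")
  c(list(ORIG = orig, DIFF = diff_map), maps)
}
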