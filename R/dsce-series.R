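#' DSCE-MRI image time series
#'
#' Container for a 4D dynamic susceptibility contrast enhanced (DSCE) MRI
#' acquisition. The signal array is stored with a fixed internal axis order
#' `(time, slice, row, col)`; all readers normalise to this convention so that
#' every downstream kernel and statistic can rely on it.
#'
#' @param signal 4D numeric array, axis order `(time, slice, row, col)`.
#'   Values must be finite and non-negative (scanner units are arbitrary).
#' @param te_ms Echo time in milliseconds (required, `> 0`).
#' @param tr_ms Repetition time (time resolution) in milliseconds (`> 0`).
#' @param voxel_size_mm Numeric triple, voxel edge lengths in mm.
#' @param field_strength_T Main field strength in Tesla.
#' @param provenance Free-text description of where the data came from.
#'
#' @return An object of class `dsce_series`: a list with elements `signal`,
#'   `n_time`, `te_ms`, `tr_ms`, `voxel_size_mm`, `field_strength_T`,
#'   `provenance`.
#' @examples
#' sig <- array(100, dim = c(8, 1, 6, 6))
#' s <- dsce_series(sig, te_ms = 47, tr_ms = 1440)
#' s$n_time
#' @export
dsce_series <- function(signal, te_ms, tr_ms,
                        voxel_size_mm = c(1.8, 1.8, 5),
                        field_strength_T = 1.5,
                        provenance = "unspecified") {
  if (!is.array(signal) || length(dim(signal)) != 4L)
    stop("`signal` must be a 4D array with axes (time, slice, row, col)")
  if (dim(signal)[1] < 4L)
    stop("a DSCE series needs at least 4 time points")
  if (!all(is.finite(signal)))
    stop("`signal` must be finite everywhere")
  if (any(signal < 0))
    stop("`signal` must be non-negative")
  if (!is.numeric(te_ms) || length(te_ms) != 1L || !is.finite(te_ms) || te_ms <= 0)
    stop("echo time required: `te_ms` must be a positive number")
  if (!is.numeric(tr_ms) || length(tr_ms) != 1L || !is.finite(tr_ms) || tr_ms <= 0)
    stop("repetition time required: `tr_ms` must be a positive number")
  structure(
    list(signal = signal,
         n_time = dim(signal)[1],
         te_ms = te_ms,
         tr_ms = tr_ms,
         voxel_size_mm = voxel_size_mm,
         field_strength_T = field_strength_T,
         provenance = provenance),
    class = "dsce_series")
}

#' @export
print.dsce_series <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("<dsce_series> %d time points, %d slice(s), %d x %d voxels\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  TE %g ms, TR %g ms, %g T (%s)\n",
              x$te_ms, x$tr_ms, x$field_strength_T, x$provenance))
  invisible(x)
}

#' @export
dim.dsce_series <- function(x) dim(x$signal)

spatial_dim <- function(series) dim(series$signal)[-1L]
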