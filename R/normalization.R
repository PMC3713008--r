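# Difference images and the twofold normalization: RF-coil-load region
# normalization on the raw series, and cardiac-output area-under-curve
# normalization on the difference series.

#' Coil-load normalization
#'
#' Differences in RF-coil load (field strength, head size, positioning) scale
#' the raw voxel intensities between examinations. The correction fixes the
#' mean baseline intensity of a user-defined reference region — conventionally
#' drawn in normal-appearing white matter on the first baseline image — to an
#' ideal value `c_ideal`: every voxel of every time point is divided by
#' `f = mean(region at baseline) / c_ideal`.
#'
#' @param series A [dsce_series].
#' @param region Reference [toi] (drawn in NAWM).
#' @param c_ideal Target mean intensity for the reference region (default
#'   100, arbitrary units; the choice cancels out of all group statistics
#'   because every tissue shares the factor).
#' @param baseline_index Time index of the baseline image (1-based).
#' @return A list with `series` (the normalized [dsce_series]) and `state`, a
#'   `normalization_state` carrying `coil_factor` and `c_ideal`.
#' @examples
#' ph <- simulate_phantom(phantom_null_config(seed = 1))
#' ref <- ph$truth$reference_toi
#' norm <- coil_load_normalize(ph$series, ref)
#' norm$state$coil_factor
#' @export
coil_load_normalize <- function(series, region, c_ideal = 100,
                                baseline_index = 1L) {
  stopifnot(inherits(series, "dsce_series"), inherits(region, "toi"))
  if (c_ideal <= 0) stop("`c_ideal` must be positive")
  mask <- toi_mask_on_grid(region, spatial_dim(series))
  base <- series$signal[baseline_index, , , ][mask]
  mu <- mean(base)
  if (!is.finite(mu) || mu <= 0) stop("degenerate reference region")
  f <- mu / c_ideal
  out <- series
  out$signal <- series$signal / f
  state <- structure(
    list(coil_factor = f, c_ideal = c_ideal, auc_factor = NA_real_,
         auc_ref = NA_real_, reference_region = region$label),
    class = "normalization_state")
  list(series = out, state = state)
}

#' Baseline-difference image series
#'
#' Subtracts each time point from the first steady-state image:
#' `diff_k = signal_baseline - signal_k`. With an intact blood-brain barrier,
#' larger values mean more susceptibility-induced signal drop, i.e. more
#' contrast agent in the voxel; negative values mean enhancement above
#' baseline, the signature of contrast leakage through a disrupted barrier.
#'
#' @inheritParams coil_load_normalize
#' @return A `difference_series`: list with `diff` (4D array, same shape as
#'   the signal), `baseline_index`, and `meta` (series metadata without the
#'   signal).
#' @export
compute_difference_series <- function(series, baseline_index = 1L) {
  stopifnot(inherits(series, "dsce_series"))
  n <- series$n_time
  if (baseline_index < 1L || baseline_index > n)
    stop("`baseline_index` out of range")
  base <- series$signal[baseline_index, , , , drop = FALSE]
  d <- series$signal
  for (k in seq_len(n)) d[k, , , ] <- base[1L, , , ] - d[k, , , ]
  meta <- series[setdiff(names(series), "signal")]
  structure(list(diff = d, baseline_index = baseline_index, meta = meta),
            class = "difference_series")
}

#' @export
print.difference_series <- function(x, ...) {
  d <- dim(x$diff)
  cat(sprintf("<difference_series> %d time points, baseline index %d, %d slice(s), %d x %d voxels\n",
              d[1], x$baseline_index, d[2], d[3], d[4]))
  invisible(x)
}

#' Region-mean concentration-time curve
#'
#' Converts the region-mean signal to a relative contrast-agent concentration
#' with the standard dynamic susceptibility contrast relation
#' `C(t) = -(1/TE) * log(S(t) / S(baseline))`. The curve is used for bolus
#' phase detection; its absolute scale never enters the reported statistics.
#'
#' @inheritParams coil_load_normalize
#' @return A `concentration_curve`: list with `values` (length `n_time`,
#'   exactly 0 at the baseline index), `region_label`, `te_ms`,
#'   `baseline_index`.
#' @export
concentration_curve <- function(series, region, baseline_index = 1L) {
  stopifnot(inherits(series, "dsce_series"), inherits(region, "toi"))
  mask <- toi_mask_on_grid(region, spatial_dim(series))
  means <- vapply(seq_len(series$n_time),
                  function(k) mean(series$signal[k, , , ][mask]), numeric(1))
  if (any(!is.finite(means)) || any(means <= 0))
    stop("log of non-positive signal: region mean must stay positive over time")
  values <- -(1 / series$te_ms) * log(means / means[baseline_index])
  structure(list(values = values, region_label = region$label,
                 te_ms = series$te_ms, baseline_index = baseline_index),
            class = "concentration_curve")
}

#' @export
print.concentration_curve <- function(x, ...) {
  cat(sprintf("<concentration_curve> region '%s', %d time points, peak %.3g at index %d\n",
              x$region_label, length(x$values), max(x$values), which.max(x$values)))
  invisible(x)
}

#' Cardiac-output normalization of the difference series
#'
#' Differences in cardiac ejection fraction change the amount of contrast
#' agent delivered per unit time, scaling the whole difference curve. The
#' correction fixes the area under the reference-region difference curve over
#' the inflow and outflow periods to `auc_ref`: with
#' `A = trapezoidal integral over IFP + OFP of the region-mean difference`,
#' every difference voxel is divided by `g = A / auc_ref`.
#'
#' The reference region must be the same NAWM region used for the coil-load
#' normalization. The correction applies to the difference series only (and
#' hence to every texture map derived from it); the raw signal map keeps only
#' the coil-load normalization.
#'
#' @param diff A `difference_series`.
#' @param region Reference [toi] (same as for [coil_load_normalize()]).
#' @param phases A [bolus_phases] object from [detect_phases()].
#' @param auc_ref Target area under the IFP+OFP difference curve
#'   (default 200, in signal x time-index units).
#' @param state Optional `normalization_state` from [coil_load_normalize()]
#'   to be completed with the AUC factor.
#' @return A list with `diff` (normalized `difference_series`) and `state`.
#' @export
cardiac_output_normalize <- function(diff, region, phases, auc_ref = 200,
                                     state = NULL) {
  stopifnot(inherits(diff, "difference_series"), inherits(region, "toi"),
            inherits(phases, "bolus_phases"))
  if (auc_ref <= 0) stop("`auc_ref` must be positive")
  mask <- toi_mask_on_grid(region, dim(diff$diff)[-1L])
  idx <- sort(c(interval_members(phases, "IFP"), interval_members(phases, "OFP")))
  curve <- vapply(idx, function(k) mean(diff$diff[k, , , ][mask]), numeric(1))
  A <- trapz_unit(curve)
  if (!is.finite(A) || A <= 0)
    stop("no detectable bolus in reference region (non-positive IFP+OFP area)")
  g <- A / auc_ref
  out <- diff
  out$diff <- diff$diff / g
  if (is.null(state))
    state <- structure(list(coil_factor = NA_real_, c_ideal = NA_real_,
                            auc_factor = NA_real_, auc_ref = NA_real_,
                            reference_region = region$label),
                       class = "normalization_state")
  state$auc_factor <- g
  state$auc_ref <- auc_ref
  list(diff = out, state = state)
}

#' @export
print.normalization_state <- function(x, ...) {
  cat(sprintf("<normalization_state> region '%s': coil factor %.6g (c_ideal %g), AUC factor %.6g (auc_ref %g)\n",
              x$reference_region, x$coil_factor, x$c_ideal,
              x$auc_factor, x$auc_ref))
  invisible(x)
}
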