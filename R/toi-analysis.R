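# Per-TOI statistics: the six region statistics per texture map and time
# point, their interval averages (the unit of the statistical battery), the
# direct kernel-free TOI mode, and the delta surrogate markers.

#' Region statistics of a set of voxel values
#'
#' Population moments of the voxel intensity distribution in a region:
#' `mean`, `stdev`, `var`, `vava` (the variance of the squared deviations,
#' `m4 - m2^2` — the region analogue of the variance-of-variance map),
#' `skew` (`m3 / m2^1.5`) and `kurt` (excess kurtosis `m4 / m2^2 - 3`).
#' Skewness and kurtosis are undetermined (`NA`) when the variance falls
#' below `1e-12 * (value range)^2` — degenerate, near-constant regions.
#'
#' @param values Numeric vector; non-finite entries are dropped.
#' @return Named list with the six statistics (`NA` where undetermined) and
#'   `n`, the number of finite values used. An empty set yields all-`NA`
#'   statistics with a warning.
#' @examples
#' region_statistics(c(1, 2, 3, 4, 5))  # mean 3, var 2, vava 2.8
#' @export
region_statistics <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n == 0L) {
    warning("empty region after validity filtering: all statistics undetermined")
    return(list(mean = NA_real_, stdev = NA_real_, var = NA_real_,
                vava = NA_real_, skew = NA_real_, kurt = NA_real_, n = 0L))
  }
  m <- mean(values)
  d <- values - m
  m2 <- mean(d^2)
  m3 <- mean(d^3)
  m4 <- mean(d^4)
  thr <- max(1e-12 * diff(range(values))^2, .Machine$double.eps)
  degenerate <- m2 <= thr
  list(mean = m,
       stdev = sqrt(m2),
       var = m2,
       vava = m4 - m2^2,
       skew = if (degenerate) NA_real_ else m3 / m2^1.5,
       kurt = if (degenerate) NA_real_ else m4 / m2^2 - 3,
       n = n)
}

# Vectorised row-wise core of region_statistics: one row per time point.
row_stats_core <- function(M) {
  fin <- is.finite(M)
  n_eff <- rowSums(fin)
  Mna <- M
  Mna[!fin] <- NA_real_
  mu <- rowMeans(Mna, na.rm = TRUE)
  d <- Mna - mu
  m2 <- rowMeans(d^2, na.rm = TRUE)
  m3 <- rowMeans(d^3, na.rm = TRUE)
  m4 <- rowMeans(d^4, na.rm = TRUE)
  lo <- suppressWarnings(do.call(pmin, c(as.data.frame(Mna), na.rm = TRUE)))
  hi <- suppressWarnings(do.call(pmax, c(as.data.frame(Mna), na.rm = TRUE)))
  rng <- ifelse(n_eff > 0L, hi - lo, 0)
  thr <- pmax(1e-12 * rng^2, .Machine$double.eps)
  degenerate <- !is.finite(m2) | (m2 <= thr)
  empty <- n_eff == 0L
  na_if_empty <- function(x) { x[empty] <- NA_real_; x }
  list(mean = na_if_empty(mu),
       stdev = na_if_empty(sqrt(pmax(m2, 0))),
       var = na_if_empty(m2),
       vava = na_if_empty(m4 - m2^2),
       skew = ifelse(degenerate, NA_real_, m3 / m2^1.5),
       kurt = ifelse(degenerate, NA_real_, m4 / m2^2 - 3),
       n = n_eff)
}

# Tibble wrapper used by the public per-TOI time-course functions.
row_region_statistics <- function(M) {
  core <- row_stats_core(M)
  tibble::tibble(time = seq_len(nrow(M)),
                 mean = core$mean, stdev = core$stdev, var = core$var,
                 vava = core$vava, skew = core$skew, kurt = core$kurt,
                 n = core$n)
}

# Flatten a TPM (or raw difference) array over a mask into a time x voxel
# matrix, applying the validity mask (invalid entries become NA).
masked_time_matrix <- function(values, valid, mask) {
  d <- dim(values)
  idx <- which(as.vector(mask))
  V <- matrix(values, d[1], prod(d[-1L]))[, idx, drop = FALSE]
  if (!is.null(valid)) {
    W <- matrix(valid, d[1], prod(d[-1L]))[, idx, drop = FALSE]
    V[!W] <- NA_real_
  }
  V
}

#' Time course of the six TOI statistics on one texture map
#'
#' Applies [region_statistics()] at every time point to the TOI's voxels,
#' restricted to the map's validity mask. The same mask is reused verbatim
#' across all texture maps (regions are drawn once and copied).
#'
#' @param tpm A `tpm_series` from [compute_tpm()] / [compute_all_tpms()].
#' @param toi A [toi].
#' @return Tibble with columns `time`, the six statistics, and `n` (voxels
#'   used). Time points with no valid voxel have undetermined statistics.
#' @export
toi_time_course <- function(tpm, toi) {
  stopifnot(inherits(tpm, "tpm_series"), inherits(toi, "toi"))
  mask <- toi_mask_on_grid(toi, dim(tpm$values)[-1L])
  M <- masked_time_matrix(tpm$values, tpm$valid, mask)
  row_region_statistics(M)
}

#' Kernel-free texture statistics directly from the TOI voxels
#'
#' Computes the six statistics from the raw difference-image voxels inside
#' the TOI at each time point, without the detour via texture maps computed
#' over a fixed kernel — no border loss, no kernel-size/SNR trade-off, at the
#' price of a single pooled estimate per region.
#'
#' @param diff A `difference_series`.
#' @param toi A [toi].
#' @return Tibble as in [toi_time_course()].
#' @export
direct_toi_texture <- function(diff, toi) {
  stopifnot(inherits(diff, "difference_series"), inherits(toi, "toi"))
  mask <- toi_mask_on_grid(toi, dim(diff$diff)[-1L])
  M <- masked_time_matrix(diff$diff, NULL, mask)
  row_region_statistics(M)
}

#' Interval averages of a TOI statistic time course
#'
#' Averages each statistic over the member time points of each bolus phase
#' interval, using only finite per-time-point values (a degenerate time point
#' does not poison its interval; the count of contributing time points is
#' recorded). This is the `6 statistics x 4 intervals` grid of one
#' (TOI, texture map) pair — the unit cell of the statistical battery.
#'
#' @param time_course Tibble from [toi_time_course()] or
#'   [direct_toi_texture()].
#' @param phases A [bolus_phases].
#' @param toi_label,tissue_class,tpm_type Key columns stamped onto the
#'   records.
#' @return Tibble of 24 records with columns `toi_label`, `tissue_class`,
#'   `tpm_type`, `statistic`, `interval`, `value`, `n_voxels`,
#'   `n_timepoints`, `undetermined`.
#' @export
interval_average <- function(time_course, phases, toi_label = "toi",
                             tissue_class = "OTHER", tpm_type = "DIFF") {
  stopifnot(inherits(phases, "bolus_phases"))
  if (nrow(time_course) != length(phases$interval_of))
    stop("time course length does not match the phase partition")
  S <- as.matrix(time_course[, TOI_STATISTICS])  # n_time x 6
  fin <- is.finite(S)
  Sz <- ifelse(fin, S, 0)
  value <- matrix(NA_real_, 6L, 4L)
  n_tp <- matrix(0L, 6L, 4L)
  for (j in seq_along(INTERVALS)) {
    idx <- which(phases$interval_of == INTERVALS[j])
    cnt <- colSums(fin[idx, , drop = FALSE])
    tot <- colSums(Sz[idx, , drop = FALSE])
    value[, j] <- ifelse(cnt > 0, tot / cnt, NA_real_)
    n_tp[, j] <- cnt
  }
  tibble::tibble(
    toi_label = toi_label,
    tissue_class = factor(tissue_class, levels = TISSUE_CLASSES),
    tpm_type = factor(tpm_type, levels = TPM_TYPES),
    statistic = factor(rep(TOI_STATISTICS, each = 4L), levels = TOI_STATISTICS),
    interval = factor(rep(INTERVALS, times = 6L), levels = INTERVALS),
    value = as.vector(t(value)),
    n_voxels = as.integer(max(time_course$n)),
    n_timepoints = as.integer(as.vector(t(n_tp))),
    undetermined = !is.finite(as.vector(t(value))))
}

#' Full TOI record grid over all texture maps
#'
#' Convenience wrapper producing the complete analysis surface: for every
#' (texture map, TOI) pair the 24 interval-averaged records. With three
#' tissue classes this yields 72 parameter cells per texture map and
#' `8 x 72 = 576` cells over the full battery.
#'
#' @param tpms Named list of `tpm_series` from [compute_all_tpms()].
#' @param tois List of [toi] objects (analysis regions; exclude the
#'   normalization reference region).
#' @param phases A [bolus_phases].
#' @return Tibble of records, `24 * length(tpms) * length(tois)` rows.
#' @export
extract_toi_records <- function(tpms, tois, phases) {
  # Equivalent to interval_average(toi_time_course(...)) per (map, TOI) pair,
  # but flattens each 4D map once and assembles a single tibble: the record
  # grid is the pipeline's inner loop.
  interval_idx <- lapply(INTERVALS, function(iv) which(phases$interval_of == iv))
  n_pairs <- length(tpms) * length(tois)
  chunks <- vector("list", n_pairs)
  ci <- 0L
  for (tpm in tpms) {
    d <- dim(tpm$values)
    V <- matrix(tpm$values, d[1], prod(d[-1L]))
    W <- matrix(tpm$valid, d[1], prod(d[-1L]))
    spatial <- d[-1L]
    for (roi in tois) {
      idx <- which(as.vector(toi_mask_on_grid(roi, spatial)))
      M <- V[, idx, drop = FALSE]
      M[!W[, idx, drop = FALSE]] <- NA_real_
      core <- row_stats_core(M)
      S <- cbind(core$mean, core$stdev, core$var, core$vava, core$skew,
                 core$kurt)
      fin <- is.finite(S)
      Sz <- ifelse(fin, S, 0)
      value <- matrix(NA_real_, 6L, 4L)
      n_tp <- matrix(0L, 6L, 4L)
      for (j in 1:4) {
        cnt <- colSums(fin[interval_idx[[j]], , drop = FALSE])
        tot <- colSums(Sz[interval_idx[[j]], , drop = FALSE])
        value[, j] <- ifelse(cnt > 0, tot / cnt, NA_real_)
        n_tp[, j] <- cnt
      }
      ci <- ci + 1L
      chunks[[ci]] <- list(toi_label = roi$label,
                           tissue_class = roi$tissue_class,
                           tpm_type = tpm$tpm_type,
                           value = as.vector(t(value)),
                           n_voxels = max(core$n),
                           n_timepoints = as.vector(t(n_tp)))
    }
  }
  tibble::tibble(
    toi_label = rep(vapply(chunks, `[[`, character(1), "toi_label"), each = 24L),
    tissue_class = factor(rep(vapply(chunks, `[[`, character(1), "tissue_class"),
                              each = 24L), levels = TISSUE_CLASSES),
    tpm_type = factor(rep(vapply(chunks, `[[`, character(1), "tpm_type"),
                          each = 24L), levels = TPM_TYPES),
    statistic = factor(rep(rep(TOI_STATISTICS, each = 4L), times = n_pairs),
                       levels = TOI_STATISTICS),
    interval = factor(rep(INTERVALS, times = 6L * n_pairs), levels = INTERVALS),
    value = unlist(lapply(chunks, `[[`, "value"), use.names = FALSE),
    n_voxels = as.integer(rep(vapply(chunks, `[[`, numeric(1), "n_voxels"),
                              each = 24L)),
    n_timepoints = unlist(lapply(chunks, `[[`, "n_timepoints"), use.names = FALSE),
    undetermined = !is.finite(unlist(lapply(chunks, `[[`, "value"),
                                     use.names = FALSE)))
}

#' Delta surrogate markers (reperfusion minus inflow)
#'
#' For each TOI and each of the five underlying texture maps, the difference
#' of the interval-averaged TOI mean between the reperfusion and inflow
#' periods: `delta = RPP - IFP`. `dTPM_DIFF` grades blood-brain-barrier
#' leakage on a continuous scale (stronger leakage pushes the late difference
#' signal below baseline, lowering the RPP value); `dTPM_VAVA`, `dTPM_STDEV`
#' and `dTPM_VAR` grade the evolution of tissue heterogeneity.
#'
#' @param records Record tibble from [extract_toi_records()].
#' @return Tibble with columns `toi_label`, `tissue_class`, `marker`,
#'   `tpm_type`, `value` (`NA` when either interval entry is undetermined).
#' @export
delta_markers <- function(records) {
  map_of <- c(dTPM_DIFF = "DIFF", dTPM_AVE = "AVER", dTPM_VAVA = "VAVA",
              dTPM_STDEV = "STDEV", dTPM_VAR = "VARI")
  base <- records |>
    dplyr::filter(.data$statistic == "mean",
                  .data$interval %in% c("IFP", "RPP"),
                  as.character(.data$tpm_type) %in% map_of) |>
    dplyr::select("toi_label", "tissue_class", "tpm_type", "interval", "value") |>
    tidyr::pivot_wider(names_from = "interval", values_from = "value")
  if (nrow(base) == 0L || !all(c("IFP", "RPP") %in% names(base)))
    stop("records lack the IFP/RPP mean entries needed for delta markers")
  base$marker <- names(map_of)[match(as.character(base$tpm_type), map_of)]
  tibble::tibble(
    toi_label = base$toi_label,
    tissue_class = base$tissue_class,
    marker = factor(base$marker, levels = names(map_of)),
    tpm_type = base$tpm_type,
    value = base$RPP - base$IFP) |>
    dplyr::arrange(.data$marker, .data$toi_label)
}
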