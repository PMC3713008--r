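# Seeded synthetic DSCE-MRI phantoms with ground truth for every pipeline
# stage: per-tissue gamma-variate bolus responses with recirculation, a
# spatial texture field, an additive cumulative-uptake leakage term for
# enhancing lesions, and additive Gaussian noise.

#' Gamma-variate bolus concentration curve
#'
#' The standard parametric first-pass bolus shape, peak-normalised so that
#' the curve attains exactly `A` at `t = t0 + alpha * beta`:
#' `c(t) = A * ((t - t0) / (alpha * beta))^alpha * exp(alpha - (t - t0) / beta)`
#' for `t > t0` and 0 before arrival.
#'
#' @param t Numeric vector of time points (index units).
#' @param t0 Bolus arrival time.
#' @param alpha Shape parameter (`> 0`).
#' @param beta Scale parameter (`> 0`, index units).
#' @param A Peak concentration (`>= 0`, arbitrary units).
#' @return Concentration at each `t`.
#' @examples
#' gamma_variate(0:20, t0 = 5, alpha = 3, beta = 1.5, A = 1)
#' @export
gamma_variate <- function(t, t0, alpha, beta, A) {
  if (alpha <= 0 || beta <= 0) stop("`alpha` and `beta` must be positive")
  if (A < 0) stop("`A` must be non-negative")
  dt <- t - t0
  out <- numeric(length(t))
  pos <- dt > 0
  out[pos] <- A * (dt[pos] / (alpha * beta))^alpha * exp(alpha - dt[pos] / beta)
  out
}

tissue_defaults <- function() {
  nawm <- list(baseline_mean = 400, texture_sd = 40,
               t0 = 10.4, alpha = 3, beta = 1.5, amp = 0.0076,
               recirc_frac = 0.2, recirc_delay = 10, recirc_beta_mult = 2,
               leakage = 0)
  el <- modifyList(nawm, list(texture_sd = 80, t0 = 9.0, amp = 0.0091,
                              leakage = 500))
  nel <- modifyList(nawm, list(amp = 0.0057))
  list(NAWM = nawm, EL = el, NEL = nel)
}

#' Phantom configuration
#'
#' Defines a synthetic DSCE examination: one 96 x 96 slice, 40 time points at
#' the 1.5 T protocol timing (TE 47 ms, TR 1440 ms), a 12 x 12 normalization
#' reference square in NAWM, and disc-shaped analysis regions (radius 3)
#' for the three tissue classes with the study's region counts
#' (37 NAWM, 27 EL, 29 NEL).
#'
#' Per-voxel signal model for a voxel of tissue `tau` with baseline field
#' `B(x) = baseline_mean + N(0, texture_sd)`:
#' `S(t, x) = B(x) * exp(-TE * c_tau(t)) + leakage * Cum_tau(t) + N(0, noise_sigma)`
#' where `c_tau` is a gamma-variate plus a delayed, broader recirculation
#' bump and `Cum_tau` its cumulative (trapezoidal) integral. Leakage thus
#' raises the late signal above baseline — the enhancing-lesion signature.
#' The default noise level corresponds to a baseline SNR of 50.
#'
#' @param tissues Named list (`NAWM`, `EL`, `NEL`) of tissue parameter lists;
#'   entries are merged over the defaults. Fields: `baseline_mean`,
#'   `texture_sd`, `t0`, `alpha`, `beta`, `amp` (peak concentration),
#'   `recirc_frac`, `recirc_delay`, `recirc_beta_mult`, `leakage`.
#' @param grid Integer triple `(n_slices, rows, cols)`.
#' @param n_time Number of time points (`>= 10`).
#' @param tr_ms,te_ms Acquisition timing in ms.
#' @param n_nawm,n_el,n_nel Number of analysis regions per tissue class.
#' @param toi_radius Disc radius of the analysis regions, voxels.
#' @param noise_sigma Additive Gaussian noise standard deviation.
#' @param bolus_scale Global multiplier on every tissue's bolus amplitude
#'   (cardiac-output surrogate).
#' @param seed Integer RNG seed; the phantom is bit-reproducible given the
#'   seed.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(tissues = list(), grid = c(1L, 96L, 96L),
                           n_time = 40L, tr_ms = 1440, te_ms = 47,
                           n_nawm = 37L, n_el = 27L, n_nel = 29L,
                           toi_radius = 3L, noise_sigma = 8,
                           bolus_scale = 1, seed = 1L) {
  stopifnot(n_time >= 10L, length(grid) == 3L, noise_sigma >= 0,
            bolus_scale > 0)
  tis <- tissue_defaults()
  for (nm in names(tissues)) tis[[nm]] <- modifyList(tis[[nm]], tissues[[nm]])
  for (nm in names(tis)) {
    if (tis[[nm]]$amp < 0 || tis[[nm]]$leakage < 0)
      stop("amplitudes and leakage coefficients must be non-negative")
  }
  structure(list(tissues = tis, grid = as.integer(grid),
                 n_time = as.integer(n_time), tr_ms = tr_ms, te_ms = te_ms,
                 n_nawm = as.integer(n_nawm), n_el = as.integer(n_el),
                 n_nel = as.integer(n_nel), toi_radius = as.integer(toi_radius),
                 noise_sigma = noise_sigma, bolus_scale = bolus_scale,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

#' Null phantom: three labelled classes, one common tissue distribution
#'
#' All regions are statistically identical NAWM; only the class labels
#' differ. Used to calibrate the false-positive behaviour of the battery.
#'
#' @param seed Integer RNG seed.
#' @param ... Passed on to [phantom_config()].
#' @return A `phantom_config`.
#' @export
phantom_null_config <- function(seed = 1L, ...) {
  nawm <- tissue_defaults()$NAWM
  phantom_config(tissues = list(EL = nawm, NEL = nawm), seed = seed, ...)
}

#' Effect phantom: heterogeneous, leaky enhancing lesions
#'
#' Enhancing lesions carry twice the NAWM texture standard deviation (four
#' times the variance), an earlier and stronger bolus, and a positive
#' leakage coefficient; non-enhancing lesions are mildly hypoperfused.
#'
#' @param seed Integer RNG seed.
#' @param el_leakage Leakage coefficient of the enhancing lesions.
#' @param ... Passed on to [phantom_config()].
#' @return A `phantom_config`.
#' @export
phantom_effect_config <- function(seed = 1L, el_leakage = 500, ...) {
  phantom_config(tissues = list(EL = list(leakage = el_leakage)),
                 seed = seed, ...)
}

disc_mask <- function(rows, cols, r0, c0, radius) {
  outer(seq_len(rows), seq_len(cols),
        function(r, c) (r - r0)^2 + (c - c0)^2 <= radius^2)
}

# Deterministic region layout: a 12x12 reference square in the corner and
# disc TOIs on a regular lattice, classes interleaved cyclically.
phantom_layout <- function(config) {
  rows <- config$grid[2]; cols <- config$grid[3]
  ref_rows <- 3:14; ref_cols <- 3:14
  centers <- expand.grid(r = seq(6L, rows - 6L, by = 8L),
                         c = seq(6L, cols - 6L, by = 8L))
  keep <- !(centers$r <= max(ref_rows) + config$toi_radius &
              centers$c <= max(ref_cols) + config$toi_radius)
  centers <- centers[keep, , drop = FALSE]
  quota <- c(NAWM = config$n_nawm, EL = config$n_el, NEL = config$n_nel)
  if (nrow(centers) < sum(quota))
    stop("grid too small for the requested number of regions")
  cls <- character(0)
  while (length(cls) < sum(quota)) {
    for (k in names(quota)) {
      if (sum(cls == k) < quota[k]) cls <- c(cls, k)
    }
  }
  cls <- cls[seq_len(sum(quota))]
  list(ref_rows = ref_rows, ref_cols = ref_cols,
       centers = centers[seq_along(cls), , drop = FALSE], classes = cls)
}

tissue_curves <- function(config) {
  t <- seq_len(config$n_time)
  lapply(config$tissues, function(p) {
    main <- gamma_variate(t, p$t0, p$alpha, p$beta, p$amp * config$bolus_scale)
    rec <- gamma_variate(t, p$t0 + p$recirc_delay, p$alpha,
                         p$beta * p$recirc_beta_mult,
                         p$amp * p$recirc_frac * config$bolus_scale)
    conc <- main + rec
    list(conc = conc, cum = cumtrapz_unit(conc))
  })
}

true_phase_landmarks <- function(conc) {
  toa <- which(conc > 0)[1]
  t_peak <- which.max(conc)
  n <- length(conc)
  t_min <- NA_integer_
  if (t_peak + 1L <= n - 1L) {
    for (i in (t_peak + 1L):(n - 1L)) {
      if (conc[i] <= conc[i - 1L] && conc[i] <= conc[i + 1L]) { t_min <- i; break }
    }
  }
  list(toa = toa, t_peak = t_peak, t_min = t_min)
}

#' Simulate a DSCE phantom examination
#'
#' Generates the 4D signal according to the model documented in
#' [phantom_config()], together with the full ground truth: the tissue label
#' map, the noise-free concentration and cumulative-uptake curves, the true
#' phase landmarks of the NAWM curve, the TOI set (reference region plus
#' analysis regions) and the leakage sign map. Bit-reproducible for a given
#' seed; the caller's RNG state is left untouched.
#'
#' @param config A [phantom_config()].
#' @return List with `series` (a [dsce_series]) and `truth`.
#' @examples
#' ph <- simulate_phantom(phantom_null_config(seed = 7))
#' ph$series
#' @export
simulate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  g <- config$grid
  if (g[1] != 1L)
    stop("phantoms are single-slice (per-slice contour analysis)")
  rows <- g[2]; cols <- g[3]
  layout <- phantom_layout(config)

  label <- matrix("NAWM", rows, cols)
  tois <- vector("list", nrow(layout$centers))
  for (i in seq_len(nrow(layout$centers))) {
    m <- disc_mask(rows, cols, layout$centers$r[i], layout$centers$c[i],
                   config$toi_radius)
    cl <- layout$classes[i]
    if (cl != "NAWM") label[m] <- cl
    tois[[i]] <- toi(sprintf("%s_%02d", cl, sum(layout$classes[seq_len(i)] == cl)),
                     cl, matrix(m, rows, cols), slice_index = 1L)
  }
  ref_mask <- matrix(FALSE, rows, cols)
  ref_mask[layout$ref_rows, layout$ref_cols] <- TRUE
  reference_toi <- toi("REF", "NAWM", ref_mask, slice_index = 1L,
                       definition_interval = "BLP")

  curves <- tissue_curves(config)
  n_time <- config$n_time
  nvox <- rows * cols
  lab_vec <- as.vector(label)
  B <- rep(NA_real_, nvox)
  S <- matrix(0, n_time, nvox)
  for (cl in names(config$tissues)) {
    idx <- which(lab_vec == cl)
    if (length(idx) == 0L) next
    p <- config$tissues[[cl]]
    B[idx] <- p$baseline_mean + rnorm(length(idx), 0, p$texture_sd)
    decay <- exp(-config$te_ms * curves[[cl]]$conc)
    S[, idx] <- outer(decay, B[idx]) + p$leakage * curves[[cl]]$cum
  }
  if (config$noise_sigma > 0)
    S <- S + matrix(rnorm(n_time * nvox, 0, config$noise_sigma), n_time, nvox)
  S[S < 0] <- 0
  signal <- array(S, dim = c(n_time, 1L, rows, cols))

  series <- dsce_series(signal, te_ms = config$te_ms, tr_ms = config$tr_ms,
                        provenance = sprintf("synthetic phantom (seed %d)",
                                             config$seed))
  curve_tbl <- purrr::map_dfr(names(curves), function(cl)
    tibble::tibble(tissue = cl, time = seq_len(n_time),
                   concentration = curves[[cl]]$conc,
                   cumulative = curves[[cl]]$cum))
  leak_sign <- matrix(0L, rows, cols)
  for (cl in names(config$tissues))
    if (config$tissues[[cl]]$leakage > 0) leak_sign[label == cl] <- 1L

  truth <- list(label_map = label,
                curves = curve_tbl,
                phases = true_phase_landmarks(curves$NAWM$conc),
                tois = tois,
                reference_toi = reference_toi,
                leakage_sign_map = leak_sign,
                baseline_field = matrix(B, rows, cols),
                config = config)
  list(series = series, truth = truth)
}

#' Write the canonical phantom fixture suite
#'
#' Writes three examinations used by the documentation and the command-line
#' interface: `F1` (null phantom, identical tissue distributions), `F2`
#' (effect phantom: heterogeneous leaky enhancing lesions, hypoperfused
#' non-enhancing lesions), and the cardiac-scaled pair `F3a`/`F3b` (same
#' anatomy and seed, bolus amplitude scaled by 1.5). Each examination gets a
#' 4D NIfTI with JSON sidecar, a TOI label raster with sidecar, a truth curve
#' TSV, and a row in `manifest.tsv` recording seeds and parameters.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed Base RNG seed.
#' @return Tibble manifest, invisibly.
#' @export
make_fixture_suite <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  specs <- list(
    F1 = phantom_null_config(seed = seed),
    F2 = phantom_effect_config(seed = seed + 1L),
    F3a = phantom_effect_config(seed = seed + 2L),
    F3b = phantom_effect_config(seed = seed + 2L, bolus_scale = 1.5))
  manifest <- purrr::map_dfr(names(specs), function(nm) {
    cfg <- specs[[nm]]
    ph <- simulate_phantom(cfg)
    write_dsce_series(ph$series, file.path(out_dir, paste0(nm, ".nii")))
    write_toi_labels(c(list(ph$truth$reference_toi), ph$truth$tois),
                     file.path(out_dir, paste0(nm, "_toi.nii")))
    curves <- ph$truth$curves
    curve_lines <- c(paste(names(curves), collapse = "\t"),
                     do.call(paste, c(lapply(curves, function(col)
                       if (is.numeric(col)) format_report_number(col)
                       else as.character(col)), sep = "\t")))
    writeLines(curve_lines, file.path(out_dir, paste0(nm, "_truth_curves.tsv")))
    tibble::tibble(
      fixture = nm, seed = cfg$seed, bolus_scale = cfg$bolus_scale,
      noise_sigma = cfg$noise_sigma,
      el_texture_sd = cfg$tissues$EL$texture_sd,
      el_leakage = cfg$tissues$EL$leakage,
      nel_amp = cfg$tissues$NEL$amp,
      nawm_amp = cfg$tissues$NAWM$amp,
      n_nawm = cfg$n_nawm, n_el = cfg$n_el, n_nel = cfg$n_nel)
  })
  lines <- c(paste(names(manifest), collapse = "\t"),
             do.call(paste, c(lapply(manifest, function(col)
               if (is.double(col)) format_report_number(col) else as.character(col)),
               sep = "\t")))
  writeLines(lines, file.path(out_dir, "manifest.tsv"))
  invisible(manifest)
}
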