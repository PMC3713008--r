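ref_square_toi <- function(rows = 8L, cols = 8L) {
  m <- matrix(FALSE, rows, cols)
  m[2:4, 2:4] <- TRUE
  toi("REF", "NAWM", m, slice_index = 1L)
}

test_that("coil-load normalization fixes the reference baseline mean", {
  s <- constant_series(400)
  ref <- ref_square_toi()
  out <- coil_load_normalize(s, ref, c_ideal = 100)
  expect_equal(out$state$coil_factor, 4)
  base <- out$series$signal[1, , , ][ref$mask]
  expect_equal(mean(base), 100, tolerance = 1e-13)
  # already at the ideal value -> identity
  out2 <- coil_load_normalize(out$series, ref, c_ideal = 100)
  expect_equal(out2$state$coil_factor, 1)
  expect_equal(out2$series$signal, out$series$signal)
  # degenerate region
  zero <- dsce_series(array(0, dim = c(4, 1, 8, 8)), 47, 1440)
  expect_error(coil_load_normalize(zero, ref), "degenerate reference region")
})

test_that("series differing only in coil load normalise to identical data", {
  ph <- simulate_phantom(small_effect_config(seed = 11))
  ref <- ph$truth$reference_toi
  s_a <- ph$series; s_a$signal <- s_a$signal * 0.7
  s_b <- ph$series; s_b$signal <- s_b$signal * 1.3
  n_a <- coil_load_normalize(s_a, ref)$series
  n_b <- coil_load_normalize(s_b, ref)$series
  expect_equal(n_a$signal, n_b$signal, tolerance = 1e-12)
})

test_that("difference images subtract the baseline with the documented sign", {
  s <- constant_series(100)
  d <- compute_difference_series(s)
  expect_true(all(d$diff == 0))
  # uniform drop of 5 after baseline -> diff of exactly 5
  sig <- array(100, dim = c(6, 1, 8, 8))
  sig[2:6, , , ] <- 95
  d2 <- compute_difference_series(dsce_series(sig, 47, 1440))
  expect_true(all(d2$diff[1, , , ] == 0))
  expect_true(all(d2$diff[2:6, , , ] == 5))
  expect_error(compute_difference_series(s, baseline_index = 9L),
               "out of range")
})

test_that("leakage drives the late difference signal negative in enhancing lesions", {
  cfg <- small_effect_config(seed = 5, noise_sigma = 0)
  cfg$tissues$EL$texture_sd <- 0
  cfg$tissues$NAWM$texture_sd <- 0
  cfg$tissues$NEL$texture_sd <- 0
  ph <- simulate_phantom(cfg)
  d <- compute_difference_series(ph$series)
  last <- d$diff[ph$series$n_time, 1, , ]
  el <- ph$truth$label_map == "EL"
  nawm <- ph$truth$label_map == "NAWM"
  expect_true(all(last[el] < 0))            # leakage signature
  expect_true(all(last[nawm] >= 0))         # intact barrier: no enhancement
  expect_equal(unname((last < 0)[el | nawm]),
               unname((ph$truth$leakage_sign_map == 1L)[el | nawm]))
})

test_that("concentration curves invert the exponential signal model", {
  s <- constant_series(200)
  ref <- ref_square_toi()
  cc <- concentration_curve(s, ref)
  expect_equal(cc$values, rep(0, s$n_time))
  # exact inversion of S_k = S_0 * exp(-TE * c_k)
  c_true <- c(0, 0.001, 0.004, 0.002, 0.0005, 0)
  sig <- array(0, dim = c(6, 1, 8, 8))
  for (k in 1:6) sig[k, , , ] <- 200 * exp(-47 * c_true[k])
  cc2 <- concentration_curve(dsce_series(sig, te_ms = 47, tr_ms = 1440), ref)
  expect_equal(cc2$values, c_true, tolerance = 1e-12)
  expect_equal(cc2$values[1], 0)
  bad <- sig; bad[3, , , ] <- 0
  expect_error(concentration_curve(dsce_series(bad, 47, 1440), ref),
               "log of non-positive signal")
})

test_that("phantom concentration recovery stays within noise tolerance", {
  ph <- simulate_phantom(phantom_effect_config(seed = 21))  # SNR 50 default
  cc <- concentration_curve(ph$series, ph$truth$reference_toi)
  truth <- ph$truth$curves$concentration[ph$truth$curves$tissue == "NAWM"]
  rms <- sqrt(mean((cc$values - truth)^2))
  expect_lt(rms, 0.05 * max(truth))
})

test_that("cardiac-output normalization fixes the IFP+OFP area under the curve", {
  ph <- simulate_phantom(phantom_effect_config(seed = 8))
  ref <- ph$truth$reference_toi
  coil <- coil_load_normalize(ph$series, ref)
  diff <- compute_difference_series(coil$series)
  phases <- detect_phases(concentration_curve(coil$series, ref))
  norm <- cardiac_output_normalize(diff, ref, phases, auc_ref = 200,
                                   state = coil$state)
  idx <- sort(c(interval_members(phases, "IFP"), interval_members(phases, "OFP")))
  mask <- ref$mask
  curve <- vapply(idx, function(k) mean(norm$diff$diff[k, , , ][mask]),
                  numeric(1))
  A <- sum((curve[-1] + curve[-length(curve)]) / 2)
  expect_equal(A, 200, tolerance = 1e-9)
  # g = A / auc_ref by construction
  curve0 <- vapply(idx, function(k) mean(diff$diff[k, , , ][mask]), numeric(1))
  A0 <- sum((curve0[-1] + curve0[-length(curve0)]) / 2)
  expect_equal(norm$state$auc_factor, A0 / 200, tolerance = 1e-12)
  # area already on target -> identity
  norm2 <- cardiac_output_normalize(norm$diff, ref, phases, auc_ref = 200)
  expect_equal(norm2$state$auc_factor, 1, tolerance = 1e-9)
})

test_that("both normalization fixed points hold simultaneously after the twofold pass", {
  ph <- simulate_phantom(phantom_effect_config(seed = 13))
  ref <- ph$truth$reference_toi
  coil <- coil_load_normalize(ph$series, ref, c_ideal = 100)
  expect_equal(mean(coil$series$signal[1, , , ][ref$mask]), 100,
               tolerance = 1e-12)
  diff <- compute_difference_series(coil$series)
  phases <- detect_phases(concentration_curve(coil$series, ref))
  norm <- cardiac_output_normalize(diff, ref, phases, state = coil$state)
  # coil fixed point is untouched by the cardiac pass (applies to diff only)
  expect_equal(mean(coil$series$signal[1, , , ][ref$mask]), 100,
               tolerance = 1e-12)
  expect_true(norm$state$coil_factor > 0 && norm$state$auc_factor > 0)
})

test_that("normalization commutes with the difference operation (linearity)", {
  ph <- simulate_phantom(small_effect_config(seed = 2))
  ref <- ph$truth$reference_toi
  f <- coil_load_normalize(ph$series, ref)$state$coil_factor
  a <- compute_difference_series(coil_load_normalize(ph$series, ref)$series)
  b <- compute_difference_series(ph$series)
  expect_equal(a$diff, b$diff / f, tolerance = 1e-12)
})

test_that("bolus amplitude differences cancel out of interval-averaged records", {
  run_one <- function(scale) {
    ph <- simulate_phantom(phantom_effect_config(seed = 31,
                                                 bolus_scale = scale))
    res <- run_dtpa(ph$series, c(list(ph$truth$reference_toi), ph$truth$tois),
                    battery = FALSE)
    res$records
  }
  r1 <- run_one(1)
  r2 <- run_one(1.5)
  pick <- function(r) r[r$tpm_type == "DIFF" & r$statistic == "mean" &
                          r$tissue_class == "NAWM" &
                          r$interval %in% c("IFP", "OFP"), ]
  v1 <- tapply(pick(r1)$value, pick(r1)$interval, mean)[c("IFP", "OFP")]
  v2 <- tapply(pick(r2)$value, pick(r2)$interval, mean)[c("IFP", "OFP")]
  expect_equal(unname(v1), unname(v2), tolerance = 0.01)
})
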