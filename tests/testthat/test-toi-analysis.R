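make_phases_1based <- function(toa = 4L, t_peak = 6L, t_min = 8L, t_end = 10L) {
  bolus_phases(toa, t_peak, t_min, t_end)
}

test_that("region statistics match direct central-moment evaluation", {
  s <- region_statistics(c(1, 2, 3, 4, 5))
  expect_equal(s$mean, 3)
  expect_equal(s$var, 2)
  expect_equal(s$stdev, sqrt(2))
  expect_equal(s$vava, 2.8)  # m4 = 6.8, m2^2 = 4
  expect_equal(s$skew, 0)
  expect_equal(s$kurt, 6.8 / 4 - 3)

  z <- region_statistics(c(0, 0, 0, 0))
  expect_equal(z$mean, 0)
  expect_equal(z$var, 0)
  expect_equal(z$vava, 0)
  expect_true(is.na(z$skew) && is.na(z$kurt))

  expect_warning(e <- region_statistics(numeric(0)), "empty region")
  expect_true(all(is.na(unlist(e[TOI_STATISTICS]))))
})

test_that("all statistics except the mean are translation invariant", {
  set.seed(10)
  for (rep in 1:10) {
    v <- rnorm(sample(5:40, 1), sd = runif(1, 0.5, 4))
    c0 <- runif(1, -50, 50)
    a <- region_statistics(v)
    b <- region_statistics(v + c0)
    expect_equal(b$mean, a$mean + c0, tolerance = 1e-9)
    for (nm in c("stdev", "var", "vava", "skew", "kurt"))
      expect_equal(b[[nm]], a[[nm]], tolerance = 1e-7)
  }
})

test_that("single-voxel and spatially constant regions behave degenerately", {
  d <- array(0, dim = c(6, 1, 10, 10))
  for (k in 1:6) d[k, 1, , ] <- k * 1.5
  diff <- structure(list(diff = d, baseline_index = 1L, meta = list()),
                    class = "difference_series")
  one <- matrix(FALSE, 10, 10); one[4, 4] <- TRUE
  tc <- direct_toi_texture(diff, toi("v", "OTHER", one, 1L))
  expect_equal(tc$mean, (1:6) * 1.5)
  expect_equal(tc$var, rep(0, 6))
  expect_true(all(is.na(tc$skew)))
  # spatially constant full-image TOI -> zero dispersion at every time point
  full <- toi("full", "OTHER", matrix(TRUE, 10, 10), 1L)
  tpm <- structure(list(tpm_type = "DIFF", values = d, kernel = NA_integer_,
                        valid = array(TRUE, dim = dim(d))),
                   class = "tpm_series")
  tc2 <- toi_time_course(tpm, full)
  expect_equal(tc2$stdev, rep(0, 6))
  expect_equal(tc2$n, rep(100L, 6))
})

test_that("interval averages reduce time courses as documented", {
  ph <- make_phases_1based()
  tc <- tibble::tibble(time = 1:10, mean = c(1, 2, 3, rep(7, 7)),
                       stdev = 1, var = 1, vava = 1, skew = 0, kurt = 0,
                       n = 25L)
  rec <- interval_average(tc, ph, toi_label = "x", tissue_class = "EL",
                          tpm_type = "DIFF")
  expect_equal(nrow(rec), 24L)
  blp_mean <- rec$value[rec$statistic == "mean" & rec$interval == "BLP"]
  expect_equal(blp_mean, 2)  # average of 1, 2, 3
  expect_equal(unique(rec$value[rec$statistic == "var"]), 1)
  # constant course -> identity in every interval
  const <- tibble::tibble(time = 1:10, mean = 4, stdev = 2, var = 4,
                          vava = 1, skew = 0.5, kurt = -1, n = 9L)
  rec2 <- interval_average(const, ph)
  expect_true(all(rec2$value[rec2$statistic == "mean"] == 4))
  expect_true(all(rec2$n_timepoints[rec2$interval == "RPP"] == 2L))
})

test_that("undetermined time points are dropped, not averaged in", {
  ph <- make_phases_1based()
  tc <- tibble::tibble(time = 1:10, mean = c(NA, 2, 4, rep(1, 7)),
                       stdev = 1, var = 1, vava = 1,
                       skew = NA_real_, kurt = NA_real_, n = 4L)
  rec <- interval_average(tc, ph)
  expect_equal(rec$value[rec$statistic == "mean" & rec$interval == "BLP"], 3)
  expect_equal(rec$n_timepoints[rec$statistic == "mean" & rec$interval == "BLP"], 2L)
  expect_true(all(rec$undetermined[rec$statistic == "skew"]))
  expect_true(all(is.na(rec$value[rec$statistic == "kurt"])))
})

test_that("the record grid has the canonical analysis-surface dimensions", {
  ph <- simulate_phantom(small_effect_config(seed = 23))
  res <- run_dtpa(ph$series, c(list(ph$truth$reference_toi), ph$truth$tois),
                  battery = FALSE)
  rec <- res$records
  # 8 maps x 15 TOIs x 6 statistics x 4 intervals
  expect_equal(nrow(rec), 8L * 15L * 24L)
  cells <- unique(rec[, c("tpm_type", "statistic", "interval", "tissue_class")])
  expect_equal(nrow(cells), 8L * 6L * 4L * 3L)
  per_tpm <- table(unique(rec[, c("tpm_type", "statistic", "interval",
                                  "tissue_class")])$tpm_type)
  expect_true(all(per_tpm == 72L))
  expect_false(anyDuplicated(rec[, c("toi_label", "tpm_type", "statistic",
                                     "interval")]) > 0)
})

test_that("the vectorised record grid equals composing the public operations", {
  ph <- simulate_phantom(small_effect_config(seed = 29))
  res <- run_dtpa(ph$series, c(list(ph$truth$reference_toi), ph$truth$tois),
                  battery = FALSE)
  for (tt in c("DIFF", "SKEW", "VAVA")) {
    roi <- ph$truth$tois[[3]]
    manual <- interval_average(toi_time_course(res$tpms[[tt]], roi),
                               res$phases, roi$label, roi$tissue_class, tt)
    fast <- res$records[res$records$toi_label == roi$label &
                          res$records$tpm_type == tt, ]
    expect_equal(fast$value, manual$value, tolerance = 1e-12, label = tt)
    expect_equal(fast$n_timepoints, manual$n_timepoints, label = tt)
  }
})

test_that("direct TOI statistics approximate kernel-map statistics on smooth data", {
  # smooth spatial field, no noise: the moving average is close to identity
  rows <- 40L; cols <- 40L
  img <- outer(seq_len(rows), seq_len(cols),
               function(r, c) 50 + 10 * sin(r / 12) + 8 * cos(c / 15))
  d <- array(0, dim = c(4, 1, rows, cols))
  for (k in 2:4) d[k, 1, , ] <- img * (k - 1)
  diff <- structure(list(diff = d, baseline_index = 1L, meta = list()),
                    class = "difference_series")
  m <- matrix(FALSE, rows, cols); m[8:32, 8:32] <- TRUE
  roi <- toi("big", "OTHER", m, 1L)
  aver <- compute_tpm(diff, "AVER", kernel = 3L)
  direct <- direct_toi_texture(diff, roi)
  kernelised <- toi_time_course(aver, roi)
  for (k in 2:4)
    expect_lt(abs(direct$mean[k] - kernelised$mean[k]) / abs(direct$mean[k]),
              0.02)
})

test_that("delta markers subtract inflow from reperfusion period values", {
  ph <- make_phases_1based()
  tc <- function(vals) tibble::tibble(time = 1:10, mean = vals, stdev = 1,
                                      var = 1, vava = 1, skew = 0, kurt = 0,
                                      n = 10L)
  # IFP (4:6) mean 10, RPP (9:10) mean 4
  vals <- c(0, 0, 0, 10, 10, 10, 5, 5, 4, 4)
  rec <- dplyr::bind_rows(lapply(c("DIFF", "AVER", "VARI", "STDEV", "VAVA"),
                                 function(tt) interval_average(tc(vals), ph,
                                                               "lesion", "EL", tt)))
  dm <- delta_markers(rec)
  expect_equal(nrow(dm), 5L)
  expect_equal(dm$value[dm$marker == "dTPM_DIFF"], -6)
  # equal interval values -> zero
  rec0 <- dplyr::bind_rows(lapply(c("DIFF", "AVER", "VARI", "STDEV", "VAVA"),
                                  function(tt) interval_average(tc(rep(3, 10)), ph,
                                                                "lesion", "EL", tt)))
  expect_true(all(delta_markers(rec0)$value == 0))
})

test_that("the leakage delta marker grades leakage monotonically", {
  deltas <- vapply(c(100, 500, 900), function(l) {
    ph <- simulate_phantom(small_effect_config(seed = 51, el_leakage = l))
    ref <- ph$truth$reference_toi
    coil <- coil_load_normalize(ph$series, ref)
    diff <- compute_difference_series(coil$series)
    phases <- detect_phases(concentration_curve(coil$series, ref))
    norm <- cardiac_output_normalize(diff, ref, phases, state = coil$state)
    dm <- delta_markers(extract_toi_records(
      list(DIFF = compute_tpm(norm$diff, "DIFF")), ph$truth$tois, phases))
    mean(dm$value[dm$tissue_class == "EL" & dm$marker == "dTPM_DIFF"])
  }, numeric(1))
  expect_true(all(diff(deltas) < 0))  # more leakage -> lower RPP - IFP
})
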