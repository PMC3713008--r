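test_that("NIfTI round trip preserves signal and acquisition metadata", {
  set.seed(42)
  sig <- array(abs(rnorm(32 * 32 * 12 * 40, 100, 10)),
               dim = c(40, 12, 32, 32))
  s <- dsce_series(sig, te_ms = 47, tr_ms = 1440,
                   voxel_size_mm = c(1.8, 1.8, 5), field_strength_T = 1.5,
                   provenance = "unit test")
  path <- file.path(withr::local_tempdir(), "series.nii")
  write_dsce_series(s, path)
  s2 <- load_dsce_series(path, format = "nifti4d")
  expect_equal(s2$n_time, 40L)
  expect_equal(dim(s2$signal)[2], 12L)
  expect_equal(s2$signal, s$signal, tolerance = 1e-12)
  expect_equal(s2$te_ms, 47)
  expect_equal(s2$tr_ms, 1440)
  expect_equal(s2$field_strength_T, 1.5)
})

test_that("loading fails cleanly without echo time metadata", {
  sig <- array(100, dim = c(4, 1, 6, 6))
  s <- dsce_series(sig, te_ms = 47, tr_ms = 1440)
  path <- file.path(withr::local_tempdir(), "series.nii")
  write_dsce_series(s, path)
  unlink(sub("\\.nii$", ".json", path))  # drop the sidecar
  expect_error(load_dsce_series(path, format = "nifti4d"),
               "echo time required")
  # explicit override recovers (TR still available from pixdim)
  s2 <- load_dsce_series(path, format = "nifti4d", te_ms = 47)
  expect_equal(s2$te_ms, 47)
})

test_that("series constructor enforces its invariants", {
  sig <- array(1, dim = c(4, 1, 5, 5))
  expect_error(dsce_series(array(1, dim = c(3, 1, 5, 5)), 47, 1440),
               "at least 4 time points")
  expect_error(dsce_series(sig, te_ms = 0, tr_ms = 1440), "echo time")
  expect_error(dsce_series(sig, te_ms = 47, tr_ms = -1), "repetition time")
  bad <- sig; bad[1] <- -3
  expect_error(dsce_series(bad, 47, 1440), "non-negative")
  bad <- sig; bad[2] <- NaN
  expect_error(dsce_series(bad, 47, 1440), "finite")
})

test_that("DICOM series directories load with metadata and time/slice structure", {
  dir <- make_test_dicom_dir(file.path(withr::local_tempdir(), "dcm"),
                             n_time = 4L, n_slices = 2L, size = 8L)
  expect_false(is.null(dir))
  s <- load_dsce_series(dir, format = "dicom_dir")
  expect_equal(s$n_time, 4L)
  expect_equal(dim(s$signal), c(4L, 2L, 8L, 8L))
  expect_equal(s$te_ms, 47)
  expect_equal(s$tr_ms, 1440)
  # values encode 100 + 10 * t + slice
  expect_equal(s$signal[1, 1, 1, 1], 100)
  expect_equal(s$signal[3, 2, 4, 4], 121)
})

test_that("non-uniform slice count across DICOM time points is a hard error", {
  dir <- make_test_dicom_dir(file.path(withr::local_tempdir(), "dcm_bad"),
                             n_time = 4L, n_slices = 2L, uniform = FALSE)
  expect_false(is.null(dir))
  expect_error(load_dsce_series(dir, format = "dicom_dir"),
               "non-uniform slice count")
})

test_that("label rasters map to TOIs through the sidecar", {
  dir <- withr::local_tempdir()
  masks <- list()
  base <- array(FALSE, dim = c(1, 10, 10))
  m1 <- base; m1[1, 2:4, 2:4] <- TRUE
  m2 <- base; m2[1, 6:8, 2:4] <- TRUE
  m3 <- base; m3[1, 2:4, 6:8] <- TRUE
  tois <- list(toi("nawm1", "NAWM", m1), toi("el1", "EL", m2),
               toi("nel1", "NEL", m3))
  path <- file.path(dir, "labels.nii")
  write_toi_labels(tois, path)
  out <- load_toi_set(path)
  expect_length(out, 3L)
  expect_equal(vapply(out, function(x) x$tissue_class, character(1)),
               c("NAWM", "EL", "NEL"))
  expect_equal(out[[2]]$mask, m2)
  # label missing from sidecar
  jsonlite::write_json(list(`1` = "NAWM", `2` = "EL"),
                       file.path(dir, "labels.json"), auto_unbox = TRUE)
  expect_error(load_toi_set(path), "absent from sidecar")
})

test_that("polygon TOIs rasterise on voxel centers with the even-odd rule", {
  sq <- toi_from_polygon("sq", "EL",
                         rbind(c(2, 2), c(2, 6), c(6, 6), c(6, 2)),
                         nrow = 10, ncol = 10)
  expect_equal(sum(sq$mask), 25L)  # boundary-inclusive 5 x 5 block
  expect_true(all(which(sq$mask[1, , ], arr.ind = TRUE) >= 3 &
                    which(sq$mask[1, , ], arr.ind = TRUE) <= 7))
  expect_error(toi_from_polygon("bad", "EL", rbind(c(0, 0), c(1, 1)), 10, 10),
               "at least 3 vertices")
})

test_that("polygon rasterisation agrees with an exhaustive point-in-polygon oracle", {
  set.seed(7)
  for (rep in 1:5) {
    k <- sample(3:8, 1)
    ang <- sort(stats::runif(k, 0, 2 * pi))
    rad <- stats::runif(k, 3, 14)
    verts <- cbind(16 + rad * sin(ang), 16 + rad * cos(ang))
    res <- toi_from_polygon("p", "OTHER", verts, nrow = 32, ncol = 32)
    oracle <- matrix(FALSE, 32, 32)
    for (r in seq_len(32)) {
      for (c in seq_len(32)) {
        oracle[r, c] <- pip_oracle_point(r - 1, c - 1, verts)
      }
    }
    expect_identical(res$mask[1, , ], oracle)
  }
})

test_that("polygon TOI JSON files load and rasterise", {
  dir <- withr::local_tempdir()
  spec <- list(
    grid = c(10, 10),
    tois = list(
      list(label = "sq", tissue_class = "EL", slice_index = 1,
           vertices = rbind(c(2, 2), c(2, 6), c(6, 6), c(6, 2))),
      list(label = "tri", tissue_class = "NAWM", slice_index = 1,
           vertices = rbind(c(1, 1), c(1, 8), c(8, 1)))))
  path <- file.path(dir, "tois.json")
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA)
  out <- load_toi_set(path)
  expect_length(out, 2L)
  expect_equal(out[[1]]$label, "sq")
  expect_equal(sum(out[[1]]$mask), 25L)
  expect_equal(out[[2]]$tissue_class, "NAWM")
})

test_that("stats reports round-trip losslessly and idempotently", {
  dir <- withr::local_tempdir()
  ph <- simulate_phantom(small_effect_config(seed = 3))
  res <- run_dtpa(ph$series, c(list(ph$truth$reference_toi), ph$truth$tois),
                  battery = FALSE)
  one_tpm <- res$records[res$records$tpm_type == "DIFF", ]
  expect_equal(nrow(one_tpm), 24L * 15L)
  report <- stat_report(res$records, header = list(kernel = 3, c_ideal = 100))
  base <- file.path(dir, "report")
  write_stats_report(report, base)
  lines <- readLines(paste0(base, "_records.tsv"))
  expect_equal(sum(!startsWith(lines, "#")), nrow(res$records) + 1L)  # header row
  back <- read_stats_report(base)
  expect_equal(back$records$value, report$records$value, tolerance = 1e-11)
  expect_equal(back$header$kernel, 3)
  # write -> read -> write is byte-identical
  base2 <- file.path(dir, "report2")
  write_stats_report(stat_report(back$records, header = back$header), base2)
  expect_identical(readLines(paste0(base2, "_records.tsv")),
                   readLines(paste0(base, "_records.tsv")))
  expect_error(stat_report(res$records[0, ]), "at least one record")
})
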