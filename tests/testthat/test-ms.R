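mk_scan <- function(intensity, t = 0, mz = NULL) {
  if (is.null(mz)) mz <- 700 + 0.1 * (seq_along(intensity) - 1)
  spectrum_record(mz, intensity, timestamp = t)
}

test_that("the total-ion chronogram sums scans in order", {
  run <- list(mk_scan(c(3, 4, 5), 0), mk_scan(c(3, 4, 5), 0.05))
  chron <- total_ion_chronogram(run)
  expect_equal(chron$tic, c(12, 12))
  expect_equal(chron$timestamp, c(0, 0.05))
  expect_error(total_ion_chronogram(list()), "empty")
})

test_that("a flat chronogram yields no events", {
  run <- lapply(0:99, function(i) mk_scan(rep(1, 10), i * 0.05))
  expect_identical(nrow(detect_cell_events(total_ion_chronogram(run))), 0L)
})

test_that("bursts are detected, merged below min_gap, split above it", {
  pr <- default_profiles()$euglena
  sp <- generate_spectrum(pr, grid_step = 0.05)
  run <- generate_run(list(list(time = 2, spectrum = sp)),
                      baseline = 0.01, scan_period = 0.05)
  ev <- detect_cell_events(total_ion_chronogram(run))
  expect_identical(nrow(ev), 1L)
  expect_true(ev$t_start < 2 && 2 < ev$t_end)
  expect_true(ev$t_start < ev$apex_time & ev$apex_time < ev$t_end)

  two <- generate_run(list(list(time = 2, spectrum = sp),
                           list(time = 4, spectrum = sp)),
                      baseline = 0.01, scan_period = 0.05)
  chron2 <- total_ion_chronogram(two)
  expect_identical(nrow(detect_cell_events(chron2, min_gap = 1)), 2L)
  expect_identical(nrow(detect_cell_events(chron2, min_gap = 3)), 1L)
})

test_that("extraction sums scans and removes the channel baseline", {
  # single scan, zero baseline: unchanged
  run <- c(lapply(0:9, function(i) mk_scan(rep(0, 5), i * 0.1)),
           list(mk_scan(c(0, 10, 0, 2, 0), 1.0)),
           lapply(11:20, function(i) mk_scan(rep(0, 5), i * 0.1)))
  run <- run[order(vapply(run, `[[`, numeric(1), "timestamp"))]
  ev <- data.frame(t_start = 0.95, t_end = 1.05, apex_time = 1.0)
  out <- extract_cell_spectrum(run, ev)
  expect_equal(out$intensity, c(0, 10, 0, 2, 0))
  expect_equal(out$timestamp, 1.0)
  # two identical scans: doubled
  run2 <- c(lapply(0:9, function(i) mk_scan(rep(0, 5), i * 0.1)),
            list(mk_scan(c(1, 5, 0, 0, 0), 1.0), mk_scan(c(1, 5, 0, 0, 0), 1.1)))
  ev2 <- data.frame(t_start = 0.95, t_end = 1.15, apex_time = 1.0)
  expect_equal(extract_cell_spectrum(run2, ev2)$intensity, c(2, 10, 0, 0, 0))
  # constant baseline is subtracted
  run3 <- c(lapply(0:9, function(i) mk_scan(rep(2, 5), i * 0.1)),
            list(mk_scan(c(2, 12, 2, 2, 2), 1.0)))
  ev3 <- data.frame(t_start = 0.95, t_end = 1.05, apex_time = 1.0)
  expect_equal(extract_cell_spectrum(run3, ev3)$intensity, c(0, 10, 0, 0, 0))
  expect_error(extract_cell_spectrum(run3,
    data.frame(t_start = 90, t_end = 91, apex_time = 90.5)), "no scans")
})

test_that("extracted burst spectra recover the injected peaks", {
  pr <- default_profiles()$phacus
  sp <- generate_spectrum(pr, noise_sd = 2, seed = 5)
  run <- generate_run(list(list(time = 2, spectrum = sp)),
                      baseline = 0.01, scan_period = 0.05, noise_sd = 0.002,
                      seed = 6)
  ev <- detect_cell_events(total_ion_chronogram(run))
  rec <- extract_cell_spectrum(run, ev[1, ], all_events = ev)
  pk <- lmdpipe:::find_peak_centroids(rec)
  top5 <- pk$mz[order(pk$height, decreasing = TRUE)][1:5]
  exp5 <- pr$peaks$mz[order(pr$peaks$abundance, decreasing = TRUE)][1:5]
  for (m in exp5) expect_lt(min(abs(top5 - m)), 0.05)
})

test_that("constant m/z shifts are corrected by lock masses", {
  pr <- default_profiles()$euglena
  sp <- generate_spectrum(pr, noise_sd = 0)
  keep <- sp$mz + 0.02 < 1000
  shifted <- spectrum_record(sp$mz[keep] + 0.02, sp$intensity[keep])
  rc <- mass_recalibrate(shifted)
  expect_false(rc$uncalibrated)
  expect_identical(nrow(rc$matches), 3L)
  pk <- lmdpipe:::find_peak_centroids(rc$spectrum)
  for (c0 in pr$peaks$mz)
    expect_lt(min(abs(pk$mz - c0)), 1e-3)
})

test_that("linear m/z drift is corrected by the two-parameter fit", {
  pr <- default_profiles()$euglena
  sp <- generate_spectrum(pr, noise_sd = 0)
  keep <- sp$mz * (1 + 2e-5) < 1000
  drift <- spectrum_record(sp$mz[keep] * (1 + 2e-5), sp$intensity[keep])
  rc <- mass_recalibrate(drift)
  # fitted slope must undo the drift within 5% of the applied deviation
  expect_lt(abs((rc$coef[2] - 1 / (1 + 2e-5)) / 2e-5), 0.05)
  pk <- lmdpipe:::find_peak_centroids(rc$spectrum)
  for (c0 in pr$peaks$mz) expect_lt(min(abs(pk$mz - c0)), 2e-3)
})

test_that("spectra without lock-mass matches are flagged, not altered", {
  mz <- mz_grid(0.01)
  y <- numeric(length(mz)); y[5000] <- 100
  lone <- spectrum_record(mz, y)
  rc <- mass_recalibrate(lone, lock_masses = c(999.5), tolerance = 0.05)
  expect_true(rc$uncalibrated)
  expect_identical(rc$spectrum$mz, lone$mz)
})

test_that("binning lands boundary masses in the right half-open bins", {
  s <- spectrum_record(c(700.0, 855.23, 999.95), c(1, 2, 3))
  b <- normalize_and_bin(s, normalize = FALSE)
  expect_length(b$values, 3000)
  expect_equal(b$values[1], 1)                       # m/z 700.0 -> bin 0
  expect_equal(b$values[floor((855.23 - 700) / 0.1) + 1], 2)
  expect_equal(b$values[3000], 3)                    # 999.95 -> last bin
  # m/z exactly 1000 is excluded by the half-open grid (unvalidated record)
  raw <- structure(list(mz = c(750, 1000), intensity = c(4, 9),
                        timestamp = 0, accumulation = 0.05),
                   class = "spectrum_record")
  expect_equal(sum(normalize_and_bin(raw, normalize = FALSE)$values), 4)
})

test_that("normalized spectra sum to one; all-zero stays unnormalized", {
  sp <- generate_spectrum(default_profiles()$euglena, noise_sd = 4, seed = 8)
  b <- normalize_and_bin(sp)
  expect_true(b$normalized)
  expect_lt(abs(sum(b$values) - 1), 1e-9)
  zero <- spectrum_record(c(700, 800), c(0, 0))
  bz <- normalize_and_bin(zero)
  expect_false(bz$normalized)
  expect_true(all(bz$values == 0))
})

test_that("binning conserves in-range totals exactly and ignores input order", {
  set.seed(9)
  mz <- sort(runif(500, 700, 999.99))
  counts <- as.numeric(rpois(500, 40))               # integer-valued: exact sums
  s <- spectrum_record(mz, counts)
  b <- normalize_and_bin(s, normalize = FALSE)
  expect_identical(sum(b$values), sum(counts))
  perm <- sample(500)
  shuffled <- structure(list(mz = mz[perm], intensity = counts[perm],
                             timestamp = 0, accumulation = 0.05),
                        class = "spectrum_record")
  expect_identical(normalize_and_bin(shuffled, normalize = FALSE)$values,
                   b$values)
})

test_that("binning is idempotent on an already-binned grid", {
  v <- numeric(3000); v[c(10, 500, 2999)] <- c(2, 5, 1)
  on_grid <- spectrum_record(bin_grid_edges()[v > 0], v[v > 0])
  expect_identical(normalize_and_bin(on_grid, normalize = FALSE)$values, v)
})

test_that("feature matrices validate and round-trip as CSV", {
  pr <- default_profiles()
  b <- lapply(1:4, function(i)
    normalize_and_bin(generate_spectrum(pr$euglena, noise_sd = 3, seed = i)))
  fm <- feature_matrix(b, labels = c("a", "a", "b", "b"), ids = 11:14)
  expect_identical(dim(fm$values), c(4L, 3000L))
  expect_error(feature_matrix(b, labels = c("a", "b", "c", "d")), "2-class")
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(fm, f)
  back <- read_feature_matrix(f)
  expect_equal(back$values, fm$values, tolerance = 1e-12)
  expect_identical(back$labels, fm$labels)
  expect_identical(back$ids, 11:14)
})

test_that("runs round-trip through CSV and mzML", {
  pr <- default_profiles()$euglena
  sp <- generate_spectrum(pr, grid_step = 0.1)
  run <- generate_run(list(list(time = 1, spectrum = sp)),
                      baseline = 0.01, scan_period = 0.05)
  d <- withr::local_tempdir()
  write_run_csv(run, file.path(d, "run"))
  back <- read_run_csv(file.path(d, "run"))
  expect_length(back$scans, length(run$scans))
  expect_equal(back$scans[[5]]$intensity, run$scans[[5]]$intensity,
               tolerance = 1e-9)
  fml <- file.path(d, "run.mzML")
  write_run_mzml(run, fml)
  back2 <- read_run_mzml(fml)
  expect_length(back2$scans, length(run$scans))
  expect_equal(back2$scans[[5]]$mz, run$scans[[5]]$mz, tolerance = 1e-6)
  expect_equal(back2$scans[[5]]$intensity, run$scans[[5]]$intensity,
               tolerance = 1e-4)
  expect_equal(vapply(back2$scans, `[[`, numeric(1), "timestamp"),
               vapply(run$scans, `[[`, numeric(1), "timestamp"),
               tolerance = 1e-6)
})
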