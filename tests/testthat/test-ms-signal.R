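make_run <- function(rts, peaks_by_scan) {
  peaks <- dplyr::bind_rows(purrr::imap(peaks_by_scan, function(p, i) {
    tibble::tibble(scan = as.integer(i), mz = p$mz, intensity = p$intensity)
  }))
  ms_run(tibble::tibble(scan = seq_along(rts), rt = rts), peaks)
}

test_that("ms_run validates and repairs its scan table", {
  expect_error(ms_run(tibble::tibble(scan = integer(), rt = numeric()),
                      tibble::tibble(scan = integer(), mz = numeric(),
                                     intensity = numeric())),
               "empty run")
  expect_warning(
    run <- ms_run(tibble::tibble(scan = 1:2, rt = c(2, 1)),
                  tibble::tibble(scan = 1L, mz = 100, intensity = 5)),
    "reordering")
  expect_equal(run$scans$rt, c(1, 2))
  expect_error(ms_run(tibble::tibble(scan = 1L, rt = 1),
                      tibble::tibble(scan = 1L, mz = 100, intensity = -1)),
               class = "xlinkxic_validation_error")
})

test_that("runs round-trip through the JSON and CSV fixture formats", {
  sim <- tiny_planted_run()
  f <- withr::local_tempfile(fileext = ".json")
  write_ms_run(sim$run, f)
  back <- read_ms_run(f)
  expect_equal(back$scans$rt, sim$run$scans$rt, tolerance = 1e-12)
  expect_equal(back$peaks$mz, sim$run$peaks$mz, tolerance = 1e-12)
  expect_equal(back$peaks$intensity, sim$run$peaks$intensity, tolerance = 1e-12)

  # the flat CSV form cannot represent peak-free scans; peak data round-trips
  fc <- withr::local_tempfile(fileext = ".csv")
  write_ms_run(sim$run, fc)
  backc <- read_ms_run(fc)
  expect_equal(backc$peaks$mz, sim$run$peaks$mz, tolerance = 1e-12)
  expect_equal(backc$peaks$intensity, sim$run$peaks$intensity, tolerance = 1e-12)
  nonempty <- sort(unique(sim$run$peaks$scan))
  expect_equal(backc$scans$rt, sim$run$scans$rt[sim$run$scans$scan %in% nonempty],
               tolerance = 1e-12)
})

test_that("runs round-trip through mzML", {
  sim <- tiny_planted_run(run_length = 4, rt = 2)
  f <- withr::local_tempfile(fileext = ".mzML")
  write_ms_run(sim$run, f)
  back <- read_ms_run(f)
  expect_equal(back$scans$rt, sim$run$scans$rt, tolerance = 1e-9)
  expect_equal(back$peaks$mz, sim$run$peaks$mz, tolerance = 1e-9)
  expect_equal(nrow(back$peaks), nrow(sim$run$peaks))
})

test_that("XIC extraction sums peaks inside the ppm window", {
  run <- make_run(c(1, 2, 3), list(
    list(mz = c(500.000, 500.003, 600), intensity = c(10, 20, 5)),
    list(mz = 500.02, intensity = 7),
    list(mz = 499.9, intensity = 3)))
  x <- extract_xic(run, 500, tol_ppm = 10)   # window +/- 0.005 Th
  expect_equal(x$intensity, c(30, 0, 0))     # two peaks summed, others outside
  expect_equal(attr(x, "apex_rt"), 1)
  # target twice the tolerance away sees nothing
  x0 <- extract_xic(run, 500.02 * (1 + 20e-6), tol_ppm = 10)
  expect_equal(sum(x0$intensity), 0)
  expect_true(is.na(attr(x0, "apex_rt")))
})

test_that("XIC traces scale linearly with global intensity", {
  sim <- tiny_planted_run()
  run2 <- sim$run
  run2$peaks$intensity <- run2$peaks$intensity * 3.5
  mz <- ion_series(6516, 5, 5)$mz
  x1 <- extract_xic(sim$run, mz)
  x2 <- extract_xic(run2, mz)
  expect_equal(x2$intensity, 3.5 * x1$intensity, tolerance = 1e-12)
  expect_equal(attr(x2, "apex_intensity"), 3.5 * attr(x1, "apex_intensity"),
               tolerance = 1e-12)
})

test_that("coelution is detected for planted charge states and not in blanks", {
  sim <- tiny_planted_run(mass = 6516, charges = 4:6, rt = 5)
  ser <- ion_series(6516, 4, 6)
  ev <- detect_coelution(sim$run, ser)
  expect_true(ev$accepted)
  expect_equal(ev$n_charges_found, 3L)
  expect_lt(ev$rt_spread, 1e-9)
  expect_equal(ev$apex_rt, 5, tolerance = 1e-9)

  # same species in a single charge fails min_charges = 2
  sim1 <- tiny_planted_run(mass = 6516, charges = 5, rt = 5)
  ev1 <- detect_coelution(sim1$run, ser)
  expect_false(ev1$accepted)
  expect_lte(ev1$n_charges_found, 1L)

  # blank run: nothing found
  blank <- simulate_run(planted_species(1, 4, -100)[0, ],
                        run_length = 10, noise = quiet_noise())
  evb <- detect_coelution(blank$run, ser)
  expect_false(evb$accepted)
  expect_equal(evb$n_charges_found, 0L)
})

test_that("deconvolution inverts the ion-form relation on clean input", {
  sim <- tiny_planted_run(mass = 6516, charges = 4:5, rt = 5)
  ser <- ion_series(6516, 4, 5)
  ev <- detect_coelution(sim$run, ser)
  dec <- deconvolute(sim$run, ser, ev)
  expect_equal(dec$mass, 6516, tolerance = 1e-6)
  expect_lt(dec$dispersion, 1e-6)
  expect_equal(sort(dec$per_charge$z), 4:5)
})

test_that("the median mass estimate resists one displaced charge", {
  m <- 6516
  ser <- ion_series(m, 4, 6)
  rts <- seq(4.9, 5.1, by = 0.01)
  mzs <- ser$mz; mzs[1] <- mzs[1] + 0.5 / 4   # z=4 displaced by 0.5 Da in mass
  peaks_by_scan <- purrr::map(rts, function(rt) {
    w <- exp(-(rt - 5)^2 / (2 * 0.03^2))
    list(mz = mzs, intensity = rep(1000 * w, 3))
  })
  run <- make_run(rts, peaks_by_scan)
  ev <- detect_coelution(run, ser, tol_ppm = 100)
  dec <- deconvolute(run, ser, ev, tol_ppm = 100)
  expect_equal(dec$mass, m, tolerance = 1e-6)     # median ignores the outlier
  expect_equal(dec$dispersion, 0.5, tolerance = 1e-3)
})

test_that("degraded deconvolution drops charges without peaks", {
  sim <- tiny_planted_run(mass = 6516, charges = 4:5, rt = 5)
  ser <- ion_series(6516, 4, 6)                   # z=6 never planted
  ev <- detect_coelution(sim$run, ser)
  dec <- deconvolute(sim$run, ser, ev)
  expect_setequal(dec$per_charge$z, 4:5)
  expect_equal(dec$mass, 6516, tolerance = 1e-6)
})

test_that("charge inference from isotope spacing handles the edge cases", {
  expect_equal(infer_charge_from_isotopes(500 + (0:3) * 1.003355 / 4), 4L)
  expect_equal(infer_charge_from_isotopes(c(800, 801.003355)), 1L)
  expect_error(infer_charge_from_isotopes(c(500, 500.47)), "ambiguous")
  expect_error(infer_charge_from_isotopes(c(500, 500.25, 500.75)), "irregular")
  expect_error(infer_charge_from_isotopes(500), "at least 2")
})
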