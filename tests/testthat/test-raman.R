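test_that("axis calibration is a pure shift that preserves areas", {
  x <- seq(400, 700, 2)
  spec <- tibble::tibble(wavenumber = x, intensity = gauss_spec(x, 520.6, 5, 2))
  same <- calibrate_axis(spec, 520.6)
  expect_equal(same$wavenumber, x)

  shifted <- calibrate_axis(spec, 522.6)
  expect_equal(shifted$wavenumber, x - 2)
  # inverse shift restores the grid
  back <- calibrate_axis(shifted, 518.6)
  expect_equal(back$wavenumber, x)
  # areas preserved under shift
  expect_equal(
    band_intensity(shifted, 480, 560),
    band_intensity(spec, 480, 560),
    tolerance = 1e-6
  )
  expect_error(calibrate_axis(spec, 900), class = "plastiN2O_calibration_error")
})

test_that("ALS baseline removes drift without eating peaks", {
  x <- seq(600, 3200, 2)
  # flat spectrum: residual essentially zero
  flat <- tibble::tibble(wavenumber = x, intensity = rep(5, length(x)))
  corr_flat <- baseline_correct(flat)
  expect_lt(max(abs(corr_flat$intensity)), 1e-6 * 5)

  # two Gaussian peaks + linear drift: areas recovered within 2%
  truth <- c(a1 = 5, a2 = 3)
  y <- gauss_spec(x, 1300, 8, truth[1]) + gauss_spec(x, 2150, 8, truth[2]) +
    0.01 + 1e-5 * (x - 600)
  spec <- tibble::tibble(wavenumber = x, intensity = y)
  corr <- baseline_correct(spec)
  a1 <- band_intensity(corr, 1300 - 40, 1300 + 40)
  a2 <- band_intensity(corr, 2150 - 40, 2150 + 40)
  expect_lt(abs(a1 - truth[1]) / truth[1], 0.02)
  expect_lt(abs(a2 - truth[2]) / truth[2], 0.02)

  # idempotence: correcting twice changes results by < 1% of peak height
  corr2 <- baseline_correct(corr[c("wavenumber", "intensity")])
  expect_lt(max(abs(corr2$intensity - corr$intensity)), 0.01 * max(corr$intensity))

  expect_error(baseline_correct(spec[1:5, ]), class = "plastiN2O_schema_error")
})

test_that("polynomial baseline is available as an alternative", {
  x <- seq(600, 3200, 2)
  y <- gauss_spec(x, 1500, 10, 4) + 0.05 + 2e-5 * (x - 600)
  corr <- baseline_correct(tibble::tibble(wavenumber = x, intensity = y),
    method = "polynomial"
  )
  a <- band_intensity(corr, 1450, 1550)
  expect_lt(abs(a - 4) / 4, 0.05)
})

test_that("band intensity integrates or peaks over the window", {
  x <- seq(2000, 2400, 2)
  zero <- tibble::tibble(wavenumber = x, intensity = 0)
  expect_equal(band_intensity(zero, 2040, 2300), 0)

  rect <- tibble::tibble(wavenumber = x, intensity = 1)
  expect_equal(band_intensity(rect, 2040, 2300), 260)
  expect_equal(band_intensity(rect, 2040, 2300, mode = "peak_height"), 1)

  # Gaussian of known area inside the window, grid step 2
  g <- tibble::tibble(wavenumber = x, intensity = gauss_spec(x, 2170, 15, 7))
  expect_lt(abs(band_intensity(g, 2040, 2300) - 7) / 7, 0.01)

  # additivity over adjacent windows sharing a grid point
  expect_equal(
    band_intensity(g, 2040, 2170) + band_intensity(g, 2170, 2300),
    band_intensity(g, 2040, 2300),
    tolerance = 1e-9
  )
  expect_error(band_intensity(g, 3000, 3100), class = "plastiN2O_band_missing")
})

test_that("C-D ratio is bounded, scale-invariant and mode-consistent", {
  x <- seq(600, 3200, 2)
  mk <- function(a_cd, a_ch) {
    tibble::tibble(
      wavenumber = x,
      intensity = gauss_spec(x, 2150, 30, a_cd) + gauss_spec(x, 2930, 30, a_ch)
    )
  }
  expect_equal(cd_ratio(mk(0, 2)), 0, tolerance = 1e-6)
  expect_equal(cd_ratio(mk(1.5, 1.5)), 0.5, tolerance = 1e-3)

  # scaling the whole spectrum cancels
  spec <- mk(1, 3)
  scaled <- dplyr::mutate(spec, intensity = intensity * 37)
  expect_equal(cd_ratio(spec), cd_ratio(scaled), tolerance = 1e-12)

  # area and peak-height modes agree in rank ordering
  specs <- list(mk(0.2, 2), mk(0.8, 2), mk(2, 2))
  areas <- vapply(specs, cd_ratio, numeric(1), mode = "area")
  peaks <- vapply(specs, cd_ratio, numeric(1), mode = "peak_height")
  expect_equal(order(areas), order(peaks))

  expect_warning(r <- cd_ratio(mk(0, 0)))
  expect_true(is.na(r))
})

test_that("cohort processing recovers per-cell and group-level truth", {
  cfg <- scenario_config(n_cells = 6)
  sim <- gen_raman(cfg, seed = 31)
  cells <- process_spectra(sim$data)
  cmp <- dplyr::left_join(cells, sim$truth, by = c("cell_id", "group"))
  expect_lt(max(abs(cmp$cd_ratio - cmp$true_cd_ratio)), 0.05)
  # group ordering: every plastisphere group above bulk water
  gm <- dplyr::summarise(dplyr::group_by(cmp, group), m = mean(cd_ratio))
  expect_true(all(
    gm$m[gm$group != "bulk_water"] > gm$m[gm$group == "bulk_water"]
  ))
  # lipid band columns present and positive
  expect_true(all(c("lipid_972", "lipid_1735") %in% names(cells)))
  expect_true(all(cells$lipid_1032 > 0))
})
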