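test_that("reduction correction inverts the reduction shift as written", {
  ci <- reduction_correct(8.1, 57.8)
  expect_equal(ci$sp_nr, 3.6)
  expect_equal(ci$d18O_nr, 38.14)

  # f_R = 0: only the oxygen-exchange shift remains
  ci0 <- reduction_correct(8.1, 57.8, reduction_params(f_R = 0))
  expect_equal(ci0$sp_nr, 8.1)
  expect_equal(ci0$d18O_nr, 57.8 - 0.91)

  expect_error(reduction_params(f_R = 1.2), class = "plastiN2O_parameter_error")
})

test_that("the 3x3 endmember solve is exact and reports raw fractions", {
  # vertex of the simplex
  expect_equal(
    as.numeric(solve_fractions(-1.5, 19)), c(1, 0, 0),
    tolerance = 1e-12
  )
  # hand-built mixture 0.5 BD + 0.3 FD + 0.2 CD
  expect_equal(
    as.numeric(solve_fractions(13.55, 29.6)), c(0.5, 0.3, 0.2),
    tolerance = 1e-10
  )
  # bulk-water-like corrected values fall outside the simplex before clipping
  raw <- solve_fractions(3.6, 38)
  expect_true(any(raw < 0 | raw > 1))

  degen <- endmember_set(
    sp_mean = c(0, 10, 20), d18O_mean = c(0, 10, 20),
    sp_sd = rep(0, 3), d18O_sd = rep(0, 3)
  )
  expect_error(solve_fractions(5, 5, degen), class = "plastiN2O_degenerate_endmembers")
})

test_that("clipping zeroes negatives and renormalises proportionally", {
  out <- clip_fractions(tibble::tibble(f_BD = 1.2, f_FD = -0.3, f_CD = 0.1))
  expect_equal(as.numeric(out[1, 1:3]), c(12 / 13, 0, 1 / 13))
  expect_equal(out$clipped, "FD")

  ok <- clip_fractions(tibble::tibble(f_BD = 0.5, f_FD = 0.3, f_CD = 0.2))
  expect_equal(as.numeric(ok[1, 1:3]), c(0.5, 0.3, 0.2))
  expect_equal(ok$clipped, "")

  lone <- clip_fractions(tibble::tibble(f_BD = -0.2, f_FD = -0.1, f_CD = 1.3))
  expect_equal(as.numeric(lone[1, 1:3]), c(0, 0, 1))

  # idempotent
  twice <- clip_fractions(out[1:3])
  expect_equal(as.numeric(twice[1, 1:3]), as.numeric(out[1, 1:3]))

  expect_error(
    clip_fractions(tibble::tibble(f_BD = 0.5, f_FD = 0.3, f_CD = 0.1)),
    class = "plastiN2O_parameter_error"
  )
})

test_that("forward model and solve are exact inverses on the simplex", {
  fwd <- forward_model(tibble::tibble(f_BD = 1, f_FD = 0, f_CD = 0))
  expect_equal(fwd$sp_measured, 3.0)
  expect_equal(fwd$d18O_measured, 38.66)

  # vertex with no reduction and no water shift is the endmember itself
  em <- endmember_set()
  fwd0 <- forward_model(
    tibble::tibble(f_BD = 0, f_FD = 1, f_CD = 0),
    red = reduction_params(f_R = 0), h2o_d18O = 0
  )
  expect_equal(fwd0$sp_measured, em$sp_mean[2])
  expect_equal(fwd0$d18O_measured, em$d18O_mean[2])

  f <- random_simplex(100, seed = 9)
  fwd <- forward_model(tibble::as_tibble(f))
  ci <- reduction_correct(fwd$sp_measured, fwd$d18O_measured)
  back <- solve_fractions(ci$sp_nr, ci$d18O_nr)
  expect_lt(max(abs(as.matrix(back) - f)), 1e-10)
})

test_that("Monte Carlo partition is seeded, degenerates correctly and covers truth", {
  em0 <- endmember_set(sp_sd = rep(0, 3), d18O_sd = rep(0, 3))
  fit0 <- monte_carlo_partition(16.3, 48.16, endmembers = em0, n_draws = 50, seed = 2)
  det <- clip_fractions(solve_fractions(
    reduction_correct(16.3, 48.16)$sp_nr, reduction_correct(16.3, 48.16)$d18O_nr
  ))
  expect_equal(fit0$mc$mean, as.numeric(det[1, 1:3]), tolerance = 1e-12)
  expect_equal(fit0$mc$se, rep(0, 3))

  fit_a <- monte_carlo_partition(16.3, 48.16, n_draws = 300, seed = 7)
  fit_b <- monte_carlo_partition(16.3, 48.16, n_draws = 300, seed = 7)
  expect_identical(fit_a$mc, fit_b$mc)

  # per-draw clipping keeps reported means on the simplex
  sums <- fit_a$mc |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(s = sum(mean))
  expect_equal(sums$s, 1, tolerance = 1e-9)

  # uncertainty coverage: the forward-modelled truth lies within the draw
  # dispersion (mean +/- 3 sd) for every source
  truth <- c(0.6, 0.3, 0.1)
  meas <- forward_model(tibble::as_tibble(as.list(stats::setNames(truth, c("f_BD", "f_FD", "f_CD")))))
  fit <- monte_carlo_partition(meas$sp_measured, meas$d18O_measured, n_draws = 2000, seed = 5)
  expect_true(all(abs(fit$mc$mean - truth) <= 3 * fit$mc$sd))

  # SE shrinks roughly as 1/sqrt(n)
  fit_small <- monte_carlo_partition(16.3, 48.16, n_draws = 500, seed = 11)
  fit_large <- monte_carlo_partition(16.3, 48.16, n_draws = 2000, seed = 11)
  ratio <- mean(fit_small$mc$se / fit_large$mc$se)
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 2.7)
})

test_that("tidy and glance expose the partition in broom style", {
  fit <- monte_carlo_partition(c(16.3, 20), c(48.16, 60),
    n_draws = 100, seed = 1,
    sample_id = c("a", "b")
  )
  td <- tidy(fit)
  expect_equal(nrow(td), 6)
  expect_named(
    td,
    c("sample_id", "source", "estimate", "mean", "sd", "se", "clip_frequency")
  )
  gl <- glance(fit)
  expect_equal(gl$n_samples, 2)
  expect_equal(gl$n_draws, 100)
})

test_that("partition_sources wraps a measurement table sample-wise", {
  f <- tibble::tibble(f_BD = c(0.7, 0.4), f_FD = c(0.2, 0.5), f_CD = c(0.1, 0.1))
  meas <- forward_model(f)
  tbl <- tibble::tibble(
    sample_id = c("p1", "p2"), group = "PE",
    sp = meas$sp_measured, d18O = meas$d18O_measured
  )
  out <- partition_sources(tbl, n_draws = 50, seed = 3)
  expect_equal(out$f_BD, f$f_BD, tolerance = 1e-9)
  expect_equal(out$f_FD, f$f_FD, tolerance = 1e-9)
  expect_true(all(c("se_BD", "clip_frequency_CD", "clipped") %in% names(out)))
})
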