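test_that("all generators are bit-reproducible under a fixed seed", {
  cfg <- scenario_config(n_per_group = 3, n_cells = 2)
  expect_identical(gen_isotopes(cfg, 5), gen_isotopes(cfg, 5))
  expect_identical(gen_otu_table(cfg, 5), gen_otu_table(cfg, 5))
  expect_identical(gen_ct_table(cfg, 5), gen_ct_table(cfg, 5))
  expect_identical(gen_ipt(cfg, 5), gen_ipt(cfg, 5))
  expect_identical(gen_raman(cfg, 5), gen_raman(cfg, 5))
  # different seeds differ
  expect_false(identical(gen_isotopes(cfg, 5)$data, gen_isotopes(cfg, 6)$data))
})

test_that("forward-model mode with zero noise hits the exact isotope targets", {
  cfg <- scenario_config(
    n_per_group = 3,
    true_fractions = list(
      PE = c(1, 0, 0), PS = c(1, 0, 0), PP = c(1, 0, 0),
      PVC = c(1, 0, 0), bulk_water = c(1, 0, 0)
    ),
    isotope_noise = c(site = 0, d18O = 0)
  )
  sim <- gen_isotopes(cfg, seed = 2)
  meas <- add_isotopocules(sim$data)
  expect_equal(meas$sp, rep(3.0, nrow(meas)), tolerance = 1e-12)
  expect_equal(meas$d18O, rep(38.66, nrow(meas)), tolerance = 1e-12)

  bad <- scenario_config(true_fractions = list(
    PE = c(0.7, 0.7, -0.4), PS = c(1, 0, 0), PP = c(1, 0, 0),
    PVC = c(1, 0, 0), bulk_water = c(1, 0, 0)
  ))
  expect_error(gen_isotopes(bad, 1), class = "plastiN2O_config_error")
})

test_that("default scenario group means sit inside the observed isotope ranges", {
  sim <- gen_isotopes(scenario_config(n_per_group = 10), seed = 8)
  meas <- add_isotopocules(sim$data) |>
    dplyr::mutate(habitat = ifelse(group == "bulk_water", "bulk", "plast")) |>
    dplyr::group_by(habitat) |>
    dplyr::summarise(sp = mean(sp), d18O = mean(d18O))
  pl <- dplyr::filter(meas, habitat == "plast")
  bk <- dplyr::filter(meas, habitat == "bulk")
  expect_gt(pl$sp, 15.56); expect_lt(pl$sp, 26.21)
  expect_gt(pl$d18O, 64.14); expect_lt(pl$d18O, 77.82)
  expect_gt(bk$sp, 7.53); expect_lt(bk$sp, 8.68)
  expect_gt(bk$d18O, 55.62); expect_lt(bk$d18O, 59.93)
})

test_that("OTU generator produces richer plastisphere and controllable separation", {
  otu <- gen_otu_table(scenario_config(n_per_group = 4), seed = 12)
  rich <- diversity_indices(otu$data) |>
    dplyr::left_join(dplyr::distinct(otu$data, sample_id, group), by = "sample_id") |>
    dplyr::mutate(habitat = ifelse(group == "bulk_water", "bulk", "plast")) |>
    dplyr::group_by(habitat) |>
    dplyr::summarise(richness = mean(richness))
  expect_gt(
    rich$richness[rich$habitat == "plast"],
    rich$richness[rich$habitat == "bulk"]
  )

  # separation 0 collapses the habitat contrast (composition-wise)
  otu0 <- gen_otu_table(scenario_config(n_per_group = 4), seed = 12, separation = 0)
  keep <- !(names(otu0$data) %in% unlist(otu0$truth))
  d <- bray_curtis(otu0$data[keep])
  hab <- ifelse(otu0$data$group == "bulk_water", "b", "p")
  r0 <- anosim_test(d, hab, n_perm = 199, seed = 1)
  r1 <- anosim_test(bray_curtis(otu$data), ifelse(otu$data$group == "bulk_water", "b", "p"),
    n_perm = 199, seed = 1
  )
  expect_gt(r1$R, 0.8)
  expect_lt(r0$R, 0.3)
})

test_that("Ct generator lands the configured nir/nos bands per habitat", {
  ct <- gen_ct_table(scenario_config(n_per_group = 6), seed = 9)
  ratios <- nir_nos_ratio(normalize_to_16s(ct$data)) |>
    dplyr::left_join(dplyr::distinct(ct$data, sample_id, group), by = "sample_id") |>
    dplyr::mutate(habitat = ifelse(group == "bulk_water", "bulk", "plast")) |>
    dplyr::group_by(habitat) |>
    dplyr::summarise(ratio = mean(nir_nos_ratio))
  pl <- ratios$ratio[ratios$habitat == "plast"]
  bk <- ratios$ratio[ratios$habitat == "bulk"]
  expect_gt(pl, 1.5); expect_lt(pl, 2.3)
  expect_gt(bk, 0.33); expect_lt(bk, 0.41)
})

test_that("IPT generator round-trips configured shares and reduction ratio", {
  cfg <- scenario_config(n_per_group = 8)
  ipt <- gen_ipt(cfg, seed = 4)
  # acetylene pairs reproduce the configured f_R exactly
  expect_equal(
    n2o_reduction_ratio(ipt$data$n2o_without_c2h2, ipt$data$n2o_with_c2h2),
    rep(0.75, nrow(ipt$data))
  )
  # shares recovered exactly (noise is shared between t29 and t30)
  shares <- ipt_rates(ipt$data) |>
    dplyr::group_by(group) |>
    dplyr::summarise(share = mean(share_denit))
  cmp <- dplyr::left_join(shares, ipt$truth, by = "group")
  expect_equal(cmp$share, cmp$share_denit, tolerance = 1e-9)
})
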