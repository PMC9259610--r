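#' Default synthetic study scenario
#'
#' Bundles every parameter the seeded generators need to emulate a
#' plastisphere-vs-bulk-water denitrification study: four plastic habitats
#' (PE, PS, PP, PVC) plus bulk water, with measured N2O isotope values
#' calibrated to the observed group ranges (plastisphere SP 15.56-26.21
#' per mil and delta-18O 64.14-77.82 per mil; bulk water 7.53-8.68 and
#' 55.62-59.93), denitrifier OTU tables with higher plastisphere richness
#' and planted bnirK (plastisphere) / bnirS (bulk) hub taxa, qPCR Ct
#' tables configured so the (nirS+nirK)/nosZ ratio falls in 1.5-2.3
#' (plastisphere) vs 0.33-0.41 (bulk), Raman cohorts with true C-D ratio
#' means 0.18-0.29 vs 0.09, and isotope-pairing rates with a
#' denitrification share of N2 production near 0.8 and an acetylene-block
#' reduction ratio of 0.75.
#'
#' The isotope generator has two modes. With `true_fractions = NULL`
#' (default) each group's measured values are drawn from Gaussians
#' calibrated to the printed ranges: the four plastic types are staggered
#' at quantiles 1/8, 3/8, 5/8, 7/8 of the plastisphere range (within-type
#' SD = range width / 8) and bulk water sits at its mid-range (SD = width
#' / 4). Supplying per-group `true_fractions` instead forward-models
#' measurements from known source fractions (plus site-delta/delta-18O
#' noise), enabling parameter-recovery tests.
#'
#' @param n_per_group Samples per habitat group (default 6).
#' @param n_cells Raman cells per habitat class (default 40).
#' @param true_fractions Optional named list of 3-vectors (BD, FD, CD) per
#'   group switching the isotope generator to forward-model mode.
#' @param isotope_noise Named vector: `site` (per-mil SD of each site
#'   delta, default 0.9) and `d18O` (default 0.6); used in forward-model
#'   mode.
#' @param ct_sd Per-measurement Ct SD (default 0.1).
#' @param endmembers,red,h2o_d18O Mixing-model parameters (see
#'   [endmember_set()], [reduction_params()]).
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_per_group = 6, n_cells = 40,
                            true_fractions = NULL,
                            isotope_noise = c(site = 0.9, d18O = 0.6),
                            ct_sd = 0.1,
                            endmembers = endmember_set(),
                            red = reduction_params(),
                            h2o_d18O = 0.91) {
  plastic <- c("PE", "PS", "PP", "PVC")
  cfg <- list(
    groups = c(plastic, "bulk_water"),
    plastic_groups = plastic,
    n_per_group = n_per_group,
    n_cells = n_cells,
    true_fractions = true_fractions,
    isotope_noise = isotope_noise,
    # measured-value calibration targets (per-mil ranges)
    isotope_ranges = list(
      plastisphere = list(sp = c(15.56, 26.21), d18O = c(64.14, 77.82)),
      bulk_water = list(sp = c(7.53, 8.68), d18O = c(55.62, 59.93))
    ),
    d15N_bulk_mean = 10, d15N_bulk_sd = 2,
    endmembers = endmembers, red = red, h2o_d18O = h2o_d18O,
    # OTU generator
    otu = list(
      n_taxa = c(bnirS = 40, bnirK = 30, fnirK = 30),
      depth = 5000, concentration = 60,
      bulk_absent_frac = 0.3, # taxa missing from bulk water -> lower richness
      n_hubs = 4, n_satellites = 6, hub_jitter = 0.05
    ),
    # qPCR generator: per-group 16S Ct and 16S-normalised gene targets
    ct = list(
      sd = ct_sd,
      ct_16S = c(PE = 15, PS = 15, PP = 15, PVC = 15, bulk_water = 18),
      ct_ITS = c(PE = 20, PS = 20, PP = 20, PVC = 20, bulk_water = 24),
      norm_targets = list(
        # (nirS+nirK)/nosZ: 1.7, 1.9, 2.0, 2.1 (plastisphere types), 0.37 (bulk)
        PE = c(narG = 0.03, nirS = 0.05, nirK = 0.035, nosZ = 0.05),
        PS = c(narG = 0.03, nirS = 0.055, nirK = 0.04, nosZ = 0.05),
        PP = c(narG = 0.03, nirS = 0.06, nirK = 0.04, nosZ = 0.05),
        PVC = c(narG = 0.03, nirS = 0.063, nirK = 0.042, nosZ = 0.05),
        bulk_water = c(narG = 0.01, nirS = 0.01, nirK = 0.0048, nosZ = 0.04)
      )
    ),
    # Raman generator: true mean C-D ratio per habitat class
    raman = list(
      cd_means = c(PE = 0.18, PS = 0.22, PP = 0.25, PVC = 0.29, bulk_water = 0.09),
      cd_sd = 0.03, grid = seq(600, 3200, by = 2),
      cd_center = 2150, cd_width = 50, ch_center = 2930, ch_width = 50,
      lipid_centers = c(972, 1032, 1080, 1250, 1735), lipid_width = 4,
      lipid_area_frac = 0.06, drift = c(intercept = 0.02, slope = 2e-5, curve = 0.01),
      intensity_jitter = 0.1, noise_sd = 2e-5
    ),
    # isotope-pairing generator (rates in ug 15N L^-1 h^-1 equivalents)
    ipt = list(
      fn = 0.99,
      denit_rate = c(PE = 90, PS = 100, PP = 110, PVC = 120, bulk_water = 40),
      share_denit = c(PE = 0.80, PS = 0.80, PP = 0.80, PVC = 0.80, bulk_water = 0.75),
      rate_cv = 0.05,
      f_R = 0.75, n2o_total_mean = 2.4, n2o_total_cv = 0.1
    )
  )
  class(cfg) <- "scenario_config"
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(
    "Synthetic plastisphere scenario:", length(x$groups), "groups x",
    x$n_per_group, "samples;", sum(x$otu$n_taxa), "taxa;",
    x$n_cells, "Raman cells per habitat class\n"
  )
  invisible(x)
}

habitat_of <- function(group) ifelse(group == "bulk_water", "bulk_water", "plastisphere")

#' Generate N2O isotope measurements
#'
#' Produces a per-sample measurement table (`sample_id`, `group`,
#' `d15N_alpha`, `d15N_beta`, `d18O`) plus a ground-truth sidecar. See
#' [scenario_config()] for the two generation modes.
#'
#' @param cfg A [scenario_config()].
#' @param seed Integer seed; output is fully reproducible.
#' @return List with `data` (measurement tibble) and `truth` (per-sample
#'   targets: source fractions in forward-model mode, group target means
#'   otherwise).
#' @export
gen_isotopes <- function(cfg = scenario_config(), seed = 1) {
  stopifnot(inherits(cfg, "scenario_config"))
  qts <- c(1, 3, 5, 7) / 8
  withr::with_seed(seed, {
    rows <- purrr::imap(cfg$groups, function(g, gi) {
      n <- cfg$n_per_group
      id <- sprintf("%s_%02d", g, seq_len(n))
      if (!is.null(cfg$true_fractions)) {
        f <- cfg$true_fractions[[g]]
        if (is.null(f) || abs(sum(f) - 1) > 1e-9 || any(f < 0)) {
          abort(sprintf("`true_fractions` for group %s must lie on the simplex.", g),
            class = "plastiN2O_config_error"
          )
        }
        fwd <- forward_model(
          tibble(f_BD = f[1], f_FD = f[2], f_CD = f[3]),
          cfg$endmembers, cfg$red, cfg$h2o_d18O
        )
        bulk15 <- stats::rnorm(n, cfg$d15N_bulk_mean, cfg$d15N_bulk_sd)
        a <- bulk15 + fwd$sp_measured / 2 + stats::rnorm(n, 0, cfg$isotope_noise[["site"]])
        b <- bulk15 - fwd$sp_measured / 2 + stats::rnorm(n, 0, cfg$isotope_noise[["site"]])
        d18 <- fwd$d18O_measured + stats::rnorm(n, 0, cfg$isotope_noise[["d18O"]])
        truth <- tibble(
          sample_id = id, group = g, f_BD = f[1], f_FD = f[2], f_CD = f[3],
          sp_target = fwd$sp_measured, d18O_target = fwd$d18O_measured
        )
      } else {
        hab <- habitat_of(g)
        rg <- cfg$isotope_ranges[[hab]]
        if (hab == "plastisphere") {
          ti <- match(g, cfg$plastic_groups)
          sp_mu <- rg$sp[1] + qts[ti] * diff(rg$sp)
          o_mu <- rg$d18O[1] + qts[ti] * diff(rg$d18O)
          sp_sd <- diff(rg$sp) / 8
          o_sd <- diff(rg$d18O) / 8
        } else {
          sp_mu <- mean(rg$sp)
          o_mu <- mean(rg$d18O)
          sp_sd <- diff(rg$sp) / 4
          o_sd <- diff(rg$d18O) / 4
        }
        sp <- stats::rnorm(n, sp_mu, sp_sd)
        d18 <- stats::rnorm(n, o_mu, o_sd)
        bulk15 <- stats::rnorm(n, cfg$d15N_bulk_mean, cfg$d15N_bulk_sd)
        a <- bulk15 + sp / 2
        b <- bulk15 - sp / 2
        truth <- tibble(
          sample_id = id, group = g,
          f_BD = NA_real_, f_FD = NA_real_, f_CD = NA_real_,
          sp_target = sp_mu, d18O_target = o_mu
        )
      }
      list(
        data = tibble(sample_id = id, group = g, d15N_alpha = a, d15N_beta = b, d18O = d18),
        truth = truth
      )
    })
  })
  list(
    data = purrr::list_rbind(purrr::map(rows, "data")),
    truth = purrr::list_rbind(purrr::map(rows, "truth"))
  )
}

# Dirichlet draw via gamma variates
rdirichlet <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x[which.max(alpha)] <- 1
  x / sum(x)
}

#' Generate a denitrifier OTU table
#'
#' Dirichlet-multinomial counts with distinct plastisphere/bulk centroids,
#' a fraction of taxa absent from bulk water (higher plastisphere
#' richness), and planted proportional "hub" taxa — bnirK-type in the
#' plastisphere, bnirS-type in bulk water — that downstream network
#' analysis should recover as keystones.
#'
#' @inheritParams gen_isotopes
#' @param separation Scales how distinct the two habitat centroids are
#'   (0 = identical composition; 1 = default contrast).
#' @return List with `data` (wide tibble: `sample_id`, `group`, one column
#'   per taxon), `markers` (tibble `taxon`, `marker`) and `truth` (planted
#'   hub taxa per habitat).
#' @export
gen_otu_table <- function(cfg = scenario_config(), seed = 1, separation = 1) {
  stopifnot(inherits(cfg, "scenario_config"), separation >= 0)
  p <- cfg$otu
  taxa <- purrr::imap(
    p$n_taxa,
    function(k, m) sprintf("%s_%03d", m, seq_len(k))
  )
  markers <- tibble(
    taxon = unlist(taxa, use.names = FALSE),
    marker = rep(names(p$n_taxa), p$n_taxa)
  )
  n_tax <- nrow(markers)
  hubs_pl <- taxa$bnirK[seq_len(p$n_hubs)]
  sat_pl <- taxa$fnirK[seq_len(p$n_satellites)]
  hubs_bk <- taxa$bnirS[seq_len(p$n_hubs)]
  sat_bk <- taxa$bnirS[p$n_hubs + seq_len(p$n_satellites)]
  planted <- list(
    plastisphere = c(hubs_pl, sat_pl),
    bulk_water = c(hubs_bk, sat_bk)
  )

  withr::with_seed(seed, {
    # habitat centroids: shared log-normal base, habitat-specific tilt
    base <- stats::rlnorm(n_tax, 0, 1)
    tilt <- stats::rnorm(n_tax, 0, 1.2) * separation
    cen_pl <- base * exp(tilt / 2)
    cen_bk <- base * exp(-tilt / 2)
    # bulk water misses a fraction of taxa (never the planted ones)
    candidates <- setdiff(markers$taxon, unlist(planted))
    absent <- sample(candidates, round(p$bulk_absent_frac * n_tax * min(1, separation)))
    cen_bk[markers$taxon %in% absent] <- 0

    tabs <- purrr::map(cfg$groups, function(g) {
      cen <- if (habitat_of(g) == "plastisphere") cen_pl else cen_bk
      plant <- planted[[habitat_of(g)]]
      purrr::map(seq_len(cfg$n_per_group), function(i) {
        pr <- rdirichlet(p$concentration * cen / sum(cen))
        cnt <- as.numeric(stats::rmultinom(1, p$depth, pr))
        # planted block: all proportional to one latent factor per sample
        lat <- stats::rlnorm(1, log(p$depth / 50), 0.6)
        w <- seq(1.5, 0.5, length.out = length(plant))
        cnt[match(plant, markers$taxon)] <-
          round(lat * w * stats::rlnorm(length(plant), 0, p$hub_jitter))
        tibble(
          sample_id = sprintf("%s_%02d", g, i), group = g,
          !!!setNames(as.list(cnt), markers$taxon)
        )
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  })
  list(data = tabs, markers = markers, truth = planted)
}

#' Generate a qPCR Ct table
#'
#' Gaussian Ct values per gene per sample, configured through per-group
#' 16S Ct levels and 16S-normalised abundance targets so that the
#' (nirS+nirK)/nosZ ratio lands in the plastisphere band 1.5-2.3 and the
#' bulk-water band 0.33-0.41.
#'
#' @inheritParams gen_isotopes
#' @return List with `data` (long tibble `sample_id`, `group`, `gene`,
#'   `ct`) and `truth` (configured normalised abundances and ratios).
#' @export
gen_ct_table <- function(cfg = scenario_config(), seed = 1) {
  stopifnot(inherits(cfg, "scenario_config"))
  p <- cfg$ct
  slope <- 3.33
  withr::with_seed(seed, {
    data <- purrr::map(cfg$groups, function(g) {
      tg <- p$norm_targets[[g]]
      ct_mu <- c(
        `16S` = p$ct_16S[[g]], ITS = p$ct_ITS[[g]],
        setNames(p$ct_16S[[g]] - slope * log10(tg), names(tg))
      )
      purrr::map(seq_len(cfg$n_per_group), function(i) {
        tibble(
          sample_id = sprintf("%s_%02d", g, i), group = g,
          gene = names(ct_mu),
          ct = stats::rnorm(length(ct_mu), unname(ct_mu), p$sd)
        )
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  })
  truth <- purrr::imap(p$norm_targets, function(tg, g) {
    tibble(
      group = g, gene = names(tg), normalized_target = unname(tg),
      nir_nos_target = (tg[["nirS"]] + tg[["nirK"]]) / tg[["nosZ"]]
    )
  }) |> purrr::list_rbind()
  list(data = data, truth = truth)
}

gaussian_peak <- function(x, center, width, area) {
  area / (width * sqrt(2 * pi)) * exp(-(x - center)^2 / (2 * width^2))
}

#' Generate single-cell Raman spectra
#'
#' Per-cell spectra built from Gaussian C-D and C-H envelopes whose areas
#' realise a drawn true C-D ratio, five narrow lipid bands, a linear plus
#' curved baseline drift, multiplicative intensity jitter and a small
#' additive noise floor.
#'
#' @inheritParams gen_isotopes
#' @return List with `data` (long tibble `cell_id`, `group`, `wavenumber`,
#'   `intensity`) and `truth` (per-cell true C-D ratio and band areas).
#' @export
gen_raman <- function(cfg = scenario_config(), seed = 1) {
  stopifnot(inherits(cfg, "scenario_config"))
  p <- cfg$raman
  x <- p$grid
  withr::with_seed(seed, {
    cells <- purrr::map(names(p$cd_means), function(g) {
      purrr::map(seq_len(cfg$n_cells), function(i) {
        r <- min(0.95, max(0, stats::rnorm(1, p$cd_means[[g]], p$cd_sd)))
        scale_i <- stats::rlnorm(1, 0, p$intensity_jitter)
        a_ch <- 1 * scale_i
        a_cd <- r / (1 - r) * a_ch
        a_lip <- p$lipid_area_frac * a_ch
        y <- gaussian_peak(x, p$cd_center, p$cd_width, a_cd) +
          gaussian_peak(x, p$ch_center, p$ch_width, a_ch)
        for (ctr in p$lipid_centers) {
          y <- y + gaussian_peak(x, ctr, p$lipid_width, a_lip)
        }
        drift <- p$drift[["intercept"]] + p$drift[["slope"]] * (x - 600) +
          p$drift[["curve"]] * sin((x - 600) / 2600 * pi) * scale_i
        y <- y + drift + stats::rnorm(length(x), 0, p$noise_sd)
        list(
          data = tibble(
            cell_id = sprintf("%s_cell_%03d", g, i), group = g,
            wavenumber = x, intensity = y
          ),
          truth = tibble(
            cell_id = sprintf("%s_cell_%03d", g, i), group = g,
            true_cd_ratio = r, true_cd_area = a_cd, true_ch_area = a_ch,
            true_lipid_area = a_lip
          )
        )
      })
    })
  })
  cells <- purrr::flatten(cells)
  list(
    data = purrr::list_rbind(purrr::map(cells, "data")),
    truth = purrr::list_rbind(purrr::map(cells, "truth"))
  )
}

#' Generate isotope-pairing and acetylene-block tables
#'
#' Draws 29N2/30N2 production rates consistent with each group's
#' configured total denitrification rate and denitrification share of N2
#' production (the anammox excess supplies the remainder), plus acetylene
#' pairs whose residual/total ratio equals the configured reduction ratio
#' exactly (noise enters through the total only).
#'
#' @inheritParams gen_isotopes
#' @return List with `data` (tibble `sample_id`, `group`, `t29`, `t30`,
#'   `fn`, `n2o_without_c2h2`, `n2o_with_c2h2`) and `truth` (configured
#'   rates, shares and reduction ratio).
#' @export
gen_ipt <- function(cfg = scenario_config(), seed = 1) {
  stopifnot(inherits(cfg, "scenario_config"))
  p <- cfg$ipt
  withr::with_seed(seed, {
    data <- purrr::map(cfg$groups, function(g) {
      n <- cfg$n_per_group
      noise <- stats::rlnorm(n, 0, p$rate_cv)
      d_rate <- p$denit_rate[[g]] * noise
      t30 <- d_rate * p$fn / 2
      anammox <- d_rate * (1 / p$share_denit[[g]] - 1)
      t29 <- 2 * t30 * (1 - p$fn) / p$fn + anammox
      total <- p$n2o_total_mean * stats::rlnorm(n, 0, p$n2o_total_cv)
      tibble(
        sample_id = sprintf("%s_%02d", g, seq_len(n)), group = g,
        t29 = t29, t30 = t30, fn = p$fn,
        n2o_without_c2h2 = p$f_R * total, n2o_with_c2h2 = total
      )
    }) |> purrr::list_rbind()
  })
  truth <- tibble(
    group = cfg$groups,
    denit_rate = unname(p$denit_rate[cfg$groups]),
    share_denit = unname(p$share_denit[cfg$groups]),
    f_R = p$f_R
  )
  list(data = data, truth = truth)
}
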