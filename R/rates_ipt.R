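#' Denitrification rate from 15N isotope pairing
#'
#' With a nitrate pool at 15N atom fraction `fn`, denitrification produces
#' 30N2 with probability `fn^2` per N2 pair; the total genuine
#' denitrification rate follows from the 30N2 production rate alone as
#' `t30 * 2 * (1 - fn) / fn + 2 * t30`, which simplifies algebraically to
#' `2 * t30 / fn`.
#'
#' @param t30 Production rate of 30N2 (mass N per volume per time).
#'   Vectorised.
#' @param fn 15N atom fraction of the nitrate pool, in `(0, 1]` (0.99 for a
#'   99 atom-percent label).
#' @return Denitrification rate in the same mass-per-volume-per-time units
#'   as `t30` (as 15N when `t30` is).
#' @export
#' @examples
#' denitrification_rate(49.5, fn = 0.99) # 100
denitrification_rate <- function(t30, fn = 0.99) {
  check_finite(t30)
  check_finite(fn)
  if (any(fn <= 0) || any(fn > 1)) {
    abort("`fn` must lie in (0, 1].", class = "plastiN2O_parameter_error")
  }
  if (any(t30 < 0)) {
    abort("`t30` must be non-negative.", class = "plastiN2O_parameter_error")
  }
  t30 * 2 * (1 - fn) / fn + 2 * t30
}

#' Denitrification vs anammox share of N2 production
#'
#' Partitions total N2 production between denitrification and anammox from
#' the 29N2 and 30N2 production rates, following the revised isotope
#' pairing convention: denitrification draws both N atoms from the nitrate
#' pool (binomially), so its expected 29N2 production is `2 * t30 * (1 -
#' fn) / fn`; any 29N2 excess over that expectation is attributed to
#' anammox (which pairs one labelled with one ambient N). The excess is
#' floored at zero (flagged) when the measured 29N2 falls below the
#' binomial expectation.
#'
#' @param t29,t30 Production rates of 29N2 and 30N2. Vectorised.
#' @inheritParams denitrification_rate
#' @return Tibble with columns `denitrification`, `anammox` (rates),
#'   `share_denit`, `share_anammox` (fractions summing to 1) and
#'   `anammox_clipped` (logical flag).
#' @export
#' @examples
#' denit_anammox_share(t29 = 0.52525, t30 = 1, fn = 0.99) # share_denit 0.8
denit_anammox_share <- function(t29, t30, fn = 0.99) {
  check_finite(t29)
  check_finite(t30)
  d <- denitrification_rate(t30, fn)
  expected_29 <- 2 * t30 * (1 - fn) / fn
  excess <- t29 - expected_29
  clipped <- excess < 0
  if (any(clipped)) {
    warn("29N2 below the binomial denitrification expectation for some samples; anammox rate floored at 0.")
  }
  a <- pmax(0, excess)
  tot <- d + a
  if (any(tot == 0)) {
    abort("Denitrification and anammox rates are both zero; shares undefined.",
      class = "plastiN2O_undefined_share"
    )
  }
  tibble(
    denitrification = d, anammox = a,
    share_denit = d / tot, share_anammox = a / tot,
    anammox_clipped = clipped
  )
}

#' Codenitrification indicator
#'
#' Codenitrification pairs one labelled and one ambient nitrogen atom and
#' therefore produces 29N2 rather than 30N2. A high `t30 / (t29 + t30)`
#' ratio indicates labelling dominated by true denitrification; low values
#' flag possible codenitrification (or anammox) contributions.
#'
#' @inheritParams denit_anammox_share
#' @return Ratio in `[0, 1]`.
#' @export
#' @examples
#' codenitrification_indicator(t29 = 1, t30 = 3) # 0.75
codenitrification_indicator <- function(t29, t30) {
  check_finite(t29)
  check_finite(t30)
  tot <- t29 + t30
  if (any(tot <= 0)) {
    abort("`t29 + t30` must be positive.", class = "plastiN2O_parameter_error")
  }
  t30 / tot
}

#' Acetylene-block N2O reduction ratio
#'
#' Acetylene blocks N2O reductase, so N2O measured with acetylene is total
#' production while N2O without acetylene is the residual after reduction.
#' Their ratio is the reduction ratio `f_R` used by the mass-balance
#' correction (0.75 in the default parameterisation).
#'
#' @param n2o_without_c2h2 Residual N2O concentration (no acetylene).
#' @param n2o_with_c2h2 Total N2O concentration (acetylene block).
#' @return `f_R` in `[0, 1]`.
#' @export
#' @examples
#' n2o_reduction_ratio(1.8, 2.4) # 0.75
n2o_reduction_ratio <- function(n2o_without_c2h2, n2o_with_c2h2) {
  check_finite(n2o_without_c2h2)
  check_finite(n2o_with_c2h2)
  if (any(n2o_without_c2h2 < 0) || any(n2o_with_c2h2 <= 0)) {
    abort("Concentrations must be non-negative with a positive total.",
      class = "plastiN2O_parameter_error"
    )
  }
  if (any(n2o_without_c2h2 > n2o_with_c2h2)) {
    abort("Residual N2O exceeds total N2O; inconsistent acetylene pair.",
      class = "plastiN2O_inconsistent_pair"
    )
  }
  n2o_without_c2h2 / n2o_with_c2h2
}

#' Per-cell normalisation
#'
#' Divides a volumetric quantity by a cell density, typically derived from
#' absolute 16S rRNA gene abundance via [cells_from_16S()] (mean rRNA
#' operon copy number 4.1 per cell).
#'
#' @param value Amount per volume. Vectorised.
#' @param cells Cells per volume (same volume basis).
#' @return Amount per cell.
#' @export
#' @examples
#' per_cell(1e6, cells_from_16S(4.1e6)) # 1
per_cell <- function(value, cells) {
  check_finite(value)
  check_finite(cells)
  if (any(cells <= 0)) {
    abort("`cells` must be positive.", class = "plastiN2O_parameter_error")
  }
  value / cells
}

#' CO2-equivalent of an N2O production rate
#'
#' Plumbing multiplier converting an N2O mass rate to CO2 equivalents with
#' a configurable global-warming-potential factor (default 298, the
#' conventional 100-year GWP; not a package-specific estimate).
#'
#' @param n2o_mass_rate N2O mass rate (e.g. mg N2O L^-1 d^-1).
#' @param gwp_factor Dimensionless GWP factor.
#' @return CO2-equivalent mass rate.
#' @export
co2_equivalent <- function(n2o_mass_rate, gwp_factor = 298) {
  check_finite(n2o_mass_rate)
  check_finite(gwp_factor)
  if (any(n2o_mass_rate < 0) || any(gwp_factor < 0)) {
    abort("Rate and GWP factor must be non-negative.", class = "plastiN2O_parameter_error")
  }
  n2o_mass_rate * gwp_factor
}

#' Isotope-pairing rates for a measurement table
#'
#' Table wrapper computing, per sample, the denitrification rate, the
#' denitrification/anammox shares and the codenitrification indicator.
#'
#' @param data Data frame with columns `sample_id`, `t29`, `t30` and
#'   optionally `fn` (default 0.99).
#' @return The input as a tibble with rate and share columns appended.
#' @export
ipt_rates <- function(data) {
  check_df_cols(data, c("sample_id", "t29", "t30"))
  out <- as_tibble(data)
  if (!"fn" %in% names(out)) out$fn <- 0.99
  bind_cols(
    out,
    denit_anammox_share(out$t29, out$t30, out$fn),
    tibble(codenit_indicator = codenitrification_indicator(out$t29, out$t30))
  )
}
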