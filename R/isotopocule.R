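#' N2O isotopocule arithmetic
#'
#' The two nitrogen atoms of the linear N2O molecule are isotopically
#' distinguishable: the central (alpha) and terminal (beta) positions carry
#' separate delta-15N values. Two derived quantities drive source
#' diagnosis:
#'
#' * bulk delta-15N, the mean of the two site deltas;
#' * site preference (SP), their difference `d15N_alpha - d15N_beta`,
#'   which is largely independent of substrate isotopic composition and
#'   differs strongly between bacterial and fungal denitrification.
#'
#' @param d15N_alpha,d15N_beta Site-specific delta-15N values (per mil vs
#'   atmospheric N2). Vectorised.
#' @return Per-mil value(s).
#' @export
#' @examples
#' site_preference(10, 4) # 6
#' bulk_delta(10, 4)      # 7
site_preference <- function(d15N_alpha, d15N_beta) {
  check_finite(d15N_alpha)
  check_finite(d15N_beta)
  d15N_alpha - d15N_beta
}

#' @rdname site_preference
#' @export
bulk_delta <- function(d15N_alpha, d15N_beta) {
  check_finite(d15N_alpha)
  check_finite(d15N_beta)
  (d15N_alpha + d15N_beta) / 2
}

#' Two-point site-preference calibration
#'
#' `sp_calibration()` builds the affine map fixed by two reference gases of
#' known SP measured on the same instrument (e.g. AK1 at -2 per mil and a
#' mixture standard at 15 per mil). `calibrate_sp()` applies it; both
#' standards map exactly to their true values.
#'
#' @param standard_a_true,standard_a_measured,standard_b_true,standard_b_measured
#'   True and measured SP of the two standards (per mil).
#' @return `sp_calibration()`: an object of class `sp_calibration` (slope,
#'   intercept and the four anchor values). `calibrate_sp()`: calibrated SP.
#' @export
#' @examples
#' cal <- sp_calibration(-2, -4, 15, 13)
#' calibrate_sp(-4, cal)  # -2
#' calibrate_sp(4.5, cal) # 6.5
sp_calibration <- function(standard_a_true, standard_a_measured,
                           standard_b_true, standard_b_measured) {
  check_finite(standard_a_true)
  check_finite(standard_a_measured)
  check_finite(standard_b_true)
  check_finite(standard_b_measured)
  if (standard_a_measured == standard_b_measured) {
    abort(
      "The two standards have identical measured SP; calibration is undefined.",
      class = "plastiN2O_calibration_undefined"
    )
  }
  slope <- (standard_b_true - standard_a_true) /
    (standard_b_measured - standard_a_measured)
  structure(
    list(
      slope = slope,
      intercept = standard_a_true - slope * standard_a_measured,
      standards = c(
        a_true = standard_a_true, a_measured = standard_a_measured,
        b_true = standard_b_true, b_measured = standard_b_measured
      )
    ),
    class = "sp_calibration"
  )
}

#' @param raw_sp Measured (uncalibrated) SP, per mil. Vectorised.
#' @param cal An `sp_calibration` object.
#' @rdname sp_calibration
#' @export
calibrate_sp <- function(raw_sp, cal) {
  check_finite(raw_sp)
  stopifnot(inherits(cal, "sp_calibration"))
  cal$intercept + cal$slope * raw_sp
}

#' @export
print.sp_calibration <- function(x, ...) {
  cat(
    "Two-point SP calibration: calibrated =",
    format(x$intercept, digits = 4), "+", format(x$slope, digits = 4), "* measured\n"
  )
  invisible(x)
}

#' Oxygen-exchange correction of N2O delta-18O
#'
#' During denitrification the N2O oxygen pool exchanges (here assumed
#' completely) with ambient water, so the water's delta-18O is subtracted
#' from the measured N2O delta-18O to place values on the N2O/H2O scale
#' used by the dual-isotope mixing model. The default water value, 0.91 per
#' mil vs VSMOW, is a literature surface-seawater value (global surface
#' seawater spans roughly -2.98 to 1 per mil).
#'
#' @param d18O_measured Measured N2O delta-18O (per mil vs VSMOW). Vectorised.
#' @param h2o_d18O Ambient-water delta-18O (per mil vs VSMOW).
#' @return Corrected delta-18O on the N2O/H2O scale, per mil.
#' @export
#' @examples
#' o_exchange_correct(55.62) # 54.71
o_exchange_correct <- function(d18O_measured, h2o_d18O = 0.91) {
  check_finite(d18O_measured)
  check_finite(h2o_d18O)
  d18O_measured - h2o_d18O
}

#' Derive isotopocule quantities for a measurement table
#'
#' Takes a per-sample table of site-specific N2O isotope values and appends
#' the derived bulk delta-15N, site preference (optionally two-point
#' calibrated) and oxygen-exchange-corrected delta-18O.
#'
#' @param data Data frame with columns `sample_id`, `group`, `d15N_alpha`,
#'   `d15N_beta`, `d18O`.
#' @param cal Optional `sp_calibration` applied to the derived SP.
#' @param h2o_d18O Ambient-water delta-18O (per mil), see
#'   [o_exchange_correct()].
#' @return The input as a tibble with `d15N_bulk`, `sp` and
#'   `d18O_corrected` columns appended.
#' @export
#' @examples
#' tbl <- tibble::tibble(
#'   sample_id = "s1", group = "bulk_water",
#'   d15N_alpha = 11.815, d15N_beta = 4.285, d18O = 55.62
#' )
#' add_isotopocules(tbl)
add_isotopocules <- function(data, cal = NULL, h2o_d18O = 0.91) {
  check_df_cols(data, c("sample_id", "group", "d15N_alpha", "d15N_beta", "d18O"))
  out <- as_tibble(data) |>
    mutate(
      d15N_bulk = bulk_delta(.data$d15N_alpha, .data$d15N_beta),
      sp = site_preference(.data$d15N_alpha, .data$d15N_beta),
      d18O_corrected = o_exchange_correct(.data$d18O, h2o_d18O)
    )
  if (!is.null(cal)) {
    out <- mutate(out, sp = calibrate_sp(.data$sp, cal))
  }
  out
}
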