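#' Default Raman band definitions
#'
#' The C-D stretch window (2040-2300 cm^-1) captures carbon-deuterium
#' bonds formed when metabolically active cells incorporate deuterium from
#' heavy water; C-H (2800-3100 cm^-1) is the corresponding protiated
#' envelope. Five single lipid/fatty-acid bands (972, 1032, 1080, 1250,
#' 1735 cm^-1) are given a configurable half-window.
#'
#' @param half_window Half-width (cm^-1) around the single lipid bands.
#' @return Tibble with columns `band`, `lo`, `hi`.
#' @export
raman_bands <- function(half_window = 10) {
  centers <- c(972, 1032, 1080, 1250, 1735)
  tibble(
    band = c("CD", "CH", paste0("lipid_", centers)),
    lo = c(2040, 2800, centers - half_window),
    hi = c(2300, 3100, centers + half_window)
  )
}

check_spectrum <- function(spec) {
  check_df_cols(spec, c("wavenumber", "intensity"))
  if (is.unsorted(spec$wavenumber, strictly = TRUE)) {
    abort("`wavenumber` must be strictly increasing.", class = "plastiN2O_schema_error")
  }
  check_finite(spec$intensity, "intensity")
  invisible(spec)
}

#' Calibrate the wavenumber axis against the silicon reference
#'
#' Shifts the wavenumber grid so that the observed position of the silicon
#' wafer band aligns with its reference value (520.6 cm^-1). A pure shift,
#' so band areas are preserved.
#'
#' @param spec Data frame with columns `wavenumber` (strictly increasing,
#'   cm^-1) and `intensity`.
#' @param observed_si_peak Observed silicon band position (must lie on the
#'   grid span).
#' @param reference Reference position, cm^-1.
#' @return The spectrum with shifted wavenumbers.
#' @export
calibrate_axis <- function(spec, observed_si_peak, reference = 520.6) {
  check_spectrum(spec)
  check_finite(observed_si_peak)
  if (observed_si_peak < min(spec$wavenumber) || observed_si_peak > max(spec$wavenumber)) {
    abort("Observed silicon peak lies outside the wavenumber grid.",
      class = "plastiN2O_calibration_error"
    )
  }
  mutate(as_tibble(spec), wavenumber = .data$wavenumber + (reference - observed_si_peak))
}

# Whittaker-smoother asymmetric least squares baseline: penalised least
# squares with second-difference penalty `smoothness` and asymmetric
# weights (`asymmetry` for points above the baseline).
als_baseline <- function(y, smoothness = 1e5, asymmetry = 0.02, n_iter = 10) {
  n <- length(y)
  D <- Matrix::bandSparse(n - 2, n,
    k = 0:2,
    diagonals = list(rep(1, n - 2), rep(-2, n - 2), rep(1, n - 2))
  )
  P <- smoothness * Matrix::crossprod(D)
  w <- rep(1, n)
  z <- y
  for (i in seq_len(n_iter)) {
    W <- Matrix::Diagonal(n, w)
    z <- as.numeric(Matrix::solve(W + P, w * y))
    w_new <- ifelse(y > z, asymmetry, 1 - asymmetry)
    if (max(abs(w_new - w)) < 1e-12) break
    w <- w_new
  }
  z
}

#' Baseline-correct a Raman spectrum
#'
#' Estimates a smooth fluorescence/drift baseline and subtracts it. The
#' default is an asymmetric least squares (Whittaker smoother) baseline
#' with two parameters: `smoothness` (penalty on the baseline's second
#' differences; larger = stiffer) and `asymmetry` (weight given to points
#' above the baseline, so peaks are ignored while the baseline hugs the
#' valleys). A polynomial baseline (iteratively peak-stripped) is
#' available as an alternative.
#'
#' @inheritParams calibrate_axis
#' @param smoothness Positive stiffness penalty (default 1e5, for grids of
#'   roughly 1-2 cm^-1 step).
#' @param asymmetry Asymmetry weight in (0, 1), default 0.02.
#' @param method `"als"` (default) or `"polynomial"`.
#' @param degree Polynomial degree for `method = "polynomial"`.
#' @return The spectrum with `intensity` replaced by the corrected values
#'   and the estimated `baseline` appended.
#' @export
baseline_correct <- function(spec, smoothness = 1e5, asymmetry = 0.02,
                             method = c("als", "polynomial"), degree = 3) {
  check_spectrum(spec)
  method <- match.arg(method)
  if (nrow(spec) < 10) {
    abort("Need at least 10 points to estimate a baseline.",
      class = "plastiN2O_schema_error"
    )
  }
  if (method == "als") {
    stopifnot(smoothness > 0, asymmetry > 0, asymmetry < 1)
    base <- als_baseline(spec$intensity, smoothness, asymmetry)
  } else {
    # iterative polynomial peak stripping: refit on the running minimum so
    # peaks stop pulling the fit upward
    y <- spec$intensity
    X <- cbind(1, stats::poly(spec$wavenumber, degree))
    base <- y
    for (i in 1:10) {
      fit <- stats::lm.fit(X, y)
      base <- as.numeric(X %*% fit$coefficients)
      y <- pmin(y, base)
    }
  }
  mutate(as_tibble(spec), baseline = base, intensity = .data$intensity - base)
}

#' Integrated or peak band intensity
#'
#' Summarises corrected intensity over a band window, either as the
#' trapezoidal integral (default, robust for the wide C-D/C-H windows) or
#' the maximum ("peak_height"). Negative corrected values are floored at
#' zero before summarising.
#'
#' @inheritParams calibrate_axis
#' @param lo,hi Band window bounds (cm^-1).
#' @param mode `"area"` (default) or `"peak_height"`.
#' @return Non-negative scalar.
#' @export
#' @examples
#' spec <- tibble::tibble(wavenumber = 2000:2400, intensity = 1)
#' band_intensity(spec, 2040, 2300) # 260 (rectangle area)
band_intensity <- function(spec, lo, hi, mode = c("area", "peak_height")) {
  check_spectrum(spec)
  mode <- match.arg(mode)
  stopifnot(lo < hi)
  sel <- spec$wavenumber >= lo & spec$wavenumber <= hi
  if (!any(sel)) {
    abort(sprintf("No grid points in band window [%s, %s].", lo, hi),
      class = "plastiN2O_band_missing"
    )
  }
  y <- pmax(0, spec$intensity[sel])
  if (mode == "area") trapz_int(spec$wavenumber[sel], y) else max(y)
}

#' Deuterium-labelling activity ratio
#'
#' The (C-D)/(C-D + C-H) band ratio quantifies deuterium incorporation
#' from heavy water into biomass and hence single-cell metabolic activity.
#' Both bands are summarised in the same mode, so the ratio is invariant
#' to overall intensity scaling.
#'
#' @inheritParams band_intensity
#' @param bands Band definitions, see [raman_bands()].
#' @return Ratio in `[0, 1]`, or `NA` (with a warning) when both bands are
#'   zero.
#' @export
cd_ratio <- function(spec, mode = c("area", "peak_height"), bands = raman_bands()) {
  mode <- match.arg(mode)
  cd <- filter(bands, .data$band == "CD")
  ch <- filter(bands, .data$band == "CH")
  i_cd <- band_intensity(spec, cd$lo, cd$hi, mode)
  i_ch <- band_intensity(spec, ch$lo, ch$hi, mode)
  if (i_cd + i_ch == 0) {
    warn("Both C-D and C-H band intensities are zero; ratio undefined.")
    return(NA_real_)
  }
  i_cd / (i_cd + i_ch)
}

#' Area-normalise a spectrum
#'
#' Scales intensities so the integrated intensity over the window (default
#' 600-3200 cm^-1) is 1, making single-band intensities comparable across
#' cells.
#'
#' @inheritParams calibrate_axis
#' @param window Normalisation window, cm^-1.
#' @return The normalised spectrum.
#' @export
normalize_spectrum <- function(spec, window = c(600, 3200)) {
  check_spectrum(spec)
  sel <- spec$wavenumber >= window[1] & spec$wavenumber <= window[2]
  total <- trapz_int(spec$wavenumber[sel], pmax(0, spec$intensity[sel]))
  if (total <= 0) {
    abort("Non-positive total intensity in the normalisation window.",
      class = "plastiN2O_schema_error"
    )
  }
  mutate(as_tibble(spec), intensity = .data$intensity / total)
}

#' Process a cohort of single-cell spectra
#'
#' For each cell in a long-format spectra table: baseline-correct, compute
#' the C-D activity ratio on the corrected (un-normalised) intensities,
#' then area-normalise and extract the five lipid-band intensities.
#'
#' @param data Long data frame with columns `cell_id`, `group`,
#'   `wavenumber`, `intensity`.
#' @param bands Band definitions, see [raman_bands()].
#' @param mode Intensity mode passed to [band_intensity()].
#' @inheritParams baseline_correct
#' @return Tibble with one row per cell: `cell_id`, `group`, `cd_ratio`
#'   and one column per lipid band.
#' @export
process_spectra <- function(data, bands = raman_bands(), mode = "area",
                            smoothness = 1e5, asymmetry = 0.02) {
  check_df_cols(data, c("cell_id", "group", "wavenumber", "intensity"))
  lipid <- filter(bands, grepl("^lipid_", .data$band))
  as_tibble(data) |>
    group_by(.data$cell_id, .data$group) |>
    group_modify(function(spec, key) {
      corr <- baseline_correct(spec, smoothness, asymmetry)
      ratio <- cd_ratio(corr, mode, bands)
      norm <- normalize_spectrum(corr)
      lip <- purrr::pmap_dbl(
        lipid[c("lo", "hi")],
        function(lo, hi) band_intensity(norm, lo, hi, mode)
      )
      bind_cols(tibble(cd_ratio = ratio), as_tibble(setNames(as.list(lip), lipid$band)))
    }) |>
    ungroup()
}
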