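#' Isotopic endmembers of the three N2O sources
#'
#' The dual-isotope mixing model places each N2O source at a point in the
#' (SP, delta-18O) plane, with literature ranges expressing endmember
#' uncertainty. Defaults are the point values and literature ranges used
#' throughout the package (delta-18O on the N2O/H2O scale):
#'
#' | source | SP point | SP range | d18O point | d18O range |
#' |--------|----------|-------------|------------|---------------|
#' | BD (bacterial denitrification) | -1.5 | -7.5 to 3.7 | 19 | 16.4 to 23.3 |
#' | FD (fungal denitrification)    | 37   | 27.2 to 39.9 | 47 | 42.0 to 55.1 |
#' | CD (chemodenitrification)      | 16   | 10 to 22     | 30 | 24.9 to 37.6 |
#'
#' Gaussian spreads for Monte Carlo sampling default to a quarter of the
#' range width, which puts about 95% of the mass inside the literature
#' range.
#'
#' @param sources Character vector of source names (rows of the table).
#' @param sp_mean,d18O_mean Point values, per mil.
#' @param sp_lo,sp_hi,d18O_lo,d18O_hi Literature range bounds, per mil.
#' @param sp_sd,d18O_sd Gaussian SDs for Monte Carlo sampling; default
#'   `(hi - lo) / 4`.
#' @return A tibble with one row per source, class `endmember_set`.
#' @export
#' @examples
#' endmember_set()
endmember_set <- function(sources = c("BD", "FD", "CD"),
                          sp_mean = c(-1.5, 37, 16),
                          sp_lo = c(-7.5, 27.2, 10),
                          sp_hi = c(3.7, 39.9, 22),
                          d18O_mean = c(19, 47, 30),
                          d18O_lo = c(16.4, 42.0, 24.9),
                          d18O_hi = c(23.3, 55.1, 37.6),
                          sp_sd = (sp_hi - sp_lo) / 4,
                          d18O_sd = (d18O_hi - d18O_lo) / 4) {
  stopifnot(
    length(sources) == 3,
    all(lengths(list(sp_mean, sp_sd, d18O_mean, d18O_sd)) == 3),
    all(sp_sd >= 0), all(d18O_sd >= 0)
  )
  out <- tibble(
    source = as.character(sources),
    sp_mean = sp_mean, sp_lo = sp_lo, sp_hi = sp_hi, sp_sd = sp_sd,
    d18O_mean = d18O_mean, d18O_lo = d18O_lo, d18O_hi = d18O_hi,
    d18O_sd = d18O_sd
  )
  class(out) <- c("endmember_set", class(out))
  out
}

#' N2O reduction correction parameters
#'
#' Partial reduction of N2O to N2 enriches the remaining N2O in both SP and
#' delta-18O. The linear correction uses the reduction ratio `f_R`
#' (fraction of produced N2O remaining, estimated by the acetylene block,
#' 0.75 by default) and net isotope effects `sp_epsilon` (-6 per mil) and
#' `d18O_epsilon` (-25 per mil); the ratio of the two effects (0.25) is the
#' slope of the reduction line in the dual-isotope plot.
#'
#' @param f_R Reduction ratio in `[0, 1]`.
#' @param sp_epsilon,d18O_epsilon Net isotope effects of reduction, per mil.
#' @return A list of class `reduction_params`.
#' @export
#' @examples
#' reduction_params()
reduction_params <- function(f_R = 0.75, sp_epsilon = -6, d18O_epsilon = -25) {
  check_finite(f_R)
  check_finite(sp_epsilon)
  check_finite(d18O_epsilon)
  if (f_R < 0 || f_R > 1) {
    abort("`f_R` must lie in [0, 1].", class = "plastiN2O_parameter_error")
  }
  structure(
    list(f_R = f_R, sp_epsilon = sp_epsilon, d18O_epsilon = d18O_epsilon),
    class = "reduction_params"
  )
}

#' @export
print.reduction_params <- function(x, ...) {
  cat(
    "N2O reduction correction: f_R =", x$f_R,
    "; SP_eps =", x$sp_epsilon, "permil; d18O_eps =", x$d18O_epsilon, "permil\n"
  )
  invisible(x)
}

# 3x3 mixing matrix [1,1,1; SP; d18O] from an endmember set, with a
# collinearity guard
mixing_matrix <- function(endmembers, sp = endmembers$sp_mean,
                          d18O = endmembers$d18O_mean) {
  A <- rbind(rep(1, 3), sp, d18O)
  dimnames(A) <- list(NULL, endmembers$source)
  if (abs(det(A)) < 1e-8) {
    abort(
      "Endmember points are collinear in the (SP, d18O) plane; the mixing system is singular.",
      class = "plastiN2O_degenerate_endmembers"
    )
  }
  A
}
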