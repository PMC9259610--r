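#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_longer pivot_wider
NULL

# assert that `x` is numeric and finite; `arg` names it in the error
check_finite <- function(x, arg = deparse(substitute(x))) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    abort(
      sprintf("`%s` must be finite numeric (got %s).", arg, class(x)[1]),
      class = "plastiN2O_invalid_measurement"
    )
  }
  invisible(x)
}

check_df_cols <- function(df, cols, arg = deparse(substitute(df))) {
  if (!is.data.frame(df)) {
    abort(sprintf("`%s` must be a data frame.", arg), class = "plastiN2O_schema_error")
  }
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(
      sprintf(
        "`%s` is missing required column%s: %s.",
        arg, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
      ),
      class = "plastiN2O_schema_error"
    )
  }
  invisible(df)
}

#' Derive per-stage seeds from one global seed
#'
#' One global seed fans out to reproducible per-stage seeds so each pipeline
#' stage can also be rerun standalone. The derivation keeps results inside
#' the 32-bit integer range R requires of `set.seed()`.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name (e.g. `"isotopes"`, `"otu"`).
#' @return A single integer seed.
#' @export
#' @examples
#' derive_seed(42, "otu")
derive_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1, is.finite(seed))
  # fold the stage name into the seed with a small polynomial hash
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.numeric(seed) * 10007 + h) %% .Machine$integer.max)
}

# trapezoidal quadrature on an arbitrary grid
trapz_int <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}
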