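#' Correct measured isotope values for N2O reduction
#'
#' Inverts the linear reduction shift to recover the pre-reduction ("NR")
#' values the mixing model partitions: the measured delta-18O is first put
#' on the N2O/H2O scale by subtracting the ambient-water delta-18O, then
#' both axes are shifted by `f_R` times the respective net isotope effect:
#' `sp_nr = sp + f_R * sp_epsilon`, `d18O_nr = (d18O - h2o_d18O) + f_R *
#' d18O_epsilon` (the epsilons are negative, so reduction correction moves
#' values down-axis). Both steps are pure shifts, so their order is
#' immaterial.
#'
#' @param sp_measured,d18O_measured Measured SP and delta-18O, per mil.
#'   Vectorised.
#' @param red A [reduction_params()] object.
#' @param h2o_d18O Ambient-water delta-18O, per mil.
#' @return Tibble with columns `sp_nr`, `d18O_nr`.
#' @export
#' @examples
#' reduction_correct(8.1, 57.8) # sp_nr 3.6, d18O_nr 38.14
reduction_correct <- function(sp_measured, d18O_measured,
                              red = reduction_params(), h2o_d18O = 0.91) {
  check_finite(sp_measured)
  check_finite(d18O_measured)
  stopifnot(inherits(red, "reduction_params"))
  tibble(
    sp_nr = sp_measured + red$f_R * red$sp_epsilon,
    d18O_nr = o_exchange_correct(d18O_measured, h2o_d18O) + red$f_R * red$d18O_epsilon
  )
}

#' Solve the three-endmember mixing system
#'
#' Solves the exact 3x3 linear system `[1,1,1; SP_em; d18O_em] f = [1;
#' sp_nr; d18O_nr]` for the raw source fractions. The raw solution is
#' returned without clipping: components may be negative or exceed 1 when
#' the corrected measurement lies outside the endmember triangle.
#'
#' @param sp_nr,d18O_nr Reduction-corrected SP and delta-18O (per mil), see
#'   [reduction_correct()]. Vectorised.
#' @param endmembers An [endmember_set()]; point values are used.
#' @return Tibble with columns `f_BD`, `f_FD`, `f_CD` (or the endmember
#'   names given), one row per input.
#' @export
#' @examples
#' solve_fractions(13.55, 29.6) # 0.5, 0.3, 0.2
solve_fractions <- function(sp_nr, d18O_nr, endmembers = endmember_set()) {
  check_finite(sp_nr)
  check_finite(d18O_nr)
  A <- mixing_matrix(endmembers)
  b <- rbind(1, sp_nr, d18O_nr)
  f <- t(solve(A, b))
  colnames(f) <- paste0("f_", endmembers$source)
  as_tibble(f)
}

# clip rows of an n x 3 fraction matrix: zero negatives, rescale survivors
clip_rows <- function(f, sources) {
  stopifnot(ncol(f) == 3)
  neg <- f < 0
  infeasible <- rowSums(f <= 0) == 3L
  if (any(infeasible)) {
    abort(
      "All three source fractions are non-positive for at least one sample; the measurement is infeasible under these endmembers.",
      class = "plastiN2O_infeasible_sample"
    )
  }
  fc <- f
  fc[neg] <- 0
  fc <- fc / rowSums(fc)
  clipped <- apply(neg, 1, function(z) paste(sources[z], collapse = ","))
  list(fractions = fc, clipped = clipped)
}

#' Clip negative fractions and renormalise
#'
#' Applies the mixing model's feasibility rule: any negative component is
#' set to zero and the remaining positive components are rescaled
#' proportionally to sum to one. If two components are non-positive the
#' survivor is set to 1; if all three are, the sample is infeasible and an
#' error is raised.
#'
#' @param fractions Data frame of raw fractions (three columns, e.g. from
#'   [solve_fractions()]).
#' @return Tibble with the clipped fractions plus a `clipped` column naming
#'   the zeroed sources (empty string when none).
#' @export
#' @examples
#' clip_fractions(solve_fractions(3.6, 38))
clip_fractions <- function(fractions) {
  stopifnot(is.data.frame(fractions), ncol(fractions) >= 3)
  fcols <- names(fractions)[1:3]
  f <- as.matrix(fractions[fcols])
  sums <- rowSums(f)
  if (any(abs(sums - 1) > 1e-9)) {
    abort("Raw fractions must sum to 1 (within 1e-9) before clipping.",
      class = "plastiN2O_parameter_error"
    )
  }
  res <- clip_rows(f, sub("^f_", "", fcols))
  out <- as_tibble(res$fractions)
  names(out) <- fcols
  out$clipped <- res$clipped
  out
}

#' Forward mixing model
#'
#' Maps source fractions to the measured isotope values they would produce:
#' `sp = sum(f * SP_em) - f_R * sp_epsilon` and `d18O = sum(f * d18O_em) -
#' f_R * d18O_epsilon + h2o_d18O`. This is the exact inverse of
#' [reduction_correct()] followed by [solve_fractions()], and is what the
#' synthetic generator uses.
#'
#' @param fractions Data frame with three fraction columns on the simplex
#'   (rows sum to 1).
#' @inheritParams reduction_correct
#' @inheritParams solve_fractions
#' @return Tibble with columns `sp_measured`, `d18O_measured`.
#' @export
#' @examples
#' forward_model(tibble::tibble(f_BD = 1, f_FD = 0, f_CD = 0)) # 3.0, 38.66
forward_model <- function(fractions, endmembers = endmember_set(),
                          red = reduction_params(), h2o_d18O = 0.91) {
  stopifnot(is.data.frame(fractions), ncol(fractions) >= 3)
  f <- as.matrix(fractions[1:3])
  if (any(abs(rowSums(f) - 1) > 1e-9) || any(f < -1e-12)) {
    abort("`fractions` rows must lie on the probability simplex.",
      class = "plastiN2O_parameter_error"
    )
  }
  tibble(
    sp_measured = drop(f %*% endmembers$sp_mean) - red$f_R * red$sp_epsilon,
    d18O_measured = drop(f %*% endmembers$d18O_mean) - red$f_R * red$d18O_epsilon + h2o_d18O
  )
}

#' Monte Carlo source partition of measured N2O isotope values
#'
#' Partitions one or more measured (SP, delta-18O) pairs among bacterial
#' denitrification, fungal denitrification and chemodenitrification. The
#' point estimate is the deterministic clipped solution at the endmember
#' point values; uncertainty is propagated by Monte Carlo over the
#' endmember signatures: in each draw every endmember's SP and delta-18O
#' are sampled independently from Gaussians (means at the point values, SDs
#' from the endmember set), the system is solved, the clipping rule is
#' applied per draw, and per-source draw means, standard errors (SD of
#' draws / sqrt(n)) and clipping frequencies are accumulated. The same
#' endmember draw is shared by all samples within a draw, since endmember
#' uncertainty is common to the cohort. Measured values are held fixed
#' unless `measurement_sd` is supplied.
#'
#' @inheritParams reduction_correct
#' @param endmembers An [endmember_set()] with point values and SDs.
#' @param n_draws Number of Monte Carlo draws (default 10000).
#' @param seed Integer seed; the full summary is reproducible under
#'   `(seed, n_draws)`.
#' @param measurement_sd Optional named vector `c(sp = ..., d18O = ...)` of
#'   measurement noise SDs added to the measured values per draw (off by
#'   default; the instrument precisions are about 0.9 per mil per site
#'   delta and 0.6 per mil for delta-18O).
#' @param sample_id Optional sample labels.
#' @return An object of class `n2o_partition`: a list with `estimate`
#'   (per-sample tibble of deterministic clipped fractions and `clipped`
#'   flags), `mc` (long tibble of per-sample, per-source draw mean, sd, se
#'   and clip frequency), `n_draws`, `seed`, and the inputs used. Use
#'   [generics::tidy()] / [generics::glance()] to extract tidy summaries.
#' @export
#' @examples
#' fit <- monte_carlo_partition(16.3, 48.16, n_draws = 200, seed = 1)
#' tidy(fit)
monte_carlo_partition <- function(sp_measured, d18O_measured,
                                  endmembers = endmember_set(),
                                  red = reduction_params(),
                                  h2o_d18O = 0.91,
                                  n_draws = 10000, seed = 1,
                                  measurement_sd = NULL,
                                  sample_id = NULL) {
  check_finite(sp_measured)
  check_finite(d18O_measured)
  stopifnot(n_draws >= 1, length(sp_measured) == length(d18O_measured))
  n <- length(sp_measured)
  if (is.null(sample_id)) sample_id <- paste0("sample_", seq_len(n))
  sources <- endmembers$source

  ci <- reduction_correct(sp_measured, d18O_measured, red, h2o_d18O)
  raw0 <- solve_fractions(ci$sp_nr, ci$d18O_nr, endmembers)
  est <- clip_fractions(raw0)

  acc_sum <- acc_sq <- acc_clip <- matrix(0, n, 3)
  withr::with_seed(seed, {
    for (d in seq_len(n_draws)) {
      sp_em <- stats::rnorm(3, endmembers$sp_mean, endmembers$sp_sd)
      o_em <- stats::rnorm(3, endmembers$d18O_mean, endmembers$d18O_sd)
      A <- rbind(rep(1, 3), sp_em, o_em)
      spv <- ci$sp_nr
      ov <- ci$d18O_nr
      if (!is.null(measurement_sd)) {
        spv <- spv + stats::rnorm(n, 0, measurement_sd[["sp"]])
        ov <- ov + stats::rnorm(n, 0, measurement_sd[["d18O"]])
      }
      f <- t(solve(A, rbind(1, spv, ov)))
      res <- clip_rows(f, sources)
      acc_sum <- acc_sum + res$fractions
      acc_sq <- acc_sq + res$fractions^2
      acc_clip <- acc_clip + (f < 0)
    }
  })
  mean_f <- acc_sum / n_draws
  sd_f <- sqrt(pmax(0, acc_sq / n_draws - mean_f^2) * n_draws / max(1, n_draws - 1))
  mc <- tibble(
    sample_id = rep(sample_id, times = 3),
    source = rep(sources, each = n),
    mean = as.vector(mean_f),
    sd = as.vector(sd_f),
    se = as.vector(sd_f) / sqrt(n_draws),
    clip_frequency = as.vector(acc_clip) / n_draws
  ) |>
    arrange(match(.data$sample_id, sample_id), match(.data$source, sources))

  structure(
    list(
      estimate = bind_cols(tibble(sample_id = sample_id), est,
        sp_nr = ci$sp_nr, d18O_nr = ci$d18O_nr
      ),
      mc = mc,
      raw = bind_cols(tibble(sample_id = sample_id), raw0),
      n_draws = n_draws, seed = seed,
      endmembers = endmembers, red = red, h2o_d18O = h2o_d18O
    ),
    class = "n2o_partition"
  )
}

#' @export
print.n2o_partition <- function(x, ...) {
  cat(
    "N2O three-source partition:", nrow(x$estimate), "sample(s),",
    x$n_draws, "Monte Carlo draws (seed", paste0(x$seed, ")\n")
  )
  print(x$estimate, ...)
  invisible(x)
}

#' Tidy a Monte Carlo N2O partition
#'
#' `tidy()` returns one row per sample and source with the deterministic
#' point estimate and the Monte Carlo draw mean, sd, standard error and
#' clip frequency. `glance()` returns a one-row summary.
#'
#' @param x An `n2o_partition` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.n2o_partition <- function(x, ...) {
  est_long <- x$estimate |>
    select("sample_id", starts_with("f_")) |>
    pivot_longer(starts_with("f_"), names_to = "source", values_to = "estimate") |>
    mutate(source = sub("^f_", "", .data$source))
  left_join(est_long, x$mc, by = c("sample_id", "source"))
}

#' @rdname tidy.n2o_partition
#' @export
glance.n2o_partition <- function(x, ...) {
  tibble(
    n_samples = nrow(x$estimate),
    n_draws = x$n_draws,
    seed = x$seed,
    f_R = x$red$f_R,
    mean_clip_frequency = mean(x$mc$clip_frequency)
  )
}

#' Partition a measurement table by sample
#'
#' Data-frame-first wrapper around [monte_carlo_partition()]: takes an
#' augmented measurement table (see [add_isotopocules()]), partitions every
#' sample and returns one row per sample with point-estimate fractions,
#' Monte Carlo standard errors and clip diagnostics.
#'
#' @param data Data frame with columns `sample_id`, `group`, `sp` and
#'   `d18O` (measured values; `d18O` is the uncorrected instrument value).
#' @inheritParams monte_carlo_partition
#' @return Tibble with columns `sample_id`, `group`, `f_BD`, `f_FD`,
#'   `f_CD`, `clipped`, and `se_*`/`clip_freq_*` per source.
#' @export
partition_sources <- function(data, endmembers = endmember_set(),
                              red = reduction_params(), h2o_d18O = 0.91,
                              n_draws = 10000, seed = 1) {
  check_df_cols(data, c("sample_id", "group", "sp", "d18O"))
  fit <- monte_carlo_partition(
    data$sp, data$d18O,
    endmembers = endmembers, red = red, h2o_d18O = h2o_d18O,
    n_draws = n_draws, seed = seed, sample_id = data$sample_id
  )
  wide_mc <- fit$mc |>
    select("sample_id", "source", "se", "clip_frequency") |>
    pivot_wider(
      names_from = "source", values_from = c("se", "clip_frequency"),
      names_glue = "{.value}_{source}"
    )
  fit$estimate |>
    left_join(tibble(sample_id = data$sample_id, group = data$group),
      by = "sample_id"
    ) |>
    relocate("group", .after = "sample_id") |>
    left_join(wide_mc, by = "sample_id")
}
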