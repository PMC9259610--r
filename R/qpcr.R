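#' Relative copy number from a qPCR threshold cycle
#'
#' High-throughput chip qPCR reports threshold cycles (Ct) without a
#' per-gene standard curve; relative copy numbers are computed against the
#' detection limit assuming 100% amplification efficiency (3.33 cycles per
#' decade): `10^((limit - ct) / slope)`. Ct values above the detection
#' limit return `NA` with a below-detection flag rather than a silent
#' zero.
#'
#' @param ct Threshold cycle(s), positive.
#' @param limit Detection-limit cycle (default 31).
#' @param slope Cycles per decade (default 3.33).
#' @return Tibble with columns `relative_copies` (`NA` when below
#'   detection) and `below_detection`.
#' @export
#' @examples
#' relative_copy_number(c(31, 27.67, 34))
relative_copy_number <- function(ct, limit = 31, slope = 3.33) {
  check_finite(ct)
  if (slope <= 0) {
    abort("`slope` must be positive.", class = "plastiN2O_parameter_error")
  }
  if (any(ct <= 0)) {
    abort("`ct` must be positive.", class = "plastiN2O_parameter_error")
  }
  below <- ct > limit
  tibble(
    relative_copies = ifelse(below, NA_real_, 10^((limit - ct) / slope)),
    below_detection = below
  )
}

#' 16S-normalised gene abundances from a Ct table
#'
#' Converts a long Ct table to relative copy numbers and divides each
#' functional gene's value by the sample's 16S rRNA value, cancelling
#' chip-level offsets. Samples whose 16S is missing or below detection are
#' dropped with a warning; below-detection functional genes propagate as
#' `NA` (never imputed zeros).
#'
#' @param data Long data frame with columns `sample_id`, `gene`, `ct`.
#' @param reference_gene Gene used as denominator (default `"16S"`).
#' @inheritParams relative_copy_number
#' @return Tibble `sample_id`, `gene`, `relative_copies`,
#'   `below_detection`, `normalized` (gene / 16S).
#' @export
normalize_to_16s <- function(data, reference_gene = "16S", limit = 31, slope = 3.33) {
  check_df_cols(data, c("sample_id", "gene", "ct"))
  out <- as_tibble(data) |>
    bind_cols(relative_copy_number(data$ct, limit, slope))
  ref <- out |>
    filter(.data$gene == reference_gene, !.data$below_detection) |>
    select("sample_id", ref_copies = "relative_copies")
  dropped <- setdiff(unique(out$sample_id), ref$sample_id)
  if (length(dropped)) {
    warn(sprintf(
      "Dropping %d sample(s) without detected %s: %s",
      length(dropped), reference_gene, paste(dropped, collapse = ", ")
    ))
  }
  out |>
    inner_join(ref, by = "sample_id") |>
    mutate(normalized = .data$relative_copies / .data$ref_copies) |>
    select(-"ref_copies")
}

#' (nirS + nirK) / nosZ ratio
#'
#' Ratio of nitrite-reductase to N2O-reductase gene abundance, an index of
#' net N2O production potential: values above 1 indicate more N2O
#' producers than consumers. Computed per sample on 16S-normalised
#' abundances; samples with any operand below detection return `NA`.
#'
#' @param data Output of [normalize_to_16s()] (long, with `normalized`).
#' @return Tibble `sample_id`, `nir_nos_ratio`.
#' @export
nir_nos_ratio <- function(data) {
  check_df_cols(data, c("sample_id", "gene", "normalized"))
  as_tibble(data) |>
    filter(.data$gene %in% c("nirS", "nirK", "nosZ")) |>
    select("sample_id", "gene", "normalized") |>
    pivot_wider(names_from = "gene", values_from = "normalized") |>
    mutate(
      nir_nos_ratio = ifelse(
        is.na(.data$nosZ) | .data$nosZ == 0, NA_real_,
        (.data$nirS + .data$nirK) / .data$nosZ
      )
    ) |>
    select("sample_id", "nir_nos_ratio")
}

#' Cell numbers from absolute 16S rRNA gene abundance
#'
#' Divides absolute 16S rRNA gene copies by the mean rRNA operon copy
#' number per cell (4.1, from ribosomal operon copy-number databases).
#'
#' @param abundance_16S Copies per volume, non-negative.
#' @return Cells per volume.
#' @export
#' @examples
#' cells_from_16S(8.2e9) # 2e9
cells_from_16S <- function(abundance_16S) {
  check_finite(abundance_16S)
  if (any(abundance_16S < 0)) {
    abort("`abundance_16S` must be non-negative.", class = "plastiN2O_parameter_error")
  }
  abundance_16S / 4.1
}
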