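#' Run the full synthetic-to-report pipeline
#'
#' Chains every stage on generated data: isotope measurement simulation,
#' isotopocule derivation, acetylene-based reduction-ratio estimation,
#' Monte Carlo source partitioning, isotope-pairing rates, qPCR
#' normalisation and (nirS+nirK)/nosZ ratios, community diversity /
#' ordination / ANOSIM / per-habitat co-occurrence networks with keystone
#' extraction, and single-cell Raman C-D ratios. Per-stage seeds are
#' derived deterministically from the global seed (see [derive_seed()]),
#' so reruns are identical and stages can be reproduced standalone.
#'
#' The reduction ratio used by the mixing model is estimated from the
#' generated acetylene pairs (mean residual/total), mirroring how the
#' ratio is obtained experimentally.
#'
#' @param cfg A [scenario_config()].
#' @param seed Global integer seed.
#' @param n_draws Monte Carlo draws for the partition stage.
#' @param out_dir Optional directory; when given, per-stage CSVs, GraphML
#'   networks and a JSON summary are written there.
#' @return List of class `pipeline_result` with elements `measurements`,
#'   `fractions`, `group_fractions`, `rates`, `f_R`, `qpcr`, `nir_nos`,
#'   `diversity`, `pcoa`, `anosim`, `networks`, `keystones`, `raman`,
#'   `summary`.
#' @export
run_pipeline <- function(cfg = scenario_config(), seed = 42, n_draws = 10000,
                         out_dir = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))

  iso <- gen_isotopes(cfg, derive_seed(seed, "isotopes"))
  ipt <- gen_ipt(cfg, derive_seed(seed, "ipt"))
  otu <- gen_otu_table(cfg, derive_seed(seed, "otu"))
  ct <- gen_ct_table(cfg, derive_seed(seed, "ct"))
  raman <- gen_raman(cfg, derive_seed(seed, "raman"))

  measurements <- add_isotopocules(iso$data, h2o_d18O = cfg$h2o_d18O)

  f_R_hat <- mean(n2o_reduction_ratio(
    ipt$data$n2o_without_c2h2, ipt$data$n2o_with_c2h2
  ))
  red <- reduction_params(
    f_R = f_R_hat,
    sp_epsilon = cfg$red$sp_epsilon, d18O_epsilon = cfg$red$d18O_epsilon
  )

  fractions <- partition_sources(
    measurements,
    endmembers = cfg$endmembers, red = red,
    h2o_d18O = cfg$h2o_d18O, n_draws = n_draws,
    seed = derive_seed(seed, "partition")
  )
  group_fractions <- fractions |>
    mutate(habitat = habitat_of(.data$group)) |>
    group_by(.data$habitat) |>
    summarise(across(c("f_BD", "f_FD", "f_CD"), mean), n = dplyr::n())

  rates <- ipt_rates(ipt$data)

  qpcr <- normalize_to_16s(ct$data)
  nir_nos <- nir_nos_ratio(qpcr) |>
    left_join(distinct(ct$data, .data$sample_id, .data$group), by = "sample_id")

  diversity <- diversity_indices(otu$data) |>
    left_join(distinct(otu$data, .data$sample_id, .data$group), by = "sample_id")
  bc <- bray_curtis(otu$data)
  ord <- pcoa(bc)
  groups_hab <- habitat_of(otu$data$group)
  ano <- anosim_test(bc, groups_hab, seed = derive_seed(seed, "anosim"))

  networks <- purrr::map(
    c(plastisphere = "plastisphere", bulk_water = "bulk_water"),
    function(h) {
      sub <- filter(otu$data, habitat_of(.data$group) == h)
      sub <- sub[c(TRUE, TRUE, colSums(as.matrix(sub[-(1:2)])) > 0)]
      suppressWarnings(build_network(
        sub,
        markers = otu$markers,
        seed = derive_seed(seed, paste0("network_", h))
      ))
    }
  )
  keystones <- purrr::imap(networks, function(net, h) {
    mutate(keystone_taxa(net), habitat = h)
  }) |> purrr::list_rbind()

  raman_cells <- process_spectra(raman$data)
  raman_groups <- raman_cells |>
    group_by(.data$group) |>
    summarise(mean_cd_ratio = mean(.data$cd_ratio), n_cells = dplyr::n())

  summary <- list(
    seed = seed, n_draws = n_draws, f_R = f_R_hat,
    group_fractions = group_fractions,
    mean_denit_rate = rates |>
      mutate(habitat = habitat_of(.data$group)) |>
      group_by(.data$habitat) |>
      summarise(denitrification = mean(.data$denitrification),
                share_denit = mean(.data$share_denit)),
    nir_nos = nir_nos |>
      mutate(habitat = habitat_of(.data$group)) |>
      group_by(.data$habitat) |>
      summarise(nir_nos_ratio = mean(.data$nir_nos_ratio, na.rm = TRUE)),
    anosim = ano,
    network_sizes = purrr::imap(networks, function(net, h) {
      tibble(habitat = h, n_nodes = net$n_nodes, n_edges = net$n_edges)
    }) |> purrr::list_rbind(),
    raman = raman_groups
  )

  result <- structure(
    list(
      measurements = measurements, fractions = fractions,
      group_fractions = group_fractions, rates = rates, f_R = f_R_hat,
      qpcr = qpcr, nir_nos = nir_nos, diversity = diversity,
      pcoa = ord, anosim = ano, networks = networks, keystones = keystones,
      raman = raman_cells, raman_groups = raman_groups,
      truth = list(isotopes = iso$truth, ipt = ipt$truth, otu = otu$truth,
                   ct = ct$truth, raman = raman$truth),
      summary = summary
    ),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) write_pipeline(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("plastiN2O pipeline result (seed", x$summary$seed, ")\n\n")
  cat("Habitat-level source fractions (point-estimate means):\n")
  print(x$group_fractions)
  cat("\nANOSIM:", sprintf("R = %.3f, p = %.4g", x$anosim$R, x$anosim$p), "\n")
  cat("Mean C-D ratio by group:\n")
  print(x$raman_groups)
  invisible(x)
}

write_pipeline <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$measurements, file.path(out_dir, "measurements.csv"))
  readr::write_csv(result$fractions, file.path(out_dir, "fractions.csv"))
  readr::write_csv(result$group_fractions, file.path(out_dir, "group_fractions.csv"))
  readr::write_csv(result$rates, file.path(out_dir, "rates.csv"))
  readr::write_csv(result$qpcr, file.path(out_dir, "qpcr_normalized.csv"))
  readr::write_csv(result$nir_nos, file.path(out_dir, "nir_nos_ratio.csv"))
  readr::write_csv(result$diversity, file.path(out_dir, "diversity.csv"))
  readr::write_csv(result$keystones, file.path(out_dir, "keystones.csv"))
  readr::write_csv(result$raman, file.path(out_dir, "raman_cells.csv"))
  purrr::iwalk(result$networks, function(net, h) {
    write_graphml(net, file.path(out_dir, paste0("network_", h, ".graphml")))
  })
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      result$summary, file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
  }
  invisible(out_dir)
}

#' Read and write measurement tables
#'
#' Thin, schema-checked CSV IO (comma-separated, period decimal, UTF-8)
#' for the tables the pipeline stages exchange.
#'
#' @param path CSV file path.
#' @param required Character vector of required column names.
#' @return `read_measurements()`: a tibble. `write_measurements()`: `path`
#'   invisibly.
#' @export
#' @examples
#' path <- system.file("extdata", "example_measurements_synthetic.csv",
#'   package = "plastiN2O"
#' )
#' add_isotopocules(read_measurements(path))
read_measurements <- function(path, required = c(
                                "sample_id", "group", "d15N_alpha",
                                "d15N_beta", "d18O"
                              )) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  check_df_cols(tbl, required, arg = path)
  tbl
}

#' @param data Data frame to write.
#' @rdname read_measurements
#' @export
write_measurements <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}
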