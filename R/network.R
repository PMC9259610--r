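#' Correlation-threshold co-occurrence network
#'
#' Builds a taxon co-occurrence network from an abundance table: pairwise
#' correlations are computed across samples (Spearman by default, which is
#' robust for abundance data; Pearson available) and an edge is retained
#' when the squared correlation exceeds `r2_min` and the p-value falls
#' below `p_max` (defaults 0.90 and 0.05). P-values come from a seeded
#' permutation null (rows of the table permuted jointly, 999 permutations
#' by default) or from the t approximation; no multiple-testing correction
#' is applied by default, with Benjamini-Hochberg available. Constant taxa
#' are excluded with a warning.
#'
#' @inheritParams niche_breadth
#' @param markers Optional tibble `taxon`, `marker` annotating each taxon
#'   with its denitrifier marker gene (bnirS / bnirK / fnirK).
#' @param r2_min Minimum squared correlation for an edge.
#' @param p_max Maximum p-value for an edge.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param p_method `"permutation"` (default) or `"asymptotic"` (t test).
#' @param n_perm Permutations for the null (default 999).
#' @param seed Integer seed.
#' @param p_adjust Apply Benjamini-Hochberg correction before thresholding
#'   (default `FALSE`, mirroring plain dual-threshold selection).
#' @return Object of class `cooccurrence_network`: list with `graph`
#'   (igraph), `edges` (tibble `taxon_a`, `taxon_b`, `correlation`, `p`),
#'   `nodes` (tibble with marker annotation and degree), `thresholds`, and
#'   summary counts.
#' @export
build_network <- function(data, markers = NULL, r2_min = 0.90, p_max = 0.05,
                          method = c("spearman", "pearson"),
                          p_method = c("permutation", "asymptotic"),
                          n_perm = 999, seed = 1, p_adjust = FALSE) {
  method <- match.arg(method)
  p_method <- match.arg(p_method)
  m <- abundance_matrix(data)
  n <- nrow(m)
  if (n < 4) {
    abort("Need at least 4 samples for correlation p-values.",
      class = "plastiN2O_schema_error"
    )
  }
  constant <- apply(m, 2, function(v) stats::sd(v) == 0)
  if (any(constant)) {
    warn(sprintf(
      "Excluding %d constant taxa from the network: %s",
      sum(constant), paste(colnames(m)[constant], collapse = ", ")
    ))
    m <- m[, !constant, drop = FALSE]
  }
  t_taxa <- colnames(m)
  x <- if (method == "spearman") apply(m, 2, rank) else m
  r_obs <- stats::cor(x)

  pair_idx <- which(upper.tri(r_obs), arr.ind = TRUE)
  if (p_method == "permutation") {
    exceed <- matrix(0, nrow(r_obs), ncol(r_obs))
    withr::with_seed(seed, {
      for (b in seq_len(n_perm)) {
        xp <- x[sample.int(n), , drop = FALSE]
        rb <- stats::cor(x, xp)
        # symmetrise: a pair's null statistic from either orientation
        rb <- (abs(rb) + abs(t(rb))) / 2
        exceed <- exceed + (rb >= abs(r_obs))
      }
    })
    p <- (exceed + 1) / (n_perm + 1)
  } else {
    tval <- abs(r_obs) * sqrt((n - 2) / pmax(1e-300, 1 - r_obs^2))
    p <- 2 * stats::pt(tval, df = n - 2, lower.tail = FALSE)
  }

  edges <- tibble(
    taxon_a = t_taxa[pair_idx[, 1]],
    taxon_b = t_taxa[pair_idx[, 2]],
    correlation = r_obs[pair_idx],
    p = p[pair_idx]
  )
  if (p_adjust) edges$p <- stats::p.adjust(edges$p, method = "BH")
  edges <- filter(edges, .data$correlation^2 > r2_min, .data$p < p_max)

  g <- igraph::graph_from_data_frame(
    edges[c("taxon_a", "taxon_b")],
    directed = FALSE,
    vertices = tibble(name = t_taxa)
  )
  igraph::E(g)$correlation <- edges$correlation
  igraph::E(g)$p <- edges$p
  nodes <- tibble(
    taxon = t_taxa,
    degree = as.numeric(igraph::degree(g)),
    betweenness = as.numeric(igraph::betweenness(g))
  )
  if (!is.null(markers)) {
    check_df_cols(markers, c("taxon", "marker"))
    nodes <- left_join(nodes, as_tibble(markers), by = "taxon")
    igraph::V(g)$marker <- nodes$marker[match(igraph::V(g)$name, nodes$taxon)]
  }
  structure(
    list(
      graph = g, edges = edges, nodes = nodes,
      thresholds = c(r2_min = r2_min, p_max = p_max),
      n_nodes = sum(nodes$degree > 0), n_edges = nrow(edges),
      marker_composition = if (!is.null(markers)) {
        count(filter(nodes, .data$degree > 0), .data$marker)
      }
    ),
    class = "cooccurrence_network"
  )
}

#' @export
print.cooccurrence_network <- function(x, ...) {
  cat(
    "Co-occurrence network:", x$n_edges, "edges among", x$n_nodes,
    "connected taxa (r^2 >", x$thresholds[["r2_min"]],
    ", p <", paste0(x$thresholds[["p_max"]], ")\n")
  )
  invisible(x)
}

#' Keystone taxa of a co-occurrence network
#'
#' Ranks connected taxa by degree (ties broken by betweenness centrality,
#' then label) and returns the top `top_k` with marker annotations, so
#' that e.g. bnirK- vs bnirS-type dominance among hubs can be summarised.
#' "Keystone" here is a topological convention, not a demonstrated
#' ecological role.
#'
#' @param net A `cooccurrence_network` from [build_network()].
#' @param top_k Number of taxa to return (default 5).
#' @return Tibble `rank`, `taxon`, `degree`, `betweenness` (and `marker`
#'   when annotated); empty for an empty network.
#' @export
keystone_taxa <- function(net, top_k = 5) {
  stopifnot(inherits(net, "cooccurrence_network"))
  connected <- filter(net$nodes, .data$degree > 0)
  if (nrow(connected) == 0) {
    return(mutate(connected, rank = integer(0)))
  }
  connected |>
    arrange(desc(.data$degree), desc(.data$betweenness), .data$taxon) |>
    mutate(rank = row_number()) |>
    relocate("rank") |>
    slice_head(n = top_k)
}

#' Write a network to GraphML
#'
#' Serialises the igraph graph of a [build_network()] result to GraphML
#' (readable by Gephi and friends).
#'
#' @param net A `cooccurrence_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "cooccurrence_network"))
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}
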