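#' Levins niche breadth
#'
#' For each taxon, the resource-use proportions across resource states
#' (here, samples) are `P_j = x_j / sum(x)`; Levins breadth is `B = 1 /
#' sum(P_j^2)`, the effective number of states used. `B` ranges from 1
#' (all use in one state) to the number of states (uniform use) and is
#' invariant to permuting or rescaling samples.
#'
#' @param data Wide abundance table: data frame with a `sample_id` column
#'   and one non-negative numeric column per taxon (samples in rows).
#' @return Tibble with columns `taxon`, `breadth`.
#' @export
#' @examples
#' tbl <- tibble::tibble(sample_id = paste0("s", 1:5), taxA = rep(2, 5))
#' niche_breadth(tbl) # breadth 5
niche_breadth <- function(data) {
  m <- abundance_matrix(data)
  tot <- colSums(m)
  if (any(tot == 0)) {
    abort(
      sprintf(
        "Taxa with zero total abundance have undefined breadth: %s",
        paste(colnames(m)[tot == 0], collapse = ", ")
      ),
      class = "plastiN2O_undefined_breadth"
    )
  }
  p <- sweep(m, 2, tot, "/")
  tibble(taxon = colnames(m), breadth = as.numeric(1 / colSums(p^2)))
}

#' Asymmetric niche overlap
#'
#' Overlap of taxon `i` onto taxon `j` follows the asymmetric alpha model:
#' `alpha_ij = sum(P_ia * P_ja) / sum(P_ia^2)` over resource states `a`,
#' where `P_i` are taxon `i`'s use proportions. The measure is asymmetric
#' (`alpha_ij != alpha_ji` in general), equals 1 on the diagonal and 0 for
#' disjoint profiles.
#'
#' @inheritParams niche_breadth
#' @return Tibble of all ordered pairs: `taxon_i`, `taxon_j`, `overlap`.
#' @export
niche_overlap <- function(data) {
  m <- abundance_matrix(data)
  tot <- colSums(m)
  if (any(tot == 0)) {
    abort("Taxa with zero total abundance have undefined overlap.",
      class = "plastiN2O_undefined_breadth"
    )
  }
  p <- sweep(m, 2, tot, "/")
  cross <- crossprod(p) # sum_a P_ia P_ja
  denom <- diag(cross) # sum_a P_ia^2
  alpha <- cross / denom # rows i: alpha_ij = cross[i,j]/denom[i]
  # row-major flatten of alpha: element (i, j) pairs with taxon_i = row i
  tibble(
    taxon_i = rep(colnames(m), each = ncol(m)),
    taxon_j = rep(colnames(m), times = ncol(m)),
    overlap = as.vector(t(alpha))
  )
}

# wide table -> samples x taxa numeric matrix
abundance_matrix <- function(data) {
  check_df_cols(data, "sample_id")
  taxa_cols <- setdiff(names(data), c("sample_id", "group"))
  m <- as.matrix(data[taxa_cols])
  if (!is.numeric(m) || any(m < 0) || anyNA(m)) {
    abort("Abundances must be non-negative numbers.", class = "plastiN2O_schema_error")
  }
  rownames(m) <- as.character(data$sample_id)
  m
}

chao1_index <- function(x) {
  x <- x[x > 0]
  s_obs <- length(x)
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (f2 > 0) s_obs + f1^2 / (2 * f2) else s_obs + f1 * (f1 - 1) / 2
}

ace_index <- function(x, rare_cutoff = 10) {
  x <- x[x > 0]
  rare <- x[x <= rare_cutoff]
  s_abund <- sum(x > rare_cutoff)
  s_rare <- length(rare)
  if (s_rare == 0) return(s_abund)
  n_rare <- sum(rare)
  f1 <- sum(rare == 1)
  c_ace <- 1 - f1 / n_rare
  if (c_ace == 0) return(NA_real_) # all rare taxa are singletons
  fi <- tabulate(rare, nbins = rare_cutoff)
  gamma2 <- max(
    0,
    s_rare / c_ace * sum(seq_len(rare_cutoff) * (seq_len(rare_cutoff) - 1) * fi) /
      (n_rare * (n_rare - 1)) - 1
  )
  s_abund + s_rare / c_ace + f1 / c_ace * gamma2
}

#' Alpha-diversity indices
#'
#' Per-sample Shannon (`-sum(p log p)`, natural log) and Gini-Simpson
#' (`1 - sum(p^2)`) via \pkg{vegan}, plus the Chao1 and ACE richness
#' estimators computed from count data. Chao1 uses the classic
#' `S_obs + F1^2 / (2 F2)` form, switching to the bias-corrected
#' `S_obs + F1 (F1 - 1) / 2` when no doubletons are present; ACE uses the
#' standard rare-taxon cutoff of 10.
#'
#' @inheritParams niche_breadth
#' @return Tibble with columns `sample_id`, `shannon`, `simpson`,
#'   `chao1`, `ace`, `richness`.
#' @export
diversity_indices <- function(data) {
  m <- abundance_matrix(data)
  if (any(abs(m - round(m)) > 1e-8)) {
    abort("Chao1/ACE need integer counts; got non-integer abundances.",
      class = "plastiN2O_mode_error"
    )
  }
  tibble(
    sample_id = rownames(m),
    shannon = as.numeric(vegan::diversity(m, index = "shannon")),
    simpson = as.numeric(vegan::diversity(m, index = "simpson")),
    chao1 = as.numeric(apply(m, 1, chao1_index)),
    ace = as.numeric(apply(m, 1, ace_index)),
    richness = as.numeric(rowSums(m > 0))
  )
}

#' Bray-Curtis distance matrix
#'
#' Pairwise Bray-Curtis dissimilarity `d(u, v) = sum|u - v| / sum(u + v)`
#' between samples, computed with [vegan::vegdist()]. Pairs of all-zero
#' samples are undefined and returned as `NA` with a warning.
#'
#' @inheritParams niche_breadth
#' @return Symmetric sample-by-sample matrix with zero diagonal.
#' @export
bray_curtis <- function(data) {
  m <- abundance_matrix(data)
  if (nrow(m) < 2) {
    abort("Need at least two samples.", class = "plastiN2O_schema_error")
  }
  if (sum(rowSums(m) == 0) >= 2) {
    warn("At least two all-zero samples; their pairwise distances are undefined (NA).")
  }
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  d[!is.finite(d)] <- NA_real_
  diag(d) <- 0
  d
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a distance matrix (double-centred
#' eigendecomposition via [stats::cmdscale()]). Coordinates are ordered by
#' eigenvalue; negative eigenvalues — which arise from semimetric inputs
#' like Bray-Curtis — are reported, not dropped, and explained proportions
#' are taken over the positive eigenvalues.
#'
#' @param dist Square symmetric distance matrix (or `dist` object).
#' @param k Number of ordination axes (default 2).
#' @return List of class `pcoa_result`: `points` (tibble `sample_id`,
#'   `axis1`, ...), `eigenvalues`, `explained` (proportions for the
#'   returned axes).
#' @export
pcoa <- function(dist, k = 2) {
  m <- as.matrix(dist)
  if (nrow(m) != ncol(m) || any(abs(m - t(m)) > 1e-8, na.rm = TRUE)) {
    abort("`dist` must be a square symmetric matrix.", class = "plastiN2O_schema_error")
  }
  k <- min(k, nrow(m) - 1)
  # cmdscale warns about negative eigenvalues for semimetric input; they are
  # expected here and reported in the result instead
  sc <- suppressWarnings(stats::cmdscale(stats::as.dist(m), k = k, eig = TRUE))
  pts <- sc$points
  if (is.null(pts) || ncol(pts) == 0) pts <- matrix(0, nrow(m), k)
  if (ncol(pts) < k) { # degenerate input (e.g. zero matrix)
    pts <- cbind(pts, matrix(0, nrow(m), k - ncol(pts)))
  }
  colnames(pts) <- paste0("axis", seq_len(ncol(pts)))
  pos <- sc$eig[sc$eig > 1e-12]
  explained <- if (length(pos)) {
    pmax(0, sc$eig[seq_len(k)]) / sum(pos)
  } else {
    rep(0, k)
  }
  structure(
    list(
      points = bind_cols(
        tibble(sample_id = rownames(m) %||% as.character(seq_len(nrow(m)))),
        as_tibble(pts)
      ),
      eigenvalues = sc$eig,
      explained = explained
    ),
    class = "pcoa_result"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pcoa_result <- function(x, ...) {
  cat(
    "PCoA:", nrow(x$points), "samples;",
    sum(x$eigenvalues < -1e-12), "negative eigenvalue(s); axis variance:",
    paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", "), "\n"
  )
  print(x$points, ...)
  invisible(x)
}

#' Analysis of similarities (ANOSIM)
#'
#' Tests whether between-group dissimilarities exceed within-group
#' dissimilarities using the rank-based ANOSIM statistic `R` (1 = complete
#' separation, 0 = none) with a seeded permutation p-value. Delegates to
#' [vegan::anosim()].
#'
#' @inheritParams pcoa
#' @param groups Group label per sample (length = number of samples; at
#'   least two groups with two members each).
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed for the permutation null.
#' @return Tibble with columns `R`, `p`, `n_perm`.
#' @export
anosim_test <- function(dist, groups, n_perm = 999, seed = 1) {
  m <- as.matrix(dist)
  groups <- as.factor(groups)
  stopifnot(length(groups) == nrow(m))
  if (nlevels(droplevels(groups)) < 2 || any(table(groups) < 2)) {
    abort("Need at least two groups with at least two members each.",
      class = "plastiN2O_schema_error"
    )
  }
  fit <- withr::with_seed(
    seed,
    vegan::anosim(stats::as.dist(m), groups, permutations = n_perm)
  )
  tibble(R = unname(fit$statistic), p = unname(fit$signif), n_perm = n_perm)
}
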