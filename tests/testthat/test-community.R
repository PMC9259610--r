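test_that("Levins breadth spans 1 to the number of resource states", {
  uniform <- abund_tbl(matrix(2, nrow = 5, ncol = 1, dimnames = list(NULL, "tA")))
  expect_equal(niche_breadth(uniform)$breadth, 5)

  conc <- abund_tbl(matrix(c(9, 0, 0), ncol = 1, dimnames = list(NULL, "tA")))
  expect_equal(niche_breadth(conc)$breadth, 1)

  hand <- abund_tbl(matrix(c(0.5, 0.3, 0.2), ncol = 1, dimnames = list(NULL, "tA")))
  expect_equal(niche_breadth(hand)$breadth, 1 / 0.38)

  # permutation invariance over samples; bounds hold for random tables
  withr::with_seed(3, m <- matrix(stats::rpois(40, 5), nrow = 8))
  tbl <- abund_tbl(m)
  b1 <- niche_breadth(tbl)
  b2 <- niche_breadth(tbl[sample.int(8), ])
  expect_equal(b1$breadth, b2$breadth)
  expect_true(all(b1$breadth >= 1 - 1e-12 & b1$breadth <= 8 + 1e-12))

  zero <- abund_tbl(matrix(c(1, 0, 1, 0), ncol = 2))
  zero$t2 <- 0
  expect_error(niche_breadth(zero), class = "plastiN2O_undefined_breadth")
})

test_that("asymmetric niche overlap matches the alpha model", {
  m <- cbind(ti = c(0.5, 0.5, 0), tj = c(0.2, 0.3, 0.5))
  ov <- niche_overlap(abund_tbl(m))
  expect_equal(ov$overlap[ov$taxon_i == "ti" & ov$taxon_j == "tj"], 0.5)

  # identical profiles: 1 both ways; diagonal is 1; disjoint: 0
  m2 <- cbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(0, 0, 5) * c(1, 1, 0) + c(5, 0, 0))
  ov2 <- niche_overlap(abund_tbl(m2))
  get <- function(i, j) ov2$overlap[ov2$taxon_i == i & ov2$taxon_j == j]
  expect_equal(get("a", "b"), 1)
  expect_equal(get("b", "a"), 1)
  expect_equal(get("a", "a"), 1)
  # scale invariance
  ov3 <- niche_overlap(abund_tbl(m2 * 10))
  expect_equal(ov3$overlap, ov2$overlap)

  disj <- abund_tbl(cbind(x = c(1, 1, 0, 0), y = c(0, 0, 1, 1)))
  ovd <- niche_overlap(disj)
  expect_equal(ovd$overlap[ovd$taxon_i == "x" & ovd$taxon_j == "y"], 0)
  expect_true(all(ovd$overlap >= 0))
})

test_that("alpha-diversity indices match their formulas", {
  unif <- abund_tbl(matrix(3, nrow = 1, ncol = 7))
  d <- diversity_indices(unif)
  expect_equal(d$shannon, log(7))
  expect_equal(d$simpson, 1 - 7 * (1 / 7)^2)

  single <- abund_tbl(matrix(c(12, 0, 0), nrow = 1))
  ds <- diversity_indices(single)
  expect_equal(ds$shannon, 0)
  expect_equal(ds$simpson, 0)

  # Chao1: S_obs 10, F1 = 4, F2 = 2 -> 10 + 16/4 = 14
  counts <- c(1, 1, 1, 1, 2, 2, 5, 6, 7, 8)
  dch <- diversity_indices(abund_tbl(matrix(counts, nrow = 1)))
  expect_equal(dch$chao1, 14)
  expect_equal(dch$richness, 10)

  # no doubletons: bias-corrected form F1(F1-1)/2
  counts2 <- c(1, 1, 1, 5, 9)
  dch2 <- diversity_indices(abund_tbl(matrix(counts2, nrow = 1)))
  expect_equal(dch2$chao1, 5 + 3 * 2 / 2)

  # ACE equals the standard estimator computed directly for a mixed sample
  counts3 <- c(1, 1, 2, 3, 4, 12, 25)
  dce <- diversity_indices(abund_tbl(matrix(counts3, nrow = 1)))
  rare <- counts3[counts3 <= 10]
  c_ace <- 1 - sum(rare == 1) / sum(rare)
  fi <- tabulate(rare, 10)
  g2 <- max(0, length(rare) / c_ace *
    sum((1:10) * (0:9) * fi) / (sum(rare) * (sum(rare) - 1)) - 1)
  expect_equal(dce$ace, 2 + length(rare) / c_ace + sum(rare == 1) / c_ace * g2)

  expect_error(
    diversity_indices(abund_tbl(matrix(c(1.5, 2), nrow = 1))),
    class = "plastiN2O_mode_error"
  )
})

test_that("Bray-Curtis distances are bounded and match hand arithmetic", {
  m <- rbind(u = c(1, 2, 3), v = c(3, 2, 1), w = c(1, 2, 3))
  d <- bray_curtis(abund_tbl(m, c("u", "v", "w")))
  expect_equal(d["u", "v"], 1 / 3)
  expect_equal(d["u", "w"], 0)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))

  disjoint <- abund_tbl(rbind(c(5, 5, 0, 0), c(0, 0, 4, 4)))
  expect_equal(bray_curtis(disjoint)[1, 2], 1)
})

test_that("PCoA reproduces Euclidean configurations and reports negatives", {
  # points on a line: first axis recovers the spacing up to sign
  x <- c(0, 1, 3, 6)
  d <- as.matrix(stats::dist(x))
  ord <- pcoa(d, k = 2)
  ax1 <- ord$points$axis1
  expect_equal(abs(diff(ax1)), diff(x), tolerance = 1e-8)

  # Euclidean input: pairwise distances reproduced
  withr::with_seed(8, pts <- matrix(stats::rnorm(12), ncol = 3))
  d2 <- as.matrix(stats::dist(pts))
  ord2 <- pcoa(d2, k = 3)
  rec <- as.matrix(stats::dist(as.matrix(ord2$points[-1])))
  expect_equal(rec, d2, tolerance = 1e-8, ignore_attr = TRUE)

  # zero matrix: all-zero coordinates
  ordz <- pcoa(matrix(0, 4, 4), k = 2)
  expect_true(all(ordz$points$axis1 == 0))

  # semimetric Bray-Curtis input yields (reported) negative eigenvalues
  withr::with_seed(9, m <- matrix(stats::rpois(60, 3), nrow = 6))
  ordb <- pcoa(bray_curtis(abund_tbl(m)))
  expect_true(length(ordb$eigenvalues) > 0)

  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), class = "plastiN2O_schema_error")
})

test_that("ANOSIM separates generated habitat clusters and is seed-stable", {
  otu <- gen_otu_table(scenario_config(n_per_group = 4), seed = 14)
  d <- bray_curtis(otu$data)
  groups <- ifelse(otu$data$group == "bulk_water", "bulk", "plastisphere")
  res <- anosim_test(d, groups, n_perm = 999, seed = 1)
  expect_gt(res$R, 0.8)
  expect_lte(res$p, 0.001)
  expect_identical(res, anosim_test(d, groups, n_perm = 999, seed = 1))

  # null: one homogeneous cloud, random labels
  withr::with_seed(2, {
    cloud <- matrix(stats::rpois(20 * 30, 8), nrow = 20)
    labels <- sample(rep(c("a", "b"), 10))
  })
  null <- anosim_test(bray_curtis(abund_tbl(cloud)), labels, n_perm = 199, seed = 3)
  expect_lt(abs(null$R), 0.25)
  expect_gt(null$p, 0.01)

  expect_error(
    anosim_test(matrix(0, 3, 3), c("a", "a", "b")),
    class = "plastiN2O_schema_error"
  )
})
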