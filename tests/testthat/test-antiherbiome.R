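toy_summaries <- function(n = 30, seed = 1) {
  set.seed(seed)
  data.frame(
    ecoregion_id = sprintf("E%02d", 1:n),
    WD_mean = runif(n, 0.4, 0.8),
    LeafSize_mean = runif(n, 5, 60),
    StemSpines_presences = rpois(n, 30),
    StemSpines_absences = rpois(n, 70),
    Latex_presences = rpois(n, 40),
    Latex_absences = rpois(n, 60),
    LeafSpines_present_species = rpois(n, 3) + 1,
    LeafSpines_absent_species = rpois(n, 5) + 1)
}

test_that("defence matrix computes proportions and standardizes", {
  s <- toy_summaries()
  s$StemSpines_presences[1] <- 3
  s$StemSpines_absences[1] <- 2
  dm <- build_defence_matrix(s)
  expect_equal(unname(dm$raw[1, "StemSpines_prop"]), 0.6)
  expect_equal(unname(colMeans(dm$std)), rep(0, 5), tolerance = 1e-12)
  expect_equal(unname(apply(dm$std, 2, sd)), rep(1, 5), tolerance = 1e-12)
  # standardizing twice equals once
  expect_equal(unname(scale(dm$std)[, ]), unname(dm$std[, ]),
               tolerance = 1e-12)
})

test_that("palm-free ecoregions are filled from model probabilities and flagged", {
  s <- toy_summaries()
  s$LeafSpines_present_species[2] <- NA
  s$LeafSpines_absent_species[2] <- NA
  fill <- c(E02 = 0.31)
  dm <- build_defence_matrix(s, spine_fill = fill)
  expect_equal(dm$filled, "E02")
  expect_equal(unname(dm$raw["E02", "LeafSpines_prop"]), 0.31)
  # without fill the ecoregion is excluded and logged
  expect_message(dm2 <- build_defence_matrix(s), "excluded")
  expect_equal(dm2$excluded, "E02")
})

test_that("constant trait columns are rejected by name", {
  s <- toy_summaries()
  s$WD_mean <- 0.5
  expect_error(build_defence_matrix(s), "WD")
})

test_that("PCA axes match a brute-force eigendecomposition of the correlation matrix", {
  dm <- build_defence_matrix(toy_summaries(40, 2))
  p <- pca_axes(dm)
  ev <- eigen(cor(dm$raw))
  expect_equal(p$var_frac, ev$values / 5, tolerance = 1e-10)
  expect_equal(sum(p$var_frac), 1, tolerance = 1e-12)
  expect_true(all(diff(p$var_frac) <= 1e-12))
  for (j in 1:5)
    expect_equal(abs(p$loadings[, j]), abs(ev$vectors[, j]),
                 ignore_attr = TRUE, tolerance = 1e-8)
  # sign convention: Dim1 loads positively on stem spines
  expect_gte(p$loadings["StemSpines_prop", 1], 0)
})

test_that("two perfectly correlated traits load equally on the shared axis", {
  s <- toy_summaries(25, 3)
  dm <- build_defence_matrix(s)
  dm$std[, "Latex_prop"] <- dm$std[, "WD"]
  dm$raw[, "Latex_prop"] <- dm$raw[, "WD"]
  p <- pca_axes(dm)
  # the duplicated pair carries identical loadings on every axis that
  # involves it
  expect_equal(abs(p$loadings["WD", 1]), abs(p$loadings["Latex_prop", 1]),
               tolerance = 1e-8)
})

test_that("rank-deficient matrices are rejected", {
  s <- toy_summaries(4, 4)     # 4 rows, rank <= 3 after centering
  dm <- build_defence_matrix(s)
  dm$std <- dm$std[1:2, ]
  expect_error(pca_axes(dm), "rank")
})

test_that("three well-separated planted clusters are recovered at k = 3", {
  sim <- simulate_defence_clusters(n = 120, k = 3, separation = 4, seed = 5)
  dm <- list(std = scale(sim$matrix), raw = sim$matrix,
             filled = character(), excluded = character())
  class(dm) <- "defence_matrix"
  p <- pca_axes(dm)
  cl <- cluster_antiherbiomes(p$scores, dm)
  expect_equal(cl$k, 3)
  skip_if_not_installed("mclust")
  expect_equal(mclust::adjustedRandIndex(cl$labels, sim$truth), 1.0)
})

test_that("clustering is invariant to row order and axis sign flips", {
  sim <- simulate_defence_clusters(n = 60, k = 3, separation = 4, seed = 6)
  dm <- list(std = scale(sim$matrix), raw = sim$matrix,
             filled = character(), excluded = character())
  class(dm) <- "defence_matrix"
  p <- pca_axes(dm)
  cl1 <- cluster_antiherbiomes(p$scores, dm)
  perm <- sample(nrow(p$scores))
  dmp <- dm; dmp$std <- dm$std[perm, ]; dmp$raw <- dm$raw[perm, ]
  cl2 <- cluster_antiherbiomes(p$scores[perm, ], dmp)
  expect_equal(cl1$k, cl2$k)
  expect_equal(cl1$labels[names(cl2$labels)], cl2$labels)
  flipped <- p$scores %*% diag(c(-1, 1, -1, 1, -1))
  rownames(flipped) <- rownames(p$scores)
  colnames(flipped) <- colnames(p$scores)
  cl3 <- cluster_antiherbiomes(flipped, dm)
  expect_equal(cl1$k, cl3$k)
  expect_equal(cl1$labels, cl3$labels)
})

test_that("a single blob emits a weak-structure warning", {
  set.seed(7)
  X <- matrix(rnorm(60 * 5), 60)
  colnames(X) <- c("WD", "LeafSize", "StemSpines_prop", "LeafSpines_prop",
                   "Latex_prop")
  rownames(X) <- sprintf("E%02d", 1:60)
  dm <- list(std = scale(X), raw = X, filled = character(),
             excluded = character())
  class(dm) <- "defence_matrix"
  p <- pca_axes(dm)
  expect_warning(cluster_antiherbiomes(p$scores, dm), "weak")
  expect_error(cluster_antiherbiomes(p$scores[1:5, ], dm, k_max = 5),
               "k_max")
})

test_that("group contrasts: Kruskal-Wallis, Dunn z and BH correction", {
  set.seed(8)
  v <- c(rnorm(20, 0), rnorm(20, 2), rnorm(20, 4))
  g <- rep(c("SLT", "ILW", "BCL"), each = 20)
  ct <- contrast_groups(v, g)
  expect_lt(ct$kw$p, 1e-6)
  expect_equal(nrow(ct$pairwise), 3)
  expect_true(all(ct$pairwise$p_adj >= ct$pairwise$p - 1e-15))
  kw_ref <- kruskal.test(v, factor(g))
  expect_equal(ct$kw$statistic, unname(kw_ref$statistic))
  # two groups: KW is the rank-sum test's chi-square equivalent, and the
  # single Dunn pair reproduces the global p
  v2 <- c(rnorm(15), rnorm(15, 1.5))
  g2 <- rep(c("A", "B"), each = 15)
  ct2 <- contrast_groups(v2, g2)
  expect_equal(ct2$pairwise$p, ct2$kw$p, tolerance = 1e-10)
  wt <- wilcox.test(v2 ~ factor(g2), exact = FALSE, correct = FALSE)
  expect_equal(ct2$kw$p, wt$p.value, tolerance = 1e-10)
})

test_that("tiny groups are excluded from contrasts and flagged", {
  v <- c(rnorm(10), rnorm(10, 1), 5)
  g <- c(rep("A", 10), rep("B", 10), "C")
  ct <- contrast_groups(v, g)
  expect_equal(ct$excluded_groups, "C")
  expect_equal(nrow(ct$pairwise), 1)
  expect_error(contrast_groups(rnorm(3), c("A", "A", "A")), "2 groups")
})

test_that("identical group distributions give calibrated KW p-values", {
  set.seed(9)
  ps <- replicate(200, {
    v <- rnorm(45)
    g <- rep(c("A", "B", "C"), each = 15)
    suppressWarnings(kruskal.test(v, factor(g))$p.value)
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
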