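test_that("Bray-Curtis matches the direct formula and vegan", {
  mat <- rbind(P1 = c(1, 1, 0), P2 = c(0, 1, 1), P3 = c(1, 1, 0))
  colnames(mat) <- c("a", "b", "c")
  bc <- as.matrix(bray_curtis(mat))
  expect_equal(bc["P1", "P2"], 0.5)
  expect_equal(bc["P1", "P3"], 0)
  disjoint <- rbind(A = c(3, 2, 0, 0), B = c(0, 0, 4, 1))
  expect_equal(as.numeric(bray_curtis(disjoint)), 1)
  expect_error(bray_curtis(rbind(c(1, 1), c(0, 0))), "zero total")
  expect_error(bray_curtis(matrix(1, 1, 3)), "at least 2")

  skip_if_not_installed("vegan")
  set.seed(5)
  m <- matrix(rpois(60, 4), nrow = 6)
  expect_equal(as.vector(bray_curtis(m)),
               as.vector(vegan::vegdist(m, method = "bray")),
               tolerance = 1e-12)
})

test_that("NMDS embeds exactly embeddable configurations at ~zero stress", {
  d3 <- as.dist(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3))
  expect_lt(nmds(d3, k = 2, n_starts = 5, seed = 1)$stress, 1e-6)

  set.seed(10)
  pts <- matrix(rnorm(20), 10, 2)
  ord <- nmds(dist(pts), k = 2, n_starts = 10, seed = 2)
  expect_lt(ord$stress, 0.05)
  # coordinates are centered
  expect_equal(colMeans(ord$points), c(NMDS1 = 0, NMDS2 = 0),
               tolerance = 1e-10)
})

test_that("NMDS is deterministic under a seed and stress never rises", {
  set.seed(13)
  mat <- matrix(rpois(70, 5), nrow = 7)
  d <- bray_curtis(mat + 1)
  o1 <- nmds(d, k = 2, n_starts = 8, seed = 99)
  o2 <- nmds(d, k = 2, n_starts = 8, seed = 99)
  expect_identical(o1$points, o2$points)
  expect_identical(o1$stress, o2$stress)
  # per-iteration stress of the winning start is non-increasing
  expect_true(all(diff(o1$trace) <= 1e-12))
  # the final stress never exceeds the metric-seeded start's initial stress
  expect_lte(o1$stress, o1$metric_initial_stress + 1e-12)
})

test_that("NMDS input validation rejects malformed matrices", {
  d <- dist(matrix(rnorm(12), 6, 2))
  expect_error(nmds(d, k = 0), "k must be")
  expect_error(nmds(d, k = 6), "k must be <")
  bad <- matrix(1, 3, 3)
  expect_error(nmds(bad, k = 1), "zero diagonal")
})

test_that("dimension selection finds low-dimensional structure", {
  # collinear points need one dimension
  dl <- dist(matrix(c(1, 2, 4, 7, 11, 16, 22, 29), ncol = 1))
  sel <- select_dimensions(dl, k_range = 1:4, trials = 5, seed = 6)
  expect_equal(sel$k, 1L)
  expect_true(sel$threshold_met)
  expect_equal(nrow(sel$stress_table), 4L)
  expect_true(all(diff(sel$stress_table$stress) <= 0.02))

  # an impossible threshold exercises the fallback path
  expect_warning(
    sel0 <- select_dimensions(dl, k_range = 1:2, trials = 3,
                              stress_threshold = 0, seed = 6),
    "falling back")
  expect_false(sel0$threshold_met)
})

test_that("Mantel self-comparison and oracles agree", {
  set.seed(31)
  pts <- matrix(rnorm(14), 7, 2)
  d <- dist(pts)
  self <- mantel_test(d, d, n_perm = 99, seed = 1)
  expect_equal(self$r, 1)
  expect_equal(self$p_value, 1 / 100)

  # naive double-loop Pearson correlation over the upper triangle
  d2 <- dist(matrix(rnorm(14), 7, 2))
  res <- mantel_test(d, d2, n_perm = 99, seed = 2)
  m1 <- as.matrix(d); m2 <- as.matrix(d2)
  v1 <- c(); v2 <- c()
  for (i in 1:6) for (j in (i + 1):7) {
    v1 <- c(v1, m1[i, j]); v2 <- c(v2, m2[i, j])
  }
  expect_equal(res$r, stats::cor(v1, v2))

  # invariance to joint relabeling of both matrices
  perm <- sample(7)
  res_p <- mantel_test(as.matrix(d)[perm, perm], as.matrix(d2)[perm, perm],
                       n_perm = 99, seed = 2)
  expect_equal(res_p$r, res$r)

  expect_error(mantel_test(d, dist(matrix(rnorm(12), 6, 2))),
               "differ in size")

  skip_if_not_installed("vegan")
  expect_equal(res$r, unname(vegan::mantel(d, d2, permutations = 0)$statistic))
})

test_that("haversine distances match the closed form", {
  md <- data.frame(plot_code = c("A", "B", "C"),
                   lat = c(0, 1, 0), lon = c(0, 0, 1))
  d <- as.matrix(haversine_matrix(md))
  expect_equal(d["A", "A"], 0)
  expect_equal(d["A", "B"], 2 * pi * 6371 / 360, tolerance = 1e-6)
  expect_equal(d["A", "C"], 2 * pi * 6371 / 360, tolerance = 1e-6)
  expect_true(isSymmetric(d))
  expect_error(haversine_matrix(data.frame(plot_code = "X", lat = 95,
                                           lon = 0)), "latitude")

  # symmetry on the packaged plot coordinates; two plots share printed
  # coordinates, so zero off-diagonal distances are legitimate
  dd <- as.matrix(haversine_matrix(regional_plot_metadata()))
  expect_true(isSymmetric(dd))
  expect_true(all(dd[upper.tri(dd)] >= 0))
  expect_gt(max(dd), 100)
})

test_that("UPGMA clustering matches hand agglomeration", {
  # one tight pair merges first
  m <- matrix(c(0, 0.1, 0.9, 0.1, 0, 0.8, 0.9, 0.8, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  cl <- upgma_cluster(as.dist(m))
  expect_equal(sort(cl$hclust$labels[cl$hclust$merge[1, ] * -1]),
               c("x", "y"))

  # cophenetic distances against a hand-computed UPGMA on 5 labels
  set.seed(17)
  pts <- matrix(rnorm(10), 5, 2)
  d <- dist(pts)
  cl5 <- upgma_cluster(d)
  brute <- brute_upgma_cophenetic(as.matrix(d))
  expect_equal(as.matrix(stats::cophenetic(cl5$hclust))[rownames(brute),
                                                        colnames(brute)],
               brute, tolerance = 1e-12)

  # Newick parses back to the same topology
  phy <- ape::read.tree(text = cl5$newick)
  expect_setequal(phy$tip.label, cl5$phylo$tip.label)
  expect_equal(suppressWarnings(ape::dist.topo(phy, cl5$phylo))[1], 0)
  expect_error(upgma_cluster(dist(1)), "at least 2")
})

test_that("environmental vectors recover known gradients", {
  set.seed(23)
  pts <- matrix(rnorm(24), 12, 2)
  ord <- structure(list(points = scale(pts, scale = FALSE)),
                   class = "nmds_ordination")
  # covariate equal to axis 1: arrow along axis 1, r^2 = 1
  fit <- suppressWarnings(fit_env_vector(ord, ord$points[, 1]))
  expect_equal(abs(fit$direction[1]), 1, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  # independent noise: r^2 near zero
  noise <- rnorm(12)
  noise <- stats::resid(stats::lm(noise ~ ord$points))
  fit0 <- fit_env_vector(ord, noise)
  expect_lt(fit0$r_squared, 1e-10)

  # agreement with the normal-equations oracle
  env <- rnorm(12)
  fit2 <- fit_env_vector(ord, env)
  x <- cbind(1, ord$points)
  beta <- solve(t(x) %*% x, t(x) %*% env)[-1]
  expect_equal(unname(fit2$coefficients), unname(beta), tolerance = 1e-10)
  expect_error(fit_env_vector(ord, rep(1, 12)), "constant")
  expect_error(fit_env_vector(ord, 1:3), "length")
})
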