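test_that("wood density resolves hierarchically", {
  tab <- data.frame(
    taxon = c("Genus1 sp1", "Genus2 sp1", "Genus2 sp2", "Fam9"),
    rank = c("species", "species", "species", "family"),
    wd_gcm3 = c(0.8, 0.5, 0.7, 0.45),
    stringsAsFactors = FALSE
  )
  expect_equal(resolve_wood_density("Genus1 sp1", table = tab),
               list(density = 0.8, level = "species"))
  # genus mean of the two congeners
  expect_equal(resolve_wood_density("Genus2 sp9", table = tab),
               list(density = 0.6, level = "genus"))
  expect_equal(resolve_wood_density("GenusX spX", family = "Fam9",
                                    table = tab),
               list(density = 0.45, level = "family"))
  unknown <- resolve_wood_density("GenusX spX", family = "FamX", table = tab)
  expect_equal(unknown$level, "default")
  expect_equal(unknown$density, mean(tab$wd_gcm3))
  expect_error(resolve_wood_density("x", table = tab[0, ]), "empty")
})

test_that("height models evaluate their closed forms and stay monotone", {
  mm <- height_model("michaelis", c(a = 40, b = 20))
  expect_equal(estimate_height(20, mm), 20)
  ident <- height_model("loglog2", c(0, 1, 0))
  expect_equal(estimate_height(c(10, 50), ident), c(10, 50))
  default <- height_model()
  grid <- estimate_height(seq(10, 200, by = 1), default)
  expect_true(all(diff(grid) >= 0))
  expect_true(all(grid > 0))
  expect_error(estimate_height(15, list(form = "loglog2")), "height_model")
  expect_error(estimate_height(-5, default), "positive")
  expect_error(height_model("weibull"), "default coefficients")
})

test_that("height models can be fit to measured heights", {
  set.seed(70)
  d <- runif(80, 10, 120)
  h_true <- exp(0.9 + 0.75 * log(d) - 0.03 * log(d)^2)
  rec <- data.frame(dbh_cm = d, height_m = h_true * exp(rnorm(80, 0, 0.05)))
  fit <- fit_height_model(rec, "loglog2")
  expect_true(fit$fitted)
  expect_equal(fit$coefficients, c(0.9, 0.75, -0.03), tolerance = 0.15)
  fit_mm <- fit_height_model(rec, "michaelis")
  expect_equal(estimate_height(40, fit_mm), estimate_height(40, fit),
               tolerance = 0.2 * estimate_height(40, fit))
  expect_error(fit_height_model(rec[1:3, ], "loglog2"), ">= 5")
})

test_that("tree biomass follows the moist-forest power law", {
  expect_equal(tree_agb(10, 15, 0.6), 0.0673 * 900^0.976, tolerance = 1e-10)
  expect_equal(tree_agb(1, 1, 1), 0.0673)
  # doubling density scales biomass by 2^0.976
  expect_equal(tree_agb(30, 25, 1.2) / tree_agb(30, 25, 0.6), 2^0.976)
  expect_error(tree_agb(-1, 10, 0.5), "positive")

  # monotone in each argument
  expect_gt(tree_agb(31, 25, 0.6), tree_agb(30, 25, 0.6))
  expect_gt(tree_agb(30, 26, 0.6), tree_agb(30, 25, 0.6))
  expect_gt(tree_agb(30, 25, 0.7), tree_agb(30, 25, 0.6))
})

test_that("plot biomass sums per-tree values and honors measured heights", {
  tab <- data.frame(taxon = "Genus001 sp1", rank = "species", wd_gcm3 = 0.6)
  rec <- data.frame(
    tag = c("T1", "T2", "T3"), species = "Genus001 sp1",
    dbh_cm = c(20, 20, 20), height_m = c(18, NA, NA), status = "alive",
    stringsAsFactors = FALSE
  )
  cen <- plot_census("P1", "2021-06-15", rec)
  hm <- height_model("michaelis", c(a = 40, b = 20))
  est <- plot_agb(cen, tab, hm, prefer_measured_heights = TRUE)
  manual <- (tree_agb(20, 18, 0.6) + 2 * tree_agb(20, 20, 0.6)) / 1000
  expect_equal(est$agb_total_t, manual, tolerance = 1e-12)
  expect_equal(est$agb_total_t, sum(est$per_tree_kg) / 1000)

  # model heights only when measured ones are not preferred
  est2 <- plot_agb(cen, tab, hm, prefer_measured_heights = FALSE)
  expect_equal(est2$agb_total_t, 3 * tree_agb(20, 20, 0.6) / 1000)

  # all-equal trees: total is exactly n times the single-tree value
  recn <- data.frame(tag = paste0("S", 1:7), species = "Genus001 sp1",
                     dbh_cm = 25, status = "alive")
  estn <- plot_agb(plot_census("P2", "2021-06-15", recn), tab, hm)
  expect_equal(estn$agb_total_t,
               7 * tree_agb(25, estimate_height(25, hm), 0.6) / 1000)

  # empty census: zero with a warning
  dead <- plot_census("P3", "2021-06-15",
                      data.frame(tag = "D1", species = "Genus001 sp1",
                                 dbh_cm = 20, status = "dead"))
  expect_warning(est0 <- plot_agb(dead, tab, hm), "empty census")
  expect_equal(est0$agb_total_t, 0)
})

test_that("biomass change annualizes the census difference", {
  expect_equal(round(agb_change(285, 316, 3), 1), 10.3)
  expect_equal(agb_change(300, 300, 5), 0)
  expect_equal(agb_change(316, 285, 3), -agb_change(285, 316, 3))
  expect_error(agb_change(285, 316, 0), "positive")
})

test_that("demographic rates follow the log-count definitions", {
  pair <- list(n0 = 549, ns = 527, nr = 55, dt_years = 3)
  dr <- demographic_rates(pair)
  expect_equal(round(dr$lambda, 2), 1.36)
  expect_equal(round(dr$mu, 2), 3.31)
  expect_equal(dr$turnover, (dr$lambda + dr$mu) / 2)
  expect_true(dr$turnover >= min(dr$lambda, dr$mu) &&
                dr$turnover <= max(dr$lambda, dr$mu))

  still <- demographic_rates(list(n0 = 100, ns = 100, nr = 0, dt_years = 2))
  expect_equal(still$lambda, 0)
  expect_equal(still$mu, 0)
  expect_equal(still$turnover, 0)
  expect_error(demographic_rates(list(n0 = 10, ns = 0, nr = 2,
                                      dt_years = 1)), "no survivors")
})

test_that("stand summaries report densities and basal areas", {
  rec <- data.frame(tag = paste0("T", 1:4), species = c("A", "A", "B", "B"),
                    dbh_cm = c(10, 10, 20, 20), status = "alive")
  cen <- plot_census("P1", "2021-06-15", rec)
  s <- stand_summary(cen, size_ha = 1)
  expect_equal(s$stems_per_ha, 4)
  expect_equal(s$iqr_dbh, 10)
  expect_equal(s$mean_dbh, 15)
  expect_equal(s$max_dbh, 20)
  # single stem of DBH 20: basal area pi * 100
  one <- stand_summary(plot_census("P2", "2021-06-15", rec[3, ]), 1)
  expect_equal(one$total_basal_area_cm2, pi * 100)
  # per-species basal areas sum to the total
  expect_equal(sum(s$species_basal_area_cm2), s$total_basal_area_cm2)
  expect_equal(stand_summary(cen, size_ha = 2)$stems_per_ha, 2)
  expect_error(stand_summary(cen, size_ha = 0), "positive")
})
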