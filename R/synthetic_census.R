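#' Configuration for the synthetic census generator
#'
#' Defines a simulated region of permanent plots: a regional species pool with
#' a log-series (or lognormal) abundance distribution, per-species habitat
#' affinity splitting composition between floodplain and terra firme,
#' truncated-Weibull stem diameters, constant-hazard annual mortality,
#' recruitment influx at the measurement threshold, and a linear precipitation
#' gradient across plots. Defaults emulate a southwestern-Amazon inventory:
#' 1-ha plots of roughly 550 stems >= 10 cm DBH, ~2 % annual mortality, and a
#' 3-year census interval.
#'
#' @param n_plots Number of plots.
#' @param stems_per_plot Target living stems per plot in census 1 (Poisson
#'   mean).
#' @param s_pool Regional species pool size.
#' @param abundance_model `"logseries"` or `"lognormal"`.
#' @param logseries_x Log-series parameter x in (0,1); larger x gives a
#'   longer abundance tail.
#' @param lognormal_meanlog,lognormal_sdlog Lognormal abundance parameters.
#' @param habitat_sd Logit-normal sd of per-species floodplain affinity;
#'   0 removes habitat structure, large values approach disjoint pools.
#' @param habitat_exclusive Round affinities to 0/1 so the floodplain and
#'   terra firme species pools are strictly disjoint (default `FALSE`).
#' @param prop_floodplain Proportion of plots assigned floodplain habitat.
#' @param dbh_shape,dbh_scale Weibull diameter parameters (cm), left-truncated
#'   at `min_dbh`.
#' @param min_dbh Measurement threshold, cm.
#' @param wd_mean,wd_sd Species wood density: Normal(mean, sd) truncated to
#'   (0.1, 1.2) g/cm^3.
#' @param mortality Annual per-stem death probability m; interval survival is
#'   (1-m)^t.
#' @param recruitment Recruits reaching `min_dbh`, stems ha^-1 yr^-1.
#' @param growth_meanlog,growth_sdlog Lognormal annual diameter increment
#'   (cm/yr).
#' @param map_range Mean-annual-precipitation gradient bounds (mm) assigned
#'   linearly across plots.
#' @param map_noise_sd Gaussian noise (mm) added to the MAP gradient.
#' @param plot_size_ha Plot area (ha).
#' @param interval_years Census interval t (yr).
#' @param seed Integer seed; identical seeds give identical regions.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_plots = 21, stems_per_plot = 550,
                              s_pool = 400,
                              abundance_model = c("logseries", "lognormal"),
                              logseries_x = 0.99,
                              lognormal_meanlog = 0, lognormal_sdlog = 1.2,
                              habitat_sd = 2, habitat_exclusive = FALSE,
                              prop_floodplain = 0.4,
                              dbh_shape = 1.1, dbh_scale = 20, min_dbh = 10,
                              wd_mean = 0.6, wd_sd = 0.1,
                              mortality = 0.02, recruitment = 12,
                              growth_meanlog = log(0.2), growth_sdlog = 0.6,
                              map_range = c(1686, 3292), map_noise_sd = 0,
                              plot_size_ha = 1, interval_years = 3,
                              seed = 1L) {
  abundance_model <- match.arg(abundance_model)
  cfg <- list(
    n_plots = n_plots, stems_per_plot = stems_per_plot, s_pool = s_pool,
    abundance_model = abundance_model, logseries_x = logseries_x,
    lognormal_meanlog = lognormal_meanlog, lognormal_sdlog = lognormal_sdlog,
    habitat_sd = habitat_sd, habitat_exclusive = habitat_exclusive,
    prop_floodplain = prop_floodplain,
    dbh_shape = dbh_shape, dbh_scale = dbh_scale, min_dbh = min_dbh,
    wd_mean = wd_mean, wd_sd = wd_sd,
    mortality = mortality, recruitment = recruitment,
    growth_meanlog = growth_meanlog, growth_sdlog = growth_sdlog,
    map_range = map_range, map_noise_sd = map_noise_sd,
    plot_size_ha = plot_size_ha, interval_years = interval_years,
    seed = as.integer(seed)
  )
  if (cfg$n_plots < 1 || cfg$stems_per_plot < 1 || cfg$s_pool < 1) {
    stop("degenerate config: n_plots, stems_per_plot and s_pool must be >= 1",
         call. = FALSE)
  }
  if (cfg$mortality < 0 || cfg$mortality > 1) {
    stop("mortality must be a probability in [0, 1]", call. = FALSE)
  }
  if (cfg$logseries_x <= 0 || cfg$logseries_x >= 1) {
    stop("logseries_x must lie in (0, 1)", call. = FALSE)
  }
  if (any(c(cfg$dbh_shape, cfg$dbh_scale, cfg$interval_years,
            cfg$plot_size_ha) <= 0) || cfg$recruitment < 0) {
    stop("scales and rates must be positive", call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

# Weibull left-truncated at `min` via inverse CDF.
rweibull_trunc <- function(n, shape, scale, min) {
  p0 <- stats::pweibull(min, shape, scale)
  stats::qweibull(p0 + stats::runif(n) * (1 - p0), shape, scale)
}

rnorm_trunc <- function(n, mean, sd, lower, upper) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pl + stats::runif(n) * (pu - pl), mean, sd)
}

# Log-series abundance sampler: P(N = n) = -x^n / (n log(1 - x)).
rlogseries <- function(n, x) {
  u <- stats::runif(n)
  out <- integer(n)
  for (i in seq_len(n)) {
    k <- 1L
    cum <- -x / log(1 - x)
    while (u[i] > cum && k < 1e6) {
      k <- k + 1L
      cum <- cum + (-x^k / (k * log(1 - x)))
    }
    out[i] <- k
  }
  out
}

make_species_pool <- function(cfg) {
  abund <- switch(cfg$abundance_model,
    logseries = rlogseries(cfg$s_pool, cfg$logseries_x),
    lognormal = stats::rlnorm(cfg$s_pool, cfg$lognormal_meanlog,
                              cfg$lognormal_sdlog)
  )
  fam <- sprintf("Family%02d", 1 + (seq_len(cfg$s_pool) - 1L) %% 40L)
  affinity <- stats::plogis(stats::rnorm(cfg$s_pool, 0, cfg$habitat_sd))
  if (isTRUE(cfg$habitat_exclusive)) affinity <- round(affinity)
  data.frame(
    species = sprintf("Genus%03d species%03d",
                      1 + (seq_len(cfg$s_pool) - 1L) %% 150L,
                      seq_len(cfg$s_pool)),
    family = fam,
    regional_abundance = as.numeric(abund),
    fp_affinity = affinity,
    wood_density = rnorm_trunc(cfg$s_pool, cfg$wd_mean, cfg$wd_sd, 0.1, 1.2),
    stringsAsFactors = FALSE
  )
}

sample_census1 <- function(cfg, pool, plot_code, habitat, tag_prefix) {
  w <- pool$regional_abundance *
    if (habitat == "floodplain") pool$fp_affinity else 1 - pool$fp_affinity
  if (sum(w) <= 0) stop("habitat weights degenerate", call. = FALSE)
  n <- max(1L, stats::rpois(1L, cfg$stems_per_plot))
  idx <- sample.int(nrow(pool), n, replace = TRUE, prob = w)
  data.frame(
    tag = sprintf("%s-%05d", tag_prefix, seq_len(n)),
    species = pool$species[idx],
    family = pool$family[idx],
    subplot = sample.int(100L, n, replace = TRUE),
    x_m = stats::runif(n, 0, 100),
    y_m = stats::runif(n, 0, 100),
    dbh_cm = round(rweibull_trunc(n, cfg$dbh_shape, cfg$dbh_scale,
                                  cfg$min_dbh), 1),
    pom_m = 1.3,
    height_m = NA_real_,
    liana = sample(0:4, n, replace = TRUE, prob = c(.45, .25, .15, .1, .05)),
    exposure = sample(1:5, n, replace = TRUE, prob = c(.2, .3, .25, .15, .1)),
    crown_damage = sample(0:4, n, replace = TRUE,
                          prob = c(.6, .2, .1, .07, .03)),
    status = "alive",
    stringsAsFactors = FALSE
  )
}

advance_census <- function(cfg, pool, rec1, habitat, tag_prefix) {
  t <- cfg$interval_years
  n <- nrow(rec1)
  surv <- stats::runif(n) < (1 - cfg$mortality)^t
  rec2 <- rec1
  rec2$status[!surv] <- "dead"
  growth <- stats::rlnorm(n, cfg$growth_meanlog, cfg$growth_sdlog) * t
  rec2$dbh_cm[surv] <- round(rec2$dbh_cm[surv] + growth[surv], 1)

  n_rec <- stats::rpois(1L, cfg$recruitment * cfg$plot_size_ha * t)
  if (n_rec > 0) {
    w <- pool$regional_abundance *
      if (habitat == "floodplain") pool$fp_affinity else 1 - pool$fp_affinity
    idx <- sample.int(nrow(pool), n_rec, replace = TRUE, prob = w)
    recruits <- data.frame(
      tag = sprintf("%s-R%04d", tag_prefix, seq_len(n_rec)),
      species = pool$species[idx],
      family = pool$family[idx],
      subplot = sample.int(100L, n_rec, replace = TRUE),
      x_m = stats::runif(n_rec, 0, 100),
      y_m = stats::runif(n_rec, 0, 100),
      dbh_cm = round(stats::runif(n_rec, cfg$min_dbh, cfg$min_dbh + 2), 1),
      pom_m = 1.3,
      height_m = NA_real_,
      liana = sample(0:4, n_rec, replace = TRUE,
                     prob = c(.45, .25, .15, .1, .05)),
      exposure = sample(1:5, n_rec, replace = TRUE,
                        prob = c(.2, .3, .25, .15, .1)),
      crown_damage = sample(0:4, n_rec, replace = TRUE,
                            prob = c(.6, .2, .1, .07, .03)),
      status = "recruit",
      stringsAsFactors = FALSE
    )
    rec2 <- rbind(rec2, recruits)
  }
  list(records = rec2, deaths = sum(!surv), recruits = n_rec)
}

#' Generate a synthetic multi-plot, multi-census region
#'
#' For each plot, census 1 is a habitat-weighted multinomial draw from the
#' regional pool; census 2 applies interval survival `(1 - m)^t` per stem,
#' lognormal diameter growth, and Poisson recruitment influx with new tags.
#' The returned truth record stores the realized deaths and recruits per plot
#' alongside the generating parameters, so downstream demographic and
#' community estimators can be validated against known ground truth.
#'
#' @param config A [simulation_config()].
#' @return List with `censuses` (per plot: `census1`, `census2`, `habitat`),
#'   `metadata` (plot metadata incl. `map_mm`), `wood_density` (species-level
#'   table), and `truth` (per-plot realized counts + the config).
#' @export
generate_region <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  pool <- make_species_pool(config)
  n_fp <- round(config$n_plots * config$prop_floodplain)
  habitats <- rep(c("floodplain", "terra_firme"),
                  c(n_fp, config$n_plots - n_fp))
  habitats <- habitats[sample.int(config$n_plots)]
  map <- if (config$n_plots == 1) mean(config$map_range) else
    seq(config$map_range[1], config$map_range[2],
        length.out = config$n_plots)
  if (config$map_noise_sd > 0) {
    map <- map + stats::rnorm(config$n_plots, 0, config$map_noise_sd)
  }

  censuses <- vector("list", config$n_plots)
  truth_rows <- vector("list", config$n_plots)
  date1 <- as.Date("2021-06-15")
  date2 <- date1 + round(config$interval_years * 365.25)
  for (i in seq_len(config$n_plots)) {
    code <- sprintf("SIM-%02d", i)
    rec1 <- sample_census1(config, pool, code, habitats[i], code)
    adv <- advance_census(config, pool, rec1, habitats[i], code)
    censuses[[i]] <- list(
      census1 = plot_census(code, date1, rec1),
      census2 = plot_census(code, date2, adv$records),
      habitat = habitats[i]
    )
    truth_rows[[i]] <- data.frame(
      plot_code = code, habitat = habitats[i], n0 = nrow(rec1),
      deaths = adv$deaths, recruits = adv$recruits,
      stringsAsFactors = FALSE
    )
  }
  metadata <- data.frame(
    plot_code = sprintf("SIM-%02d", seq_len(config$n_plots)),
    name = sprintf("Synthetic plot %02d", seq_len(config$n_plots)),
    lat = -13 + seq_len(config$n_plots) * 0.15,
    lon = -71 + seq_len(config$n_plots) * 0.12,
    cluster = "Synthetic",
    elevation_m = 250,
    habitat = habitats,
    size_ha = config$plot_size_ha,
    map_mm = map,
    stringsAsFactors = FALSE
  )
  wood_density <- data.frame(
    taxon = pool$species, rank = "species", wd_gcm3 = pool$wood_density,
    stringsAsFactors = FALSE
  )
  list(
    censuses = censuses, metadata = metadata, wood_density = wood_density,
    truth = list(per_plot = do.call(rbind, truth_rows),
                 pool = pool, config = config)
  )
}

#' Worked census-pair fixture
#'
#' A runnable census pair with exactly 549 first-census stems, 22 deaths, 55
#' recruits and a 3-year interval — the published worked example of interval
#' demography, with arbitrary synthetic species labels.
#'
#' @param seed Integer seed controlling tags/species labels.
#' @return A `census_pair` (see [link_censuses()]); attributes `census1` and
#'   `census2` hold the underlying censuses.
#' @export
generate_worked_fixture <- function(seed = 1L) {
  set.seed(seed)
  n0 <- 549L; deaths <- 22L; nr <- 55L
  species <- sprintf("Genus%03d species%03d",
                     1 + (seq_len(200L) - 1L) %% 80L, seq_len(200L))
  rec1 <- data.frame(
    tag = sprintf("FIX-%05d", seq_len(n0)),
    species = sample(species, n0, replace = TRUE),
    dbh_cm = round(rweibull_trunc(n0, 1.1, 20, 10), 1),
    status = "alive",
    stringsAsFactors = FALSE
  )
  dead_idx <- sample.int(n0, deaths)
  rec2 <- rec1
  rec2$status[dead_idx] <- "dead"
  recruits <- data.frame(
    tag = sprintf("FIX-R%04d", seq_len(nr)),
    species = sample(species, nr, replace = TRUE),
    dbh_cm = round(stats::runif(nr, 10, 12), 1),
    status = "recruit",
    stringsAsFactors = FALSE
  )
  c1 <- plot_census("FLPX-01", "2021-06-15", rec1)
  c2 <- plot_census("FLPX-01", "2024-06-15", rbind(rec2, recruits))
  pair <- link_censuses(c1, c2, dt_years = 3)
  attr(pair, "census1") <- c1
  attr(pair, "census2") <- c2
  pair
}
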