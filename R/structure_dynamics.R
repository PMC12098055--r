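#' Read a wood-density CSV
#'
#' Columns `taxon, rank, wd_gcm3`, with `rank` one of species/genus/family
#' and densities in (0.05, 1.5) g/cm^3.
#'
#' @param path CSV file path.
#' @return Data frame usable by [resolve_wood_density()].
#' @export
read_wood_density_csv <- function(path) {
  wd <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("taxon", "rank", "wd_gcm3") %in% names(wd)))
  if (!all(wd$rank %in% c("species", "genus", "family"))) {
    stop("rank must be species, genus or family", call. = FALSE)
  }
  if (any(wd$wd_gcm3 <= 0.05 | wd$wd_gcm3 >= 1.5)) {
    stop("wood densities outside (0.05, 1.5) g/cm3", call. = FALSE)
  }
  wd
}

#' Resolve a wood density hierarchically
#'
#' Species-level match first; otherwise the genus-level mean, then the
#' family-level mean, then the global table mean. Always resolves; the level
#' used is reported.
#'
#' @param species Binomial (genus inferred from its first word when `genus`
#'   is `NULL`).
#' @param genus,family Optional explicit taxon names.
#' @param table Wood-density table (`taxon`, `rank`, `wd_gcm3`); genus- and
#'   family-level rows are averaged together with the means of their
#'   species-level entries.
#' @return List with `density` (g/cm^3) and `level` (one of
#'   `"species"`, `"genus"`, `"family"`, `"default"`).
#' @export
resolve_wood_density <- function(species, genus = NULL, family = NULL,
                                 table) {
  if (nrow(table) == 0) stop("empty wood-density table", call. = FALSE)
  if (is.null(genus) && !is.na(species)) {
    genus <- strsplit(species, "[ _]")[[1]][1]
  }
  sp <- table$wd_gcm3[table$rank == "species" & table$taxon == species]
  if (length(sp)) {
    return(list(density = mean(sp), level = "species"))
  }
  if (!is.null(genus)) {
    gen_direct <- table$wd_gcm3[table$rank == "genus" & table$taxon == genus]
    gen_species <- table$wd_gcm3[table$rank == "species" &
                                   startsWith(table$taxon, paste0(genus, " "))]
    gen <- c(gen_direct, gen_species)
    if (length(gen)) return(list(density = mean(gen), level = "genus"))
  }
  if (!is.null(family)) {
    fam <- table$wd_gcm3[table$rank == "family" & table$taxon == family]
    if (length(fam)) return(list(density = mean(fam), level = "family"))
  }
  list(density = mean(table$wd_gcm3), level = "default")
}

#' Construct a height-diameter allometric model
#'
#' Supported forms (D in cm, H in m):
#' \itemize{
#'   \item `loglog2`: `ln H = a + b ln D + c (ln D)^2` — the default, with
#'     pantropical-style coefficients `a = 0.893, b = 0.760, c = -0.0340`;
#'   \item `weibull`: `H = a (1 - exp(-b D^c))`;
#'   \item `michaelis`: `H = a D / (b + D)`.
#' }
#' Predictions are checked to be positive and non-decreasing over
#' D in [10, 200] at construction.
#'
#' @param form Model form.
#' @param coefficients Named or positional vector `(a, b, c)` (`michaelis`
#'   uses `(a, b)`).
#' @param fitted Whether the coefficients came from [fit_height_model()].
#' @return A `height_model`.
#' @export
height_model <- function(form = c("loglog2", "weibull", "michaelis"),
                         coefficients = NULL, fitted = FALSE) {
  form <- match.arg(form)
  if (is.null(coefficients)) {
    if (form != "loglog2") {
      stop("default coefficients exist only for loglog2", call. = FALSE)
    }
    coefficients <- c(a = 0.893, b = 0.760, c = -0.0340)
  }
  coefficients <- as.numeric(coefficients)
  need <- if (form == "michaelis") 2L else 3L
  if (length(coefficients) < need) {
    stop("form ", form, " needs ", need, " coefficients", call. = FALSE)
  }
  m <- structure(list(form = form, coefficients = coefficients,
                      fitted = fitted), class = "height_model")
  grid <- predict_height(m, seq(10, 200, by = 5))
  if (any(!is.finite(grid)) || any(grid <= 0)) {
    stop("model predicts non-positive heights on [10, 200]", call. = FALSE)
  }
  if (any(diff(grid) < -1e-8)) {
    warning("height predictions not monotone over [10, 200]", call. = FALSE)
  }
  m
}

predict_height <- function(model, dbh) {
  co <- model$coefficients
  switch(model$form,
    loglog2 = exp(co[1] + co[2] * log(dbh) + co[3] * log(dbh)^2),
    weibull = co[1] * (1 - exp(-co[2] * dbh^co[3])),
    michaelis = co[1] * dbh / (co[2] + dbh)
  )
}

#' Estimate tree height from diameter
#'
#' @param dbh Diameter(s) at breast height, cm (>= the measurement
#'   threshold).
#' @param model A [height_model()].
#' @return Predicted height(s), m.
#' @export
estimate_height <- function(dbh, model) {
  if (!inherits(model, "height_model")) {
    stop("model must be a height_model", call. = FALSE)
  }
  if (any(dbh <= 0, na.rm = TRUE)) stop("dbh must be positive", call. = FALSE)
  predict_height(model, dbh)
}

#' Fit a height-diameter model to measured heights
#'
#' `loglog2` is fit by least squares on the log scale; `weibull` and
#' `michaelis` by Levenberg-Marquardt nonlinear least squares.
#'
#' @param census A `plot_census` (or data frame) containing `dbh_cm` and
#'   measured `height_m`.
#' @param form Model form (see [height_model()]).
#' @return A fitted `height_model`.
#' @export
fit_height_model <- function(census, form = "loglog2") {
  rec <- if (inherits(census, "plot_census")) census$records else census
  rec <- rec[!is.na(rec$height_m) & !is.na(rec$dbh_cm) & rec$height_m > 0, ]
  if (nrow(rec) < 5) stop("need >= 5 measured heights", call. = FALSE)
  d <- rec$dbh_cm; h <- rec$height_m
  co <- switch(form,
    loglog2 = {
      ld <- log(d)
      stats::coef(stats::lm(log(h) ~ ld + I(ld^2)))
    },
    weibull = stats::coef(minpack.lm::nlsLM(
      h ~ a * (1 - exp(-b * d^c)),
      start = list(a = max(h) * 1.2, b = 0.03, c = 0.9),
      lower = c(1, 1e-5, 0.1)
    )),
    michaelis = stats::coef(minpack.lm::nlsLM(
      h ~ a * d / (b + d), start = list(a = max(h) * 1.5, b = 20),
      lower = c(1, 0.1)
    )),
    stop("unknown form ", form, call. = FALSE)
  )
  height_model(form, co, fitted = TRUE)
}

#' Per-tree aboveground biomass
#'
#' Moist-forest allometry `AGB = a (rho D^2 H)^b` kg, with the default
#' coefficients `a = 0.0673`, `b = 0.976` (D in cm, H in m, rho in g/cm^3).
#' Coefficients are arguments so alternative published sets can be swapped in.
#'
#' @param dbh Diameter, cm.
#' @param height Height, m.
#' @param density Wood density, g/cm^3.
#' @param coef_a,coef_b Allometry coefficients.
#' @return Biomass in kg (vectorized).
#' @export
tree_agb <- function(dbh, height, density, coef_a = 0.0673,
                     coef_b = 0.976) {
  if (any(c(dbh, height, density) <= 0, na.rm = TRUE)) {
    stop("dbh, height and density must be positive", call. = FALSE)
  }
  coef_a * (density * dbh^2 * height)^coef_b
}

#' Plot-level aboveground biomass
#'
#' Sums per-tree allometric biomass over the living stems of a census. Wood
#' densities are resolved hierarchically per species; heights use field
#' measurements where present (and preferred) and the height model otherwise.
#'
#' @param census A `plot_census`.
#' @param wd_table Wood-density table (see [read_wood_density_csv()]).
#' @param hmodel A [height_model()].
#' @param prefer_measured_heights Use `height_m` where available (default
#'   `TRUE`).
#' @param coef_a,coef_b Passed to [tree_agb()].
#' @return An `agb_estimate`: `plot_code`, `census_date`, `agb_total_t`,
#'   `per_tree_kg`, `n_trees`, `n_failed`, `wd_levels` (resolution tally).
#' @export
plot_agb <- function(census, wd_table, hmodel = height_model(),
                     prefer_measured_heights = TRUE,
                     coef_a = 0.0673, coef_b = 0.976) {
  stopifnot(inherits(census, "plot_census"))
  rec <- living_records(census)
  if (nrow(rec) == 0) {
    warning("empty census: zero biomass", call. = FALSE)
    return(structure(list(plot_code = census$plot_code,
                          census_date = census$census_date,
                          agb_total_t = 0, per_tree_kg = numeric(0),
                          n_trees = 0L, n_failed = 0L,
                          wd_levels = table(character(0))),
                     class = "agb_estimate"))
  }
  res <- lapply(seq_len(nrow(rec)), function(i) {
    tryCatch({
      wd <- resolve_wood_density(rec$species[i], family = rec$family[i],
                                 table = wd_table)
      h <- if (prefer_measured_heights && !is.na(rec$height_m[i]) &&
               rec$height_m[i] > 0) rec$height_m[i]
           else estimate_height(rec$dbh_cm[i], hmodel)
      list(kg = tree_agb(rec$dbh_cm[i], h, wd$density, coef_a, coef_b),
           level = wd$level)
    }, error = function(e) list(kg = NA_real_, level = NA_character_))
  })
  kg <- vapply(res, `[[`, numeric(1), "kg")
  lev <- vapply(res, `[[`, character(1), "level")
  n_failed <- sum(is.na(kg))
  if (n_failed > 0) {
    warning(n_failed, " stems skipped in biomass total", call. = FALSE)
  }
  structure(
    list(plot_code = census$plot_code, census_date = census$census_date,
         agb_total_t = sum(kg, na.rm = TRUE) / 1000,
         per_tree_kg = kg, n_trees = nrow(rec), n_failed = n_failed,
         wd_levels = table(lev[!is.na(lev)])),
    class = "agb_estimate"
  )
}

#' @export
print.agb_estimate <- function(x, ...) {
  cat(sprintf("<agb_estimate> %s (%s): %.1f t over %d stems\n",
              x$plot_code, format(x$census_date), x$agb_total_t, x$n_trees))
  invisible(x)
}

#' Annualized change in aboveground biomass
#'
#' @param e1,e2 `agb_estimate`s (or bare totals in t) for the same plot,
#'   first and second census.
#' @param dt_years Census interval, yr.
#' @return Change in t per year: `(total2 - total1) / dt_years`.
#' @export
agb_change <- function(e1, e2, dt_years) {
  if (dt_years <= 0) stop("dt_years must be positive", call. = FALSE)
  if (inherits(e1, "agb_estimate") && inherits(e2, "agb_estimate") &&
      e1$plot_code != e2$plot_code) {
    stop("estimates are for different plots", call. = FALSE)
  }
  t1 <- if (inherits(e1, "agb_estimate")) e1$agb_total_t else e1
  t2 <- if (inherits(e2, "agb_estimate")) e2$agb_total_t else e2
  (t2 - t1) / dt_years
}

#' Annualized mortality, recruitment and turnover rates
#'
#' From a linked census pair with `n0` initial stems, `ns` survivors, `nr`
#' recruits over `t` years:
#' `lambda = (ln n0 - ln ns) / t * 100` (% per year mortality),
#' `mu = (ln(ns + nr) - ln ns) / t * 100` (% per year recruitment),
#' and turnover is their mean.
#'
#' @param pair A `census_pair` from [link_censuses()], or a list with `n0`,
#'   `ns`, `nr`, `dt_years`.
#' @return A `demographic_rates` list: `lambda`, `mu`, `turnover` (% yr^-1)
#'   plus the inputs.
#' @export
demographic_rates <- function(pair) {
  n0 <- pair$n0; ns <- pair$ns; nr <- pair$nr; t <- pair$dt_years
  if (is.null(n0) || is.null(ns) || is.null(nr) || is.null(t)) {
    stop("pair must carry n0, ns, nr and dt_years", call. = FALSE)
  }
  if (ns <= 0) stop("no survivors: rates diverge", call. = FALSE)
  if (n0 < ns) stop("survivors exceed initial stems", call. = FALSE)
  if (t <= 0) stop("census interval must be positive", call. = FALSE)
  lambda <- (log(n0) - log(ns)) / t * 100
  mu <- (log(ns + nr) - log(ns)) / t * 100
  structure(
    list(lambda = lambda, mu = mu, turnover = (lambda + mu) / 2,
         n0 = n0, ns = ns, nr = nr, dt_years = t),
    class = "demographic_rates"
  )
}

#' @export
print.demographic_rates <- function(x, ...) {
  cat(sprintf(
    "<demographic_rates> mortality %.2f, recruitment %.2f, turnover %.2f %% yr-1\n",
    x$lambda, x$mu, x$turnover))
  invisible(x)
}

#' Stand structure summary
#'
#' Stem density, diameter summaries and basal areas for one census.
#'
#' @param census A `plot_census`.
#' @param size_ha Plot area, ha (> 0).
#' @return List with `stems_per_ha`, `mean_dbh`, `max_dbh`, `iqr_dbh` (cm),
#'   `total_basal_area_cm2`, and `species_basal_area_cm2` (named, summing to
#'   the total).
#' @export
stand_summary <- function(census, size_ha) {
  stopifnot(inherits(census, "plot_census"))
  if (size_ha <= 0) stop("size_ha must be positive", call. = FALSE)
  rec <- living_records(census)
  dbh <- rec$dbh_cm[!is.na(rec$dbh_cm)]
  ba <- pi / 4 * rec$dbh_cm^2
  sp_ba <- tapply(ba, rec$species, sum, na.rm = TRUE)
  list(
    stems_per_ha = nrow(rec) / size_ha,
    mean_dbh = mean(dbh),
    max_dbh = if (length(dbh)) max(dbh) else NA_real_,
    iqr_dbh = stats::IQR(dbh),
    total_basal_area_cm2 = sum(ba, na.rm = TRUE),
    species_basal_area_cm2 = sort(sp_ba, decreasing = TRUE)
  )
}
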