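#' Configuration for a full-plot-network analysis run
#'
#' @param censuses Named list: per plot either a single `plot_census` or a
#'   list of two (`census1`, `census2`).
#' @param metadata Plot metadata data frame (see [read_metadata_csv()]) with
#'   a `map_mm` column.
#' @param wood_density Wood-density table (may be `NULL` to skip biomass).
#' @param out_dir Output directory.
#' @param min_dbh Measurement threshold, cm.
#' @param seed Master seed for every stochastic stage.
#' @param nmds_k_range,nmds_trials,stress_threshold NMDS dimension-selection
#'   settings.
#' @param n_perm Permutations for Mantel and IndVal tests.
#' @param rarefaction_step Rarefaction step size, stems.
#' @param agb_coef `(a, b)` allometry coefficients.
#' @param prefer_measured_heights Use field heights where recorded.
#' @return A `run_config` list with a stable `config_hash`.
#' @export
run_config <- function(censuses, metadata, wood_density = NULL,
                       out_dir = tempfile("forestcensus-run-"),
                       min_dbh = 10, seed = 42L,
                       nmds_k_range = 1:10, nmds_trials = 100,
                       stress_threshold = 0.1, n_perm = 999,
                       rarefaction_step = 5,
                       agb_coef = c(0.0673, 0.976),
                       prefer_measured_heights = TRUE) {
  cfg <- list(
    censuses = censuses, metadata = metadata, wood_density = wood_density,
    out_dir = out_dir, min_dbh = min_dbh, seed = as.integer(seed),
    nmds_k_range = nmds_k_range, nmds_trials = nmds_trials,
    stress_threshold = stress_threshold, n_perm = n_perm,
    rarefaction_step = rarefaction_step, agb_coef = agb_coef,
    prefer_measured_heights = prefer_measured_heights
  )
  settings <- cfg[setdiff(names(cfg),
                          c("censuses", "metadata", "wood_density",
                            "out_dir"))]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(settings, auto_unbox = TRUE, digits = NA), tmp)
  cfg$config_hash <- unname(tools::md5sum(tmp))
  structure(cfg, class = "run_config")
}

write_tsv_with_header <- function(df, path, cfg, extra = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  version <- as.character(utils::packageVersion("forestcensus"))
  writeLines(c(
    sprintf("# forestcensus %s | config_hash=%s | seed=%d",
            version, cfg$config_hash, cfg$seed),
    extra
  ), con)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
}

#' Run the full plot-network analysis
#'
#' Orchestrates every stage over a set of censuses: diversity and rarefaction,
#' Bray-Curtis dissimilarities, NMDS with dimension selection and an
#' environmental (precipitation) vector, UPGMA clustering with Newick export,
#' Mantel tests against geographic and precipitation distances, IndVal and
#' IVI by habitat, stand structure, biomass, and interval demography, plus a
#' consolidated per-plot summary table. Each stage is logged; a failing stage
#' is recorded and its dependents skipped. Deterministic for a fixed seed.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `outputs` (paths), `status` (per-stage
#'   ok/failed/skipped), and the in-memory `results`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  status <- list()
  outputs <- list()
  results <- list()
  log_msg <- function(...) message("[forestcensus] ", sprintf(...))
  stage <- function(name, deps = character(0), fun) {
    failed_dep <- deps[vapply(deps, function(d) {
      !identical(status[[d]], "ok")
    }, logical(1))]
    if (length(failed_dep)) {
      log_msg("stage %s skipped (needs %s)", name,
              paste(failed_dep, collapse = ", "))
      status[[name]] <<- "skipped"
      return(invisible(NULL))
    }
    res <- tryCatch({
      out <- fun()
      status[[name]] <<- "ok"
      log_msg("stage %s ok", name)
      out
    }, error = function(e) {
      status[[name]] <<- "failed"
      log_msg("stage %s FAILED: %s", name, conditionMessage(e))
      NULL
    })
    results[[name]] <<- res
    invisible(res)
  }

  latest <- lapply(config$censuses, function(x) {
    if (inherits(x, "plot_census")) x else x[[length(x)]]
  })
  pairs_avail <- Filter(function(x) !inherits(x, "plot_census") &&
                          length(x) >= 2, config$censuses)

  stage("diversity", fun = function() {
    div <- diversity_table(latest)
    div <- merge(div, config$metadata[, c("plot_code", "habitat", "size_ha",
                                          "map_mm")],
                 by = "plot_code", sort = TRUE)
    outputs$diversity <<- file.path(config$out_dir, "diversity.tsv")
    write_tsv_with_header(div, outputs$diversity, config)
    div
  })

  stage("rarefaction", fun = function() {
    mat <- build_abundance_matrix(latest)
    curves <- do.call(rbind, lapply(rownames(mat), function(p) {
      cbind(plot_code = p,
            rarefaction_curve(mat[p, ], step = config$rarefaction_step))
    }))
    outputs$rarefaction <<- file.path(config$out_dir, "rarefaction.tsv")
    write_tsv_with_header(curves, outputs$rarefaction, config)
    curves
  })

  stage("spearman", deps = "diversity", fun = function() {
    div <- results$diversity
    rows <- lapply(c(shannon = "shannon", evenness = "evenness"),
                   function(col) {
      r <- spearman_correlation(div$map_mm, div[[col]])
      data.frame(metric = col, n = r$n, rho = r$rho, p_value = r$p_value)
    })
    one_ha <- div[div$size_ha == 1, ]
    r <- spearman_correlation(one_ha$map_mm, one_ha$richness)
    rows$richness <- data.frame(metric = "richness_1ha", n = r$n, rho = r$rho,
                                p_value = r$p_value)
    tab <- do.call(rbind, rows)
    outputs$spearman <<- file.path(config$out_dir, "spearman.tsv")
    write_tsv_with_header(tab, outputs$spearman, config)
    tab
  })

  stage("dissimilarity", fun = function() {
    mat <- build_abundance_matrix(latest)
    bc <- bray_curtis(mat)
    outputs$bray_curtis <<- file.path(config$out_dir, "bray_curtis.tsv")
    write_tsv_with_header(as.data.frame(as.matrix(bc)), outputs$bray_curtis,
                          config)
    list(matrix = mat, bc = bc)
  })

  stage("ordination", deps = "dissimilarity", fun = function() {
    sel <- select_dimensions(results$dissimilarity$bc,
                             k_range = config$nmds_k_range,
                             trials = config$nmds_trials,
                             stress_threshold = config$stress_threshold,
                             seed = config$seed)
    ord <- sel$ordination
    md <- config$metadata[match(rownames(ord$points),
                                config$metadata$plot_code), ]
    env <- fit_env_vector(ord, md$map_mm)
    coords <- data.frame(plot_code = rownames(ord$points), ord$points)
    outputs$ordination <<- file.path(config$out_dir, "ordination.tsv")
    write_tsv_with_header(coords, outputs$ordination, config,
                          extra = sprintf("# k=%d stress=%.6f", ord$k,
                                          ord$stress))
    outputs$ordination_json <<- file.path(config$out_dir, "ordination.json")
    jsonlite::write_json(
      list(k = ord$k, stress = ord$stress, seed = ord$seed,
           threshold_met = sel$threshold_met,
           stress_table = sel$stress_table,
           env_vector = list(direction = env$direction,
                             r_squared = env$r_squared),
           config_hash = config$config_hash),
      outputs$ordination_json, auto_unbox = TRUE, digits = NA)
    list(selection = sel, env = env)
  })

  stage("cluster", deps = "dissimilarity", fun = function() {
    cl <- upgma_cluster(results$dissimilarity$bc)
    outputs$dendrogram <<- file.path(config$out_dir, "dendrogram.nwk")
    writeLines(cl$newick, outputs$dendrogram)
    cl
  })

  stage("mantel", deps = "dissimilarity", fun = function() {
    md <- config$metadata[match(rownames(results$dissimilarity$matrix),
                                config$metadata$plot_code), ]
    geo <- haversine_matrix(md)
    dmap <- stats::dist(md$map_mm)
    attr(dmap, "Labels") <- md$plot_code
    bc <- results$dissimilarity$bc
    m_geo <- mantel_test(bc, geo, n_perm = config$n_perm, seed = config$seed)
    m_map <- mantel_test(bc, dmap, n_perm = config$n_perm,
                         seed = config$seed + 1L)
    tab <- data.frame(
      comparison = c("bray_curtis~geographic_km", "bray_curtis~delta_map_mm"),
      r = c(m_geo$r, m_map$r), p_value = c(m_geo$p_value, m_map$p_value),
      n_perm = config$n_perm
    )
    outputs$mantel <<- file.path(config$out_dir, "mantel.tsv")
    write_tsv_with_header(tab, outputs$mantel, config)
    tab
  })

  stage("indval", deps = "dissimilarity", fun = function() {
    md <- config$metadata[match(rownames(results$dissimilarity$matrix),
                                config$metadata$plot_code), ]
    iv <- indval_analysis(results$dissimilarity$matrix, md$habitat,
                          n_perm = config$n_perm, seed = config$seed)
    outputs$indval <<- file.path(config$out_dir, "indval.tsv")
    write_tsv_with_header(iv, outputs$indval, config)
    iv
  })

  stage("ivi", fun = function() {
    pooled <- do.call(rbind, lapply(names(latest), function(p) {
      rec <- living_records(latest[[p]])
      hab <- config$metadata$habitat[config$metadata$plot_code == p]
      if (!length(hab) || !nrow(rec)) return(NULL)
      data.frame(species = rec$species, dbh_cm = rec$dbh_cm, habitat = hab,
                 stringsAsFactors = FALSE)
    }))
    ivi <- importance_value_index(pooled)
    outputs$ivi <<- file.path(config$out_dir, "ivi.tsv")
    write_tsv_with_header(ivi, outputs$ivi, config)
    ivi
  })

  stage("structure", fun = function() {
    tab <- do.call(rbind, lapply(names(latest), function(p) {
      size <- config$metadata$size_ha[config$metadata$plot_code == p]
      if (!length(size)) size <- 1
      s <- stand_summary(latest[[p]], size)
      data.frame(plot_code = p, stems_per_ha = s$stems_per_ha,
                 mean_dbh = s$mean_dbh, max_dbh = s$max_dbh,
                 iqr_dbh = s$iqr_dbh,
                 total_basal_area_cm2 = s$total_basal_area_cm2)
    }))
    outputs$structure <<- file.path(config$out_dir, "structure.tsv")
    write_tsv_with_header(tab, outputs$structure, config)
    tab
  })

  stage("agb", fun = function() {
    if (is.null(config$wood_density)) stop("no wood-density table supplied")
    hm <- height_model()
    tab <- do.call(rbind, lapply(names(config$censuses), function(p) {
      cen <- config$censuses[[p]]
      cens <- if (inherits(cen, "plot_census")) list(cen) else cen
      ests <- lapply(cens, plot_agb, wd_table = config$wood_density,
                     hmodel = hm,
                     prefer_measured_heights = config$prefer_measured_heights,
                     coef_a = config$agb_coef[1], coef_b = config$agb_coef[2])
      change <- if (length(ests) >= 2) {
        dt <- as.numeric(ests[[length(ests)]]$census_date -
                           ests[[1]]$census_date) / 365.25
        agb_change(ests[[1]], ests[[length(ests)]], dt)
      } else NA_real_
      data.frame(plot_code = p,
                 agb_t = ests[[length(ests)]]$agb_total_t,
                 annual_agb_change_t = change)
    }))
    outputs$agb <<- file.path(config$out_dir, "agb.tsv")
    write_tsv_with_header(tab, outputs$agb, config)
    tab
  })

  stage("dynamics", fun = function() {
    if (!length(pairs_avail)) stop("no multi-census plots supplied")
    tab <- do.call(rbind, lapply(names(pairs_avail), function(p) {
      cc <- pairs_avail[[p]]
      pair <- link_censuses(cc[[1]], cc[[2]])
      dr <- demographic_rates(pair)
      data.frame(plot_code = p, n0 = dr$n0, ns = dr$ns, nr = dr$nr,
                 deaths = pair$deaths, dt_years = dr$dt_years,
                 lambda_pct = dr$lambda, mu_pct = dr$mu,
                 turnover_pct = dr$turnover)
    }))
    outputs$dynamics <<- file.path(config$out_dir, "dynamics.tsv")
    write_tsv_with_header(tab, outputs$dynamics, config)
    tab
  })

  stage("summary", deps = c("diversity", "structure"), fun = function() {
    tab <- merge(results$diversity,
                 results$structure[, c("plot_code", "stems_per_ha",
                                       "mean_dbh", "max_dbh")],
                 by = "plot_code")
    if (identical(status$agb, "ok")) {
      tab <- merge(tab, results$agb, by = "plot_code", all.x = TRUE)
    }
    if (identical(status$dynamics, "ok")) {
      tab <- merge(tab,
                   results$dynamics[, c("plot_code", "lambda_pct", "mu_pct",
                                        "turnover_pct")],
                   by = "plot_code", all.x = TRUE)
    }
    outputs$summary <<- file.path(config$out_dir, "plot_summary.tsv")
    write_tsv_with_header(tab, outputs$summary, config)
    tab
  })

  outputs$status <- file.path(config$out_dir, "run_status.json")
  jsonlite::write_json(
    list(status = status, config_hash = config$config_hash,
         seed = config$seed,
         package_version =
           as.character(utils::packageVersion("forestcensus"))),
    outputs$status, auto_unbox = TRUE)
  invisible(list(outputs = outputs, status = status, results = results))
}
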