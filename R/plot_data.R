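# Canonical census CSV columns. The field protocol defines measurements and
# scores, not a file layout; this dialect is fixed so round-trips are exact.
CENSUS_COLUMNS <- c(
  "tag", "species", "family", "subplot", "x_m", "y_m", "dbh_cm", "pom_m",
  "height_m", "liana", "exposure", "crown_damage", "status"
)
REQUIRED_COLUMNS <- c("tag", "species", "dbh_cm", "status")
VALID_STATUS <- c("alive", "dead", "recruit")

#' Construct a plot census
#'
#' A `plot_census` bundles one complete enumeration of a plot: every
#' self-supporting woody stem at or above the minimum diameter, with its tag,
#' identification, position, diameter and condition scores.
#'
#' @param plot_code Plot identifier, e.g. `"FLP-01"`.
#' @param census_date A `Date` (or string coercible to one).
#' @param records Data frame with (at least) columns `tag`, `species`,
#'   `dbh_cm`, `status`; optional columns `family`, `subplot`, `x_m`, `y_m`,
#'   `pom_m`, `height_m`, `liana`, `exposure`, `crown_damage`.
#' @param validate Run structural validation (default `TRUE`).
#'
#' @return An object of class `plot_census`.
#' @export
plot_census <- function(plot_code, census_date, records, validate = TRUE) {
  stopifnot(is.character(plot_code), length(plot_code) == 1L)
  census_date <- as.Date(census_date)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  for (col in setdiff(CENSUS_COLUMNS, names(records))) {
    records[[col]] <- if (col %in% c("species", "family", "status")) {
      NA_character_
    } else {
      NA_real_
    }
  }
  if (all(is.na(records$status))) records$status <- "alive"
  records$tag <- as.character(records$tag)
  records <- records[, CENSUS_COLUMNS, drop = FALSE]
  obj <- structure(
    list(plot_code = plot_code, census_date = census_date, records = records),
    class = "plot_census"
  )
  if (validate) {
    rep <- validate_census(obj)
    if (!rep$valid) {
      stop("invalid census for plot ", plot_code, ":\n",
           paste(rep$issues$message, collapse = "\n"), call. = FALSE)
    }
  }
  obj
}

#' @export
print.plot_census <- function(x, ...) {
  cat(sprintf("<plot_census> %s (%s): %d stems, %d species\n",
              x$plot_code, format(x$census_date), nrow(x$records),
              length(unique(x$records$species[!is.na(x$records$species)]))))
  invisible(x)
}

#' Number of stems in a census
#'
#' Counts living stems (status `alive` or `recruit`) by default.
#'
#' @param census A `plot_census`.
#' @param alive_only Count only living stems (default `TRUE`).
#' @return Integer stem count.
#' @export
n_stems <- function(census, alive_only = TRUE) {
  stopifnot(inherits(census, "plot_census"))
  if (alive_only) sum(census$records$status %in% c("alive", "recruit"))
  else nrow(census$records)
}

#' Living records of a census
#' @param census A `plot_census`.
#' @return Data frame of records with status `alive` or `recruit`.
#' @export
living_records <- function(census) {
  stopifnot(inherits(census, "plot_census"))
  census$records[census$records$status %in% c("alive", "recruit"), ,
                 drop = FALSE]
}

#' Validate a census
#'
#' Structural checks: duplicate tags, condition scores within their defined
#' ranges (liana and crown damage 0-4, exposure 1-5), plot-local coordinates
#' within the plot, positive diameters, known status labels.
#'
#' @param census A `plot_census`.
#' @param plot_side_m Side length used to bound x/y coordinates (default 100).
#' @return A list with `valid` (logical) and `issues` (data frame of
#'   `row`, `tag`, `message`).
#' @export
validate_census <- function(census, plot_side_m = 100) {
  rec <- census$records
  issues <- list()
  add <- function(rows, msg) {
    if (length(rows)) {
      issues[[length(issues) + 1L]] <<- data.frame(
        row = rows, tag = rec$tag[rows],
        message = sprintf("row %d (tag %s): %s", rows, rec$tag[rows], msg),
        stringsAsFactors = FALSE
      )
    }
  }
  dup <- which(duplicated(rec$tag) | duplicated(rec$tag, fromLast = TRUE))
  add(dup, "duplicate tag")
  add(which(!is.na(rec$dbh_cm) & rec$dbh_cm <= 0), "non-positive dbh")
  add(which(is.na(rec$dbh_cm) & rec$status != "dead"), "missing dbh")
  add(which(!is.na(rec$liana) & !(rec$liana %in% 0:4)), "liana score outside 0-4")
  add(which(!is.na(rec$exposure) & !(rec$exposure %in% 1:5)),
      "exposure score outside 1-5")
  add(which(!is.na(rec$crown_damage) & !(rec$crown_damage %in% 0:4)),
      "crown damage score outside 0-4")
  add(which(!is.na(rec$x_m) & (rec$x_m < 0 | rec$x_m > plot_side_m)),
      "x coordinate outside plot")
  add(which(!is.na(rec$y_m) & (rec$y_m < 0 | rec$y_m > plot_side_m)),
      "y coordinate outside plot")
  add(which(!rec$status %in% VALID_STATUS),
      paste0("status not one of ", paste(VALID_STATUS, collapse = "/")))
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(row = integer(), tag = character(), message = character(),
               stringsAsFactors = FALSE)
  list(valid = nrow(issues) == 0L, issues = issues)
}

#' Write a validation report as JSON
#'
#' @param report Result of [validate_census()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  jsonlite::write_json(
    list(valid = report$valid, n_issues = nrow(report$issues),
         issues = report$issues),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a census CSV
#'
#' Reads the canonical census table (UTF-8, comma-separated, one header row;
#' columns `tag, species, family, subplot, x_m, y_m, dbh_cm, pom_m, height_m,
#' liana, exposure, crown_damage, status`). Gzip-compressed files are read
#' transparently. Living rows below the minimum diameter are rejected and
#' reported via the `rejected` attribute rather than raising an error;
#' structural problems (missing required columns, duplicate tags, out-of-range
#' scores) abort with a message listing offending rows.
#'
#' @param path CSV (or CSV.gz) file path.
#' @param min_dbh Minimum diameter at breast height in cm (default 10).
#' @param plot_code,census_date Used when not present as `plot_code` /
#'   `census_date` columns in the file.
#' @return A `plot_census`; attribute `rejected` holds rows dropped for
#'   sub-threshold diameter.
#' @export
read_census_csv <- function(path, min_dbh = 10, plot_code = NULL,
                            census_date = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("no records in ", path, call. = FALSE)
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(plot_code)) {
    plot_code <- if ("plot_code" %in% names(df)) df$plot_code[1L] else
      stop("plot_code neither in file nor supplied", call. = FALSE)
  }
  if (is.null(census_date)) {
    census_date <- if ("census_date" %in% names(df)) df$census_date[1L] else
      stop("census_date neither in file nor supplied", call. = FALSE)
  }
  df$plot_code <- NULL
  df$census_date <- NULL
  if (!"status" %in% names(df)) df$status <- "alive"
  below <- !is.na(df$dbh_cm) & df$dbh_cm < min_dbh & df$status != "dead"
  rejected <- df[below, , drop = FALSE]
  df <- df[!below, , drop = FALSE]
  if (nrow(df) == 0L) stop("no records at or above min_dbh", call. = FALSE)
  cen <- plot_census(plot_code, census_date, df)
  attr(cen, "rejected") <- rejected
  attr(cen, "min_dbh") <- min_dbh
  cen
}

#' Write a census CSV
#'
#' Inverse of [read_census_csv()] on the canonical column set; a read/write
#' round trip is content-identical.
#'
#' @param census A `plot_census`.
#' @param path Output path (`.gz` suffix writes gzip).
#' @return `path`, invisibly.
#' @export
write_census_csv <- function(census, path) {
  stopifnot(inherits(census, "plot_census"))
  out <- cbind(
    data.frame(plot_code = census$plot_code,
               census_date = format(census$census_date),
               stringsAsFactors = FALSE),
    census$records
  )
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plot metadata CSV
#'
#' Columns: `plot_code, name, lat, lon, cluster, elevation_m, habitat,
#' size_ha` (optionally `census_year`, `map_mm`). Habitat must be
#' `floodplain` or `terra_firme`; plot sizes must be positive.
#'
#' @param path CSV file path.
#' @return Data frame of plot metadata.
#' @export
read_metadata_csv <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("plot_code", "lat", "lon", "habitat", "size_ha")
  missing_cols <- setdiff(need, names(md))
  if (length(missing_cols)) {
    stop("metadata missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- !md$habitat %in% c("floodplain", "terra_firme")
  if (any(bad)) {
    stop("habitat must be floodplain or terra_firme; offending plots: ",
         paste(md$plot_code[bad], collapse = ", "), call. = FALSE)
  }
  if (any(md$size_ha <= 0)) stop("size_ha must be positive", call. = FALSE)
  if (any(abs(md$lat) > 90) || any(abs(md$lon) > 180)) {
    stop("lat/lon out of range", call. = FALSE)
  }
  md
}

#' Packaged southwestern-Amazon plot metadata
#'
#' Metadata for the 21 published plots (code, name, coordinates, geographic
#' cluster, elevation, habitat, size, census year) shipped with the package.
#'
#' @return Data frame, one row per plot.
#' @export
regional_plot_metadata <- function() {
  read_metadata_csv(system.file("extdata", "plot_metadata.csv",
                                package = "forestcensus", mustWork = TRUE))
}

#' Packaged southwestern-Amazon plot summary statistics
#'
#' Published per-plot summaries: species richness, Shannon index, stems,
#' evenness, mean annual precipitation (mm), aboveground biomass (t), and —
#' for the plots with published dynamics — annual AGB change and annualized
#' mortality/recruitment/turnover rates (% per year).
#'
#' @return Data frame, one row per plot.
#' @export
regional_plot_stats <- function() {
  utils::read.csv(system.file("extdata", "plot_statistics.csv",
                              package = "forestcensus", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Link two censuses of the same plot
#'
#' Classifies every stem of the first census as survivor or death, and every
#' stem appearing only in the second census as a recruit, by tag identity.
#' The decomposition satisfies `n0 = ns + deaths` and
#' `stems(census 2) = ns + nr`.
#'
#' @param c1,c2 `plot_census` objects for the same plot, `c2` later.
#' @param dt_years Census interval override in decimal years; by default the
#'   date difference in days / 365.25.
#' @return A `census_pair`: list with `plot_code`, `n0`, `ns`, `nr`,
#'   `deaths`, `dt_years`, and a `matched` data frame
#'   (`tag`, `fate` in survivor/death/recruit).
#' @export
link_censuses <- function(c1, c2, dt_years = NULL) {
  stopifnot(inherits(c1, "plot_census"), inherits(c2, "plot_census"))
  if (c1$plot_code != c2$plot_code) {
    stop("censuses are from different plots: ", c1$plot_code, " vs ",
         c2$plot_code, call. = FALSE)
  }
  if (!is.null(c1$census_date) && !is.null(c2$census_date) &&
      c2$census_date <= c1$census_date && is.null(dt_years)) {
    stop("second census must post-date the first", call. = FALSE)
  }
  alive1 <- c1$records$tag[c1$records$status %in% c("alive", "recruit")]
  dead1 <- c1$records$tag[c1$records$status == "dead"]
  alive2 <- c2$records$tag[c2$records$status %in% c("alive", "recruit")]
  dead2 <- c2$records$tag[c2$records$status == "dead"]

  bad <- intersect(dead1, alive2)
  if (length(bad)) {
    stop("tags recorded dead in census 1 but alive in census 2: ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  survivors <- intersect(alive1, alive2)
  deaths <- setdiff(alive1, survivors) # missing from c2 or flagged dead there
  recruits <- setdiff(alive2, alive1)

  if (is.null(dt_years)) {
    dt_years <- as.numeric(c2$census_date - c1$census_date) / 365.25
  }
  if (dt_years <= 0) stop("dt_years must be positive", call. = FALSE)

  matched <- data.frame(
    tag = c(survivors, deaths, recruits),
    fate = rep(c("survivor", "death", "recruit"),
               c(length(survivors), length(deaths), length(recruits))),
    stringsAsFactors = FALSE
  )
  structure(
    list(plot_code = c1$plot_code, n0 = length(alive1),
         ns = length(survivors), nr = length(recruits),
         deaths = length(deaths), dt_years = dt_years, matched = matched),
    class = "census_pair"
  )
}

#' @export
print.census_pair <- function(x, ...) {
  cat(sprintf(
    "<census_pair> %s: n0=%d, survivors=%d, deaths=%d, recruits=%d, dt=%.2f yr\n",
    x$plot_code, x$n0, x$ns, x$deaths, x$nr, x$dt_years))
  invisible(x)
}

#' Build a plots-by-species abundance matrix
#'
#' Counts living stems per species in each census; the species set is the
#' union across plots and all-zero species columns are dropped. Row sums equal
#' each plot's living stem count.
#'
#' @param censuses List of `plot_census` objects, one per plot.
#' @param drop_indet Drop indeterminate morphospecies (species strings
#'   containing `"indet"`, case-insensitive)? Default `FALSE`.
#' @return Integer matrix; rows named by plot code, columns by species.
#' @export
build_abundance_matrix <- function(censuses, drop_indet = FALSE) {
  stopifnot(length(censuses) >= 1L)
  codes <- vapply(censuses, function(x) x$plot_code, character(1))
  if (anyDuplicated(codes)) {
    stop("duplicate plot codes: ",
         paste(unique(codes[duplicated(codes)]), collapse = ", "),
         call. = FALSE)
  }
  counts <- lapply(censuses, function(cen) {
    rec <- living_records(cen)
    sp <- rec$species
    sp[is.na(sp)] <- "Indet indet"
    table(sp)
  })
  species <- sort(unique(unlist(lapply(counts, names))))
  mat <- matrix(0L, nrow = length(codes), ncol = length(species),
                dimnames = list(codes, species))
  for (i in seq_along(counts)) {
    mat[i, names(counts[[i]])] <- as.integer(counts[[i]])
  }
  if (drop_indet) {
    mat <- mat[, !grepl("indet", colnames(mat), ignore.case = TRUE),
               drop = FALSE]
  }
  mat[, colSums(mat) > 0, drop = FALSE]
}
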