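test_that("census CSV reading enforces the diameter threshold and reports rejects", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_fixture_csv(path)
  cen <- read_census_csv(path, min_dbh = 10)
  expect_s3_class(cen, "plot_census")
  expect_equal(nrow(cen$records), 4L)           # the 9.5 cm row is rejected
  expect_equal(attr(cen, "rejected")$tag, "T3")
  expect_equal(cen$plot_code, "TST-01")
  # threshold is inclusive: the 10.0 cm stem stays
  expect_true("T5" %in% cen$records$tag)
})

test_that("census CSV reading reads gzip and errors on structural problems", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_fixture_csv(path)
  gz <- withr::local_tempfile(fileext = ".csv.gz")
  con <- gzfile(gz, "w")
  writeLines(readLines(path), con)
  close(con)
  expect_equal(nrow(read_census_csv(gz)$records), 4L)

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("plot_code,census_date,tag,species,dbh_cm,status", empty)
  expect_error(read_census_csv(empty), "no records")

  nocol <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plot_code,census_date,tag,species", "P,2021-01-01,T1,x"),
             nocol)
  expect_error(read_census_csv(nocol), "missing required columns")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "plot_code,census_date,tag,species,dbh_cm,liana,status",
    "P,2021-01-01,T1,Genus sp,12,9,alive",
    "P,2021-01-01,T1,Genus sp,13,0,alive"
  ), bad)
  err <- tryCatch(read_census_csv(bad), error = conditionMessage)
  expect_match(err, "duplicate tag")
  expect_match(err, "liana score")
})

test_that("census CSV round-trips content-identically", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_fixture_csv(path)
  cen <- read_census_csv(path, min_dbh = 5)  # keep all rows
  out <- withr::local_tempfile(fileext = ".csv")
  write_census_csv(cen, out)
  expect_identical(read_census_csv(out, min_dbh = 5)$records, cen$records)
})

test_that("census linking classifies survivors, deaths and recruits", {
  c1 <- make_census(c(A = 3, B = 2), census_date = "2021-06-15")
  rec2 <- c1$records
  rec2$status[1] <- "dead"
  recruit <- data.frame(tag = "TST-01-R1", species = "C", dbh_cm = 10.5,
                        status = "recruit", stringsAsFactors = FALSE)
  c2 <- plot_census("TST-01", "2024-06-15",
                    rbind(rec2[, c("tag", "species", "dbh_cm", "status")],
                          recruit))
  pair <- link_censuses(c1, c2)
  expect_equal(pair$n0, 5L)
  expect_equal(pair$deaths, 1L)
  expect_equal(pair$nr, 1L)
  expect_equal(pair$n0, pair$ns + pair$deaths)
  expect_equal(n_stems(c2), pair$ns + pair$nr)
  expect_equal(pair$dt_years, 3, tolerance = 0.01)

  # identical censuses: no deaths, no recruits
  c2b <- plot_census("TST-01", "2024-06-15", c1$records)
  pair2 <- link_censuses(c1, c2b)
  expect_equal(pair2$deaths, 0L)
  expect_equal(pair2$nr, 0L)

  # a tag dead in census 1 cannot reappear alive
  rec1d <- c1$records
  rec1d$status[2] <- "dead"
  c1d <- plot_census("TST-01", "2021-06-15", rec1d)
  expect_error(link_censuses(c1d, c2b), "dead in census 1")
  # different plots refuse to link
  expect_error(
    link_censuses(c1, plot_census("OTHER", "2024-01-01", c1$records)),
    "different plots")
})

test_that("linking recovers the worked FLP-01 interval counts", {
  pair <- generate_worked_fixture(seed = 3)
  expect_equal(pair$n0, 549L)
  expect_equal(pair$deaths, 22L)
  expect_equal(pair$ns, 527L)
  expect_equal(pair$nr, 55L)
  expect_equal(pair$ns + pair$nr, 582L)
  expect_equal(pair$dt_years, 3)
})

test_that("abundance matrices respect stem counts and drop empty species", {
  c1 <- make_census(c(A = 2, B = 3), plot_code = "P1")
  c2 <- make_census(c(C = 4, D = 1), plot_code = "P2")
  mat <- build_abundance_matrix(list(c1, c2))
  expect_equal(rowSums(mat), c(P1 = 5, P2 = 5))
  # disjoint plots give a block-diagonal matrix
  expect_equal(sum(mat["P1", c("C", "D")]), 0)
  expect_equal(sum(mat["P2", c("A", "B")]), 0)
  expect_true(all(colSums(mat) > 0))
  expect_error(build_abundance_matrix(list(c1, c1)), "duplicate plot codes")

  # morphospecies filtering is opt-in
  c3 <- make_census(c(`Inga indet` = 2, E = 1), plot_code = "P3")
  m2 <- build_abundance_matrix(list(c1, c3), drop_indet = TRUE)
  expect_false("Inga indet" %in% colnames(m2))
})

test_that("pair decomposition invariants hold on simulated regions", {
  reg <- generate_region(simulation_config(n_plots = 3, stems_per_plot = 80,
                                           seed = 11))
  for (i in seq_along(reg$censuses)) {
    pair <- link_censuses(reg$censuses[[i]]$census1,
                          reg$censuses[[i]]$census2)
    expect_equal(pair$n0, pair$ns + pair$deaths)
    expect_equal(n_stems(reg$censuses[[i]]$census2), pair$ns + pair$nr)
    expect_equal(pair$deaths, reg$truth$per_plot$deaths[i])
    expect_equal(pair$nr, reg$truth$per_plot$recruits[i])
  }
})

test_that("metadata validation rejects bad habitats and sizes", {
  md <- regional_plot_metadata()
  expect_equal(nrow(md), 21L)
  expect_true(all(md$habitat %in% c("floodplain", "terra_firme")))
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("plot_code,lat,lon,habitat,size_ha",
               "X,0,0,swamp,1"), bad)
  expect_error(read_metadata_csv(bad), "habitat")
})

test_that("validation reports serialize to JSON", {
  cen <- make_census(c(A = 2))
  rep <- validate_census(cen)
  expect_true(rep$valid)
  path <- withr::local_tempfile(fileext = ".json")
  write_validation_report(rep, path)
  parsed <- jsonlite::read_json(path)
  expect_true(parsed$valid)
  expect_equal(parsed$n_issues, 0L)
})
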