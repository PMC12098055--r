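# Small in-code fixtures shared across test files.

# A census built from a named species->count vector; tags are sequential,
# diameters default to 15 cm.
make_census <- function(counts, plot_code = "TST-01",
                        census_date = "2021-06-15", dbh = 15,
                        tag_prefix = plot_code) {
  species <- rep(names(counts), counts)
  n <- length(species)
  plot_census(plot_code, census_date, data.frame(
    tag = sprintf("%s-%04d", tag_prefix, seq_len(n)),
    species = species,
    dbh_cm = rep_len(dbh, n),
    status = "alive",
    stringsAsFactors = FALSE
  ))
}

# Canonical five-row census CSV, one row below the 10 cm threshold.
write_fixture_csv <- function(path) {
  writeLines(c(
    "plot_code,census_date,tag,species,family,subplot,x_m,y_m,dbh_cm,pom_m,height_m,liana,exposure,crown_damage,status",
    "TST-01,2021-06-15,T1,Genus001 sp1,Fam1,1,5,5,12.0,1.3,14,0,3,0,alive",
    "TST-01,2021-06-15,T2,Genus001 sp2,Fam1,2,15,5,25.5,1.3,22,1,4,1,alive",
    "TST-01,2021-06-15,T3,Genus002 sp3,Fam2,3,25,5,9.5,1.3,9,0,2,0,alive",
    "TST-01,2021-06-15,T4,Genus002 sp3,Fam2,4,35,5,48.0,1.6,28,2,5,0,alive",
    "TST-01,2021-06-15,T5,Genus003 sp4,Fam3,5,45,5,10.0,1.3,11,0,1,0,alive"
  ), path)
  path
}

# The published regional summary table and metadata, joined on plot code.
regional_fixture <- function() {
  merge(regional_plot_stats(),
        regional_plot_metadata()[, c("plot_code", "size_ha", "habitat")],
        by = "plot_code")
}

# Naive UPGMA by direct agglomeration; returns the cophenetic matrix.
brute_upgma_cophenetic <- function(dm) {
  labels <- rownames(dm)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(dm)))
  dimnames(dm) <- list(labels, labels)
  clusters <- as.list(labels)
  coph <- matrix(0, length(labels), length(labels),
                 dimnames = list(labels, labels))
  while (length(clusters) > 1) {
    k <- length(clusters)
    best <- c(NA, NA); best_d <- Inf
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      d_ij <- mean(dm[clusters[[i]], clusters[[j]]])
      if (d_ij < best_d) { best_d <- d_ij; best <- c(i, j) }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- best_d
    coph[b, a] <- best_d
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}
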