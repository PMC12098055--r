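#' IndVal indicator-species analysis
#'
#' For each species and site group g the indicator value combines specificity
#' `A` and fidelity `B`:
#' \itemize{
#'   \item group-equalized (default): `A = mean abundance in g / sum over
#'     groups of mean abundances`, so unequal group sizes do not bias A;
#'   \item raw: `A = summed abundance in g / total summed abundance`.
#' }
#' `B` is the fraction of g's plots where the species occurs, and the
#' statistic is `sqrt(A * B)` for the best group. Significance comes from
#' permuting plot-to-group labels:
#' `p = (1 + #(stat_perm >= stat_obs)) / (n_perm + 1)`, or from exhaustive
#' enumeration of all distinct label assignments when `exact = TRUE`
#' (then `p = #(stat_perm >= stat_obs) / n_assignments`, the identity
#' assignment included). No multiple-testing correction is applied.
#'
#' @param mat Plots-by-species abundance matrix.
#' @param groups Group label per plot (>= 2 groups, each non-empty).
#' @param n_perm Number of permutations (default 999).
#' @param equalize Use the group-equalized A (default `TRUE`).
#' @param exact Enumerate all label assignments instead of sampling (feasible
#'   for small plot counts only; capped at 50000 assignments).
#' @param seed Integer seed for the permutations.
#' @return Data frame with one row per species: `species`, `group` (best),
#'   `A`, `B`, `stat`, `p_value`, sorted by decreasing `stat`.
#' @export
indval_analysis <- function(mat, groups, n_perm = 999, equalize = TRUE,
                            exact = FALSE, seed = 42L) {
  mat <- as.matrix(mat)
  groups <- as.character(groups)
  if (length(groups) != nrow(mat)) {
    stop("one group label per plot required", call. = FALSE)
  }
  lev <- sort(unique(groups))
  if (length(lev) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(tabulate(factor(groups, lev)) == 0)) {
    stop("every group needs at least one plot", call. = FALSE)
  }

  components <- function(g) {
    # per-group mean (or summed) abundance and occupancy, per species
    agg <- rowsum(mat, g)               # groups x species sums
    sizes <- as.vector(table(factor(g, lev)))[match(rownames(agg), lev)]
    num <- if (equalize) agg / sizes else agg
    a <- sweep(num, 2, colSums(num), "/")
    b <- rowsum((mat > 0) + 0, g) / sizes
    iv <- sqrt(a * b)
    iv[is.na(iv)] <- 0
    list(a = a, b = b, iv = iv)
  }
  stat_fun <- function(g) components(g)$iv

  cmp <- components(groups)
  iv_obs <- cmp$iv
  best <- apply(iv_obs, 2, which.max)
  sel <- cbind(best, seq_len(ncol(mat)))
  obs <- iv_obs[sel]

  if (exact) {
    perms <- enumerate_assignments(groups)
    if (is.null(perms)) stop("too many assignments for exact enumeration",
                             call. = FALSE)
    exceed <- integer(ncol(mat))
    for (i in seq_len(nrow(perms))) {
      s <- apply(stat_fun(perms[i, ]), 2, max)
      exceed <- exceed + (s >= obs - 1e-12)
    }
    p <- exceed / nrow(perms)
  } else {
    set.seed(seed)
    exceed <- integer(ncol(mat))
    for (i in seq_len(n_perm)) {
      s <- apply(stat_fun(sample(groups)), 2, max)
      exceed <- exceed + (s >= obs - 1e-12)
    }
    p <- (1 + exceed) / (n_perm + 1)
  }

  out <- data.frame(
    species = colnames(mat), group = rownames(iv_obs)[best],
    A = cmp$a[sel], B = cmp$b[sel], stat = obs, p_value = p,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- out[order(-out$stat, out$species), ]
  rownames(out) <- NULL
  out
}

# All distinct reassignments of a multiset of group labels to plots.
enumerate_assignments <- function(groups, cap = 50000L) {
  n <- length(groups)
  lev <- sort(unique(groups))
  counts <- as.vector(table(factor(groups, lev)))
  total <- factorial(n) / prod(factorial(counts))
  if (total > cap) return(NULL)
  rec <- function(remaining, slots) {
    if (length(slots) == 0L) return(matrix(character(0), 1, 0))
    avail <- which(remaining > 0)
    out <- list()
    for (a in avail) {
      rem <- remaining
      rem[a] <- rem[a] - 1L
      sub <- rec(rem, slots[-1L])
      out[[length(out) + 1L]] <- cbind(lev[a], sub)
    }
    do.call(rbind, out)
  }
  rec(counts, seq_len(n))
}

#' Importance value indices
#'
#' For stems pooled by habitat, each species' IVI is
#' `(relative density + relative basal area) / 2`, where relative density is
#' its share of stems and relative basal area its share of
#' `(pi / 4) * DBH^2` (cm^2). Within each habitat the IVIs sum to 1.
#'
#' @param records Data frame of tree records with columns `species`,
#'   `dbh_cm`, and `habitat` (or a named list of per-habitat data frames).
#' @return Data frame with `habitat`, `species`, `rel_density`,
#'   `rel_basal_area`, `ivi`, sorted by decreasing IVI within habitat. Rows
#'   with missing DBH are excluded; attribute `n_excluded` counts them.
#' @export
importance_value_index <- function(records) {
  if (is.list(records) && !is.data.frame(records)) {
    records <- do.call(rbind, lapply(names(records), function(h) {
      cbind(records[[h]][, c("species", "dbh_cm")], habitat = h)
    }))
  }
  stopifnot(all(c("species", "dbh_cm", "habitat") %in% names(records)))
  excluded <- sum(is.na(records$dbh_cm))
  if (excluded > 0) {
    warning(excluded, " records without DBH excluded", call. = FALSE)
    records <- records[!is.na(records$dbh_cm), , drop = FALSE]
  }
  if (nrow(records) == 0) stop("no usable records", call. = FALSE)
  records$ba <- pi / 4 * records$dbh_cm^2
  out <- do.call(rbind, lapply(split(records, records$habitat), function(rh) {
    dens <- tapply(rh$species, rh$species, length) / nrow(rh)
    ba <- tapply(rh$ba, rh$species, sum) / sum(rh$ba)
    sp <- names(dens)
    df <- data.frame(
      habitat = rh$habitat[1L], species = sp,
      rel_density = as.numeric(dens),
      rel_basal_area = as.numeric(ba[sp]),
      stringsAsFactors = FALSE
    )
    df$ivi <- (df$rel_density + df$rel_basal_area) / 2
    df[order(-df$ivi, df$species), ]
  }))
  rownames(out) <- NULL
  attr(out, "n_excluded") <- excluded
  out
}
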