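#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum(|x_i - y_i|) / sum(x_i + y_i)`, in `[0, 1]`: 0 for
#' identical abundance vectors, 1 for plots sharing no species.
#'
#' @param mat Plots-by-species abundance matrix (rows named by plot).
#' @return A `dist` object of pairwise Bray-Curtis dissimilarities.
#' @export
bray_curtis <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("need at least 2 plots", call. = FALSE)
  if (any(rowSums(mat) <= 0)) {
    stop("plot with zero total abundance: ",
         paste(rownames(mat)[rowSums(mat) <= 0], collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <-
        sum(abs(mat[i, ] - mat[j, ])) / sum(mat[i, ] + mat[j, ])
    }
  }
  stats::as.dist(d)
}

# Kruskal stress-1 given configuration distances d and disparities theta.
stress1 <- function(d, theta) sqrt(sum((d - theta)^2) / sum(d^2))

# Monotone (isotonic) regression of configuration distances on the rank order
# of the input dissimilarities. Primary tie treatment: tied dissimilarities
# are ordered by current configuration distance, so they may fit freely among
# themselves.
monotone_fit <- function(delta, d) {
  ord <- order(delta, d)
  fit <- numeric(length(d))
  fit[ord] <- stats::isoreg(d[ord])$yf
  fit
}

# One NMDS run from a given start configuration (n x k matrix).
nmds_single <- function(delta, x, max_iter, tol) {
  n <- nrow(x)
  d <- as.vector(stats::dist(x))
  theta <- monotone_fit(delta, d)
  s <- stress1(d, theta)
  trace <- s
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    # Guttman transform with the current disparities as targets
    dm <- as.matrix(stats::dist(x))
    tm <- matrix(0, n, n)
    tm[lower.tri(tm)] <- theta
    tm <- tm + t(tm)
    ratio <- ifelse(dm > 0, tm / dm, 0)
    b <- -ratio
    diag(b) <- rowSums(ratio)
    x_new <- b %*% x / n
    x_new <- scale(x_new, center = TRUE, scale = FALSE)

    d_new <- as.vector(stats::dist(x_new))
    theta_new <- monotone_fit(delta, d_new)
    s_new <- stress1(d_new, theta_new)
    if (s_new > s + 1e-12) { # safeguard: never accept an uphill step
      converged <- TRUE
      break
    }
    improved <- s - s_new
    x <- x_new; d <- d_new; theta <- theta_new; s <- s_new
    trace <- c(trace, s)
    if (improved < tol) {
      converged <- TRUE
      break
    }
  }
  list(points = x, stress = s, trace = trace, converged = converged)
}

#' Nonmetric multidimensional scaling
#'
#' Minimizes Kruskal stress-1,
#' `sqrt(sum((d - theta)^2) / sum(d^2))`, where `d` are configuration
#' distances and `theta` the monotone (pool-adjacent-violators) regression of
#' `d` on the dissimilarity ranks, by iterated Guttman transforms. Runs one
#' metric-MDS-seeded start plus `n_starts` random starts and keeps the best;
#' deterministic under `seed`.
#'
#' @param d Dissimilarity matrix (`dist` or square matrix).
#' @param k Number of dimensions (>= 1).
#' @param n_starts Random starts in addition to the metric seed (default 20).
#' @param max_iter Maximum iterations per start (default 300).
#' @param tol Stress-improvement convergence tolerance (default 1e-7).
#' @param seed Integer seed for the random starts.
#' @return An `nmds_ordination`: `points` (centered n x k coordinates),
#'   `stress`, `k`, `n_starts`, `best_start` (0 = metric seed), `converged`,
#'   `trace` (per-iteration stress of the best start), `seed`.
#' @export
nmds <- function(d, k, n_starts = 20, max_iter = 300, tol = 1e-7,
                 seed = 42L) {
  dm <- as.matrix(d)
  if (!isSymmetric(unname(dm)) || any(diag(dm) != 0)) {
    stop("d must be symmetric with zero diagonal", call. = FALSE)
  }
  n <- nrow(dm)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (k >= n) stop("k must be < number of points", call. = FALSE)
  delta <- as.vector(stats::as.dist(dm))
  set.seed(seed)

  starts <- vector("list", n_starts + 1L)
  cmd <- suppressWarnings(stats::cmdscale(dm, k = k))
  if (ncol(cmd) < k) { # degenerate metric solution: pad with tiny noise
    cmd <- cbind(cmd, matrix(stats::rnorm(n * (k - ncol(cmd)), 0, 1e-4),
                             n, k - ncol(cmd)))
  }
  starts[[1L]] <- cmd
  for (i in seq_len(n_starts)) {
    starts[[i + 1L]] <- matrix(stats::rnorm(n * k), n, k)
  }

  best <- NULL
  best_idx <- NA_integer_
  metric_initial_stress <- NA_real_
  for (i in seq_along(starts)) {
    run <- nmds_single(delta, starts[[i]], max_iter, tol)
    if (i == 1L) metric_initial_stress <- run$trace[1L]
    if (is.null(best) || run$stress < best$stress) {
      best <- run
      best_idx <- i - 1L
    }
  }
  pts <- scale(best$points, center = TRUE, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  dimnames(pts) <- list(rownames(dm), paste0("NMDS", seq_len(k)))
  structure(
    list(points = pts, stress = best$stress, k = k, n_starts = n_starts,
         best_start = best_idx, converged = best$converged,
         trace = best$trace, metric_initial_stress = metric_initial_stress,
         seed = seed),
    class = "nmds_ordination"
  )
}

#' @export
print.nmds_ordination <- function(x, ...) {
  cat(sprintf(
    "<nmds_ordination> %d points, k=%d, stress=%.4f (%s, best start %s)\n",
    nrow(x$points), x$k, x$stress,
    if (x$converged) "converged" else "max_iter reached",
    if (x$best_start == 0) "metric seed" else x$best_start))
  invisible(x)
}

#' Choose the NMDS dimensionality by a stress threshold
#'
#' Runs NMDS over a range of dimensions and returns the smallest k whose best
#' stress is at or below the threshold, with the full stress-versus-k table.
#' If no k qualifies, the first k with stress below 0.2 is returned with
#' `threshold_met = FALSE` and a warning.
#'
#' @param d Dissimilarity matrix.
#' @param k_range Candidate dimensions (default `1:10`; capped at n - 2).
#' @param trials Random starts per dimension (default 100).
#' @param stress_threshold Acceptable stress (default 0.1).
#' @param seed Integer seed.
#' @param ... Passed to [nmds()].
#' @return List with `k`, `stress_table` (k, stress), `threshold_met`, and
#'   `ordination` (the NMDS result at the chosen k).
#' @export
select_dimensions <- function(d, k_range = 1:10, trials = 100,
                              stress_threshold = 0.1, seed = 42L, ...) {
  n <- nrow(as.matrix(d))
  k_range <- k_range[k_range <= max(n - 2L, 1L)]
  runs <- lapply(seq_along(k_range), function(i) {
    nmds(d, k = k_range[i], n_starts = trials, seed = seed + i, ...)
  })
  stress <- vapply(runs, `[[`, numeric(1), "stress")
  tab <- data.frame(k = k_range, stress = stress)
  ok <- which(stress <= stress_threshold)
  if (length(ok)) {
    idx <- ok[1L]
    met <- TRUE
  } else {
    warning("no dimensionality reached stress <= ", stress_threshold,
            "; falling back to stress < 0.2", call. = FALSE)
    fallback <- which(stress < 0.2)
    idx <- if (length(fallback)) fallback[1L] else which.min(stress)
    met <- FALSE
  }
  list(k = k_range[idx], stress_table = tab, threshold_met = met,
       ordination = runs[[idx]])
}

#' Mantel permutation test
#'
#' Correlation between the off-diagonal elements of two distance matrices,
#' with significance from joint row/column permutations of the second matrix:
#' `p = (1 + #(r_perm >= r_obs)) / (n_perm + 1)` (one-tailed, greater).
#'
#' @param d1,d2 Distance matrices (`dist` or square) with matching labels.
#' @param n_perm Number of permutations (default 999).
#' @param method `"pearson"` or `"spearman"` correlation.
#' @param seed Integer seed.
#' @return List with `r`, `p_value`, `n_perm`, `method`.
#' @export
mantel_test <- function(d1, d2, n_perm = 999,
                        method = c("pearson", "spearman"), seed = 42L) {
  method <- match.arg(method)
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  if (!identical(dim(m1), dim(m2))) {
    stop("distance matrices differ in size", call. = FALSE)
  }
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2))) {
    stop("distance matrix labels do not match", call. = FALSE)
  }
  n <- nrow(m1)
  ut <- upper.tri(m1)
  v1 <- m1[ut]
  r_obs <- stats::cor(v1, m2[ut], method = method)
  set.seed(seed)
  count <- 0L
  for (i in seq_len(n_perm)) {
    p <- sample.int(n)
    r_perm <- stats::cor(v1, m2[p, p][ut], method = method)
    if (r_perm >= r_obs - 1e-12) count <- count + 1L
  }
  list(r = r_obs, p_value = (1 + count) / (n_perm + 1), n_perm = n_perm,
       method = method)
}

#' Great-circle distance matrix
#'
#' Haversine distances between plot coordinates, Earth radius 6371 km.
#'
#' @param metadata Data frame with `plot_code`, `lat`, `lon` (decimal
#'   degrees).
#' @return A `dist` of distances in km, labelled by plot code.
#' @export
haversine_matrix <- function(metadata) {
  lat <- metadata$lat; lon <- metadata$lon
  if (any(abs(lat) > 90)) stop("latitude outside [-90, 90]", call. = FALSE)
  if (any(abs(lon) > 180)) stop("longitude outside [-180, 180]", call. = FALSE)
  r_earth <- 6371
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  n <- length(lat)
  d <- matrix(0, n, n, dimnames = list(metadata$plot_code,
                                       metadata$plot_code))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- sin((phi[j] - phi[i]) / 2)^2 +
        cos(phi[i]) * cos(phi[j]) * sin((lam[j] - lam[i]) / 2)^2
      d[i, j] <- d[j, i] <- 2 * r_earth * asin(pmin(1, sqrt(a)))
    }
  }
  stats::as.dist(d)
}

#' UPGMA cluster dendrogram
#'
#' Average-linkage agglomerative clustering of a dissimilarity matrix, with
#' Newick export via `ape`.
#'
#' @param d Dissimilarity matrix (`dist` or square) for >= 2 plots.
#' @return List with `hclust` (the tree), `phylo` (`ape` tree, ultrametric,
#'   cophenetic branch lengths) and `newick` (string with branch lengths).
#' @export
upgma_cluster <- function(d) {
  dd <- stats::as.dist(d)
  if (attr(dd, "Size") < 2) stop("need at least 2 plots", call. = FALSE)
  hc <- stats::hclust(dd, method = "average")
  phy <- ape::as.phylo(hc)
  list(hclust = hc, phylo = phy,
       newick = ape::write.tree(phy))
}

#' Fit an environmental vector to an ordination
#'
#' Least-squares regression of a covariate on the ordination coordinates; the
#' arrow direction is the unit coefficient vector and its length is
#' proportional to `sqrt(r^2)`.
#'
#' @param ordination An `nmds_ordination` (or coordinate matrix).
#' @param env Covariate vector, one value per plot.
#' @return List with `direction` (unit vector), `r_squared`, `arrow`
#'   (direction scaled by `sqrt(r_squared)`), `coefficients`.
#' @export
fit_env_vector <- function(ordination, env) {
  pts <- if (inherits(ordination, "nmds_ordination")) ordination$points
         else as.matrix(ordination)
  if (length(env) != nrow(pts)) {
    stop("env length must equal plot count", call. = FALSE)
  }
  if (length(unique(env)) == 1L) stop("constant covariate", call. = FALSE)
  fit <- stats::lm(env ~ pts)
  beta <- stats::coef(fit)[-1L]
  norm <- sqrt(sum(beta^2))
  if (norm == 0) stop("covariate unrelated to all axes", call. = FALSE)
  r2 <- summary(fit)$r.squared
  direction <- beta / norm
  names(direction) <- colnames(pts)
  list(direction = direction, r_squared = r2,
       arrow = direction * sqrt(r2), coefficients = beta)
}
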