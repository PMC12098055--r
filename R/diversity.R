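#' Shannon diversity index
#'
#' `H = -sum(p_i * log(p_i))` in nats, over relative abundances
#' `p_i = n_i / N`; zero-count species are ignored.
#'
#' @param counts Non-negative species abundance vector with positive total.
#' @return Shannon index in nats.
#' @export
shannon <- function(counts) {
  counts <- as.numeric(counts)
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("counts must be non-negative and complete", call. = FALSE)
  }
  total <- sum(counts)
  if (total <= 0) stop("all-zero abundance vector", call. = FALSE)
  p <- counts[counts > 0] / total
  -sum(p * log(p))
}

#' Pielou evenness
#'
#' `J = H / log(S)`, the Shannon index normalized by its maximum for the
#' observed richness; in `[0, 1]`, with 1 for perfectly even communities.
#'
#' @param counts Species abundance vector with at least two species present.
#' @return Evenness J.
#' @seealso [pielou_from_shannon()] for the identity applied to already
#'   computed `(H, S)` pairs.
#' @export
pielou_evenness <- function(counts) {
  s <- sum(counts > 0)
  if (s < 2) stop("evenness undefined for fewer than 2 species", call. = FALSE)
  shannon(counts) / log(s)
}

#' Evenness from a Shannon index and richness
#'
#' @param h Shannon index (nats).
#' @param s Species richness (>= 2).
#' @return `h / log(s)`.
#' @export
pielou_from_shannon <- function(h, s) {
  if (any(s < 2)) stop("evenness undefined for fewer than 2 species",
                       call. = FALSE)
  h / log(s)
}

#' Analytic rarefaction curve
#'
#' Expected species richness in a without-replacement subsample of n stems:
#' `E[S_n] = sum_i (1 - choose(N - N_i, n) / choose(N, n))` (hypergeometric
#' expectation), tabulated at `n = step, 2 step, ...` up to and including the
#' full stem count, where the curve equals the observed richness exactly.
#'
#' @param counts Species abundance vector.
#' @param step Step size in stems (default 5).
#' @return Data frame with columns `n` and `expected_richness`.
#' @export
rarefaction_curve <- function(counts, step = 5) {
  if (step <= 0) stop("step must be positive", call. = FALSE)
  counts <- as.numeric(counts[counts > 0])
  n_total <- sum(counts)
  if (n_total < step) stop("fewer stems than one step", call. = FALSE)
  ns <- unique(c(seq(step, n_total, by = step), n_total))
  exp_s <- vapply(ns, function(n) {
    # log-scale binomial ratios; species with N - N_i < n contribute 1
    sum(1 - exp(lchoose(n_total - counts, n) - lchoose(n_total, n)))
  }, numeric(1))
  data.frame(n = ns, expected_richness = exp_s)
}

#' Spearman rank correlation
#'
#' Rho on midranks with a two-sided p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))`; optionally an exact permutation
#' p-value by full enumeration for small samples.
#'
#' @param x,y Numeric vectors of equal length `n >= 4`.
#' @param exact Use exhaustive permutation enumeration (only for `n <= 10`).
#' @return List with `rho`, `p_value`, `n`, `method`.
#' @export
spearman_correlation <- function(x, y, exact = FALSE) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4 || length(y) != n) {
    stop("need equal-length vectors with n >= 4", call. = FALSE)
  }
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("rho undefined for a constant vector", call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (exact) {
    if (n > 10) stop("exact enumeration limited to n <= 10", call. = FALSE)
    perms <- permute_all(n)
    null_rho <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
    p_value <- mean(abs(null_rho) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p_value <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p_value = p_value, n = n, method = method)
}

# All permutations of 1..n (n small).
permute_all <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- permute_all(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (i in seq_len(nrow(sub))) {
    for (pos in seq_len(n)) {
      out[row, ] <- append(sub[i, ], n, after = pos - 1L)
      row <- row + 1L
    }
  }
  out
}

#' Per-plot diversity summaries
#'
#' Richness, Shannon index, Pielou evenness and stem count for each census.
#'
#' @param censuses List of `plot_census` objects (one per plot).
#' @return Data frame with columns `plot_code`, `richness`, `shannon`,
#'   `evenness`, `stems`.
#' @export
diversity_table <- function(censuses) {
  mat <- build_abundance_matrix(censuses)
  data.frame(
    plot_code = rownames(mat),
    richness = apply(mat, 1, function(r) sum(r > 0)),
    shannon = apply(mat, 1, shannon),
    evenness = apply(mat, 1, pielou_evenness),
    stems = rowSums(mat),
    stringsAsFactors = FALSE, row.names = NULL
  )
}
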