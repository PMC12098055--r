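---
title: "Methods: diversity, composition, structure and dynamics of permanent forest plots"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, composition, structure and dynamics of permanent forest plots}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestcensus)
```

## The data model

Permanent forest dynamics plots enumerate every self-supporting woody stem
at or above a diameter threshold — 10 cm DBH by convention, measured at
1.3 m or above trunk irregularities (the point of measurement, POM). Each
stem carries a permanent tag, a species or morphospecies determination,
plot-local coordinates, and condition scores for liana infestation (0–4),
sun exposure (1–5) and crown damage (0–4). Re-censusing the same plot years
later and matching stems by tag decomposes the interval into survivors,
deaths and recruits (stems that crossed the threshold between censuses).

`read_census_csv()` reads a fixed CSV dialect (UTF-8, comma-separated,
columns `tag, species, family, subplot, x_m, y_m, dbh_cm, pom_m, height_m,
liana, exposure, crown_damage, status`), rejects living rows below the
threshold with a per-row report, and aborts on structural errors (duplicate
tags, out-of-range scores). `link_censuses()` produces the tag-matched
decomposition; its invariants `n0 = ns + deaths` and
`stems2 = ns + nr` hold by construction and are asserted across the test
suite. The census interval defaults to the date difference in days/365.25,
with an explicit override because published interval summaries are often
stated against whole-year intervals.

## Alpha diversity and rarefaction

Per plot we compute richness `S`, the Shannon index
`H = -Σ p_i ln p_i` (natural log, nats), and Pielou evenness `J = H / ln S`.
The natural-log convention is pinned by internal consistency of the
packaged regional table: its evenness column is recovered from its `H` and
`S` columns by `H / ln S` to within one unit in the third decimal (the
printed inputs are themselves rounded, so exact three-decimal agreement is
not attainable from the table alone).

Richness comparisons across plots with different stem counts use analytic
rarefaction: the expected richness of a uniform without-replacement
subsample of `n` stems,

    E[S_n] = Σ_i (1 − C(N − N_i, n) / C(N, n)),

evaluated on a five-stem grid up to the full count. We use the expectation
rather than a single random subsample because it is deterministic and is, by
definition, the mean of the resampling distribution — the test suite checks
agreement with a 10,000-draw Monte Carlo mean to within 0.05 species.
Binomial ratios are computed on the log scale (`lchoose`) to avoid overflow
at realistic stem counts. The curve is non-decreasing and concave in `n`,
which the property tests assert on random abundance vectors.

Rank correlations between precipitation and the diversity metrics use
Spearman's rho on midranks, with the two-sided t-approximation
`t = rho sqrt((n−2)/(1−rho²))` for the p-value (an exact enumeration is
available for n ≤ 10). This matches the convention of base R's
`cor.test(..., exact = FALSE)`, which is what readers of regional plot
papers will have used.

## Composition: Bray–Curtis, NMDS, clustering, Mantel

Compositional analyses start from the plots-by-species abundance matrix of
living stems (`build_abundance_matrix()`), with no abundance
pre-transformation by default: dissimilarity is
`BC(x, y) = Σ|x_i − y_i| / Σ(x_i + y_i)`. Morphospecies are kept as
distinct labels; a flag can exclude indeterminate taxa.

`nmds()` is a full implementation of nonmetric multidimensional scaling
minimizing Kruskal stress-1,

    stress = sqrt( Σ (d_ij − θ_ij)² / Σ d_ij² ),

where `d` are configuration distances and `θ` the monotone regression of
`d` on the rank order of the input dissimilarities. Each iteration fits `θ`
by pool-adjacent-violators (via `stats::isoreg` after sorting; ties in the
dissimilarities are treated as *primary* — tied values are sub-ordered by
the current configuration distances, so they may fit freely among
themselves) and then moves the configuration by a Guttman transform with
`θ` as the target distances. A safeguard rejects any step that would
increase stress-1, so the per-iteration stress trace is non-increasing by
construction; convergence is declared when the improvement falls below
`tol` (default 1e-7). Each call runs one metric-MDS-seeded start
(`stats::cmdscale`) plus `n_starts` random Gaussian starts and keeps the
best; all randomness flows from the `seed` argument, so repeated calls are
bit-identical. Degenerate inputs are handled explicitly: an exactly
embeddable configuration (e.g., three equidistant points in the plane)
terminates at stress ~0 from the metric seed, and a rank-deficient metric
solution is padded with tiny noise before iteration. One behaviour worth
knowing: when the dissimilarities have clean group structure (every
within-group value ranking below every between-group value), the global
stress-1 minimum is a *degenerate* configuration that collapses each group
to a point and reaches stress ≈ 0 even at k = 1. This is a property of the
stress criterion itself, not an implementation artifact; strongly
habitat-structured communities will trigger it, and the stress-versus-k
table from `select_dimensions()` makes it visible (near-zero stress at
every k).

`select_dimensions()` repeats this over k = 1..10 and returns the smallest
dimensionality whose best stress is at or below 0.1, together with the full
stress-versus-k table; when nothing qualifies it falls back to the first
k below 0.2 and flags the result. The default of 100 starts per k keeps a
21-plot ordination interactive while remaining configurable upward (the
published workflow this mirrors used 1000 trials; whether those were per k
or in total is not stated, so the trial count is simply a parameter).

Clustering of the same dissimilarities is UPGMA (average linkage) via
`stats::hclust`, exported to Newick through `ape`; UPGMA is a documented
choice — average linkage is the common default for compositional
dendrograms, but other linkages would change the tree. Mantel tests
correlate the Bray–Curtis matrix with great-circle distance (haversine,
Earth radius 6371 km) and with pairwise precipitation differences, using
Pearson correlation of the upper triangles and a one-tailed (greater)
permutation p-value, `p = (1 + #{r_perm ≥ r_obs}) / (n_perm + 1)`, with 999
permutations by default. The test suite checks the statistic against a
naive double-loop oracle and vegan, and checks the null p-value
distribution for uniformity.

## Indicator species and importance values

`indval_analysis()` implements IndVal for habitat groups. For species `i`
and group `g`, specificity `A` is the group-equalized form — mean abundance
in `g` divided by the sum of the per-group mean abundances — so unequal
numbers of floodplain and terra firme plots do not bias `A`; fidelity `B`
is the fraction of `g`'s plots occupied, and the statistic is
`sqrt(A·B)` for the best group. The raw (summed-abundance) variant is
available via `equalize = FALSE`. Significance comes from permuting
plot-to-group labels; for small plot sets an exhaustive enumeration over
all distinct assignments replaces sampling, and the permutation p is tested
against that enumeration. No multiple-testing correction is applied, by
design: per-species face-value p-values are the convention in the
indicator-species literature this follows, and the type-I behaviour under
null labels is checked explicitly (~5% of species at p ≤ 0.05).

Importance value indices pool stems by habitat:
`IVI = (relative density + relative basal area) / 2`, with basal area
`(π/4)·DBH²` in cm². Within each habitat the three relative columns each
sum to 1.

## Structure, biomass and demography

Wood density resolves hierarchically — species match, then genus mean, then
family mean, then the global table mean — with the resolution level
reported per stem. Heights, where not field-measured, come from a
height–diameter model; the default is the log-log quadratic
`ln H = a + b ln D + c (ln D)²` with coefficients
`(0.893, 0.760, −0.0340)`, a pantropical-style parameterization appropriate
for lowland moist forest; Weibull and Michaelis–Menten forms can be fit to
any census with measured heights (log-scale least squares, or
Levenberg–Marquardt via minpack.lm). Per-tree biomass uses the moist-forest
power law `AGB = 0.0673 (ρ D² H)^0.976` kg with the coefficients exposed as
arguments, because published totals depend on the exact coefficient set and
height model used; plot totals are sums in metric tons, and annualized
change is the census difference divided by the interval.

Interval demography follows the log-count definitions: annual mortality
`λ = (ln N₀ − ln N_s)/t × 100`, annual recruitment
`μ = (ln(N_s + N_r) − ln N_s)/t × 100`, and stem turnover as their mean.
With constant annual survival `1 − m`, `λ` estimates `−ln(1 − m) × 100`,
which is what the simulation-based recovery test asserts. One published
worked example prints a turnover of 2.23 %/yr alongside λ = 1.36 and
μ = 3.31; the mean of those two values is 2.34, and no admissible interval
choice reconciles the printed turnover with the stated definition, so this
package follows the definition and reports 2.34 for those inputs.

## The synthetic census generator

`generate_region()` exists so that every estimator in the package can be
exercised against known ground truth without access to restricted plot
databases. It emulates: a regional pool with log-series abundances
(`P(N=n) ∝ x^n/n`, default x = 0.99; lognormal optional); per-species
floodplain affinity from a logit-normal (sd 2 by default, giving strong but
not absolute habitat structuring; `habitat_exclusive = TRUE` makes the two
pools strictly disjoint); Weibull(1.1, 20) diameters left-truncated at
10 cm, giving a mean diameter near 21–22 cm as observed in regional plots;
species wood densities from a truncated Normal(0.6, 0.1) on (0.1, 1.2)
g/cm³; constant-hazard mortality (default m = 0.02/yr, matching regional
mortality rates of 1.4–3.1 %/yr) applied as interval survival `(1−m)^t`;
lognormal diameter growth; Poisson recruitment influx (default 12 stems
ha⁻¹ yr⁻¹) entering at Uniform(10, 12) cm, a choice made here because field
protocols record recruits only once they cross the threshold; and a linear
precipitation gradient spanning 1686–3292 mm, the range of the packaged
regional table. Defaults of 21 plots × ~550 stems and a 3-year interval
mirror the regional study design. Mortality is size-independent by default;
real stem mortality is U-shaped in size, gap-phase dynamics, spatial
clustering and drought pulses are all absent, so passing parameter-recovery
tests demonstrates estimator correctness under the stated model, not
realism of the generator.

All randomness is R's default Mersenne-Twister under an explicit integer
seed stored in the configuration; identical seeds give identical regions.

## Problem sizes and numerical choices

The shipped test suite runs simulations sized for a desk check: regions of
1–6 plots with 60–500 stems, 200 replicate census pairs for the
mortality-recovery check (asserting the mean estimate within two Monte
Carlo standard errors of `−ln(0.98)·100 ≈ 2.02`), 500 Mantel simulations at
99 permutations for the null-uniformity check, and 10,000 resampling draws
for the rarefaction oracle. NMDS dimension selection in tests uses 5–10
starts per k; analyses of real data should raise `trials` (the default is
100).

Two empirical reproductions deserve caveats. First, evenness: printed
`(H, S)` pairs are rounded, so recovery of a published evenness column is
asserted to one unit in the third decimal. Second, precipitation–diversity
rank correlations recomputed from the packaged 21-plot summary table give
rho = −0.33 (Shannon), −0.52 (evenness) and 0.37 (1-ha richness); the
published analysis, computed from full-precision per-stem data that is
restricted, reports −0.28, −0.29 and 0.39. The packaged table is the only
public input, and the discrepancy — largest for evenness, whose printed
three-decimal values carry heavy ties and rounding — is documented rather
than papered over: the acceptance checks for those three correlations fail
against the published values and are expected to.

## Orchestration

`run_full_analysis()` chains every stage over a configured set of censuses
(diversity, rarefaction, rank correlations, dissimilarity, ordination with
an environmental vector, clustering, Mantel, IndVal, IVI, structure,
biomass, demography, consolidated summary), logging to stderr, writing TSV
outputs with a provenance header (package version, configuration hash,
seed), skipping dependents of failed stages, and producing byte-identical
outputs under a fixed seed. A thin command-line wrapper with one subcommand
per stage ships in `inst/cli/forestcensus.R`.
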