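---
title: "Phylogenetic relatedness and non-native fish establishment: models and design"
author: "invaphylo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic relatedness and non-native fish establishment: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invaphylo)
```

## The question

Darwin's naturalization conundrum poses two opposed predictions about which
non-native species establish. Under the naturalization hypothesis, species
*distantly* related to the resident natives succeed, because they escape
competition and shared enemies. Under the pre-adaptation hypothesis, species
*closely* related to the natives succeed, because close relatives share the
adaptations the local environment demands. For freshwater fishes the question
can be put to a global test: every river basin carries a recorded native
fauna, non-native occurrences are catalogued per basin, and a dated phylogeny
supplies distances between any focal invader and the natives it meets.

This package implements that test as a reusable pipeline: classify non-native
occurrences, measure nonnative–native relatedness, build establishment
success/failure records, and fit mixed models that ask whether relatedness
predicts establishment — together with a mediation analysis separating the
direct effects of native diversity from those routed through relatedness.

## Data model and classification

The occurrence database is two tables: records `(species, basin_id, status)`
with `status` either `native` or `nonnative`, and basin metadata
`(basin_id, country, realm, area_km2, lat, lon)`. Basins nest in exactly one
country (the primary country for shared basins), countries nest in one of the
seven biogeographical realms. Validation enforces unique `(species, basin)`
pairs, so a species can never be simultaneously native and non-native in a
basin. Species names are compared after trimming, collapsing internal
whitespace, and treating spaces and underscores as equivalent, which makes
occurrence tables and Newick tip labels interoperable.

A non-native occurrence of species *s* in basin *b* is **translocated** within
the administrative unit *U* containing *b* (country by default, realm under
the broadened scope) when *s* is also recorded native in at least one basin of
*U*; otherwise it is **exotic**. The rule is applied per unit, so one species
can be exotic in one country and translocated in its neighbor. Because
countries nest in realms, country-scope translocation implies realm-scope
translocation — an invariant the tests check on every simulated database.

## Relatedness and diversity metrics

All metrics derive from the cophenetic (patristic) distance matrix $d(i,j)$,
the sum of branch lengths on the tree path between tips. For a focal
non-native $s$ and the native set $N_b$ of basin $b$:

* nonnative–native MPD: $\frac{1}{|N_b|}\sum_{j \in N_b} d(s, j)$,
* nonnative–native MNTD: $\min_{j \in N_b} d(s, j)$.

Native community diversity per basin: richness $|N_b|$, native MPD (mean over
unordered native pairs) and native MNTD (mean distance of each native to its
nearest native neighbor). With fewer than two natives those two are undefined
and carried as `NA`, never zero; with zero natives the focal metrics are
undefined and the row is dropped before modeling. The phylogenetic covariance
matrix $C$ (shared root-to-MRCA branch length) is exposed for phylogenetic
mixed models fitted outside the package; it satisfies
$d(i,j) = C_{ii} + C_{jj} - 2C_{ij}$, which the tests verify against the
distance matrix.

## The modeling table

For each species carrying the focal label in at least one basin of a unit,
one row per candidate basin of that unit is emitted: all basins for exotics
("failures" are basins of the invaded country the species did not reach),
and all basins minus the species' native (origin) basins for translocations.
`presence` is 1 where the species is recorded non-native. Each row carries
the focal relatedness metrics, the basin's native diversity, and basin area
(entered log-transformed, since areas span orders of magnitude). Continuous
predictors are z-scored with the sample SD **per emitted table**, so global,
per-realm and per-country fits are each standardized over the rows they use
and coefficients are comparable within a fit.

Before the table is built, two cleaning rules apply: units with no non-native
record at all are removed wholesale (relatedness of invaders to natives
cannot be evaluated there), and species absent from the phylogeny are removed
(their distances are unavailable).

## Establishment model

Establishment is modeled as a Bernoulli GLMM on the link scale,

$$g(p_{sb}) = \beta_0 + \beta_1\, x_{sb} + u_s + u_c + u_{b:c},$$

with $x$ a single z-scored relatedness metric (MPD or MNTD, never both —
they are fit separately), and independent Gaussian random intercepts for
species, country, and basin nested in country (basin only, for
single-country fits). Estimation is Laplace-approximate maximum likelihood
(`lme4::glmer`); a variance component estimated on the zero boundary is
reported as a singular fit, not a convergence failure. The logit link is the
default; when successes are much rarer than failures (success fraction below
a configurable threshold, default 0.10) the asymmetric complementary log-log
link is preferred, and the decision is logged with the observed fraction.
On the synthetic study the two links agree in the sign of $\beta_1$.

Variance explained follows the Nakagawa–Schielzeth decomposition:
$R^2_m = \sigma^2_f / (\sigma^2_f + \sum\sigma^2_u + \sigma^2_d)$ and
$R^2_c$ adds $\sum\sigma^2_u$ to the numerator, where $\sigma^2_f$ is the
sample variance of the fixed-effect linear predictor and $\sigma^2_d$ is the
link-specific distribution variance, $\pi^2/3$ for logit and $\pi^2/6$ for
cloglog. With $\sigma^2_f = 1$, one random variance of 1 and the logit link
this gives $R^2_m = 1/(2 + \pi^2/3) = 0.18904$ and $R^2_c = 0.37808$ — the
closed forms the tests pin down. Collinearity among relatedness and
diversity predictors is screened with OLS-based VIFs ($1/(1-R^2_k)$), with
exact collinearity reported as an infinite VIF rather than an error.

## Mediation: direct and indirect effects

Native richness and native phylogenetic diversity can act on establishment
directly, and indirectly by changing how closely related the arriving species
is to the resident fauna. The decomposition is a piecewise structural
equation model of two component fits sharing the GLMM's random-intercept
structure:

1. Gaussian: `relatedness_z ~ richness_z + diversity_z + REs`
2. Bernoulli: `presence ~ relatedness_z + richness_z + diversity_z + REs`

All continuous variables are z-scored over the rows entering the fit; rows
with undefined native diversity (single-native basins) are dropped first and
counted. Direct effects are the paths into `presence` (latent/link scale);
the indirect effect of a predictor is the product of its path into
relatedness and the relatedness → presence path, an arithmetic identity of
the output, which the tests assert exactly. Interval estimates are Wald 95%;
for products we use the exact variance of a product of independent normals
($a^2\sigma_b^2 + b^2\sigma_a^2 + \sigma_a^2\sigma_b^2$) rather than the
first-order delta method, which we measured to be slightly anti-conservative
in the replicate studies. The Bayesian multivariate formulation of the same
path structure is deliberately out of scope: maximum-likelihood point
estimates with Wald intervals carry the identical path definitions, and the
posterior machinery is an estimation detail, not part of the path structure.

## The synthetic study

Because the deposited global database cannot be bundled, every stage is
exercised against a generator with known truth. Its defaults define the
study conditions used throughout the tests: 100 species, 3 realms × 2
countries × 8 basins, a pure-birth ultrametric tree (birth rate 1), Brownian
habitat traits ($\sigma^2_{BM} = 1$), and a Gaussian environmental filter
(width 1.5 realized trait SDs around country optima, basin jitter 0.3 SD,
baseline occupancy 0.35) assembling the native faunas. Introductions are
proposed for half the (species, country) pairs — translocated when the
species is native somewhere in the country, exotic otherwise — and each
candidate (species, basin) establishes with probability
$\mathrm{logit}^{-1}(\beta_0 + \beta_{mpd}\,\mathrm{MPD}_z +
\beta_{rich}\,\mathrm{rich}_z + u_s + u_c + u_b)$ with defaults
$\beta_0 = -1$, $\beta_{mpd} = -0.5$ (the pre-adaptation pattern),
$\beta_{rich} = 0.2$ (biotic acceptance), and random-intercept SDs
0.5/0.3/0.3. The driver metric is z-scored over the proposal set — the same
convention as the record builder — so the programmed coefficient is
recoverable on the fitted scale. Random streams are split per stage (tree,
traits, assembly, establishment), so changing one stage's parameters leaves
the other draws untouched, and a fixed seed reproduces files byte for byte.

What the generator does **not** emulate: the real database's skewed richness
geography, sampling-effort bias, propagule pressure, introduction history,
or non-equilibrium dynamics. Passing tests therefore demonstrate that the
pipeline measures what it claims and that the estimator is calibrated under
the assumed model — not that the empirical conclusions are correct for any
particular dataset.

## Calibration studies and problem sizes

The replication studies were sized for desk-scale runs while keeping the
estimator in a well-behaved regime: type-I error of the Wald test uses 200
null replicates of a 60 species × 16 basin grid; sign recovery and interval
coverage at $\beta_1 = -0.5$ use 100 replicates of 100 species × 50 basins;
mediation recovery of the programmed product $(-0.4)(-0.6) = +0.24$ uses 100
replicates of 40 species × 16 basins. In the mediation study the simulated
covariates are constructed with exactly unit sample SD and exact
orthogonality, so the programmed paths coincide exactly with the z-scale
estimands the fit reports; without this, the per-fit re-standardization makes
the estimand jitter with the realized covariate SDs and interval coverage is
not interpretable against a fixed constant.

## Numerical choices and degenerate inputs

* Sample (n−1) SD everywhere z-scores are computed; constant columns are an
  error naming the column.
* Distances are computed once into a dense matrix (trees here are far below
  the size where that matters).
* Undefined metrics are `NA` markers; the record builder drops
  relatedness-`NA` rows, the SEM drops diversity-`NA` rows with a count.
* Polytomies and zero-length branches are accepted; duplicate tips are not.
* Percentages in descriptive summaries are half-up rounded to 2 decimals.
* A response that is all-0 or all-1, or a constant predictor, is a
  pre-flight error; non-convergence of the optimizer is a flagged fit, not
  an exception.

## Known limitations

Absences conflate "introduced but failed" with "never introduced"; the
model reads them all as failures, as the record construction defines.
Translocation status is inferred from within-unit native presence, not from
introduction records. The phylogenetic covariance matrix is built but no
phylogenetically correlated random effect is fitted in-package. Realm-scope
fits on the default synthetic study are thin (few exotic records survive at
realm scale) and serve as interface demonstrations rather than calibrated
analyses.
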