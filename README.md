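# invaphylo

Does being closely related to the resident native fauna help or hinder a
non-native freshwater fish? Darwin left both answers on the table: distant
relatives might escape competition (the naturalization hypothesis), close
relatives might arrive pre-adapted to the same environments (the
pre-adaptation hypothesis). `invaphylo` is an analysis pipeline for putting
that question to species-by-basin occurrence data and a phylogeny: it
classifies non-native occurrences into **exotic** (introduced from outside a
country or realm) and **translocated** (moved between basins within one),
measures nonnative–native phylogenetic relatedness, builds establishment
success/failure records, and fits the mixed models and mediation
decomposition that test the two hypotheses. It is aimed at invasion
ecologists and macroecologists working with basin-level occurrence databases
and dated phylogenies.

## The model

For a focal non-native species *s* and the native set of basin *b*, the two
relatedness metrics are the mean and the minimum patristic distance:

- MPD(s, b) = mean over natives *j* of d(s, j)
- MNTD(s, b) = min over natives *j* of d(s, j)

Establishment (presence 1 / absence 0 of *s* across the candidate basins of
each invaded administrative unit) is modeled as a binomial GLMM,

```
g(p) = β0 + β1 · relatedness_z + u_species + u_country + u_basin:country
```

with logit link (complementary log-log when successes are rare), Wald tests
on β1, and Nakagawa–Schielzeth marginal/conditional R². Negative β1 means
closer relatives establish more readily — the pre-adaptation pattern. A
piecewise structural-equation model with the same random effects separates
the direct effects of native richness and native phylogenetic diversity on
establishment from their indirect effects routed through relatedness
(indirect = product of the two paths, reported with exact product-normal
intervals). A synthetic-data generator with programmed coefficients and
known random intercepts makes every stage testable end to end; see the
methods vignette (`vignettes/relatedness-pipeline.Rmd`) for the full model
and design account.

## Worked example

```r
library(invaphylo)

sim <- simulate_database(sim_config(seed = 1))   # synthetic global study
print(sim$db)
#> Occurrence database:
#>   basins:    48 (6 countries, 3 realms)
#>   species:   100
#>   records:   1129 native, 532 non-native

a <- classify_nonnatives(sim$db, "country")
print(a)
#> Status assignment (country scope): 1129 native, 114 exotic, 418 translocated

cl  <- clean_database(sim$db, a, sim$tree)
D   <- cophenetic_distances(sim$tree)
rec <- standardize_records(
  build_records(cl$db, classify_nonnatives(cl$db, "country"), D,
                "translocated"))
fit <- fit_occurrence_glmm(rec, "mpd_z")
print(fit)
#> Binomial mixed model (logit link), n = 1119
#>          term estimate      se      z         p
#> 1 (Intercept)  -0.5779 0.10312 -5.605 2.088e-08
#> 2       mpd_z  -0.3393 0.07536 -4.503 6.706e-06
#> Random-intercept variances:
#>          species basin_id:country          country
#>           0.0570           0.1321           0.0144
#> R2 marginal = 0.0319, conditional = 0.0883
```

The 1119 rows pair each translocated species with every basin of its country
except its native (origin) basins; presence is 1 where it established. The
negative `mpd_z` coefficient (−0.34 ± 0.08, p < 1e-5) says establishment
probability rises as the invader gets phylogenetically closer to the resident
natives — the generator's programmed β of −0.5 on this seed, attenuated by
sampling, with R² decomposing the variance between the relatedness fixed
effect (3.2%) and the random intercepts.

## The analysis workflow

The numbered drivers under `analysis/` run the full study over the synthetic
database and write their tables under `results/`:

1. `01_simulate.R` — generate the study database, tree, and ground truth.
2. `02_patterns.R` — descriptive biogeography: realm colonization
   percentages, basin richness/percentages, country tallies, most
   widespread invaders.
3. `03_relatedness_glmm.R` — the occurrence GLMMs for both groups × both
   relatedness metrics.
4. `04_mediation_sem.R` — direct/indirect effect decomposition for both
   diversity pairings.
5. `05_sensitivity.R` — realm-scale reclassification, link choice, basin
   area covariate, VIFs.

Each script is a thin narrative over the package functions; run them in
order with `Rscript analysis/01_simulate.R` etc.

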