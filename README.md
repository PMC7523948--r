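# foodwebkit

Food-web metrics and permutational multivariate statistics for staged
ecological disturbance studies.

`foodwebkit` implements the full analysis chain used in river food-web
monitoring around a large disturbance (for example a staged dam removal):
invertebrate prey availability from benthic, drift and fallout samples; fish
diet composition from stomach contents; energy budgets from body-length
regressions; and the permutational statistics that compare community
composition across river sections and years. The multivariate machinery —
PERMANOVA with Type III sums of squares and residual permutation, pairwise
pseudo-*t* comparisons, ANOSIM, SIMPER, non-metric multidimensional scaling
and Bray–Curtis resemblance — is implemented from scratch in base R and is
cross-checked against independent oracles (including `vegan`) in the test
suite.

## What the package computes

1. **Data model** (`sample_set()`, `load_tables()`, `build_matrix()`):
   long-format CSV tables (taxa, samples, observations, fish) with strict
   validation, aggregated into samples-by-taxa matrices at any taxonomic rank,
   on a count, density, energy or energy-density basis.
2. **Energetics** (`conversion_table()`, `resolve_factors()`,
   `annotate_energy()`): dry mass from the invertebrate length–mass power law
   DM = a·L^b, energy from taxon-specific energy densities, with taxonomic
   fallback (species → genus → family → order → class, exact life stage before
   stage "unknown") and documented imputation for unmeasured individuals.
3. **Sample metrics** (`sample_metrics()`, `diet_metrics()`,
   `group_summary()`, `percent_change()`, `anova_tukey()`): numeric and
   energetic density, richness, terrestrial percentage; group mean ± SD
   tables; percent declines; classical two-way ANOVA with Tukey HSD letters.
4. **Resemblance** (`transform_abundance()`, `add_dummy()`, `bray_curtis()`):
   square-root or fourth-root transformation, a dummy species so that empty
   samples stay defined, Bray–Curtis similarity on the 0–100 scale.
5. **Permutational statistics** (`permanova()`, `pairwise_permanova()`,
   `anosim()`, `simper()`): Type III partial SS via Gower-centred
   inner-product traces, Freedman–Lane permutation of reduced-model residuals,
   exhaustive enumeration when all n! relabelings fit in the permutation
   budget, pseudo-*t* pairwise tests with Bonferroni correction and a
   moment-matched Monte Carlo fallback for tiny groups.
6. **Ordination** (`nmds()`, `centroid_matrix()`, `centroid_trajectory()`):
   Kruskal stress-1 nMDS by isotonic regression + Guttman majorisation with
   multistart, and centroid trajectories in principal-coordinate space.
7. **Prey selectivity** (`iri()`, `selectivity_coords()`,
   `classify_selection()`): an energy-based Index of Relative Importance,
   IRI = F·(N + J), normalised to %IRI per group, with log–log diet-vs-
   availability coordinates and 1:1-line classification.
8. **Synthetic data + pipeline** (`sim_params()`, `simulate_community()`,
   `simulate_diets()`, `run_pipeline()`): a generator with known ground truth
   (imposed declines, taxon losses, selectivity weights) and a deterministic
   end-to-end pipeline that reproduces the whole analysis sequence.

## Worked example

Simulate a two-section, three-period drift study with an imposed 96% decline
in section LE in 2013, then run the analysis chain:

```r
library(foodwebkit)

p   <- sim_params(sections = c("LE", "TR"), periods = c("Pre", "2012", "2013"),
                  n_samples = c(LE = 6, TR = 5), seed = 42)
com <- simulate_diets(simulate_community(p))
x   <- annotate_energy(com$data, com$conversions)

sm  <- sample_metrics(x)
env <- sm[sm$gear != "diet", ]
group_summary(env$numeric_density, env[c("section", "period")])
#>   section period n  mean     sd
#> 1      LE   2012 6 1.275 0.1781
#> 2      LE   2013 6 0.286 0.0722
#> 3      LE    Pre 6 5.462 0.3181
#> 4      TR   2012 5 5.726 0.5654
#> 5      TR   2013 5 5.754 0.2041
#> 6      TR    Pre 5 5.727 0.0532

percent_change(5.462, 0.286, digits = 0)   # LE, Pre -> 2013
#> [1] 95
```

The imposed 96% decline is recovered at 95% from 6 samples per cell, and the
reference section TR stays flat. Composition testing:

```r
mat <- build_matrix(x, basis = "count_density", rank = "family", gear = "drift")
m   <- transform_abundance(add_dummy(mat$abund), "sqrt")
bc  <- bray_curtis(m, as = "dissimilarity")

permanova(bc, mat$meta, ~ period * section, n_perm = 999, seed = 1)
#> PERMANOVA (Type III SS, residual permutation under reduced model)
#> design: ~period * section   n = 33  [999 permutations]
#>            term df       SS   ECV perm pseudo_F     P
#>          period  2  5897.92 16.01  999    23.06 0.001
#>         section  1  8158.70 22.06  999    63.81 0.001
#>  period:section  2  5659.92 22.17  999    22.13 0.001
#>        Residual 27  3452.41 11.31   NA       NA    NA
#>           Total 32 24314.20    NA   NA       NA    NA

pairwise_permanova(bc, mat$meta$period, n_perm = 999, seed = 2)
#> Pairwise PERMANOVA (Bonferroni-adjusted alpha = 0.0167 ; Monte Carlo P flagged)
#>  group1 group2 df   perm pseudo_t     P monte_carlo adjusted_alpha significant
#>    2012   2013 20 705432    1.643 0.076       FALSE        0.01667       FALSE
#>    2012    Pre 20 705432    3.103 0.008       FALSE        0.01667        TRUE
#>    2013    Pre 20 705432    3.051 0.006       FALSE        0.01667        TRUE
```

Which taxa drive the Pre-vs-2013 dissimilarity, and how well does a 2-D
ordination represent it?

```r
sel <- mat$meta$period %in% c("Pre", "2013")
simper(m[sel, ], mat$meta$period[sel])
#> SIMPER Pre vs 2013: average dissimilarity 37.68 (cutoff 2)
#>               taxon mean_Pre mean_2013 contribution contribution_pct ...
#>  EphemeropteraidaeA   1.3011    0.7188        7.271           19.295
#>     ColeopteraidaeB   1.1020    0.6570        5.590           14.834
#>     PlecopteraidaeB   1.0149    0.5682        5.397           14.323
#>  ...

nmds(bc, k = 2, restarts = 10, seed = 3)
#> nMDS: 33 points in 2 dimensions, stress-1 = 0.02182
```

Prey selectivity from the paired environment/diet %IRI tables:

```r
co <- classify_selection(selectivity_coords(iri(x, "environment"),
                                            iri(x, "diet")))
head(co[c("section", "period", "taxon", "x", "y", "selection")])
```

Orders above the 1:1 line (`y > x`) are selected, below it avoided;
percentages under 0.1% are pinned at −2.

The same sequence runs as one deterministic call:

```r
res <- run_pipeline(run_config(sim = p, n_perm = 999, seed = 42))
res$declines      # headline percent declines vs the baseline period
res$permanova     # main test
res$selection     # selectivity classification
```

## Testing

```r
testthat::test_dir("tests/testthat", package = "foodwebkit",
                   load_package = "installed")
```

The suite (~2000 assertions) checks every module against independent
brute-force oracles (distance-sum pseudo-F, exhaustive permutation
enumeration, rank-bookkeeping ANOSIM, per-pair SIMPER tallies, exhaustive-scan
conversion lookup) and against `vegan` where an external reference exists.
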