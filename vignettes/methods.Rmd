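---
title: "Methods: energy-based food-web metrics and permutational statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: energy-based food-web metrics and permutational statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodwebkit)
```

This vignette documents the statistical model behind each `foodwebkit`
routine, the numerical choices made in the implementation, the scope of the
synthetic-data generator, and the known limitations. It states no empirical
results beyond what the code in this document computes.

## 1. Data model

Input data are four long-format CSV tables (UTF-8, comma-separated, header
row, empty string for missing): a taxon catalog with a five-rank path
(class–species, trailing ranks may be empty), sample metadata (section,
season, period, habitat, gear, effort), per-taxon observations (counts plus
optional semicolon-separated body measurements in mm) and optional fish
records for diet samples. `sample_set()` enforces referential integrity,
controlled vocabularies, positive effort in the gear's unit (m² for benthic
and fallout, m³ for drift, per-fish for diets), and the invariant that
measurements never exceed counts.

`build_matrix()` aggregates observations to a samples-by-taxa matrix at a
chosen rank. Taxa identified only at a coarser rank than requested are kept
as their own column under their finest label and flagged, rather than
discarded or double-counted. Density bases divide by effort; energy density
is reported as kJ/m² for areal gears and J/m³ for drift.

## 2. Energetics

Dry mass of a measured individual follows the invertebrate length–mass power
law DM = a·L^b (mg; L in mm). Energy is DM × ED with ED in J per mg dry mass,
or wet mass × ED (wet mass = DM / pDM) when a table entry declares
`ed_basis = "wet"`. Conversion entries are keyed by a rank-path prefix plus a
life stage; `resolve_factors()` returns the deepest matching prefix,
preferring the exact life stage over stage `"unknown"` at each depth, and
resolves the mass regression and the energy factor independently. The lookup
is order-independent: tables are canonically sorted at construction.

Unmeasured individuals are imputed in a fixed order: mean per-individual
energy of measured conspecifics in the same sample, else the taxon mean
across all samples, else the order mean, else the table's `default_joules`.
If none applies, `annotate_energy()` errors naming the taxon; silent zeros
are never produced.

## 3. Univariate metrics

`sample_metrics()` reports numeric density, energy density, richness at the
finest identified level and the terrestrial percentage (count or energy
basis); zero-total samples are flagged and get a terrestrial share of 0.
`percent_change(pre, during)` is 100·(1 − during/pre), undefined (error) for
a non-positive baseline. `anova_tukey()` wraps `stats::aov` and
`stats::TukeyHSD` — a deliberately standard step — with optional log10(x + c)
or arcsine-square-root transformations and a compact letter display computed
by insert-and-absorb merging.

## 4. Bray–Curtis resemblance

Similarity between samples i and j is 100·(1 − Σ|x_i − x_j| / Σ(x_i + x_j)),
on the 0–100 scale. Abundances are usually square-root (drift convention) or
fourth-root transformed first to balance common and rare taxa. A pair of
all-zero samples is undefined; the standard remedy implemented by
`add_dummy()` is a constant dummy species (default 0.1) added to the raw
abundances before transformation, which makes empty samples identical
(similarity 100) rather than undefined. `bray_curtis()` errors on undefined
pairs instead of guessing.

```{r bray-hand}
# hand-checkable example: sum|diff| = 2, sum = 12
bray_curtis(rbind(a = c(1, 2, 3), b = c(2, 2, 2)))["a", "b"]
```

## 5. PERMANOVA

Let D be the n×n dissimilarity matrix, A = −½D², and G = JAJ with
J = I − 11'/n (Gower centring). For the hat matrix H of any design matrix,
tr(HG) is the sum of squares explained by that design; the total SS is
tr(G). `permanova()` fits one-way or two-way crossed fixed-effect designs
with sum-to-zero contrasts and reports **Type III** partial SS: for each
term, SS_term = tr(H_full G) − tr(H_reduced G) where the reduced model omits
only that term. The pseudo-F is (SS_term/df_term)/(SS_res/df_res).

Significance uses **permutation of residuals under the reduced model**
(Freedman–Lane): with H_r the reduced-model hat matrix and R_r = I − H_r,
each permutation applies M = H_r + P R_r to both sides of G and recomputes
the statistic. The reported P value includes the observed statistic,
P = (b + 1)/(m + 1), with ties (|F* − F| within 1e-12) counted as
exceedances. When n! is no larger than the permutation budget, all
relabelings are enumerated and P = mean(F* ≥ F) is exact. A residual SS
within 1e-8·SS_total of zero is clamped to zero so that perfectly separated
groups yield F = +Inf rather than a sign-flipped statistic; genuinely
negative residual SS (possible for semi-metric measures) is left untouched.

The ECV column is the signed square root of the estimated component of
variation (MS_term − MS_res)/q, with q = n divided by the term's number of
level combinations; negative components are reported as negative roots
rather than truncated, matching how such tables are conventionally printed.

`pairwise_permanova()` runs all two-group tests, reporting the signed root
pseudo-t = sign(F)·√|F| (negative pseudo-F can arise under the null for
semi-metric measures).
The number of distinct relabelings of a pair is choose(n1+n2, n1); when that
is small enough the distribution is enumerated exactly. With fewer than 40
distinct relabelings the permutation distribution is too coarse for
inference, and a Monte Carlo P value is reported instead (flagged): a gamma
distribution is moment-matched to the permutation F distribution and its
upper tail integrated. Significance is judged against a Bonferroni-adjusted
level, alpha divided by the number of comparisons.

```{r permanova-euclid}
# one-way PERMANOVA on Euclidean distances of univariate data is classical ANOVA
set.seed(1)
g <- rep(c("a", "b", "c"), each = 5)
y <- rnorm(15) + ifelse(g == "a", 1, 0)
fit <- permanova(as.matrix(dist(y)), data.frame(g = g), ~ g,
                 n_perm = 999, seed = 2)
c(pseudo_F = fit$aov.tab$pseudo_F[1],
  anova_F = anova(aov(y ~ g))$`F value`[1])
```

## 6. ANOSIM and SIMPER

ANOSIM ranks all n(n−1)/2 dissimilarities (mid-ranks for ties) and computes
R = (mean between-group rank − mean within-group rank)/(M/2), M = n(n−1)/2,
so R ∈ [−1, 1] and R = 1 means every between-group dissimilarity exceeds
every within-group one. Significance is by label permutation with the
observed statistic included in the count.

SIMPER decomposes the average between-group Bray–Curtis dissimilarity: taxon
j contributes the mean over between-group pairs of 100·|x1j − x2j| /
Σk(x1k + x2k). Contributions sum exactly to the average between-group
dissimilarity; taxa above a cutoff (default 2 percentage points) are flagged
for reporting.

## 7. Non-metric multidimensional scaling

`nmds()` minimises Kruskal stress-1, √(Σ(d − d̂)²/Σd²), where d are
configuration distances and d̂ the isotonic regression of d on the rank
order of the input dissimilarities (primary tie treatment: tied
dissimilarities may untie). Each iteration alternates `stats::isoreg` with a
Guttman majorisation update, which cannot increase stress. The best of
several starts is kept — the first start is the metric principal-coordinate
solution, the rest random — and the final configuration is centred, rotated
to principal axes and sign-fixed, so results are reproducible for a given
seed. Two-dimensional solutions with stress above 0.2 are flagged as
untrustworthy by the print method.

## 8. Index of Relative Importance and selectivity

For each group (default section × season × period) and invertebrate order:
F is the percentage of sampling units containing the order (environmental
samples, or individual stomachs for diets, empty stomachs excluded from the
denominator by default); N its percentage of total individuals; J its
percentage of total joules. IRI = F·(N + J), normalised so %IRI sums to 100
within each group; a single order therefore scores IRI = 100·(100 + 100) =
20000 and %IRI = 100. J replaces the volumetric term of the classic index —
an energetic rather than volumetric weighting.

`selectivity_coords()` pairs the environment and diet tables per group and
returns x = log10(environmental %IRI), y = log10(diet %IRI), so 100% maps to
+2. Percentages below 0.1% (including diet absences) are pinned to the fixed
display value −2, below every unclamped coordinate. Orders found in diets
but absent from the environmental samples are excluded, since their
selectivity is not estimable from availability. `classify_selection()` calls
orders above the 1:1 line selected and below it avoided.

## 9. Synthetic data generator: scope

`simulate_community()` draws per-taxon baseline densities from a log-normal
(default meanlog = log 0.2, sdlog = 1, individuals/m³), scales terrestrial
taxa by `terrestrial_baseline_factor` (default 0.08, making terrestrial
inputs a small share of baseline drift), applies per-section × period
multiplicative disturbance factors to aquatic taxa and enrichment factors to
terrestrial taxa, optionally removes aquatic taxa with `taxon_loss_prob`,
and generates Poisson(effort × density) counts with log-normal body lengths.
`simulate_diets()` gives each fish a negative-binomial stomach total
(default size 2, mean 15), an empty stomach with probability 0.05, and a
multinomial prey composition proportional to availability × per-order
selectivity weight. Ground truth (baseline densities, factors, lost taxa,
weights) is always returned, so recovery tests never re-derive it. The same
seed reproduces the data bit for bit.

The generator is deliberately phenomenological: Poisson sampling around
log-normal baselines and multinomial feeding are the minimal structures the
analysis assumes. It does not model sediment transport, hydrology, temporal
autocorrelation within a period, or fish growth.

## 10. Pipeline

`run_pipeline()` executes the standard sequence on ingested or simulated
data: energy annotation; univariate metric tables with ANOVA/Tukey; headline
percent declines against the baseline period; dummy species, transformation
and Bray–Curtis; PERMANOVA main test and Bonferroni-corrected pairwise
comparisons; an ANOSIM age-class pooling check when fish are present; SIMPER
between the baseline and each later period; nMDS and centroid trajectories;
and environment/diet %IRI with selectivity classification and per-event
diet–availability overlap. Seeds and permutation counts are recorded in
`$log`; outputs are pure functions of (inputs, config).

```{r pipeline, eval = FALSE}
p <- sim_params(sections = c("LE", "TR"), periods = c("Pre", "2012", "2013"),
                n_samples = c(LE = 6, TR = 5), seed = 42)
res <- run_pipeline(run_config(sim = p, n_perm = 999, seed = 42))
res$declines
```

## 11. Limitations

* Designs are limited to one-way and two-way crossed fixed effects; no
  nesting, no random factors, no covariates, no repeated-measures structure.
* Type III tests assume the cell layout is estimable; aliased designs error.
* The Monte Carlo fallback for tiny groups is an approximation (gamma moment
  matching); its accuracy degrades in the extreme tail.
* The ECV expected-mean-squares coefficient uses the average cell size for
  unbalanced designs.
* nMDS is a local optimiser; multistart reduces but cannot eliminate the
  chance of a local minimum, and stress comparisons across k assume
  comparable convergence.
* Bray–Curtis is semi-metric: principal-coordinate embeddings can have
  negative eigenvalues, and squared centroid distances are truncated at zero
  when numerically negative.
* The simulator's defaults describe one study shape; they are starting
  points, not estimates fitted to any particular dataset.
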