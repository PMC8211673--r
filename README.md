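# gutdrift

Year-to-year stability analysis of gut microbiota compositions.

Population studies of the elderly gut microbiome find that most people's
family-level composition is stable from one year to the next, while a
minority (~9%) undergo a wholesale replacement of their predominant
bacterial families. `gutdrift` is an R package for quantifying and
testing that phenomenon in longitudinal cohorts where each subject
contributes one fecal sample per year for two or three consecutive
years. It is aimed at microbiome epidemiologists working from
family-level relative-abundance tables (the output of standard 16S
pipelines); no sequence processing is included or required.

## What it computes

**Distances.** The dissimilarity between two samples *a*, *b* with
family abundance distributions *P<sub>a</sub>*, *P<sub>b</sub>* is the
Jensen-Shannon distance

> JSD(a, b) = sqrt( JSd(P<sub>a</sub>, P<sub>b</sub>) ),
> JSd = ½ KLD(x, m) + ½ KLD(y, m), m = (x + y)/2,
> KLD(x, y) = Σ<sub>i</sub> x<sub>i</sub> log(x<sub>i</sub>/y<sub>i</sub>)

with natural logarithms, after adding a pseudocount of 1e-7 to every
entry and renormalizing (so zero abundances are safe). JSD is a metric
bounded by sqrt(ln 2) ≈ 0.833. Bray-Curtis dissimilarity
(1 − 2Σmin/Σ(a+b)) is available in parallel.

**Stability classification.** Distances between the same subject's
samples in consecutive years (intra-individual) are compared with
distances between different subjects in the same year
(inter-individual). A subject whose intra-individual JSD is **≥ 0.4**
— roughly the median inter-individual JSD, i.e. "as different from
their former self as from another person" — is classed as having
undergone a substantial change. Over three yearly waves the package
types each subject as `stable_both`, `transient`,
`continuous_reverted` (changed twice but back near the starting
composition) or `continuous_progressive`.

**Statistics.** The battery used around that classification:
Fisher's exact test (probability-summation two-sided p) and Pearson
chi-square on 2×2 tables, Steel's many-to-one rank test (max-T
permutation variant), covariate-adjusted group comparison
(OLS/ANCOVA), Levene's dispersion test, Spearman rank correlation,
and a distance-matrix PERMANOVA — all returning a common result object
with broom-style `tidy()`/`glance()` methods.

**Synthetic cohorts.** A calibrated logistic-normal generator
(`simulation_config()`, `generate_cohort()`) emulates the study
design: 218 subjects, 15 families, rare predominant-family replacement
events whose odds depend on a fermented-milk-intake covariate
(< 3 vs ≥ 3 days/week), and drift everywhere else. The frozen defaults
reproduce the field-reported medians (intra ≈ 0.205, inter ≈ 0.401),
so every pipeline stage is testable without any data download.

## Worked example

```r
library(gutdrift)

cohort <- generate_cohort(calibrate_defaults(seed = 1))
#> <gut_cohort> 436 samples, 218 subjects, 15 families, waves 1/2

intra <- intra_individual(cohort, year_pair = c(1, 2), metric = "jsd")
inter <- inter_individual(cohort, year = 1, metric = "jsd")
median(intra$distance)   # 0.209  — typical within-subject yearly change
median(inter$distance)   # 0.407  — typical between-subject difference
derive_threshold(inter)  # 0.407  — data-derived analogue of the 0.4 cut

cl <- classify_stability(intra, threshold = 0.4)
attr(cl, "counts")       # stable 198, changed 20 (prevalence 9.2%)

md  <- subset(cohort$metadata, year_index == 1)
grp <- md$intake_group_10y[match(intra$subject_id, md$subject_id)]
tab <- table(factor(grp, c("lt3", "ge3")),
             factor(cl$class, c("changed", "stable")))
fisher_exact(tab)
#> Fisher's exact test (two-sided, probability summation)
#> statistic = 7.6809, p-value = 0.01798
```

The intra median (0.209) being about half the inter median (0.407)
says a person resembles their year-ago self far more than they
resemble anyone else; the 20/218 subjects above the 0.4 line are the
ones whose composition changed as much as a between-person difference,
and the Fisher test shows that change is rarer in the frequent-intake
(`ge3`) group — 1/58 vs 19/160 here.

With a three-wave cohort (`simulation_config(n_years = 3)`),
`stability_report()` adds the persistence typology and its 2×2
first-interval × second-interval contingency table, and
`autoplot()` / `plot_distance_comparison()` / `plot_family_deltas()`
draw the standard figures.

`reproduce_reference_checks()` re-runs the worked examples embedded in the
package (the 2×2 tables and count breakdowns above) through the
package's own routines and prints one PASS/FAIL line per check.

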