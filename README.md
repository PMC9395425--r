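# rpgrowth

Tools for relating a long-period dental biorhythm — the **Retzius
periodicity (RP)** recorded in primary-molar enamel — to longitudinal
adolescent growth. The package is aimed at biological anthropologists and
growth researchers who have (a) enamel histology measurements from
naturally exfoliated primary molars and (b) roughly monthly anthropometry
(height, lower-leg length, weight) for the same children, and who want a
reproducible route from those raw tables to the full suite of association
analyses.

## What it computes

**RP estimation.** Retzius lines are long-period incremental markings in
enamel; the number of daily cross striations between adjacent lines is the
periodicity in days (human range ~5–12, mode near 7). Two standard
estimators are provided: direct counting of cross striations along a prism,
and the daily-secretion-rate (DSR) ratio method, where the mean prism length
spanning six cross striations (= 5 days of secretion) gives a grand-mean DSR
in µm/day, and the width of one Retzius repeat interval divided by the DSR
gives the periodicity. A participant enters analysis only when two
independent estimates agree exactly (from two molars, or two fields of one
molar).

**Growth modelling.** Each child's height (or lower-leg-length) series is
smoothed by fixed-bandwidth tricube-kernel-weighted robust local cubic
regression; the velocity curve is the analytic derivative of the local
polynomial. From the velocity curve's shape each child receives one of four
maturity stages: 1 *pre* (before the pre-spurt minimum velocity), 2 *early*
(past the minimum, not near peak), 3 *peak* (at or just past peak height
velocity), 4 *late* (clearly past peak, approaching the adult asymptote).

**Anthropometry.** BMI, LMS-based BMI-for-age z-scores and percentiles
(z = ((x/M)^L − 1)/(L·S), percentile = Φ(z)·100), obesity classification at
the 95th percentile, window gains with a standardised months-of-30.4375-days
rate, average weights, and Southern-Hemisphere season plus Covid-19 lockdown
period labels.

**Statistics.** Quadratic (curvilinear) regression of log10 gains on
log10 RP with the fitted optimum −β1/(2β2); Kruskal–Wallis H with Dunn
post-hoc pairwise z-tests (Bonferroni-adjusted); Pearson and partial
correlation; pooled/Welch t-tests; 2×2 chi-square with relative risk and
odds ratio; standardised betas; Tukey-fence outlier flags; Bonferroni
family-wise thresholds.

**Synthetic cohort.** `simulate_cohort()` generates a 61-child cohort
(34 F / 27 M, starting age 10.33 ± 0.57 y) with Preece–Baines model-1
height curves, monthly visits from September 2019 to October 2020 with a
January holiday and an autumn 2020 lockdown gap, sex-specific integer RPs on
5–10 days, and an expected 14-month weight gain that is quadratic in
log10 RP with its optimum at 7.6 days — together with the matching enamel
histology fields and a ground-truth table for validation.

## Worked example

```r
library(rpgrowth)

sim  <- simulate_cohort(sim_config(seed = 42))
hist <- simulate_cohort_histology(sim$truth, sim$config)
rep  <- run_pipeline(sim$cohort, hist,
                     synthetic_lms_reference("bmi"),
                     synthetic_lms_reference("height"))

rep$descriptive[, c("group", "n", "rp_mode", "rp_mean", "weight_gain_mean")]
#> # A tibble: 3 × 5
#>   group      n rp_mode rp_mean weight_gain_mean
#>   <chr>  <int>   <int>   <dbl>            <dbl>
#> 1 all       61       6    7.23             6.08
#> 2 female    34       8    7.82             7.46
#> 3 male      27       6    6.48             4.34

rep$quadratic_fits$gains[3, c("analysis", "b2", "r2", "p", "vertex_rp")]
#> # A tibble: 1 × 5
#>   analysis     b2    r2           p vertex_rp
#>   <chr>     <dbl> <dbl>       <dbl>     <dbl>
#> 1 gain_14mo -27.7 0.520 0.000000290      7.68
```

The negative quadratic coefficient with the fitted optimum near 7.7 days
says the simulated cohort reproduces the curvilinear pattern the package is
built to detect: children with a 5–6-day periodicity gain the least weight
over 14 months, those near 7–8 days the most. The female RP mode of 8 vs
the male mode of 6 days mirrors the emulated sex difference.

File-based workflows use `read_cohort()`, `read_histology()` and
`read_lms()`; `write_report()` serialises the full report to JSON and
`report_to_tables()` renders the headline tables as text. The shipped LMS
tables (`inst/extdata/*_synthetic.csv`) are synthetic stand-ins — swap in a
national reference CSV with the same `sex,age_years,L,M,S` layout for real
analyses.

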