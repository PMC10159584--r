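# mitodiv

What determines how much mitochondrial genetic variation a species
carries? `mitodiv` is an R package for comparative analyses of
within-species mitochondrial diversity: it estimates synonymous and
nonsynonymous nucleotide diversity (π<sub>S</sub>, π<sub>N</sub>,
π<sub>N</sub>/π<sub>S</sub>) from in-frame codon alignments, tests
phylogenetic signal, and relates diversity to life-history and
demographic variables with phylogenetically independent contrasts —
including a population-substructure control based on the generalized
mixed Yule–coalescent (GMYC) model. It is written for datasets of the
kind compiled for birds: hundreds of species, 2–400+ sequenced
individuals each, a dated species phylogeny, and a species-level trait
table.

## The statistics at the core

* **Diversity.** Nei–Gojobori (1986) counting under the vertebrate
  mitochondrial code: per-codon synonymous/nonsynonymous site fractions
  (stop changes excluded position-wise), pathway-averaged difference
  counts, pairwise deletion at codon granularity, and π as the
  unweighted mean of pair-level proportions — uncorrected, as
  within-species mitochondrial divergence is far too small for
  multiple-hit corrections to matter.
* **Phylogenetic signal.** Pagel's λ by maximum likelihood (profile
  Brownian likelihood with the off-diagonal covariance scaled by λ),
  with a boundary-corrected LRT and an optional permutation test.
* **Comparative tests.** Felsenstein contrasts of log-transformed
  variables, correlated and regressed **through the origin**
  (r = Σxy/√(Σx²Σy²); no-intercept least squares), pairwise deletion
  per trait pair. A log–log slope *b* translates into
  100·(2<sup>b</sup>−1)% change in diversity per doubling of the
  predictor.
* **Substructure control.** Single-threshold GMYC on each species'
  ultrametric gene tree — node ages older than the fitted threshold
  follow a Yule process, younger ages a within-cluster coalescent; when
  the mixed model is significantly preferred, diversity is re-estimated
  from the largest cluster (the subsample consistent with a single
  panmictic population) and the correlation battery is rerun.
* **Synthetic studies.** A generator (`make_study()`) that simulates
  the whole data-generating process — Yule species tree, Kingman
  genealogies (with optional cryptic two-cluster structure), codon
  sequences under purifying selection, correlated Brownian traits —
  with every true parameter written to a truth file.

## Worked example

Simulate a 200-species study and push it through the full pipeline:

```r
library(mitodiv)

cfg <- synthetic_config(n_species = 200, ind_range = c(2, 200), seed = 7)
dir <- file.path(tempdir(), "demo-study")
make_study(cfg, dir)

report <- run_study(dir, verbose = FALSE)
report
#> <study_report>
#>   species: 198 retained (2 excluded); individuals 2/21/200 (min/median/max)
#>   log_pi_s ~ log_range_km2: slope 0.204 (0.117), +15.2% per doubling, n = 197
#>   log_ratio ~ log_range_km2: slope -0.183 (0.094), -11.9% per doubling, n = 181
#>   gmyc: 38 of 200 species re-estimated from their largest cluster
```

The generator's true π<sub>S</sub>–range slope is 0.20; the pipeline
recovers 0.204 with SE 0.117, i.e. ~15% more synonymous diversity per
doubling of range, and the π<sub>N</sub>/π<sub>S</sub> slope comes back
negative (−0.183, truth −0.16) — the signature of effective population
size driving the diversity–range relationship. Each table in the report
is a tibble:

```r
report$table1[1:3, ]           # phylogenetic signal per log-variable
#>   trait           n lambda   lrt    p_lrt
#>   log_pi_s      198  0.511  71.0 1.78e-17
#>   log_ratio     182  0.363  21.8 1.51e- 6
#>   log_range_km2 198  1.000 228.  1.04e-51

dplyr::filter(report$rerun_table2, predictor == "log_range_km2")
#>   response  predictor         n      r       p
#>   log_pi_s  log_range_km2   195  0.188 0.00828
#>   log_ratio log_range_km2   179 -0.211 0.00438
```

Note the λ pattern — life-history traits near 1, the diversity
statistics much lower — and that the substructure-controlled rerun
*strengthens* the range correlations (raw r = 0.124/−0.143), because
removing cryptic-cluster inflation de-noises π<sub>S</sub>. Both
behaviours mirror what such analyses find on real bird data.
`tidy()`/`glance()` methods expose every fitted object as a tibble, and
`plot_contrasts(report$dataset)` / `autoplot(report)` draw the
contrast scatterplots with their through-origin fits.

Individual stages are ordinary functions: `pairwise_pi()`,
`assemble_dataset()`, `fit_lambda()`, `compute_contrasts()`,
`origin_regression()`, `fit_gmyc()`, `largest_cluster()`,
`reestimate_diversity()` — see the methods vignette
(`vignettes/mitochondrial-diversity.Rmd`) for the models, assumptions
and design choices. A thin command-line wrapper lives at
`inst/cli/mitodiv.R` (`simulate`, `diversity`, `run` verbs).

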