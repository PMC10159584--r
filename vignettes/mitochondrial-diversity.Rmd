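---
title: "Methods: correlates of mitochondrial synonymous diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlates of mitochondrial synonymous diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitodiv)
```

## The question and the model

Why do some species harbour far more mitochondrial genetic variation than
others? Under neutral theory, synonymous nucleotide diversity within a
species, $\pi_S$, is proportional to $N_e \mu$ — effective population size
times mutation rate — so comparing $\pi_S$ across species against
life-history and demographic variables (geographic range, census
population size, body mass, longevity, metabolic rate, egg mass, clutch
size, latitude) asks which of these predict $N_e$. The ratio
$\pi_N/\pi_S$ serves as an inverse proxy for $N_e$: if synonymous
mutations are neutral and nonsynonymous ones neutral or deleterious,
$\pi_N/\pi_S$ estimates the fraction of nonsynonymous mutations that
drift allows through, which shrinks as $N_e$ grows. A positive
$\pi_S$–range and a negative $\pi_N/\pi_S$–range relationship together
implicate population size rather than, say, mutation-rate variation.
The log–log slope of diversity on range is the quantitative summary: a
slope $b$ means a doubling of range multiplies diversity by $2^b$
(`percent_change_per_doubling()`), and shallow slopes (around 0.2) are
the comparative signature of Lewontin's paradox — diversity varies far
less than census size does.

mitodiv implements this entire analysis as composable, tested stages:

1. **diversity** — $\pi_S$, $\pi_N$, $\pi_N/\pi_S$ per species from
   in-frame codon alignments (`pairwise_pi()`);
2. **assembly** — joining diversity, trait table and dated species tree
   under explicit inclusion rules (`assemble_dataset()`);
3. **comparative** — Pagel's $\lambda$ (`fit_lambda()`), Felsenstein
   independent contrasts (`compute_contrasts()`), through-origin
   correlation and regression of contrasts (`origin_correlation()`,
   `origin_regression()`);
4. **substructure control** — single-threshold GMYC on per-species
   ultrametric gene trees (`fit_gmyc()`), re-estimating diversity from
   the largest cluster (`largest_cluster()`, `reestimate_diversity()`);
5. **synthetic data** — a generator producing complete studies with
   known truth (`synthetic_config()`, `make_study()`);
6. **pipeline** — `run_study()` orchestrates everything and emits the
   three headline tables.

## Counting synonymous and nonsynonymous change

Published compilations of this kind rarely pin down their counting
scheme, so the package adopts the field default for "in-house"
$\pi_S/\pi_N$ scripts:
Nei–Gojobori (1986) site counting with unweighted pathway averaging and
uncorrected proportions. Each position of a sense codon contributes the
fraction of its single-nucleotide changes that are synonymous, with
changes to stop codons removed from that position's denominator; for a
codon pair differing at 2–3 positions the per-step classifications are
averaged over all mutational pathways, dropping pathways that pass
through a stop. Two details deserve note:

* Under the vertebrate mitochondrial code (the default; table 2, with
  ATA = Met, TGA = Trp, AGA/AGG = stop, 60 sense codons) there exist
  sense–sense pairs whose *every* pathway is stop-blocked — e.g.
  AAA (Lys) ↔ TGA (Trp), whose two intermediates TAA and AGA are both
  stops. Such pairs fall back to counting all pathways with their stop
  steps dropped, which tallies (0, 0); they are vanishingly rare within
  species.
* No multiple-hit correction is applied. Within-species mitochondrial
  divergence is well below 0.1 per site, where the correction is smaller
  than the Monte-Carlo noise of any realistic dataset.

Pairs are handled with pairwise deletion at codon granularity (a codon
column is skipped for a pair if either codon carries N, a gap, or is a
stop), the site denominator is the average of the two sequences' counts
over retained codons, and $\pi_S$ is the unweighted mean of pair-level
proportions. Identical haplotypes are collapsed before the pair loop, so
species sampled at hundreds of individuals stay fast. Multi-gene
species follow the compilation rule: genes sequenced from the same
individuals are concatenated (`concatenate_alignments()`) before
estimation; genes from different individuals are averaged
(`aggregate_species()`), with $\pi_S$ the unweighted gene mean and the
ratio averaged over genes with $\pi_S > 0$.

## Inclusion rules and logs

All analysis happens on $\log_{10}$ scale (slopes of log–log regressions
are base-invariant, so the choice only matters for intercepts, which are
never reported). $\log \pi_S$ is undefined for species without
synonymous variation: those are excluded with reason `"zero-diversity"`.
Species with $\pi_S > 0$ but $\pi_N = 0$ are *retained* for the $\pi_S$
analyses and simply have a missing ratio — this matches the way the
sample sizes differ between the $\pi_S$ and $\pi_N/\pi_S$ rows of the
correlation table, and it is what pairwise deletion implies. Species
absent from the species tree (`"no-tree"`) or without a single trait
value (`"no-traits"`) are also excluded, and every exclusion is recorded
so that retained + excluded always equals the input count. Non-positive
trait values (logs undefined) are flagged and treated as missing at
read time.

## Phylogenetic signal and contrasts

Pagel's $\lambda$ multiplies the off-diagonal of the Brownian tip
covariance; `bm_loglik()` evaluates the profile log-likelihood with the
ancestral mean and rate $\sigma^2$ at their conditional ML values, and
`fit_lambda()` maximizes it over $[0,1]$ by bounded optimization from
three starts (0.05, 0.5, 0.95; tolerance $10^{-6}$). Two tests are
emitted:

* an LRT against $\lambda = 0$ with the boundary-mixture p-value
  $\tfrac12 P(\chi^2_1 \ge \mathrm{LRT})$. Simulation shows this is
  *conservative* for this problem: with 200 tips and no signal the MLE
  sits exactly at 0 over 80% of the time (not the asymptotic 50%),
  because profiling the ancestral mean pushes the boundary score
  negative, so realized size is nearer 1% than 5%. The estimate itself
  is unbiased where it matters (mean $\hat\lambda$ within 0.01 of truth
  at $\lambda \in \{0.5, 1\}$ on 200-tip trees), and matches
  `phytools::phylosig()` to five decimals.
* an optional permutation test (`n_perm` tip-label shuffles), whose
  smallest attainable p is $1/(1+n_\text{perm})$ — with 999 shuffles,
  0.001, the floor visible in published signal tables. Being calibrated
  by construction, it is the headline p whenever computed.

Contrasts use the standard pruning recursion (via `ape::pic`) after
deterministic polytomy resolution (tip-label order, zero branches padded
by $10^{-8} \times$ depth). Because a contrast's sign is arbitrary,
correlation and regression of contrasts are forced through the origin:
$r = \sum x_i y_i / \sqrt{\sum x_i^2 \sum y_i^2}$ with
$t = r\sqrt{(n-1)/(1-r^2)}$ on $n-1$ df, and no-intercept least squares
with df $= n - k$. Spearman correlations are computed on positivized
pairs (each pair jointly flipped so the x contrast is non-negative),
since ranks are not invariant to joint sign flips. Species missing
either variable of a pair are dropped pairwise and the tree re-pruned,
so each table row carries its own $n$.

## The GMYC substructure control

Rising $\pi_S$ with range could be an artefact of population structure or
cryptic species accumulating with range. The control models each
species' ultrametric gene tree as a mixture: node ages older than a
threshold are branching events of a Yule process over "species"
lineages; younger nodes are coalescences inside clusters seeded where
lineages cross the threshold. Between successive node ages the waiting
time is exponential with total rate

$$b_i \;=\; \lambda_y\, n_{y,i}^{p_y} \;+\; \lambda_c \sum_j
n_{j,i}\,(n_{j,i}-1)^{p_c},$$

each event contributing $\log b_i$; the root is conditioned on in every
model so all candidates compare the same $n-2$ events. Scaling exponents
default to 1 (pure Yule + Kingman). The threshold is scanned over
midpoints between consecutive distinct node ages (plus the root = null
single-coalescent model and a sub-youngest candidate); at each
candidate the two rates are profiled — in closed form when only one
process is active, otherwise by Nelder–Mead on the log scale. The LRT
against the null uses $\chi^2_3$, the original method's convention. We
measured the alternatives on simulated single-coalescent trees
($n = 20$): with 1 df the threshold-scan multiplicity inflates size to
0.16–0.22, while 3 df gives ~0.03–0.05 with no practical power cost
(median LRT ≈ 60 on well-separated two-scale trees). An early design
that attributed each event only its own process's rate (a
competing-risks likelihood) recovered known clusters in barely 30% of
two-scale simulations and was discarded in favour of the total-rate
form above, which recovers ≥ 95%.

Clusters are threshold-crossing lineages with ≥ 2 sampled tips;
single-tip crossers are reported as singletons and never chosen as the
"largest cluster" unless nothing else exists; ties break to the cluster
holding the alphabetically first tip. In the pipeline a species is
re-estimated from its largest cluster only when the mixed model is
significantly preferred (p < 0.05) *and* splits it into more than one
cluster — gating on the test matters, because the unconstrained ML
cluster count exceeds one on most single-population trees.

## The synthetic-data generator

`make_study()` writes a complete study — FASTA codon alignments, dated
species tree, per-species gene trees, trait CSV, and a truth JSON — with
the statistical structure the analysis assumes. Defaults describe the
kind of compiled avian dataset the pipeline targets, chosen once as
follows and held fixed:

* **300 species**, sample sizes drawn from a log-normal with median 21
  truncated to [2, 420] (`ind_sdlog = 1.1`).
* **Traits** evolve by Brownian motion on the unit-depth species tree
  (λ configurable, default 1 — the model contrasts assume; most real
  life-history traits sit near 1). Log-range has sd 1.3 per unit depth
  (bird ranges span several orders of magnitude); log population size is
  log-range plus independent noise sized for r ≈ 0.79, the strength of
  the empirical range–abundance relationship.
* **Diversity**: per-species $\theta_S$ (expected $\pi_S$) is
  log-linear in range with slope 0.20 around a median of
  $10^{-1.7} \approx 0.02$ per synonymous site, with independent BM
  noise (sd 0.35) and clipping to $[3\times10^{-4}, 0.2]$; the neutral
  nonsynonymous fraction is log-linear in range with slope −0.16 around
  0.08. Sequences (500 codons by default, the scale of one-to-two
  concatenated mitochondrial genes) evolve on Kingman genealogies whose
  branch lengths are in expected-pairwise-diversity units.
* **Selection as rejection sampling**: proposed nonsynonymous changes
  are kept with probability equal to the neutral fraction, stops always
  rejected, synonymous changes always kept. This controls
  $E[\pi_N/\pi_S]$ directly. One subtlety: NG86 site denominators
  exclude stops while the mutation process simply never proposes them,
  so the realized synonymous opportunity is ~6% below the NG86 site
  count. `ng86_calibration()` returns the correction factor
  (≈ 1.06 for the vertebrate mitochondrial code) by which the proposal
  rate is multiplied so that $E[\hat\pi_S] = \theta_S$ under NG86
  counting; the generator applies it automatically.
* **Substructure**: 20% of species get a two-cluster genealogy whose
  between-cluster split is `coal_depth_ratio` (default 50) times the
  within-cluster depth — deep enough that GMYC should find it.
* **Missingness** per trait mimics real compilations (population size
  and metabolic rate sparsest), so pairwise deletion is exercised.

Everything is reproducible from `(config, seed)` alone.

### What the generator does and does not emulate

Passing tests certify the estimators against *this* generative model:
a single non-recombining locus, panmictic (or two-deme) species,
equilibrium coalescent genealogies, uniform codon usage at the root, no
rate variation among sites or lineages, no sequencing error, and traits
that are exactly (λ-transformed) Brownian. Real data violate most of
these mildly and some severely (selection on synonymous sites,
hitchhiking, non-equilibrium demography). In particular, the
within-species coalescent plus Poisson mutation makes $\log \pi_S$ a
noisy measurement of $\log \theta_S$ — noise that is *white* on the
tips, and therefore amplified by contrasts at shallow splits of the
Yule tree. The end-to-end contrast correlation between $\pi_S$ and
range in a default study is consequently much weaker (r ≈ 0.1–0.2)
than the trait-level calibration (r ≈ 0.4). The regression slope stays
unbiased in expectation, but the coalescent noise and the occasional
cryptic-structure inflation are heavy-tailed across contrasts, so
single-study slope estimates scatter around the truth somewhat more
than the homoskedastic standard error suggests; at the trait level
(where the model is exactly Brownian) 2-SE coverage is nominal. The same dilution
operates on Pagel's λ: generated $\theta_S$ has λ = 1 but estimated
$\hat\lambda$ for $\log \pi_S$ lands near 0.1–0.4 — pleasingly, the
same qualitative pattern (diversity statistics far below the λ ≈ 1 of
morphological traits) seen in real tables.

## Numerical choices and degenerate inputs

* Ultrametricity: relative depth-spread tolerance $10^{-6}$; trees
  failing it are fine for contrasts and λ but rejected by GMYC, which
  needs a total order of node ages.
* λ search on [0, 1] with three restarts; singular covariances (e.g.
  duplicate zero-distance tips at λ = 1) raise a classed error
  suggesting epsilon branch lengths.
* Collinear predictors (condition number > $10^8$) and zero-variance
  contrast sets raise classed errors rather than returning NaN.
* Frame offsets are per-alignment (default 0); trailing incomplete
  codons are trimmed silently.
* GMYC threshold ties prefer the root (fewer clusters); cluster-size
  ties in `largest_cluster()` break lexicographically.

## Problem sizes used in the shipped checks

The test-suite simulations run at the sizes where each property is
informative: λ recovery at 200 tips (100 replicates per truth value,
500 for test size), diversity calibration at 200 six-tip alignments of
200 codons, GMYC recovery at 200 five-species × six-tip trees plus 200
twenty-tip null trees, and slope recovery at 100 studies of 361 species
(trait level). The acceptance script repeats the same computations at
reduced replicate counts and pushes one 100-species study with
sequences end-to-end through `run_study()`. A default 300-species
study generates in seconds and analyses in about a minute.

## Known limitations

* The boundary LRT for λ is conservative (see above); use the
  permutation p when calibrated size matters.
* Contrast standard errors assume the Brownian model; when traits are
  generated (or evolve) with λ well below 1, through-origin SEs are
  anticonservative. The pipeline reports λ per variable precisely so
  readers can judge this.
* GMYC is fit with scaling exponents fixed at 1; the exponent-estimating
  variant of the original method is not exposed.
* $\pi_N/\pi_S$ tracks the neutral fraction only to first order
  (measured within ~5%); pathway averaging on multiply-hit codons can
  create fractional nonsynonymous counts even under complete
  constraint, though this needs two hits in one codon on one pairwise
  path and essentially never occurs at within-species divergences.
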