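---
title: "Inference for clonal triploid populations: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inference for clonal triploid populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalpop)
```

`clonalpop` analyses populations in which every individual is a clone of a
single founder — the situation of invasive marbled crayfish, a triploid,
apomictically parthenogenetic animal.  This vignette is the package's own
account of the science it implements: the models, their assumptions, the
thresholds and defaults, the numerical choices, and the places where the
underlying procedures were genuinely open and a design decision had to be
made.

## 1. The genomic model

### Dosage recoding

In a triploid, a biallelic site has four genotypes.  The package recodes
each genotype to its **alternative-allele dosage**: `0/0/0 → 0`,
`0/0/1 → 1`, `0/1/1 → 2`, `1/1/1 → 3`.  All downstream computation
(distances, trees, PCA, sharing) runs on the resulting samples × sites
integer matrix.  Missing genotypes carry a missing code (`NA`) and are
dropped from any pairwise comparison that involves them, never imputed —
except in PCA, where per-site mean imputation is applied before centering
(the standard choice for probabilistic/NIPALS-style PCA on genotype data,
and configurable by pre-imputing the matrix differently).

### Filters

`filter_config()` defaults implement the hard-filter triple used for
clonal SNV calling:

| parameter | default | unit | rationale |
|---|---|---|---|
| `min_depth` | 20 | reads, per sample | below this, triploid dosage (thirds!) is not resolvable |
| `max_depth` | 200 | reads, per sample | collapsed repeats masquerade as variants |
| `min_site_quality` | 30 | Phred | standard 1-in-1000 error bound |
| `require_reference_coverage` | `TRUE` | — | a site absent from the reference cannot be compared to it |
| `drop_reference_het` | `TRUE` | — | see below |

The depth window applies **for each sample**: a site failing in any sample
is removed for all, keeping the matrix rectangular.  The quality filter is
applied to the site-level record quality; whether the original protocol
used site or per-sample genotype quality is not decidable from its
description, so the site reading was chosen (it is the conservative one —
it removes the whole record) and the threshold is configurable.

**Reference heterozygosity.**  The reference specimen is itself triploid
with an AAB genome: a large fraction of positions are heterozygous in the
reference (mostly dosage 1, the divergent B haplotype).  At such sites
every clone is "variant" and no polymorphism signal exists, so they are
removed; a *polymorphic site* is a reference-homozygous position where at
least one retained sample has dosage > 0.  Sharing statistics are computed
on presence/absence of the alternative allele, not on the dosage value: a
mutation event creates presence, and a clone either inherited it or did
not.

Filtering is total (it never raises an error) and idempotent; the
per-step removal counts are attached to the result and logged by the
pipeline, giving the per-sample statistics table of a sequencing run.

### Distances, trees, PCA, aggregation

* `pairwise_distance()` offers Euclidean (default) and Manhattan metrics
  on dosage vectors.  The procedure this follows did not name its metric;
  Euclidean is the default of the distance function in the tree package it
  used, and Manhattan is provided because on dosage vectors it equals the
  total allele-count difference (one dosage unit at one site contributes
  exactly 1, which makes tree scale bars directly interpretable as allele
  counts).
* `nj_tree()` is classical Saitou–Nei neighbor joining, delegated to
  `ape::nj()` (the implementation the original analysis itself used, with
  default parameters).  NJ can return negative branch lengths on
  non-additive input; they are clamped to zero for display and the raw
  estimates kept in `attr(tree, "raw_edge_length")`.  On additive matrices
  NJ is exact, which the tests verify against hand-solved 4-taxon branch
  lengths and randomly generated ≤ 6-taxon trees.
* `dosage_pca()` centers columns (no unit-variance scaling — dosage is
  already on a common scale) and decomposes by SVD, returning
  `min(samples − 1, sites)` components.  Because singular vectors are
  defined only up to sign, the sign of each component is fixed so that its
  largest-magnitude loading is positive; this makes scores reproducible
  across platforms.  An all-constant matrix yields a zero-variance result
  with a warning rather than an error.
* `kmeans_row_aggregate()` clusters *sites* with Lloyd's k-means
  (k-means++ initialisation under a fixed seed, ≤ 100 iterations,
  `k = 200` by default, the row-aggregation setting used for SNV-pattern
  heatmaps) and returns the k centroid rows — average dosage per site
  cluster — ordered by hierarchical clustering of the centroids.  Dosage
  matrices contain many duplicated site patterns; the k-means++ seeding
  therefore draws from the distinct patterns (no two initial centers
  coincide), and if the matrix has fewer distinct patterns than `k`, each
  pattern simply becomes its own centroid.

## 2. The VAF / loss-of-heterozygosity scan

Apomixis predicts that reference-heterozygous positions stay heterozygous
in every clone.  Recombination or gene conversion would create runs of
homozygosity, visible as the variant allele frequency (VAF = alt reads /
total reads) drifting away from its dosage expectation (1/3 or 2/3).

`vaf_config()` defaults: heterozygous positions are selected from the
reference profile with strict thresholds (quality > 30, coverage > 5
reads), and averaged in windows of 10,000 heterozygous positions — a
count of sites, not base pairs, so sparse regions do not produce noisy
windows.  Windows never span a contig boundary (coordinates are only
comparable within a contig); the final partial window of each contig is
kept and flagged with its actual site count.  The underlying analysis was
purely visual; the quantitative flag rule here — |observed mean −
expected mean| > `loh_delta`, default 0.10, half the 1/3 ↔ 2/3 gap — is
this package's addition, and the expected mean is the sitewise average of
reference dosage / 3, so windows mixing dosage-1 and dosage-2 sites are
handled correctly.

**A known blind spot**: a conversion event that sends dosage-1 sites to 0
and dosage-2 sites to 3 in exactly balancing numbers leaves the *window
mean* unchanged.  This is a property of any windowed-mean scan, not of
this implementation; with the realistic AAB composition (dosage-1 sites
dominate heterozygosity, the generator default is 80/20) the cancellation
does not occur and an LOH segment spanning one full window shifts the mean
by ≈ 0.2, double the flag threshold.  Segmentation methods (CBS, HMMs)
that model site-level signs would detect balanced conversion but are out
of scope.

## 3. Mark–recapture and extrapolation

### Schnabel estimator

For a closed population sampled on consecutive occasions with persistent
marks, `schnabel()` pools all traps per day and computes
N̂ = Σ C·M / Σ R with C the daily catch, M the marked animals at large and
R the recaptures.  Closure is a design assumption: a short (10-day)
survey is used precisely to make reproduction, death, migration and
moulting negligible.  The original report does not state its SE formula;
the package uses the classical Poisson treatment of the recapture total,
SE = N̂/√ΣR, documented here and swappable (the bootstrap takes whatever
SE the estimate carries).  With zero recaptures the estimator is
undefined; a Chapman-style +1 correction is available by flag.

### Saturation regression

When marking has not saturated by the end of the survey, the cumulative
number of distinct marked animals is extrapolated with the two-parameter
negative exponential y = a(1 − e^(−cx)).  `fit_saturation()` estimates
both parameters by Levenberg–Marquardt least squares, initialised at
a₀ = 1.2·max(y) and a rate from log-linearising the first informative
point, capped at 2/max(x) so the Jacobian starts well-conditioned (the
optimiser grows the rate from there; plateau-shaped data drive c upward
essentially unboundedly, which is the correct degenerate answer — the
asymptote is then the plateau).  Parameter SEs come from the Jacobian at
the optimum (RSS/dof · (JᵀJ)⁻¹); on data where the rate is unidentified
the SE is reported as `NA` rather than invented.  Non-convergence raises
an error carrying the optimiser's diagnostic message.

### Stratified extrapolation

`lake_strata()` encodes the published bathymetric design: depth ≤ 4 m →
47,500 m² with 10 traps (4,750 m² per trap), 5–10 m → 16,000 m² with 4
traps (4,000 m²), > 10 m → 29,000 m² with 4 traps (7,250 m²); the areas
sum to the lake surface.  `stratified_total()` allocates the mature
abundance estimate to strata by catch share, converts to per-stratum
densities over the assumed sampled areas, and re-extrapolates over the
true stratum areas.  Under the canonical design (area-per-trap =
area/traps, i.e. the traps tile the lake) this correction is exactly
measure-preserving and the mature abundance equals the input estimate —
the published arithmetic for how the correction enters the final total is
under-specified, and this identity-preserving reading is the one that
makes the single-stratum case reduce to the plain Schnabel estimate.  The
total population is mature abundance / f, where f is the fraction of the
hand-catch size distribution above the 6 cm trap cutoff (traps are
size-selective; small nets are not).  A second path — mean hand-catch
density × lake area — is always computed and reported as a cross-check,
because it is ambiguous which path produced the published total.

### Bootstrap SE

`bootstrap_se()` (default 10,000 replicates) perturbs, per replicate:
the Schnabel estimate (normal, its SE), the saturation asymptote when
supplied (normal, its fit SE, scaled into the mature-abundance slot in
alternating replicates so both abundance readings contribute), each
stratum area (normal, 10% relative SE — an assumed value, as in the
original design), and the hand-catch sizes (resampled with replacement,
re-estimating f).  Non-positive draws are rejected and redrawn, with the
rejection count reported.  The combined SE is the SD of replicate totals.
Interpreting the "population-ratio" component as resampling the
hand-catch size ratios is this package's reading of an ambiguous
description, and is flagged as such.

## 4. Growth and genetic-variability simulation

Three discrete models step a founder population of N₀ = 1:

* exponential: N_{i+1} = N_i · e^{g·dt}, exactly consistent with the
  closed form under any partition of time;
* logistic: N_{i+1} = N_i + g·dt·N_i(1 − N_i/N_max), fixed point N_max,
  monotone for 0 < g·dt ≤ 1 (a warning is issued in the overshooting
  regime g·dt > 1);
* strong Allee: ΔN = N_i·g·dt·(1 − A/N_i) with the established threshold
  A = −3.1; a negative threshold makes the low-density multiplier exceed
  1, so growth dominates the discrete exponential increment, and N = 0 is
  absorbing.

Central parameters: exp(g) = 200 offspring per animal per year (spread
± 100), N_max = 192,000 animals (the total population estimate, SE
34.98%), μ = 3.6 × 10⁻⁹ mutations per bp per year, G = 3,511,656,756 bp.
The per-step updates are stated without a time unit; the package scales
the rate as g·dt per step with dt defaulting to 1/365 years, because with
exp(g) = 200 a unit-step update is numerically meaningless and a daily
step keeps g·dt ≈ 0.0145, deep inside the smooth regime.

### The variability mapping (an open design point)

"Total genetic variability" of a simulated population must be
reconstructed from first principles; the procedure's exact functional
form is not stated.  The package implements two documented strategies in
`variability_trajectory()` and records the choice in every output:

* **`cumulative`** (package default): v(t) = μ·G·∫₀ᵗ N(s) ds.  Each
  lineage mutates at μ·G per year; integrating census size counts
  lineage-years, so v(t) is the expected total number of mutation events
  that have occurred in the population since founding — the natural
  measure of how much variation the population has generated.  Evaluated
  by the cumulative trapezoid rule on the trajectory grid.
* **`census_age`**: v(t) = N(t)·μ·G·t, the expected per-lineage mutation
  load since founding multiplied by census size.

Both agree on the boundary cases (v(0) = 0; a constant single-animal
population accumulates μ·G ≈ 12.64 expected mutations in its first
year).  The current population's variability is
`variability_current()` = mean SNVs per specimen × census estimate; with
the observed per-specimen range 5,722–6,007 and N = 192,000 this is
1.13 × 10⁹, order of magnitude 10⁹.  Under the cumulative strategy at the
central exp(g) = 200, the simulated exponential curve reaches that level
at t* ≈ 3.77 years (the acceptance script recomputes this); under
census_age the central rate gives t* ≈ 3.23 and the lower end of the
spread (exp(g) = 100) gives ≈ 3.67.  The cumulative strategy was made the
default because it is the more defensible construction (it counts
mutation events rather than multiplying a per-lineage load by an
unrelated census) — not because of the value it produces; both curves are
exported and labelled.

`intersection_time()` returns the smallest t with v(t) ≥ target, located
on the simulation grid and refined between the bracketing steps to 10⁻³
years.  `intersection_band()` re-simulates at the ends of the
offspring-rate spread (and optionally N_max ± its SE for the logistic
model) and reports the half-width of the two extreme times as the error
band.

## 5. The synthetic-data generator

The generator produces data with exactly the statistical structure the
analysis assumes, so that every downstream stage has a computable truth:

* a triploid reference with a controlled heterozygous fraction (dosage 1
  vs 2 in a configurable ratio, default 80/20 as in an AAB genome);
* clonal genotypes on a fixed founder → populations → individuals
  star-of-stars lineage, with mutations modelled exclusively as dosage
  0 → 1 at reference-homozygous sites.  This mirrors the analysis domain
  (reference-het sites are filtered out anyway) and the fact that a new
  mutation hits one of three haplotypes;
* VCFs with negative-binomial per-sample depths (Poisson when the
  dispersion is 0) and binomial alternative reads around dosage/3,
  contaminated by a symmetric error rate;
* optional LOH segments (heterozygous dosages homogenized to the nearest
  homozygote, with every change recorded);
* closed-population trap surveys: each day each animal is captured with
  probability 1 − Π(1 − p_trap) and assigned to a trap proportionally to
  the per-trap rates; marks persist; hand-catch densities and a
  two-component size distribution with a controllable mature fraction.

Survey defaults mirror the study conditions: 10 consecutive days, 18
traps, a 6 cm size cutoff; the mature fraction defaults to 0.12 (the
ratio implied by a mature estimate of ~23,000 in a total of ~192,000) and
the hand-catch density to 2.1 animals/m² (that total over the 92,500 m²
of summed stratum areas).  Per-day catch variance was not reported for
the real survey, so the generator's capture model (independent
Bernoulli per day, one probability per trap) is the simplest credible
choice and its parameters are free.

What the generator does **not** emulate — and hence what green tests do
not certify on real data: mapping and alignment artifacts, indels,
multi-nucleotide variants, linked errors along reads, batch effects
between sequencing runs, trap-shyness or behavioural response to capture,
and open-population demography during the survey.

## 6. Problem sizes and numerical tolerances

The test-suite simulations are sized to exercise the statistics while
staying small: genotype worlds of 2,000–5,000 sites and 6–15 samples;
LOH operating characteristics over 100 seeds with 3,000 heterozygous
sites and 1,000-site windows (flag rate ≤ 1% under the null, ≥ 99%
detection of a window-spanning segment); Schnabel recovery over 100–200
simulated surveys (N = 500, p = 0.05, 10 days; mean within 10%, ± 2 SE
coverage ≥ 90%); saturation-fit calibration over 200 noisy replicates
(mean asymptote within twice its parameter SE).  Key tolerances:
exponential step composition to 10⁻¹² relative; zero-noise saturation
recovery to 10⁻⁶; logistic convergence to a 10⁻⁶ animal increment;
intersection times to 10⁻³ years; PCA reconstruction to 10⁻⁸.

## 7. Limitations

* The Schnabel SE and the bootstrap's ratio component are documented
  reconstructions of unstated procedures; alternative choices plug in.
* The windowed-mean LOH scan cannot see dosage-balanced conversion
  (section 2) and has window-scale resolution only.
* The variability mapping is a modelling choice (section 4); reported
  intersection times always carry the strategy label.
* NJ topology is exact only for additive distances; no bootstrap support
  values are computed.
* The nonlinear saturation fit carries the usual O(σ²) small-sample bias
  of NLS estimators; its calibration is judged against the parameter's
  own SE.
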