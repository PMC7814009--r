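# clonalpop

Population genomics and abundance estimation for nearly monoclonal,
triploid crayfish populations.

Marbled crayfish (*Procambarus virginalis*) reproduce by apomictic
parthenogenesis: every animal is a genetic copy of its mother, and whole
invasive meta-populations descend from a single founder.  The only nuclear
variation is the slow accumulation of new mutations, so population history
has to be read from a handful of single-nucleotide variants (SNVs) layered
on a triploid (AAB) genome.  `clonalpop` implements the full analysis chain
for this setting, for invasion biologists and population genomicists
working on clonal animals:

* **Variants** — read VCF calls against the clonal reference, apply the
  hard filters (per-sample depth 20–200, site quality ≥ 30, reference
  coverage required, reference-heterozygous sites removed, indels
  discarded), recode each triploid genotype to its alternative-allele
  dosage (`0/0/0 → 0` … `1/1/1 → 3`), and partition SNV sharing within and
  between sample groups (per-sample, shared-by-*k*, fixed, two-group Venn).
* **Structure** — pairwise Euclidean/Manhattan distances on the dosage
  matrix, neighbor-joining trees (Saitou–Nei, negative branches clamped
  with raw values kept), centered PCA, and k-means row aggregation of
  sites for heatmap display.
* **VAF/LOH** — per-site variant allele frequency `alt reads / total reads`
  at reference-heterozygous positions, averaged in windows of a fixed
  count of heterozygous sites (default 10,000), with windows flagged when
  the observed mean deviates from the dosage-based expectation (1/3 or
  2/3) by more than a configurable `loh_delta` (default 0.10) — a scan for
  loss of heterozygosity, whose absence is the signature of apomixis.
* **Mark–recapture** — the Schnabel estimator for a closed population
  surveyed on consecutive days,

  $$\hat N = \frac{\sum_t C_t M_t}{\sum_t R_t}, \qquad
    SE = \hat N / \sqrt{\textstyle\sum_t R_t},$$

  the saturation regression $y = a(1 - e^{-cx})$ fitted by
  Levenberg–Marquardt to predict the marking plateau, bathymetry-stratified
  extrapolation (area-per-trap per depth stratum), extrapolation from
  mature (trappable, > 6 cm) animals to the whole population via the
  hand-catch size distribution, and a 10,000-replicate bootstrap combining
  all uncertainty components.
* **Growth** — discrete exponential ($N_{i+1} = N_i e^{g\,dt}$), logistic
  ($N_{i+1} = N_i + g\,dt\,N_i(1 - N_i/N_{max})$) and strong-Allee
  ($\Delta N = N_i\,g\,dt\,(1 - A/N_i)$) models; conversion of census
  trajectories to genetic-variability curves using the arthropod mutation
  rate $\mu = 3.6\times10^{-9}$ per bp per year and the 3,511,656,756 bp
  genome assembly; and location of the time at which simulated variability
  reaches the current population's level, with an error band from the
  200 ± 100 offspring-rate spread.
* **Synthetic data** — a generator for triploid clonal truth sets
  (founder → population → individual mutation lineages), VCFs with
  negative-binomial depths and binomial allele reads, injectable LOH
  segments, and closed-population trap surveys with persistent marks — so
  every stage above is testable without any sequencing or field data.

## Worked example

```r
library(clonalpop)

# a clonal world: 2 populations x 5 samples, 120 shared / 60 per-population
# / 15 per-sample SNVs on a 5,000-site triploid reference (20% het)
ref   <- generate_reference_profile(5000, het_fraction = 0.2, seed = 7)
spec  <- population_spec(2, 5, 5000, 60, 15, 120, 0.2, seed = 7)
truth <- generate_clonal_genotypes(spec, ref)
emit_vcf(truth, read_model(mean_depth = 40), "synthetic.vcf", seed = 8)

mat  <- recode_dosage(apply_filters(read_vcf("synthetic.vcf"),
                                    filter_config(), ref))
polymorphic_partition(mat, truth$groups)
#> SNV sharing partition: 327 polymorphic sites, 103 fixed in all samples
#>   per-sample SNV counts: pop1_s1=164, pop1_s2=166, ... pop2_s5=164
#>   group-shared Venn (pop1 | pop2): 151 | 153 shared, 103 in both, union 201

tree <- nj_tree(pairwise_distance(mat, "euclidean"))   # ape::phylo
dosage_pca(mat)
#> Dosage-matrix PCA: 10 samples, 9 components
#>   variance explained: PC1 71.9%, PC2 4.1%, ...
```

Each sample was seeded with 120 + 60 + 15 = 195 SNVs; the counts around
164 show the depth filter at work (sites where any sample's
negative-binomial depth leaves 20–200 are dropped), while the Venn
`151 | 153 shared, 103 in both` recovers the 103 surviving founder SNVs
plus each population's private set, and PC1 carries the between-population
split.

```r
sv  <- generate_trap_survey(22962, n_days = 10, traps = 18,
                            capture_prob_per_trap = 2e-4, seed = 9)
est <- schnabel(sv)
est
#> Schnabel mark-recapture estimate: N = 19807 (SE = 4952), 16 recaptures over 10 days
bootstrap_se(est, lake_strata(), sv$hand_catch, n_reps = 10000, seed = 10)
#> Stratified abundance: mature N = 19807, mature fraction f = 0.187, total N = 106110
#>   bootstrap SE = 34466
#>   hand-catch density path (all sizes): 202416 animals

vp <- variability_params(snv_per_specimen = mean(c(5722, 6007)),
                         current_N = 192000)
v_now <- variability_current(vp)   # 1.126e+09, magnitude 1e+09
intersection_band("exponential", growth_params(200, horizon = 6), vp,
                  v_now$value, strategy = "cumulative")
#> Variability intersection (exponential model, strategy 'cumulative'): t* = 3.77 (+- 0.40) years
```

With 16 recaptures the Schnabel point estimate sits within one SE of the
simulated truth (22,962 trappable animals); `lake_strata()` carries the
published three-stratum design (4,750 / 4,000 / 7,250 m² per trap), and
the bootstrap SE combines the recapture, asymptote, trap-area (10%) and
size-ratio components.  The growth simulation says a clonal population
founded by one animal reaches today's genetic variability (~10⁹) in under
four years of exponential growth.

An end-to-end run (simulate → variants → structure → VAF → census →
growth) is available as `run_pipeline(default_run_config())` or from the
shell:

```sh
Rscript scripts/clonalpop.R all --out run1 --seed 3
```

## Vignette

`vignettes/clonal-population-inference.Rmd` documents the models and their
assumptions, every tunable threshold with its default and rationale, what
the synthetic generator does and does not emulate, and the package's
design choices where the underlying procedures are ambiguous.
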