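# Shared fixture builders; everything is generated in code at test time.

# Small clonal world: reference + truth with the given structure.
make_world <- function(n_populations = 2, samples_per_population = 3,
                       n_sites = 2000, het_fraction = 0.2,
                       private_pop = 10, private_sample = 4, shared = 20,
                       seed = 1) {
  ref <- generate_reference_profile(n_sites, het_fraction, seed = seed)
  spec <- population_spec(n_populations, samples_per_population, n_sites,
                          private_pop, private_sample, shared,
                          het_fraction, seed = seed)
  truth <- generate_clonal_genotypes(spec, ref)
  list(ref = ref, spec = spec, truth = truth)
}

# In-memory variant_calls drawn from a truth set (no VCF file round trip),
# mirroring the VCF emitter's read model.
synth_calls <- function(truth, rm = read_model(), seed = 1) {
  sites <- clonalpop:::variant_site_index(truth)
  reads <- clonalpop:::simulate_read_counts(truth, rm, sites, seed = seed)
  ref <- truth$ref[sites, , drop = FALSE]
  samples <- rownames(truth$genotypes)
  gt_str <- clonalpop:::dosage_to_gt
  GT <- t(matrix(gt_str[truth$genotypes[, sites, drop = FALSE] + 1L],
                 nrow = length(samples),
                 dimnames = list(samples, NULL)))
  structure(list(
    sites = data.frame(contig = ref$contig, pos = ref$pos,
                       ref = "A", alt = "G", qual = reads$qual,
                       is_snv = TRUE, stringsAsFactors = FALSE),
    GT = GT,
    DP = reads$DP,
    AD_alt = reads$AD,
    allele_index = rep(1L, length(sites)),
    samples = samples), class = "variant_calls")
}

# Truth dosage matrix restricted to the analysis domain
# (reference-homozygous sites carrying at least one alternative allele).
truth_polymorphic_matrix <- function(world) {
  hom <- !world$ref$het
  m <- world$truth$genotypes[, hom, drop = FALSE]
  m[, colSums(m) > 0, drop = FALSE]
}
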