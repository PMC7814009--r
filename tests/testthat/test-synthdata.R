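test_that("reference profile honours the het fraction and is deterministic", {
  ref0 <- generate_reference_profile(500, 0, seed = 1)
  expect_equal(sum(ref0$ref_dosage), 0)
  expect_false(any(ref0$het))

  ref <- generate_reference_profile(1000, 0.1, seed = 1)
  expect_equal(sum(ref$het), floor(0.1 * 1000))
  expect_true(all(ref$ref_dosage[ref$het] %in% 1:2))
  expect_true(all(ref$covered))

  expect_identical(ref, generate_reference_profile(1000, 0.1, seed = 1))
  expect_error(generate_reference_profile(-5), "non-negative")
})

test_that("clonal genotypes place mutations on the declared lineage branches", {
  w <- make_world(n_populations = 2, samples_per_population = 2,
                  private_pop = 5, private_sample = 3, shared = 7, seed = 4)
  tr <- w$truth
  ev <- tr$events

  # population-private SNVs: carried by all of that population, none of the other
  for (p in c("pop1", "pop2")) {
    sites <- ev$site[ev$branch == paste0("pop:", p)]
    expect_length(sites, 5)
    in_pop <- tr$genotypes[tr$groups == p, sites, drop = FALSE]
    out_pop <- tr$genotypes[tr$groups != p, sites, drop = FALSE]
    expect_true(all(in_pop > 0))
    expect_true(all(out_pop == 0))
  }
  # per-sample private count is exactly 3 (set difference over truth matrix)
  hom <- !w$ref$het
  pres <- tr$genotypes[, hom] > 0
  uniq <- colSums(pres) == 1
  for (s in rownames(tr$genotypes)) {
    expect_equal(sum(pres[s, ] & uniq), 3)
  }
  # root SNVs present in everyone
  root_sites <- ev$site[ev$branch == "root"]
  expect_true(all(tr$genotypes[, root_sites] > 0))
  # no site mutated twice
  expect_false(any(duplicated(ev$site)))
})

test_that("zero mutation counts give perfect clonality", {
  ref <- generate_reference_profile(800, 0.3, seed = 2)
  spec <- population_spec(2, 3, 800, 0, 0, 0, 0.3, seed = 2)
  tr <- generate_clonal_genotypes(spec, ref)
  for (s in rownames(tr$genotypes)) {
    expect_equal(unname(tr$genotypes[s, ]), ref$ref_dosage)
  }
  d <- pairwise_distance(tr$genotypes, "manhattan")
  expect_true(all(d == 0))
})

test_that("mutation capacity is enforced", {
  ref <- generate_reference_profile(100, 0.5, seed = 1)
  spec <- population_spec(1, 1, 100, 0, 0, 49, 0.5, seed = 1)
  expect_silent(generate_clonal_genotypes(spec, ref))
  spec2 <- population_spec(1, 1, 100, 0, 0, 60, 0.5, seed = 1)
  expect_error(generate_clonal_genotypes(spec2, ref), "exceed")
  expect_error(population_spec(1, 1, 100, 0, 0, 200, 0.5), "exceed")
})

test_that("emitted VCFs are deterministic and respect the read model", {
  w <- make_world(seed = 7)
  p1 <- tempfile(fileext = ".vcf"); p2 <- tempfile(fileext = ".vcf")
  rm0 <- read_model(mean_depth = 300, depth_dispersion = 0, error_rate = 0)
  emit_vcf(w$truth, rm0, p1, seed = 11)
  emit_vcf(w$truth, rm0, p2, seed = 11)
  expect_identical(readLines(p1), readLines(p2))

  calls <- read_vcf(p1)
  dos <- t(w$truth$genotypes[, clonalpop:::variant_site_index(w$truth)])
  # dosage 3, no error: alt reads equal depth
  full <- dos == 3
  expect_equal(calls$AD_alt[full], calls$DP[full])
  # dosage 0, no error: zero alt reads
  none <- dos == 0
  expect_equal(unname(calls$AD_alt[none]), rep(0, sum(none)))
  # dosage 1 at depth ~300: VAF within 5 binomial SD of 1/3
  one <- dos == 1
  vafs <- calls$AD_alt[one] / calls$DP[one]
  bound <- 5 * sqrt((1 / 3) * (2 / 3) / calls$DP[one])
  expect_true(all(abs(vafs - 1 / 3) < bound))
})

test_that("injected LOH homogenizes exactly the reported sites", {
  w <- make_world(het_fraction = 0.5, seed = 9)
  s <- rownames(w$truth$genotypes)[1]
  rng <- c(1, 50 * 100)        # first 50 site slots
  tr2 <- inject_loh(w$truth, s, rng)
  het_in_range <- w$ref$pos <= rng[2] & w$truth$genotypes[s, ] %in% 1:2
  expect_equal(sort(tr2$loh$site),
               sort(colnames(w$truth$genotypes)[het_in_range]))
  expect_true(all(tr2$genotypes[s, tr2$loh$site] %in% c(0, 3)))
  expect_equal(tr2$loh$new, ifelse(tr2$loh$old == 1, 0, 3))
  # other samples untouched
  others <- setdiff(rownames(w$truth$genotypes), s)
  expect_equal(tr2$genotypes[others, ], w$truth$genotypes[others, ])
  # degenerate range with no het sites changes nothing
  tr3 <- inject_loh(w$truth, s, c(1, 1))
  expect_equal(tr3$genotypes, w$truth$genotypes)
  expect_error(inject_loh(w$truth, s, c(10, 5)), "site_range")
})

test_that("trap surveys obey the mark-recapture accounting identities", {
  sv <- generate_trap_survey(300, 8, 3, 0.04, seed = 5)
  d <- sv$daily
  expect_true(all(diff(d$M) >= 0))
  expect_true(all(d$R <= pmin(d$C, d$M)))
  expect_true(all(d$C <= 300))
  # distinct marked animals equals the sum of newly marked
  expect_equal(sum(d$new_marks), d$M[nrow(d)] + d$new_marks[nrow(d)])
  # per-trap rows pool back to the daily table
  agg <- aggregate(sv$days[c("catch", "recaptures")],
                   by = list(day = sv$days$day), FUN = sum)
  expect_equal(agg$catch, d$C)
  expect_equal(agg$recaptures, d$R)
  # determinism
  sv2 <- generate_trap_survey(300, 8, 3, 0.04, seed = 5)
  expect_identical(sv$days, sv2$days)

  # saturation: capture probability 1 catches everyone on day 1
  sat <- generate_trap_survey(50, 2, 1, 1, seed = 1)
  expect_equal(sat$daily$C, c(50, 50))
  expect_equal(sat$daily$R, c(0, 50))
  expect_warning(generate_trap_survey(50, 2, 1, 0, seed = 1), "degenerate")
})

test_that("survey CSV round-trips through the reader", {
  sv <- generate_trap_survey(200, 6, 4, 0.03, seed = 8)
  p <- tempfile(fileext = ".csv")
  write_survey_csv(sv, p)
  back <- read_survey_csv(p)
  expect_equal(back$days$catch, sv$days$catch)
  expect_equal(back$daily$C, sv$daily$C)
  expect_equal(back$daily$M, sv$daily$M)
  expect_equal(back$daily$R, sv$daily$R)
  expect_equal(coef(schnabel(back)), coef(schnabel(sv)))
})

test_that("hand-catch size distribution tracks the mature fraction", {
  sv <- generate_trap_survey(1000, 5, 2, 0.02, mature_fraction = 0.96,
                             n_hand_sizes = 400, seed = 3)
  expect_gt(mean(sv$hand_catch$sizes > 6), 0.9)
  sv2 <- generate_trap_survey(1000, 5, 2, 0.02, mature_fraction = 0.12,
                              n_hand_sizes = 400, seed = 3)
  expect_lt(mean(sv2$hand_catch$sizes > 6), 0.25)
  expect_equal(nrow(sv$hand_catch$densities), 3)
  expect_true(all(sv$hand_catch$densities$density > 0))
})
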