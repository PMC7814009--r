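test_that("VCF reading round-trips the emitted truth and flags non-SNVs", {
  w <- make_world(seed = 21)
  p <- tempfile(fileext = ".vcf")
  emit_vcf(w$truth, read_model(mean_depth = 60, depth_dispersion = 0,
                               error_rate = 0), p, seed = 2)
  calls <- read_vcf(p)
  expect_s3_class(calls, "variant_calls")
  expect_equal(nrow(calls$sites),
               length(clonalpop:::variant_site_index(w$truth)))
  expect_true(all(calls$sites$pos >= 1))

  # empty body
  empty <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1"),
             empty)
  expect_equal(nrow(read_vcf(empty)$sites), 0)
  expect_error(read_vcf(tempfile()), "no such")
})

test_that("indel and multi-allelic records are handled at parse", {
  p <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    "chr1\t100\t.\tA\tAT\t50\tPASS\t.\tGT:DP:AD\t0/0/1:30:20,10",
    "chr1\t200\t.\tC\tG,T\t50\tPASS\t.\tGT:DP:AD\t1/1/2:30:0,20,10",
    "chr1\t300\t.\tG\tA\t50\tPASS\t.\tGT:DP:AD\t0/1/1:28:10,18"),
    p)
  calls <- read_vcf(p)
  expect_equal(nrow(calls$sites), 4)       # multi-allelic split in two
  expect_false(calls$sites$is_snv[1])      # "AT" insertion
  expect_true(all(calls$sites$is_snv[2:4]))
  # per-allele dosage of the split record (columns sorted by position)
  mat <- recode_dosage(calls)
  expect_equal(colnames(mat), c("chr1:100", "chr1:200", "chr1:200",
                                "chr1:300"))
  expect_equal(unname(mat["s1", 2:3]), c(2L, 1L))
  # per-allele AD follows the allele index
  expect_equal(unname(calls$AD_alt[2:3, "s1"]), c(20, 10))
})

test_that("filters implement the depth/quality/reference rules", {
  w <- make_world(seed = 22)
  calls <- synth_calls(w$truth, read_model(mean_depth = 60,
                                           depth_dispersion = 0,
                                           error_rate = 0), seed = 1)
  # force specific violations
  calls$sites$qual[1] <- 25           # below the quality minimum of 30
  calls$DP[2, 1] <- 250               # above the depth maximum of 200
  calls$DP[3, 2] <- 10                # below the depth minimum of 20
  calls$sites$is_snv[4] <- FALSE      # indel
  f <- apply_filters(calls, filter_config(), w$ref)
  kept <- paste0(f$sites$contig, ":", f$sites$pos)
  dropped <- paste0(calls$sites$contig, ":", calls$sites$pos)[1:4]
  expect_false(any(dropped %in% kept))
  # no reference-het site survives
  ref_het <- paste0(w$ref$contig, ":", w$ref$pos)[w$ref$het]
  expect_false(any(kept %in% ref_het))
  # idempotence
  f2 <- apply_filters(f, filter_config(), w$ref)
  expect_equal(f2$sites, f$sites)
  expect_equal(f2$DP, f$DP)
  # sites absent from the reference are removed when coverage is required
  calls2 <- calls
  calls2$sites$pos[5] <- 1L           # not a reference position
  f3 <- apply_filters(calls2, filter_config(), w$ref)
  expect_false("chr1:1" %in% paste0(f3$sites$contig, ":", f3$sites$pos))
})

test_that("dosage recoding is the bijection on triploid genotypes", {
  p <- tempfile(fileext = ".vcf")
  gts <- c("0/0/0", "0/0/1", "0/1/1", "1/1/1", "./././.", ".")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
    sprintf("chr1\t%d\t.\tA\tG\t50\tPASS\t.\tGT:DP:AD\t%s:30:10,20",
            seq(100, by = 100, length.out = 4), gts[1:4]),
    "chr1\t500\t.\tA\tG\t50\tPASS\t.\tGT:DP:AD\t.:30:10,20"),
    p)
  mat <- recode_dosage(read_vcf(p))
  expect_equal(unname(mat["s1", 1:4]), 0:3)
  expect_true(is.na(mat["s1", 5]))    # missing genotype -> missing code

  # non-triploid genotype errors
  p2 <- sub("0/0/1", "0/1", readLines(p))
  writeLines(p2, p)
  expect_error(recode_dosage(read_vcf(p)), "ploidy")
})

test_that("sharing partition identities hold on generated truth", {
  w <- make_world(n_populations = 2, samples_per_population = 3,
                  private_pop = 5, private_sample = 2, shared = 9, seed = 30)
  mat <- truth_polymorphic_matrix(w)
  part <- polymorphic_partition(mat, w$truth$groups)

  # partition identity: sum over k of shared-by-k equals total polymorphic
  expect_equal(sum(part$shared_by_k$n_sites), part$n_polymorphic)
  # root SNVs are fixed, not unique
  expect_equal(part$n_fixed, 9)
  expect_equal(part$shared_by_k$n_sites[part$shared_by_k$k == 6], 9)
  # population-private SNVs appear as the exclusive Venn counts
  expect_equal(part$venn$A_only, 5)
  expect_equal(part$venn$B_only, 5)
  expect_equal(part$venn$both, 9)
  # Venn identity |A| + |B| - |both| = |union|
  expect_equal(part$venn$A_shared + part$venn$B_shared - part$venn$both,
               part$venn$union)
  # per-sample unique counts equal the per-sample private rate
  expect_equal(part$per_sample$n_unique, rep(2, 6))
  expect_error(polymorphic_partition(mat, c(bogus = "x")), "every sample")
})

test_that("high-depth error-free VCF reproduces truth SNV counts exactly", {
  w <- make_world(seed = 31)
  p <- tempfile(fileext = ".vcf")
  emit_vcf(w$truth, read_model(mean_depth = 60, depth_dispersion = 0,
                               error_rate = 0), p, seed = 3)
  mat <- recode_dosage(apply_filters(read_vcf(p), filter_config(), w$ref))
  tr <- truth_polymorphic_matrix(w)
  expect_equal(dim(mat), dim(tr))
  expect_equal(unclass(mat)[rownames(tr), colnames(tr)],
               unclass(tr)[, ], ignore_attr = TRUE)
  part <- polymorphic_partition(mat)
  truth_counts <- rowSums(tr > 0)
  expect_equal(setNames(part$per_sample$n_snv, part$per_sample$sample),
               truth_counts)
})

test_that("SNV annotation classifies by overlap and tallies the spectrum", {
  skip_if_not_installed("rtracklayer")
  # gene spanning 10% of a 100 kb contig, CDS the inner part, SNVs uniform
  gff <- tempfile(fileext = ".gff3")
  write_toy_gff(data.frame(contig = "chr1", start = 40001, end = 50000,
                           cds_start = 42001, cds_end = 48000), gff)
  pos <- seq(500, 100000, by = 500)
  sites <- data.frame(contig = "chr1", pos = pos,
                      ref = rep(c("G", "G", "C", "A"), length.out = length(pos)),
                      alt = rep(c("A", "A", "T", "C"), length.out = length(pos)))
  ann <- annotate_snvs(sites, gff)
  frac <- ann$summary$fraction[ann$summary$category == "intergenic"]
  expect_equal(frac, 0.9, tolerance = 0.02)
  expect_equal(sum(ann$category == "coding"),
               sum(pos >= 42001 & pos <= 48000))
  # the toy gene is exon-covering, so nothing is intronic
  expect_equal(sum(ann$category == "intronic"), 0)
  # spectrum: {G>A, G>A, C>T, A>C} repeated -> 3 transitions : 1 transversion
  expect_equal(ann$transitions / length(pos), 0.75)
  expect_equal(ann$transversions / length(pos), 0.25)
  expect_equal(sum(ann$spectrum$n), length(pos))
  # contig mismatch warns and defaults to intergenic
  sites2 <- data.frame(contig = "chrX", pos = 1000, ref = "A", alt = "G")
  expect_warning(ann2 <- annotate_snvs(sites2, gff), "absent")
  expect_equal(as.character(ann2$category), "intergenic")
})
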