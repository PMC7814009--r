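#' Specification of a synthetic clonal meta-population
#'
#' Describes a set of populations descending clonally from a single triploid
#' founder.  Every sample starts as an exact copy of the reference genotype
#' (apomictic parthenogenesis: no recombination); single-nucleotide mutations
#' are then placed on a fixed lineage topology
#' (founder -> population branches -> individual leaves), so that SNVs are
#' either shared by all samples, private to one population, or private to one
#' individual.
#'
#' @param n_populations Number of populations.
#' @param samples_per_population Samples (individuals) per population; a
#'   scalar, or a vector of length `n_populations` for unequal cohorts.
#' @param n_sites Total genotyped sites in the reference profile.
#' @param private_snvs_per_population Mutations on each population branch.
#' @param private_snvs_per_sample Mutations on each leaf branch.
#' @param shared_snvs_all Mutations on the root branch (carried by all
#'   samples but absent from the reference).
#' @param reference_het_fraction Fraction of reference sites that are
#'   heterozygous (alternative-allele dosage 1 or 2) in the triploid
#'   reference specimen.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return A list of class `population_spec`.
#' @seealso [generate_clonal_genotypes()], [generate_reference_profile()]
#' @export
population_spec <- function(n_populations = 2L,
                            samples_per_population = 5L,
                            n_sites = 10000L,
                            private_snvs_per_population = 50L,
                            private_snvs_per_sample = 10L,
                            shared_snvs_all = 100L,
                            reference_het_fraction = 0.1,
                            seed = 1L) {
  spec <- list(
    n_populations = check_count(n_populations),
    samples_per_population = vapply(samples_per_population, check_count,
                                    integer(1)),
    n_sites = check_count(n_sites),
    private_snvs_per_population = check_count(private_snvs_per_population),
    private_snvs_per_sample = check_count(private_snvs_per_sample),
    shared_snvs_all = check_count(shared_snvs_all),
    reference_het_fraction = check_fraction(reference_het_fraction),
    seed = as.integer(seed)
  )
  if (!length(spec$samples_per_population) %in% c(1L, spec$n_populations)) {
    stop("samples_per_population must be scalar or one value per population",
         call. = FALSE)
  }
  spec$pop_sizes <- rep_len(spec$samples_per_population, spec$n_populations)
  n_samples <- sum(spec$pop_sizes)
  spec$total_snvs <- spec$shared_snvs_all +
    spec$n_populations * spec$private_snvs_per_population +
    n_samples * spec$private_snvs_per_sample
  if (spec$total_snvs > spec$n_sites) {
    stop("total assigned SNV sites exceed n_sites", call. = FALSE)
  }
  class(spec) <- "population_spec"
  spec
}

#' Read-sampling model for synthetic VCF generation
#'
#' Per-site total depth is drawn from a negative binomial law with the given
#' mean and dispersion (Poisson in the limit `depth_dispersion = 0`);
#' alternative-allele reads are binomial with success probability
#' `dosage/3` contaminated by a symmetric sequencing error rate.
#'
#' @param mean_depth Mean sequencing depth per site (reads).
#' @param depth_dispersion Non-negative dispersion; variance is
#'   `mu + dispersion * mu^2`.  Zero selects a Poisson depth law.
#' @param error_rate Per-read error fraction in `[0, 0.5)`.
#' @param qual_mean Mean Phred-scaled site quality.
#' @return A list of class `read_model`.
#' @export
read_model <- function(mean_depth = 40, depth_dispersion = 0.05,
                       error_rate = 0.001, qual_mean = 60) {
  stopifnot(mean_depth > 0, depth_dispersion >= 0)
  check_fraction(error_rate, lo = 0, hi = 0.5 - 1e-12)
  structure(list(mean_depth = mean_depth,
                 depth_dispersion = depth_dispersion,
                 error_rate = error_rate,
                 qual_mean = qual_mean),
            class = "read_model")
}

#' Generate a triploid reference genotype profile
#'
#' The reference specimen is triploid with an AAB-like genotype: a fraction
#' `het_fraction` of sites carries alternative-allele dosage 1 or 2
#' (heterozygous), the remainder dosage 0.  Exactly
#' `floor(het_fraction * n_sites)` sites are flagged heterozygous.  All sites
#' are marked as covered in the reference, with per-site quality and depth
#' drawn around typical resequencing values.
#'
#' @param n_sites Number of sites.
#' @param het_fraction Fraction of heterozygous sites in `[0, 1]`.
#' @param seed Integer seed.
#' @param contigs Character vector of contig names over which sites are
#'   distributed evenly (in order).
#' @param het_dosage_probs Probabilities of dosage 1 vs dosage 2 at
#'   heterozygous sites.  The default favours dosage 1, as in an AAB
#'   genome where most heterozygosity is the single divergent haplotype.
#' @param mean_depth,qual_mean Location parameters for the reference's own
#'   coverage and site quality annotations.
#' @return A data frame of class `reference_profile` with columns
#'   `contig`, `pos`, `ref_dosage` (0, 1 or 2), `het`, `qual`, `depth`,
#'   `covered`.
#' @export
generate_reference_profile <- function(n_sites, het_fraction = 0.1,
                                       seed = 1L, contigs = "chr1",
                                       het_dosage_probs = c(0.8, 0.2),
                                       mean_depth = 40, qual_mean = 60) {
  n_sites <- check_count(n_sites)
  check_fraction(het_fraction)
  with_seed(seed, {
    per <- diff(floor(seq(0, n_sites, length.out = length(contigs) + 1L)))
    contig <- rep(contigs, per)
    pos <- unlist(lapply(per, function(k) 100L * seq_len(k)), use.names = FALSE)
    if (n_sites == 0L) pos <- integer(0)
    ref_dosage <- integer(n_sites)
    n_het <- floor(het_fraction * n_sites)
    het_idx <- if (n_het > 0) sort(sample.int(n_sites, n_het)) else integer(0)
    ref_dosage[het_idx] <- sample(c(1L, 2L), n_het, replace = TRUE,
                                  prob = het_dosage_probs)
    prof <- data.frame(
      contig = contig, pos = pos,
      ref_dosage = ref_dosage,
      het = ref_dosage > 0L,
      qual = round(pmax(1, rnorm(n_sites, qual_mean, 8)), 1),
      depth = rpois(n_sites, mean_depth),
      covered = rep(TRUE, n_sites),
      stringsAsFactors = FALSE
    )
    class(prof) <- c("reference_profile", "data.frame")
    prof
  })
}

#' @method print reference_profile
#' @export
print.reference_profile <- function(x, ...) {
  cat(sprintf("Triploid reference profile: %d sites on %d contig(s), %d heterozygous (dosage 1-2)\n",
              nrow(x), length(unique(x$contig)), sum(x$het)))
  invisible(x)
}

#' Generate clonal triploid genotypes on a fixed lineage
#'
#' All samples start as exact copies of the reference genotype.  Mutations
#' (dosage 0 -> 1 at reference-homozygous sites) are placed on a star-of-stars
#' lineage: `shared_snvs_all` on the root branch, `private_snvs_per_population`
#' on each population branch and `private_snvs_per_sample` on each leaf.  No
#' site is mutated twice; the branch of every mutation is recorded in the
#' truth table.
#'
#' @param spec A [population_spec()].
#' @param ref A [generate_reference_profile()] result covering
#'   `spec$n_sites` sites.
#' @return A list of class `clonal_truth`: `genotypes` (samples x sites
#'   dosage matrix), `ref`, `events` (one row per mutation with its branch),
#'   `groups` (population label per sample), `tree` (Newick lineage),
#'   `loh` (empty; see [inject_loh()]).
#' @export
generate_clonal_genotypes <- function(spec, ref) {
  stopifnot(inherits(spec, "population_spec"),
            inherits(ref, "reference_profile"))
  if (nrow(ref) < spec$n_sites) {
    stop("reference profile does not cover n_sites", call. = FALSE)
  }
  pool <- which(!ref$het)
  if (spec$total_snvs > length(pool)) {
    stop("requested SNVs exceed available non-heterozygous reference sites",
         call. = FALSE)
  }
  pops <- paste0("pop", seq_len(spec$n_populations))
  samples <- unlist(lapply(seq_along(pops), function(i) {
    paste0(pops[i], "_s", seq_len(spec$pop_sizes[i]))
  }))
  groups <- rep(pops, times = spec$pop_sizes)
  names(groups) <- samples

  keys <- site_key(ref$contig, ref$pos)
  geno <- matrix(rep(ref$ref_dosage, each = length(samples)),
                 nrow = length(samples), ncol = nrow(ref),
                 dimnames = list(samples, keys))

  with_seed(spec$seed, {
    chosen <- sample(pool, spec$total_snvs)
    take <- function(n) {
      out <- head(chosen, n); chosen <<- tail(chosen, -n); out
    }
    events <- list()
    root_sites <- take(spec$shared_snvs_all)
    if (length(root_sites)) {
      geno[, root_sites] <- geno[, root_sites, drop = FALSE] + 1L
      events[[length(events) + 1L]] <- data.frame(
        site = keys[root_sites], branch = "root", carrier = "*",
        stringsAsFactors = FALSE)
    }
    for (p in pops) {
      psites <- take(spec$private_snvs_per_population)
      if (length(psites)) {
        rows <- which(groups == p)
        geno[rows, psites] <- geno[rows, psites, drop = FALSE] + 1L
        events[[length(events) + 1L]] <- data.frame(
          site = keys[psites], branch = paste0("pop:", p), carrier = p,
          stringsAsFactors = FALSE)
      }
    }
    for (s in samples) {
      ssites <- take(spec$private_snvs_per_sample)
      if (length(ssites)) {
        geno[s, ssites] <- geno[s, ssites] + 1L
        events[[length(events) + 1L]] <- data.frame(
          site = keys[ssites], branch = paste0("sample:", s), carrier = s,
          stringsAsFactors = FALSE)
      }
    }
    events <- if (length(events)) do.call(rbind, events) else
      data.frame(site = character(0), branch = character(0),
                 carrier = character(0), stringsAsFactors = FALSE)

    tip_clades <- vapply(pops, function(p) {
      paste0("(", paste(samples[groups == p], collapse = ","), ")", p)
    }, character(1))
    tree <- paste0("(", paste(tip_clades, collapse = ","), ")founder;")

    structure(list(genotypes = geno, ref = ref, events = events,
                   groups = groups, tree = tree,
                   loh = data.frame(sample = character(0), site = character(0),
                                    old = integer(0), new = integer(0),
                                    stringsAsFactors = FALSE)),
              class = "clonal_truth")
  })
}

#' @method print clonal_truth
#' @export
print.clonal_truth <- function(x, ...) {
  cat(sprintf("Clonal truth set: %d samples x %d sites; %d mutation events (%d root, %d population, %d sample)\n",
              nrow(x$genotypes), ncol(x$genotypes), nrow(x$events),
              sum(x$events$branch == "root"),
              sum(startsWith(x$events$branch, "pop:")),
              sum(startsWith(x$events$branch, "sample:"))))
  if (nrow(x$loh)) cat(sprintf("  %d sites homogenized by injected LOH\n",
                               nrow(x$loh)))
  invisible(x)
}

#' Inject a loss-of-heterozygosity segment into one sample
#'
#' Within `site_range` (positions, inclusive) on `contig`, heterozygous
#' dosages of `sample` are homogenized toward the nearest homozygote
#' (1 -> 0, 2 -> 3), producing the variant-allele-frequency shift a genuine
#' LOH event would leave.  Modified sites are appended to `truth$loh`.
#'
#' @param truth A `clonal_truth` object.
#' @param sample Sample id to modify.
#' @param site_range Numeric length-2 vector `c(start, end)` of positions.
#' @param contig Contig on which the range lies.
#' @return The modified `clonal_truth`.
#' @export
inject_loh <- function(truth, sample, site_range,
                       contig = truth$ref$contig[1]) {
  stopifnot(inherits(truth, "clonal_truth"))
  if (!sample %in% rownames(truth$genotypes)) {
    stop("unknown sample: ", sample, call. = FALSE)
  }
  if (length(site_range) != 2L || site_range[2] < site_range[1]) {
    stop("site_range must be c(start, end) with end >= start", call. = FALSE)
  }
  in_range <- truth$ref$contig == contig &
    truth$ref$pos >= site_range[1] & truth$ref$pos <= site_range[2]
  idx <- which(in_range & truth$genotypes[sample, ] %in% c(1L, 2L))
  if (length(idx)) {
    old <- truth$genotypes[sample, idx]
    new <- ifelse(old == 1L, 0L, 3L)
    truth$genotypes[sample, idx] <- new
    truth$loh <- rbind(truth$loh, data.frame(
      sample = sample, site = colnames(truth$genotypes)[idx],
      old = as.integer(old), new = as.integer(new),
      stringsAsFactors = FALSE))
  }
  truth
}

# Sites that appear as records in an emitted VCF: any sample carries
# alternative alleles (reference-het sites qualify through inheritance).
variant_site_index <- function(truth) {
  which(apply(truth$genotypes > 0L, 2L, any))
}

# Draw per-sample depths and alternative-read counts for the given site
# indices of the truth matrix.  Returns list(DP, AD, qual) with sites in rows.
simulate_read_counts <- function(truth, rm, sites, seed = NULL) {
  stopifnot(inherits(rm, "read_model"))
  n_s <- nrow(truth$genotypes)
  n_v <- length(sites)
  with_seed(seed, {
    dp <- if (rm$depth_dispersion > 0) {
      matrix(rnbinom(n_v * n_s, mu = rm$mean_depth,
                     size = 1 / rm$depth_dispersion), nrow = n_v)
    } else {
      matrix(rpois(n_v * n_s, rm$mean_depth), nrow = n_v)
    }
    dos <- t(truth$genotypes[, sites, drop = FALSE])
    p <- (dos / 3) * (1 - rm$error_rate) + (1 - dos / 3) * rm$error_rate
    ad <- matrix(rbinom(n_v * n_s, size = as.vector(dp), prob = as.vector(p)),
                 nrow = n_v)
    dimnames(dp) <- dimnames(ad) <- list(colnames(truth$genotypes)[sites],
                                         rownames(truth$genotypes))
    qual <- round(pmax(1, rnorm(n_v, rm$qual_mean, 8)), 1)
    list(DP = dp, AD = ad, qual = qual)
  })
}

dosage_to_gt <- c("0/0/0", "0/0/1", "0/1/1", "1/1/1")

#' Write a synthetic VCF for a clonal truth set
#'
#' Emits one VCF v4.2 record per variant site (any sample with
#' alternative-allele dosage > 0), with a triploid `GT`, total depth `DP`
#' drawn from the read model's negative-binomial law, allele depths `AD`
#' drawn binomially around `dosage/3` (adjusted by the error rate), and a
#' Phred-scaled site `QUAL`.  Coordinates are 1-based; the file round-trips
#' through [read_vcf()].
#'
#' @param truth A `clonal_truth` object.
#' @param rm A [read_model()].
#' @param path Output file path.
#' @param seed Integer seed; a fixed seed yields a byte-identical file.
#' @return `path`, invisibly.
#' @export
emit_vcf <- function(truth, rm = read_model(), path, seed = 1L) {
  stopifnot(inherits(truth, "clonal_truth"))
  sites <- variant_site_index(truth)
  reads <- simulate_read_counts(truth, rm, sites, seed = seed)
  ref <- truth$ref[sites, , drop = FALSE]
  samples <- rownames(truth$genotypes)

  bases <- c("A", "C", "G", "T")
  ref_allele <- bases[1L + (sites %% 4L)]
  alt_allele <- vapply(ref_allele, function(b) setdiff(bases, b)[1], "")

  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=clonalpop-synthdata",
    paste0("##contig=<ID=", unique(ref$contig), ">"),
    "##INFO=<ID=NS,Number=1,Type=Integer,Description=\"Number of samples with data\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Triploid genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )

  gt <- matrix(dosage_to_gt[truth$genotypes[, sites, drop = FALSE] + 1L],
               nrow = length(samples))
  body <- vapply(seq_along(sites), function(i) {
    cells <- sprintf("%s:%d:%d,%d", gt[, i], reads$DP[i, ],
                     reads$DP[i, ] - reads$AD[i, ], reads$AD[i, ])
    paste(c(ref$contig[i], ref$pos[i], ".", ref_allele[i], alt_allele[i],
            sprintf("%.1f", reads$qual[i]), "PASS",
            sprintf("NS=%d", length(samples)), "GT:DP:AD", cells),
          collapse = "\t")
  }, character(1))

  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Simulate a closed-population multi-day trap survey
#'
#' A closed population of `true_N` trappable (sexually mature) individuals is
#' exposed to baited traps for `n_days` consecutive days.  Each day each
#' individual is captured independently with probability
#' `1 - prod(1 - p_trap)` and assigned to one trap proportionally to the
#' per-trap probabilities; newly caught animals are marked and marks persist.
#' A hand-catch table supplies point densities (animals per square meter at
#' `n_hand_points` net-sampling points) and a size distribution whose
#' fraction above the 6 cm trap-size cutoff equals `mature_fraction` in
#' expectation.
#'
#' @param true_N Closed trappable population size.
#' @param n_days Number of consecutive trapping days (>= 2).
#' @param traps Data frame with columns `trap_id`, `stratum_id` and
#'   optionally `capture_prob`; or an integer number of traps in one stratum.
#' @param capture_prob_per_trap Default per-trap daily capture probability
#'   used when `traps` has no `capture_prob` column.
#' @param mature_fraction Fraction of the whole population above the 6 cm
#'   cutoff (used for the hand-catch size distribution).
#' @param hand_density_mean Mean hand-catch density, animals per square meter.
#' @param n_hand_points Number of hand-catch sampling points.
#' @param n_hand_sizes Number of measured animals in the size table.
#' @param seed Integer seed.
#' @return A list of class `trap_survey`: `days` (per-day, per-trap counts),
#'   `daily` (pooled per-day `C`, `M`, `R`, `new_marks`), `hand_catch`
#'   (densities and sizes), `true_N`, `mature_fraction`.
#' @export
generate_trap_survey <- function(true_N, n_days = 10L, traps = 18L,
                                 capture_prob_per_trap = 0.005,
                                 mature_fraction = 0.12,
                                 hand_density_mean = 2.1,
                                 n_hand_points = 3L, n_hand_sizes = 150L,
                                 seed = 1L) {
  true_N <- check_count(true_N)
  n_days <- check_count(n_days)
  if (n_days < 2L) stop("n_days must be >= 2", call. = FALSE)
  if (is.numeric(traps) && length(traps) == 1L) {
    traps <- data.frame(trap_id = paste0("T", seq_len(traps)),
                        stratum_id = "S1", stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(traps), all(c("trap_id", "stratum_id") %in%
                                        names(traps)))
  if (!"capture_prob" %in% names(traps)) {
    traps$capture_prob <- capture_prob_per_trap
  }
  if (any(traps$capture_prob < 0 | traps$capture_prob > 1)) {
    stop("capture probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (all(traps$capture_prob == 0)) {
    warning("all capture probabilities are zero: degenerate survey, no recaptures possible")
  }
  check_fraction(mature_fraction, strict = FALSE)

  p_any <- 1 - prod(1 - traps$capture_prob)
  trap_w <- if (p_any > 0) traps$capture_prob / sum(traps$capture_prob) else
    rep(1 / nrow(traps), nrow(traps))

  with_seed(seed, {
    marked <- logical(true_N)
    rows <- vector("list", n_days)
    daily <- data.frame(day = seq_len(n_days), C = 0L, M = 0L, R = 0L,
                        new_marks = 0L)
    for (d in seq_len(n_days)) {
      caught <- which(runif(true_N) < p_any)
      trap_of <- if (length(caught)) {
        sample.int(nrow(traps), length(caught), replace = TRUE, prob = trap_w)
      } else integer(0)
      was_marked <- marked[caught]
      daily$C[d] <- length(caught)
      daily$M[d] <- sum(marked)
      daily$R[d] <- sum(was_marked)
      daily$new_marks[d] <- sum(!was_marked)
      per_trap <- data.frame(
        day = d, trap_id = traps$trap_id, stratum_id = traps$stratum_id,
        catch = as.integer(tabulate(trap_of, nbins = nrow(traps))),
        new_marks = as.integer(tabulate(trap_of[!was_marked],
                                        nbins = nrow(traps))),
        recaptures = as.integer(tabulate(trap_of[was_marked],
                                         nbins = nrow(traps))),
        stringsAsFactors = FALSE)
      rows[[d]] <- per_trap
      marked[caught] <- TRUE
    }

    n_mat <- rbinom(1L, n_hand_sizes, mature_fraction)
    sizes <- c(pmax(6.05, rnorm(n_mat, 9, 1.5)),
               pmin(5.95, pmax(0.8, rnorm(n_hand_sizes - n_mat, 4, 1))))
    hand <- list(
      densities = data.frame(
        point = paste0("P", seq_len(n_hand_points)),
        density = rgamma_mean(n_hand_points, hand_density_mean, cv = 0.2)),
      sizes = round(sizes, 1)
    )

    structure(list(days = do.call(rbind, rows), daily = daily,
                   hand_catch = hand, true_N = true_N,
                   mature_fraction = mature_fraction, traps = traps),
              class = "trap_survey")
  })
}

rgamma_mean <- function(n, mean, cv) {
  shape <- 1 / cv^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

#' @method print trap_survey
#' @export
print.trap_survey <- function(x, ...) {
  cat(sprintf("Trap survey: %d days, %d traps, %d animals caught (%d distinct marked), %d recaptures\n",
              max(x$daily$day), nrow(x$traps), sum(x$daily$C),
              sum(x$daily$new_marks), sum(x$daily$R)))
  invisible(x)
}

#' Write the per-day, per-trap survey table as CSV
#'
#' Columns: `day, trap_id, stratum_id, catch, new_marks, recaptures`.
#'
#' @param survey A `trap_survey`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_survey_csv <- function(survey, path) {
  stopifnot(inherits(survey, "trap_survey"))
  utils::write.csv(survey$days, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a per-day, per-trap survey table from CSV
#'
#' Inverse of [write_survey_csv()]; pooled daily totals (`C`, `M`, `R`) are
#' rebuilt from the per-trap counts, with `M` accumulated from `new_marks`.
#'
#' @param path CSV with columns `day, trap_id, stratum_id, catch, new_marks,
#'   recaptures`.
#' @return A `trap_survey` (without hand-catch data or `true_N`).
#' @export
read_survey_csv <- function(path) {
  days <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("day", "trap_id", "stratum_id", "catch", "new_marks", "recaptures")
  if (!all(need %in% names(days))) {
    stop("survey CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  agg <- aggregate(days[c("catch", "new_marks", "recaptures")],
                   by = list(day = days$day), FUN = sum)
  agg <- agg[order(agg$day), ]
  daily <- data.frame(day = agg$day, C = agg$catch,
                      M = cumsum(c(0L, head(agg$new_marks, -1L))),
                      R = agg$recaptures, new_marks = agg$new_marks)
  traps <- unique(days[c("trap_id", "stratum_id")])
  structure(list(days = days, daily = daily, hand_catch = NULL,
                 true_N = NA_integer_, mature_fraction = NA_real_,
                 traps = traps),
            class = "trap_survey")
}

#' Write a toy GFF3 annotation for synthetic contigs
#'
#' Emits `gene`, `exon` and `CDS` features (1-based, inclusive) covering the
#' requested intervals, for testing SNV annotation.
#'
#' @param genes Data frame with columns `contig`, `start`, `end` and
#'   optionally `cds_start`, `cds_end` (defaults to the inner 60% of the
#'   gene).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_toy_gff <- function(genes, path) {
  stopifnot(all(c("contig", "start", "end") %in% names(genes)))
  if (!"cds_start" %in% names(genes)) {
    span <- genes$end - genes$start
    genes$cds_start <- floor(genes$start + 0.2 * span)
    genes$cds_end <- ceiling(genes$end - 0.2 * span)
  }
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    gid <- sprintf("gene%03d", i)
    lines <- c(lines,
      sprintf("%s\ttoy\tgene\t%d\t%d\t.\t+\t.\tID=%s", genes$contig[i],
              genes$start[i], genes$end[i], gid),
      sprintf("%s\ttoy\texon\t%d\t%d\t.\t+\t.\tID=%s.e1;Parent=%s",
              genes$contig[i], genes$start[i], genes$end[i], gid, gid),
      sprintf("%s\ttoy\tCDS\t%d\t%d\t.\t+\t0\tID=%s.c1;Parent=%s",
              genes$contig[i], genes$cds_start[i], genes$cds_end[i], gid, gid))
  }
  writeLines(lines, path)
  invisible(path)
}
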