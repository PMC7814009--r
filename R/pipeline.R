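#' Default configuration for the end-to-end pipeline
#'
#' @param seed Master seed recorded in every output's metadata.
#' @param out_dir Output directory for artifacts and the run report.
#' @return A nested list of class `run_config` with sections `simulate`
#'   (population/read/survey settings), `filters`, `vaf`, `growth` and
#'   `census`.
#' @export
default_run_config <- function(seed = 1L, out_dir = "clonalpop_run") {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    force = FALSE,
    simulate = list(
      n_populations = 2L, samples_per_population = 5L, n_sites = 8000L,
      private_snvs_per_population = 60L, private_snvs_per_sample = 15L,
      shared_snvs_all = 120L, reference_het_fraction = 0.2,
      mean_depth = 40, depth_dispersion = 0.05, error_rate = 0.001,
      survey = list(true_N = 2000L, n_days = 10L, n_traps = 18L,
                    capture_prob_per_trap = 2e-3, mature_fraction = 0.12)),
    filters = list(min_site_quality = 30, min_depth = 20, max_depth = 200),
    vaf = list(min_quality = 30, min_depth = 5, window_size = 100L,
               loh_delta = 0.10),
    census = list(n_boot = 2000L),
    growth = list(offspring_rate = 200, N_max = 192000, A = -3.1,
                  dt = 1 / 365, horizon = 6,
                  mu = 3.6e-9, G = 3511656756,
                  snv_per_specimen = 5864.5,
                  strategy = "cumulative")
  ), class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' Values present in the file override the defaults of
#' [default_run_config()]; missing values keep their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  user <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  merge_lists <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]])) {
        merge_lists(base[[nm]], over[[nm]])
      } else over[[nm]]
    }
    base
  }
  cfg <- merge_lists(unclass(default_run_config()), user)
  class(cfg) <- "run_config"
  cfg
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full synthetic-to-inference pipeline
#'
#' Executes the requested stages in order — `simulate` (reference, clonal
#' genotypes, VCF, trap survey), `variants` (read, filter, dosage recode,
#' sharing partition), `structure` (distances, neighbor-joining tree, PCA,
#' k-means row aggregation), `vaf` (windowed VAF tracks and LOH scan),
#' `census` (Schnabel, saturation fit, stratified extrapolation, bootstrap
#' SE) and `growth` (trajectories, variability curves, intersection times)
#' — writing each stage's tables under `config$out_dir` together with a
#' JSON run report recording the package version, seed, parameters and the
#' per-step filter counts.
#'
#' @param config A `run_config` (see [default_run_config()],
#'   [read_run_config()]).
#' @param stages Character vector of stages to run (default all).
#' @return The run report, invisibly (a nested list; also written as
#'   `run_report.json`).
#' @export
run_pipeline <- function(config = default_run_config(),
                         stages = c("simulate", "variants", "structure",
                                    "vaf", "census", "growth")) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  report_path <- file.path(config$out_dir, "run_report.json")
  if (file.exists(report_path) && !isTRUE(config$force)) {
    stop("output already exists in ", config$out_dir,
         " (set config$force = TRUE to overwrite)", call. = FALSE)
  }
  report <- list(package = "clonalpop",
                 version = as.character(utils::packageVersion("clonalpop")),
                 seed = config$seed, config = unclass(config))
  sim <- config$simulate

  ref <- generate_reference_profile(sim$n_sites, sim$reference_het_fraction,
                                    seed = config$seed)
  spec <- population_spec(sim$n_populations, sim$samples_per_population,
                          sim$n_sites, sim$private_snvs_per_population,
                          sim$private_snvs_per_sample, sim$shared_snvs_all,
                          sim$reference_het_fraction, seed = config$seed)
  truth <- generate_clonal_genotypes(spec, ref)
  rmod <- read_model(sim$mean_depth, sim$depth_dispersion, sim$error_rate)
  vcf_path <- file.path(config$out_dir, "synthetic.vcf")
  survey <- generate_trap_survey(sim$survey$true_N, sim$survey$n_days,
                                 sim$survey$n_traps,
                                 sim$survey$capture_prob_per_trap,
                                 sim$survey$mature_fraction,
                                 seed = config$seed + 1L)

  if ("simulate" %in% stages) {
    emit_vcf(truth, rmod, vcf_path, seed = config$seed + 2L)
    write_survey_csv(survey, file.path(config$out_dir, "survey.csv"))
    write_tsv(truth$events, file.path(config$out_dir, "truth_events.tsv"))
    report$simulate <- list(n_samples = nrow(truth$genotypes),
                            n_sites = ncol(truth$genotypes),
                            n_mutations = nrow(truth$events),
                            vcf = vcf_path)
  }

  mat <- NULL
  if (any(c("variants", "structure", "vaf") %in% stages)) {
    calls <- read_vcf(vcf_path)
    fcfg <- filter_config(config$filters$min_site_quality,
                          config$filters$min_depth,
                          config$filters$max_depth)
    filtered <- apply_filters(calls, fcfg, ref)
    mat <- recode_dosage(filtered)
    if ("variants" %in% stages) {
      part <- polymorphic_partition(mat, truth$groups)
      write_tsv(part$per_sample,
                file.path(config$out_dir, "snv_per_sample.tsv"))
      write_tsv(part$shared_by_k,
                file.path(config$out_dir, "snv_shared_by_k.tsv"))
      report$variants <- list(
        filter_counts = as.list(attr(filtered, "filter_counts")),
        per_sample = part$per_sample,
        n_polymorphic = part$n_polymorphic, n_fixed = part$n_fixed,
        venn = part$venn[c("A_shared", "B_shared", "both", "A_only",
                           "B_only", "union")])
    }
    if ("structure" %in% stages) {
      d <- pairwise_distance(mat, "euclidean")
      tree <- nj_tree(d)
      write_newick(tree, file.path(config$out_dir, "nj_tree.nwk"))
      p <- dosage_pca(mat)
      write_tsv(data.frame(sample = rownames(p$scores),
                           round(p$scores[, 1:min(4, ncol(p$scores))], 4)),
                file.path(config$out_dir, "pca_scores.tsv"))
      agg <- kmeans_row_aggregate(mat, k = min(50L, ncol(mat)),
                                  seed = config$seed)
      write_tsv(as.data.frame(round(unclass(agg), 3)),
                file.path(config$out_dir, "kmeans_centroids.tsv"))
      report$structure <- list(
        tree = "nj_tree.nwk",
        pca_variance_explained = round(p$variance_explained, 4))
    }
    if ("vaf" %in% stages) {
      vcfg <- vaf_config(config$vaf$min_quality, config$vaf$min_depth,
                         config$vaf$window_size, config$vaf$loh_delta)
      tracks <- do.call(rbind, lapply(filtered$samples, function(s) {
        loh_scan(vaf_track(calls, ref, s, vcfg), vcfg)
      }))
      write_tsv(tracks, file.path(config$out_dir, "vaf_track.tsv"))
      report$vaf <- list(n_windows = nrow(tracks),
                         n_flagged = sum(tracks$flagged))
    }
  }

  if ("census" %in% stages) {
    est <- schnabel(survey)
    cum_marked <- cumsum(survey$daily$new_marks)
    sat <- fit_saturation(survey$daily$day, cum_marked)
    strata <- lake_strata()
    total <- bootstrap_se(est, strata, survey$hand_catch, saturation = sat,
                          n_reps = config$census$n_boot,
                          seed = config$seed + 3L)
    report$census <- list(
      schnabel_N = est$N_hat, schnabel_SE = est$SE, sum_R = est$sum_R,
      saturation_a = sat$a, saturation_c = sat$c,
      mature_fraction = total$f, total_N = total$N_total,
      total_SE = total$SE)
  }

  if ("growth" %in% stages) {
    g <- config$growth
    gp <- growth_params(g$offspring_rate, g$N_max, g$A, g$dt,
                        horizon = g$horizon)
    vp <- variability_params(g$mu, g$G, g$snv_per_specimen,
                             current_N = g$N_max)
    v_target <- variability_current(vp)$value
    models <- c("exponential", "logistic", "allee")
    curves <- lapply(models, function(m) {
      variability_trajectory(simulate_growth(m, gp), vp,
                             strategy = g$strategy)
    })
    names(curves) <- models
    for (m in models) {
      write_tsv(curves[[m]][seq(1, nrow(curves[[m]]), by = 10L), ],
                file.path(config$out_dir, paste0("variability_", m, ".tsv")))
    }
    inter <- intersection_band("exponential", gp, vp, v_target,
                               strategy = g$strategy)
    report$growth <- list(strategy = g$strategy, v_target = v_target,
                          t_star = inter$t_star, band = inter$band)
  }

  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(report)
}
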