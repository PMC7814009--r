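#' Configuration for the windowed VAF / LOH scan
#'
#' Heterozygous reference positions are selected with strict thresholds
#' (quality > 30, coverage > 5 reads by default), averaged in windows of a
#' fixed count of heterozygous positions (default 10,000), and each window's
#' mean variant allele frequency is compared to its expectation from the
#' reference dosage (1/3 or 2/3 per site).  A window deviating by more than
#' `loh_delta` is flagged as a candidate loss-of-heterozygosity segment;
#' the default 0.10 is half the 1/3 - 2/3 gap.
#'
#' @param min_quality Minimum Phred site quality (strict `>`).
#' @param min_depth Minimum coverage in reads (strict `>`).
#' @param window_size Heterozygous positions per window.
#' @param loh_delta Absolute VAF deviation that flags a window, in (0, 0.5).
#' @return A list of class `vaf_config`.
#' @export
vaf_config <- function(min_quality = 30, min_depth = 5,
                       window_size = 10000L, loh_delta = 0.10) {
  window_size <- check_count(window_size)
  if (window_size < 1L) stop("window_size must be >= 1", call. = FALSE)
  check_fraction(loh_delta, lo = 0, hi = 0.5, strict = TRUE)
  structure(list(min_quality = min_quality, min_depth = min_depth,
                 window_size = window_size, loh_delta = loh_delta),
            class = "vaf_config")
}

#' Select heterozygous reference positions for VAF analysis
#'
#' Positions where the reference specimen's alternative-allele dosage is 1
#' or 2, with site quality strictly above `cfg$min_quality` and coverage
#' strictly above `cfg$min_depth`, sorted by (contig, position).
#'
#' @param ref A `reference_profile`.
#' @param cfg A [vaf_config()].
#' @return The subset of `ref` rows passing the filters, ordered by genome
#'   coordinate.
#' @export
select_het_positions <- function(ref, cfg = vaf_config()) {
  stopifnot(inherits(ref, "reference_profile"))
  keep <- ref$ref_dosage %in% c(1L, 2L) & ref$qual > cfg$min_quality &
    ref$depth > cfg$min_depth
  out <- ref[keep, , drop = FALSE]
  out[site_order(out$contig, out$pos), , drop = FALSE]
}

#' Variant allele frequency of a genotype call
#'
#' The ratio of the alternative-allele read count to the total read count at
#' a site.  Sites with zero depth have undefined VAF and return `NA`
#' (skipped upstream).
#'
#' @param alt_reads Alternative-allele read count(s).
#' @param depth Total read count(s).
#' @return Numeric VAF in `[0, 1]`, `NA` where `depth == 0`.
#' @export
vaf <- function(alt_reads, depth) {
  stopifnot(all(alt_reads <= depth, na.rm = TRUE),
            all(alt_reads >= 0, na.rm = TRUE))
  ifelse(depth > 0, alt_reads / depth, NA_real_)
}

#' Windowed mean VAF track over heterozygous positions
#'
#' Consecutive blocks of `cfg$window_size` heterozygous positions (count of
#' sites, not base pairs), never spanning a contig boundary; the final
#' partial block of each contig is retained with its actual site count.
#' Each window records the observed mean VAF and the expected mean
#' (reference dosage / 3 averaged over its sites).
#'
#' @param vaf_values Per-site VAF for one sample, aligned with `positions`.
#' @param positions Data frame with `contig`, `pos`, `ref_dosage` for the
#'   selected heterozygous positions (see [select_het_positions()]),
#'   ordered by coordinate.
#' @param cfg A [vaf_config()].
#' @param sample_id Label stored in the track.
#' @return A data frame of class `vaf_track` with one row per window:
#'   `sample`, `contig`, `start`, `end`, `n_sites`, `mean_vaf`,
#'   `expected_vaf`, `partial`.
#' @export
windowed_vaf <- function(vaf_values, positions, cfg = vaf_config(),
                         sample_id = "sample") {
  stopifnot(length(vaf_values) == nrow(positions))
  ok <- !is.na(vaf_values)
  if (!any(ok)) {
    warning("no valid VAF positions: empty track")
    out <- data.frame(sample = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      n_sites = integer(0), mean_vaf = numeric(0),
                      expected_vaf = numeric(0), partial = logical(0))
    class(out) <- c("vaf_track", "data.frame")
    return(out)
  }
  positions <- positions[ok, , drop = FALSE]
  vaf_values <- vaf_values[ok]
  rows <- list()
  for (ctg in unique(positions$contig)) {
    sel <- positions$contig == ctg
    v <- vaf_values[sel]
    p <- positions$pos[sel]
    ed <- positions$ref_dosage[sel] / 3
    n <- length(v)
    starts <- seq(1L, n, by = cfg$window_size)
    for (s in starts) {
      e <- min(s + cfg$window_size - 1L, n)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sample_id, contig = ctg,
        start = p[s], end = p[e], n_sites = e - s + 1L,
        mean_vaf = mean(v[s:e]), expected_vaf = mean(ed[s:e]),
        partial = (e - s + 1L) < cfg$window_size,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("vaf_track", "data.frame")
  out
}

#' Build a windowed VAF track for one sample straight from variant calls
#'
#' Convenience wrapper: restricts `calls` to the selected heterozygous
#' reference positions, computes per-site VAF from `AD_alt / DP`, and
#' windows it with [windowed_vaf()].
#'
#' @param calls A `variant_calls` object.
#' @param ref A `reference_profile`.
#' @param sample_id Sample column of `calls` to use.
#' @param cfg A [vaf_config()].
#' @return A `vaf_track` data frame.
#' @export
vaf_track <- function(calls, ref, sample_id, cfg = vaf_config()) {
  stopifnot(inherits(calls, "variant_calls"),
            sample_id %in% calls$samples)
  het <- select_het_positions(ref, cfg)
  key <- site_key(calls$sites$contig, calls$sites$pos)
  idx <- match(site_key(het$contig, het$pos), key)
  present <- !is.na(idx)
  v <- rep(NA_real_, nrow(het))
  v[present] <- vaf(calls$AD_alt[idx[present], sample_id],
                    calls$DP[idx[present], sample_id])
  windowed_vaf(v, het[, c("contig", "pos", "ref_dosage")], cfg,
               sample_id = sample_id)
}

#' Scan a VAF track for loss-of-heterozygosity windows
#'
#' Flags windows whose observed mean VAF deviates from the expected mean by
#' more than `cfg$loh_delta`, reporting the deviation magnitude and
#' direction.
#'
#' @param track A `vaf_track`.
#' @param cfg A [vaf_config()].
#' @return The track with added columns `deviation` (observed - expected)
#'   and `flagged`.
#' @export
loh_scan <- function(track, cfg = vaf_config()) {
  stopifnot(inherits(track, "vaf_track"))
  track$deviation <- track$mean_vaf - track$expected_vaf
  track$flagged <- abs(track$deviation) > cfg$loh_delta
  track
}

#' @method print vaf_track
#' @export
print.vaf_track <- function(x, ...) {
  cat(sprintf("VAF track: %d window(s) over %d contig(s), %d het sites total\n",
              nrow(x), length(unique(x$contig)), sum(x$n_sites)))
  if ("flagged" %in% names(x)) {
    cat(sprintf("  %d window(s) flagged as candidate LOH\n", sum(x$flagged)))
  }
  invisible(x)
}

#' @method plot vaf_track
#' @export
plot.vaf_track <- function(x, ...) {
  mid <- (x$start + x$end) / 2
  plot(mid, x$mean_vaf, type = "l", ylim = c(0, 1),
       xlab = "position", ylab = "mean VAF per window", ...)
  lines(mid, x$expected_vaf, lty = 2, col = "red")
  legend("topright", c("observed", "expected"), lty = c(1, 2),
         col = c("black", "red"), bty = "n")
  invisible(x)
}
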