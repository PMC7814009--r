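#' Filtering thresholds for variant sites
#'
#' Defaults follow the pipeline's hard filters: a minimum read depth of 20
#' and a maximum of 200 required for each sample, and a minimum Phred-scaled
#' site quality of 30.  Sites not covered in the reference specimen and
#' sites heterozygous in the reference are removed, restricting the analysis
#' of polymorphic sites to reference-homozygous loci.
#'
#' @param min_site_quality Minimum Phred-scaled record quality (inclusive).
#' @param min_depth,max_depth Per-sample read-depth bounds (inclusive).
#' @param require_reference_coverage Drop sites absent from (or uncovered
#'   in) the reference profile.
#' @param drop_reference_het Drop sites heterozygous in the reference.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(min_site_quality = 30, min_depth = 20,
                          max_depth = 200, require_reference_coverage = TRUE,
                          drop_reference_het = TRUE) {
  if (!(min_depth > 0 && min_depth <= max_depth)) {
    stop("need 0 < min_depth <= max_depth", call. = FALSE)
  }
  structure(list(min_site_quality = min_site_quality, min_depth = min_depth,
                 max_depth = max_depth,
                 require_reference_coverage = isTRUE(require_reference_coverage),
                 drop_reference_het = isTRUE(drop_reference_het)),
            class = "filter_config")
}

#' Read per-sample variant calls from a VCF file
#'
#' Parses a VCF v4.2 file (via \pkg{vcfR}) with triploid `GT`, `DP` and `AD`
#' FORMAT fields into a tabular call set.  Multi-allelic records are split
#' into one row per alternative allele; records whose REF or ALT is not a
#' single base are kept but flagged `is_snv = FALSE`.  Coordinates stay
#' 1-based.
#'
#' @param path Path to a VCF file.
#' @return A list of class `variant_calls`: `sites` (data frame with
#'   `contig`, `pos`, `ref`, `alt`, `qual`, `is_snv`), and sites x samples
#'   matrices `GT` (genotype strings), `DP` (total depth) and `AD_alt`
#'   (reads supporting the row's alternative allele).
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("no such VCF file: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  samples <- colnames(v@gt)[-1L]
  n <- nrow(fix)
  if (n == 0L) {
    return(structure(list(
      sites = data.frame(contig = character(0), pos = integer(0),
                         ref = character(0), alt = character(0),
                         qual = numeric(0), is_snv = logical(0)),
      GT = matrix(character(0), 0, length(samples),
                  dimnames = list(NULL, samples)),
      DP = matrix(numeric(0), 0, length(samples),
                  dimnames = list(NULL, samples)),
      AD_alt = matrix(numeric(0), 0, length(samples),
                      dimnames = list(NULL, samples)),
      samples = samples), class = "variant_calls"))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP",
                                          as.numeric = TRUE))
  ad <- vcfR::extract.gt(v, element = "AD")
  if (is.null(gt) || is.null(dp) || is.null(ad)) {
    stop("VCF is missing required FORMAT fields GT/DP/AD", call. = FALSE)
  }
  gt <- matrix(gt, nrow = n); dp <- matrix(dp, nrow = n)
  ad <- matrix(ad, nrow = n)

  out_sites <- vector("list", n)
  out_rows <- vector("list", n)
  for (i in seq_len(n)) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    ad_i <- strsplit(ad[i, ], ",", fixed = TRUE)
    for (k in seq_along(alts)) {
      is_snv <- nchar(fix$REF[i]) == 1L && nchar(alts[k]) == 1L &&
        alts[k] %in% c("A", "C", "G", "T")
      out_sites[[i]][[k]] <- data.frame(
        contig = fix$CHROM[i], pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts[k],
        qual = suppressWarnings(as.numeric(fix$QUAL[i])),
        is_snv = is_snv, stringsAsFactors = FALSE)
      ad_alt <- vapply(ad_i, function(x) {
        if (length(x) >= k + 1L) suppressWarnings(as.numeric(x[k + 1L]))
        else NA_real_
      }, numeric(1))
      out_rows[[i]][[k]] <- list(GT = gt[i, ], DP = dp[i, ], AD = ad_alt,
                                 allele = k)
    }
  }
  sites <- do.call(rbind, lapply(out_sites, function(x) do.call(rbind, x)))
  rows <- unlist(out_rows, recursive = FALSE)
  GT <- do.call(rbind, lapply(rows, `[[`, "GT"))
  DP <- do.call(rbind, lapply(rows, `[[`, "DP"))
  AD <- do.call(rbind, lapply(rows, `[[`, "AD"))
  allele_of <- vapply(rows, `[[`, numeric(1), "allele")
  dimnames(GT) <- dimnames(DP) <- dimnames(AD) <- list(NULL, samples)
  rownames(sites) <- NULL
  structure(list(sites = sites, GT = GT, DP = DP, AD_alt = AD,
                 allele_index = allele_of, samples = samples),
            class = "variant_calls")
}

#' @method print variant_calls
#' @export
print.variant_calls <- function(x, ...) {
  cat(sprintf("Variant calls: %d site records (%d SNV) x %d samples\n",
              nrow(x$sites), sum(x$sites$is_snv), length(x$samples)))
  invisible(x)
}

subset_calls <- function(calls, keep) {
  calls$sites <- calls$sites[keep, , drop = FALSE]
  rownames(calls$sites) <- NULL
  calls$GT <- calls$GT[keep, , drop = FALSE]
  calls$DP <- calls$DP[keep, , drop = FALSE]
  calls$AD_alt <- calls$AD_alt[keep, , drop = FALSE]
  calls$allele_index <- calls$allele_index[keep]
  calls
}

#' Apply site and sample filters to variant calls
#'
#' Retains only single-nucleotide substitutions whose record quality meets
#' `min_site_quality` and whose read depth lies within
#' `[min_depth, max_depth]` for every sample.  When a reference profile is
#' supplied, sites not covered in the reference are removed and (by default)
#' so are sites heterozygous in the reference, restricting polymorphic-site
#' calculation to reference-homozygous loci.  Filtering is total (never
#' errors) and idempotent.
#'
#' @param calls A `variant_calls` object.
#' @param cfg A [filter_config()].
#' @param ref Optional `reference_profile`.
#' @return The filtered `variant_calls`, with an attribute
#'   `filter_counts` recording how many records each step removed.
#' @export
apply_filters <- function(calls, cfg = filter_config(), ref = NULL) {
  stopifnot(inherits(calls, "variant_calls"), inherits(cfg, "filter_config"))
  counts <- c(input = nrow(calls$sites))

  keep <- calls$sites$is_snv
  counts["non_snv_removed"] <- sum(!keep)
  calls <- subset_calls(calls, keep)

  keep <- !is.na(calls$sites$qual) & calls$sites$qual >= cfg$min_site_quality
  counts["low_quality_removed"] <- sum(!keep)
  calls <- subset_calls(calls, keep)

  dp_ok <- calls$DP >= cfg$min_depth & calls$DP <= cfg$max_depth
  keep <- apply(dp_ok & !is.na(dp_ok), 1L, all)
  counts["depth_removed"] <- sum(!keep)
  calls <- subset_calls(calls, keep)

  if (!is.null(ref)) {
    ref_key <- site_key(ref$contig, ref$pos)
    idx <- match(site_key(calls$sites$contig, calls$sites$pos), ref_key)
    if (cfg$require_reference_coverage) {
      keep <- !is.na(idx) & ref$covered[idx]
      counts["uncovered_in_reference_removed"] <- sum(!keep)
      calls <- subset_calls(calls, keep)
      idx <- idx[keep]
    }
    if (cfg$drop_reference_het) {
      keep <- is.na(idx) | !ref$het[idx]
      counts["reference_het_removed"] <- sum(!keep)
      calls <- subset_calls(calls, keep)
    }
  }
  counts["retained"] <- nrow(calls$sites)
  attr(calls, "filter_counts") <- counts
  calls
}

#' Recode triploid genotypes to alternative-allele dosage
#'
#' Each triploid genotype is mapped to the integer count of its row's
#' alternative allele: `0/0/0 -> 0`, `0/0/1 -> 1`, `0/1/1 -> 2`,
#' `1/1/1 -> 3`.  Missing genotypes become `NA` (the designated missing
#' code), recorded in the matrix rather than imputed.
#'
#' @param calls A `variant_calls` object (typically filtered).
#' @return An integer samples x sites matrix of class `genotype_matrix`,
#'   with column names `contig:pos` sorted by (contig, position) and an
#'   attribute `sites` holding the site table.
#' @export
recode_dosage <- function(calls) {
  stopifnot(inherits(calls, "variant_calls"))
  n <- nrow(calls$sites)
  keys <- site_key(calls$sites$contig, calls$sites$pos)
  allele <- as.character(if (is.null(calls$allele_index)) rep(1L, n)
                         else calls$allele_index)
  dos <- matrix(NA_integer_, nrow = length(calls$samples), ncol = n,
                dimnames = list(calls$samples, keys))
  for (i in seq_len(n)) {
    parts <- strsplit(calls$GT[i, ], "[/|]")
    dos[, i] <- vapply(parts, function(g) {
      if (length(g) == 1L && (is.na(g) || g %in% c(".", ""))) {
        return(NA_integer_)
      }
      if (length(g) != 3L) {
        stop("genotype ploidy is not 3: ", paste(g, collapse = "/"),
             call. = FALSE)
      }
      if (any(g == ".")) return(NA_integer_)
      sum(g == allele[i])
    }, integer(1))
  }
  ord <- site_order(calls$sites$contig, calls$sites$pos)
  dos <- dos[, ord, drop = FALSE]
  structure(dos, sites = calls$sites[ord, , drop = FALSE],
            class = c("genotype_matrix", class(dos)))
}

#' Partition SNV sharing across samples and groups
#'
#' A site is a polymorphic SNV for a sample when its dosage is greater than
#' zero (presence/absence; dosage values are not compared).  Reports
#' per-sample SNV and unique-SNV counts, the number of sites shared by
#' exactly `k` samples, the number fixed in all samples, and — when `groups`
#' labels exactly two cohorts — the two-set Venn of group-shared sites
#' (sites present in every member of a group).
#'
#' @param mat A `genotype_matrix` (samples x sites dosage).
#' @param groups Optional named character vector, `names = sample ids`,
#'   giving each sample's cohort.
#' @return A list of class `snv_partition`: `per_sample`, `shared_by_k`,
#'   `n_polymorphic`, `n_fixed`, and `venn` (when two groups are given:
#'   `A_shared`, `B_shared`, `both`, `A_only`, `B_only`, `union`).
#' @export
polymorphic_partition <- function(mat, groups = NULL) {
  stopifnot(is.matrix(mat), nrow(mat) >= 1L)
  pres <- !is.na(mat) & mat > 0L
  poly <- colSums(pres) > 0L
  n_poly <- sum(poly)
  k_count <- colSums(pres)[poly]

  per_sample <- data.frame(
    sample = rownames(mat),
    n_snv = rowSums(pres),
    n_unique = vapply(seq_len(nrow(mat)), function(i) {
      sum(pres[i, ] & colSums(pres) == 1L)
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)

  shared_by_k <- as.data.frame(table(factor(k_count,
                                            levels = seq_len(nrow(mat)))),
                               stringsAsFactors = FALSE)
  names(shared_by_k) <- c("k", "n_sites")
  shared_by_k$k <- as.integer(shared_by_k$k)

  out <- list(per_sample = per_sample, shared_by_k = shared_by_k,
              n_polymorphic = n_poly,
              n_fixed = sum(k_count == nrow(mat)))

  if (!is.null(groups)) {
    if (!all(rownames(mat) %in% names(groups))) {
      stop("groups must name every sample in the matrix", call. = FALSE)
    }
    g <- groups[rownames(mat)]
    lv <- unique(g)
    if (length(lv) == 2L) {
      shared_in <- function(lab) colSums(pres[g == lab, , drop = FALSE]) ==
        sum(g == lab)
      a <- shared_in(lv[1]); b <- shared_in(lv[2])
      out$venn <- list(groups = lv,
                       A_shared = sum(a), B_shared = sum(b),
                       both = sum(a & b),
                       A_only = sum(a & !b), B_only = sum(b & !a),
                       union = sum(a | b))
    }
  }
  class(out) <- "snv_partition"
  out
}

#' @method print snv_partition
#' @export
print.snv_partition <- function(x, ...) {
  cat(sprintf("SNV sharing partition: %d polymorphic sites, %d fixed in all samples\n",
              x$n_polymorphic, x$n_fixed))
  cat(sprintf("  per-sample SNV counts: %s\n",
              paste(sprintf("%s=%d", x$per_sample$sample, x$per_sample$n_snv),
                    collapse = ", ")))
  if (!is.null(x$venn)) {
    cat(sprintf("  group-shared Venn (%s | %s): %d | %d shared, %d in both, union %d\n",
                x$venn$groups[1], x$venn$groups[2], x$venn$A_shared,
                x$venn$B_shared, x$venn$both, x$venn$union))
  }
  invisible(x)
}
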