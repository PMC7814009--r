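#' Annotate SNVs by genic context and base-change spectrum
#'
#' Classifies each SNV as `coding` (inside a CDS), `intronic` (inside a gene
#' but outside all exons), `exon_noncoding` (inside an exon but outside all
#' CDS, i.e. UTR or non-coding exon) or `intergenic`, by interval overlap
#' against a GFF3 annotation (1-based inclusive coordinates honoured at
#' parse).  Also tabulates the base-change spectrum over the 12 ordered
#' substitutions with transition/transversion totals.
#'
#' @param sites Data frame with columns `contig`, `pos`, `ref`, `alt`
#'   (e.g. the `sites` element of a `variant_calls`, restricted to SNVs).
#' @param gff Path to a GFF3 file with `gene`/`exon`/`CDS` features.
#' @return A list of class `snv_annotation`: `category` (factor per SNV),
#'   `summary` (counts and fractions per category), `spectrum` (counts per
#'   ordered substitution), `transitions`, `transversions`,
#'   `n_contig_mismatch`.
#' @export
annotate_snvs <- function(sites, gff) {
  for (pkg in c("rtracklayer", "GenomicRanges", "IRanges", "S4Vectors")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      stop("package '", pkg, "' is required for annotate_snvs()",
           call. = FALSE)
    }
  }
  stopifnot(all(c("contig", "pos") %in% names(sites)))
  ann <- rtracklayer::import(gff)
  snv <- GenomicRanges::GRanges(sites$contig,
                                IRanges::IRanges(sites$pos, sites$pos))

  mism <- !(sites$contig %in% as.character(
    GenomicRanges::seqnames(ann)@values))
  if (any(mism)) {
    warning(sum(mism), " SNV(s) on contigs absent from the annotation; ",
            "classified intergenic by default")
  }
  in_feat <- function(type) {
    feat <- ann[ann$type == type]
    # mismatched contigs already warned about above; silence the
    # seqlevel chatter from the overlap engine
    suppressWarnings(
      GenomicRanges::countOverlaps(snv, feat, ignore.strand = TRUE) > 0L)
  }
  in_cds <- in_feat("CDS")
  in_exon <- in_feat("exon")
  in_gene <- in_feat("gene")
  category <- factor(ifelse(in_cds, "coding",
                     ifelse(in_exon, "exon_noncoding",
                     ifelse(in_gene, "intronic", "intergenic"))),
                     levels = c("coding", "exon_noncoding", "intronic",
                                "intergenic"))

  summary <- data.frame(category = levels(category),
                        n = as.vector(table(category)))
  summary$fraction <- if (nrow(sites)) summary$n / nrow(sites) else NA_real_

  spectrum <- NULL; transitions <- NA_integer_; transversions <- NA_integer_
  if (all(c("ref", "alt") %in% names(sites))) {
    bases <- c("A", "C", "G", "T")
    combos <- expand.grid(ref = bases, alt = bases,
                          stringsAsFactors = FALSE)
    combos <- combos[combos$ref != combos$alt, ]
    sub <- paste0(sites$ref, ">", sites$alt)
    spectrum <- data.frame(substitution = paste0(combos$ref, ">", combos$alt))
    spectrum$n <- vapply(spectrum$substitution,
                         function(s) sum(sub == s), numeric(1))
    is_ts <- sub %in% c("A>G", "G>A", "C>T", "T>C")
    transitions <- sum(is_ts)
    transversions <- nrow(sites) - transitions
  }
  structure(list(category = category, summary = summary, spectrum = spectrum,
                 transitions = transitions, transversions = transversions,
                 n_contig_mismatch = sum(mism)),
            class = "snv_annotation")
}

#' @method print snv_annotation
#' @export
print.snv_annotation <- function(x, ...) {
  cat("SNV annotation summary:\n")
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-15s %6d  (%.1f%%)\n", x$summary$category[i],
                x$summary$n[i], 100 * x$summary$fraction[i]))
  }
  if (!is.na(x$transitions)) {
    cat(sprintf("  transitions %d, transversions %d (Ts/Tv = %.2f)\n",
                x$transitions, x$transversions,
                x$transitions / max(1, x$transversions)))
  }
  invisible(x)
}
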