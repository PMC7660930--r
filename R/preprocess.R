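#' Quality-control filter for a genotype panel
#'
#' Removes SNPs with minor allele frequency below `maf_min`, strand-ambiguous
#' SNPs (complementary allele pairs A/T and C/G; indels are never treated as
#' ambiguous), and monomorphic (constant-dosage) SNPs. Missing dosages are
#' mean-imputed per SNP before the monomorphism check, so the returned panel
#' contains no missing values and no constant column. Sample order is
#' unchanged. The operation is idempotent.
#'
#' @param panel A [genotype_panel()].
#' @param maf_min Minimum minor allele frequency to retain (default 0.01).
#' @return A filtered `tgen_panel`.
#' @export
qc_filter <- function(panel, maf_min = 0.01) {
  stopifnot(inherits(panel, "tgen_panel"))
  if (n_snps(panel) == 0) stop("empty panel: no SNPs to filter")
  dos <- panel$dosages
  # per-SNP mean imputation of missing dosages
  miss <- which(colSums(is.na(dos)) > 0)
  for (j in miss) {
    nas <- is.na(dos[, j])
    mj <- if (all(nas)) 0 else mean(dos[!nas, j])
    dos[nas, j] <- mj
  }
  af <- colMeans(dos) / 2
  maf <- pmin(af, 1 - af)
  ambiguous <- is_ambiguous_pair(panel$snps$ref, panel$snps$alt)
  constant <- apply(dos, 2, function(x) max(x) - min(x) == 0)
  keep <- which(maf >= maf_min & !ambiguous & !constant)
  if (length(keep) == 0) stop("empty panel: all SNPs removed by QC")
  snps <- panel$snps[keep, , drop = FALSE]
  snps$maf <- unname(maf[keep])
  genotype_panel(dos[, keep, drop = FALSE], snps, panel$sample_ids)
}

# strand-ambiguous = complementary single-base pairs; indels never ambiguous
is_ambiguous_pair <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  (ref == "A" & alt == "T") | (ref == "T" & alt == "A") |
    (ref == "C" & alt == "G") | (ref == "G" & alt == "C")
}

#' Restrict a panel to a gene's cis window
#'
#' Retains SNPs on the gene's chromosome with position in
#' `[tss - window_bp, tes + window_bp]`, both ends inclusive.
#'
#' @param panel A [genotype_panel()].
#' @param gene A [gene_info()].
#' @param window_bp Window size in base pairs beyond the TSS/TES (default
#'   1e6, i.e. 1 Mb).
#' @return A `tgen_panel` restricted to the cis window; empty (with a warning)
#'   when the chromosome is absent from the panel.
#' @export
cis_snps <- function(panel, gene, window_bp = 1e6) {
  stopifnot(inherits(panel, "tgen_panel"), inherits(gene, "tgen_gene"),
            window_bp >= 0)
  if (!gene$chrom %in% panel$snps$chrom) {
    warning("chromosome ", gene$chrom, " absent from panel; empty cis set for ",
            gene$gene_id)
    return(panel_subset(panel, integer(0)))
  }
  lo <- gene$tss - window_bp
  hi <- gene$tes + window_bp
  keep <- which(panel$snps$chrom == gene$chrom &
                  panel$snps$pos >= lo & panel$snps$pos <= hi)
  panel_subset(panel, keep)
}

#' Significance-mask an annotation matrix
#'
#' Epigenetic signal values are only trusted where the underlying peak or
#' methylation call is significant; entries whose signal p-value is at or
#' above `alpha` are set to 0 and flagged as masked, the rest keep their raw
#' continuous values (fold enrichments or methylation fractions).
#'
#' @param raw_values Non-negative p x m matrix of continuous annotation values.
#' @param signal_pvalues p x m matrix of per-entry signal p-values.
#' @param alpha Significance threshold (default 1e-2).
#' @param standardize Optionally z-standardize each unmasked track column
#'   after masking (default `FALSE`; raw values are used as-is).
#' @return A [annotation_matrix()].
#' @export
mask_annotations <- function(raw_values, signal_pvalues, alpha = 1e-2,
                             standardize = FALSE) {
  raw_values <- as.matrix(raw_values)
  signal_pvalues <- as.matrix(signal_pvalues)
  if (!identical(dim(raw_values), dim(signal_pvalues))) {
    stop("raw_values and signal_pvalues shapes differ")
  }
  if (any(raw_values < 0)) stop("annotation values must be non-negative")
  masked <- signal_pvalues >= alpha
  values <- raw_values
  values[masked] <- 0
  if (standardize && ncol(values) > 0) {
    # scale (not centre) each track so values stay non-negative and masked
    # entries stay exactly zero
    values <- apply(values, 2, function(x) {
      s <- sd(x)
      if (s == 0) x else x / s
    })
  }
  annotation_matrix(values, colnames(raw_values), masked)
}

#' Join interval annotation tracks onto a panel's SNPs
#'
#' Maps BED-style intervals (0-based half-open, already converted to 1-based
#' inclusive by [read_annotation_bed()]) onto SNP positions. A SNP takes, per
#' track, the maximum value over all overlapping intervals and the most
#' significant (smallest) of their signal p-values; SNPs with no overlapping
#' interval get value 0 and p-value 1. The result is then significance-masked
#' via [mask_annotations()].
#'
#' @param panel A [genotype_panel()].
#' @param tracks Tibble of intervals with columns `chrom`, `start`, `end`
#'   (1-based inclusive), `track`, `value`, `pvalue`.
#' @param alpha Masking threshold passed to [mask_annotations()].
#' @return A [annotation_matrix()] with rows in panel SNP order.
#' @export
annotate_panel <- function(panel, tracks, alpha = 1e-2) {
  stopifnot(inherits(panel, "tgen_panel"))
  tracks <- tibble::as_tibble(tracks)
  track_names <- sort(unique(tracks$track))
  p <- n_snps(panel)
  values <- matrix(0, p, length(track_names), dimnames = list(NULL, track_names))
  pvals <- matrix(1, p, length(track_names), dimnames = list(NULL, track_names))
  for (tn in track_names) {
    tr <- tracks[tracks$track == tn, ]
    for (chr in unique(tr$chrom)) {
      on_chr <- which(panel$snps$chrom == chr)
      if (length(on_chr) == 0) next
      trc <- tr[tr$chrom == chr, ]
      hits <- IRanges::findOverlaps(
        IRanges::IRanges(start = panel$snps$pos[on_chr], width = 1L),
        IRanges::IRanges(start = as.integer(trc$start), end = as.integer(trc$end)))
      if (length(hits) == 0) next
      qi <- S4Vectors::queryHits(hits)
      si <- S4Vectors::subjectHits(hits)
      for (g in split(seq_along(qi), qi)) {
        row <- on_chr[qi[g[1]]]
        values[row, tn] <- max(trc$value[si[g]])
        pvals[row, tn] <- min(trc$pvalue[si[g]])
      }
    }
  }
  mask_annotations(values, pvals, alpha = alpha)
}
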