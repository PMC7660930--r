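#' Genotype panel
#'
#' A sample-by-SNP dosage matrix with per-SNP metadata. Dosages count copies
#' of the alternative (effect) allele, so values lie in \[0, 2\]; missing
#' dosages are allowed before [qc_filter()] mean-imputes them.
#'
#' @param dosages Numeric n x p matrix of dosages in \[0, 2\] (NA allowed).
#' @param snps Data frame with one row per SNP: `snp_id`, `chrom`, `pos`
#'   (1-based), `ref`, `alt`, and optionally `maf`. When `maf` is absent it is
#'   computed from the dosages (minor-allele folded, so in \[0, 0.5\]).
#' @param sample_ids Character vector of sample identifiers, one per row.
#'
#' @return An object of class `tgen_panel`: a list with elements `dosages`
#'   (matrix), `snps` (tibble), `sample_ids`.
#' @export
#' @examples
#' p <- genotype_panel(matrix(c(0, 1, 2, 1), 2, 2),
#'                     data.frame(snp_id = c("s1", "s2"), chrom = "1",
#'                                pos = c(100L, 200L), ref = "A", alt = "G"),
#'                     c("ind1", "ind2"))
#' n_snps(p)
genotype_panel <- function(dosages, snps, sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  snps <- tibble::as_tibble(snps)
  required <- c("snp_id", "chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(required, names(snps))
  if (length(missing_cols) > 0) {
    stop("snps table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(sample_ids)) {
    sample_ids <- rownames(dosages) %||% paste0("sample_", seq_len(nrow(dosages)))
  }
  if (nrow(dosages) != length(sample_ids)) {
    stop("dosage row count (", nrow(dosages), ") != number of samples (",
         length(sample_ids), ")")
  }
  if (ncol(dosages) != nrow(snps)) {
    stop("dosage column count (", ncol(dosages), ") != number of SNPs (",
         nrow(snps), ")")
  }
  if (length(dosages) > 0 && !all(is.na(dosages))) {
    rng <- range(dosages, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2]")
  }
  snps$chrom <- as.character(snps$chrom)
  snps$pos <- as.integer(snps$pos)
  if (any(snps$pos < 1L)) stop("SNP positions must be 1-based (>= 1)")
  if (any(!nzchar(snps$ref)) || any(!nzchar(snps$alt)) ||
      any(snps$ref == snps$alt)) {
    stop("alleles must be non-empty and distinct")
  }
  if (!"maf" %in% names(snps)) {
    af <- colMeans(dosages, na.rm = TRUE) / 2
    snps$maf <- unname(pmin(af, 1 - af))
  }
  if (any(snps$maf < 0 | snps$maf > 0.5, na.rm = TRUE)) {
    stop("maf must lie in [0, 0.5]")
  }
  dimnames(dosages) <- list(sample_ids, snps$snp_id)
  structure(list(dosages = dosages, snps = snps,
                 sample_ids = as.character(sample_ids)),
            class = "tgen_panel")
}

#' @rdname genotype_panel
#' @param x,object A `tgen_panel`.
#' @export
n_snps <- function(x) nrow(x$snps)

#' @rdname genotype_panel
#' @export
n_samples <- function(x) length(x$sample_ids)

#' @rdname genotype_panel
#' @param ... Unused.
#' @export
print.tgen_panel <- function(x, ...) {
  cat("<tgen_panel> ", n_samples(x), " samples x ", n_snps(x), " SNPs\n", sep = "")
  cat("  chrom: ", paste(unique(x$snps$chrom), collapse = ", "),
      "; pos ", min(x$snps$pos), "-", max(x$snps$pos), "\n", sep = "")
  invisible(x)
}

# subset a panel to SNP indices, keeping metadata in step
panel_subset <- function(panel, idx) {
  genotype_panel(panel$dosages[, idx, drop = FALSE],
                 panel$snps[idx, , drop = FALSE],
                 panel$sample_ids)
}

#' Gene annotation record
#'
#' Genomic coordinates defining a gene's cis window. `tss` and `tes` are stored
#' on genomic coordinates, so `tss <= tes` regardless of strand.
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome name, matching the panel's `chrom` values.
#' @param tss,tes 1-based transcription start/end positions (genomic order).
#' @param strand `"+"` or `"-"`.
#' @return A `tgen_gene` list.
#' @export
gene_info <- function(gene_id, chrom, tss, tes, strand = "+") {
  tss <- as.integer(tss); tes <- as.integer(tes)
  if (tss > tes) stop("tss must be <= tes on genomic coordinates")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  structure(list(gene_id = as.character(gene_id), chrom = as.character(chrom),
                 tss = tss, tes = tes, strand = strand),
            class = "tgen_gene")
}

#' Covariate-adjusted expression for one gene
#'
#' @param gene_id Gene identifier.
#' @param values Numeric vector of residual (pre-adjusted) expression values.
#' @param sample_ids Sample identifiers matching the paired genotype panel
#'   order.
#' @return A `tgen_expression` list.
#' @export
expression_vector <- function(gene_id, values, sample_ids = NULL) {
  values <- as.numeric(values)
  if (is.null(sample_ids)) sample_ids <- names(values) %||% paste0("sample_", seq_along(values))
  if (length(values) != length(sample_ids)) {
    stop("expression length (", length(values), ") != number of samples (",
         length(sample_ids), ")")
  }
  structure(list(gene_id = as.character(gene_id), values = values,
                 sample_ids = as.character(sample_ids)),
            class = "tgen_expression")
}

#' SNP-by-track annotation matrix
#'
#' Continuous epigenetic values (fold enrichments, methylation fractions) for
#' each SNP on each track, with a parallel logical matrix marking entries
#' zeroed by significance masking (see [mask_annotations()]).
#'
#' @param values Non-negative p x m numeric matrix; rows follow the paired
#'   panel's SNP order.
#' @param track_names Track (annotation category) names, length m.
#' @param masked Logical p x m matrix; masked entries must hold value 0.
#'   Defaults to all-`FALSE`.
#' @return A `tgen_annotation` list.
#' @export
annotation_matrix <- function(values, track_names = NULL, masked = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(values < 0)) stop("annotation values must be non-negative")
  if (is.null(track_names)) {
    track_names <- colnames(values) %||%
      (if (ncol(values) > 0) paste0("track_", seq_len(ncol(values))) else character())
  }
  if (length(track_names) != ncol(values)) stop("track_names length != ncol(values)")
  if (is.null(masked)) masked <- matrix(FALSE, nrow(values), ncol(values))
  masked <- as.matrix(masked)
  if (!identical(dim(masked), dim(values))) stop("masked and values shapes differ")
  if (any(values[masked] != 0)) stop("masked entries must have value 0")
  colnames(values) <- track_names
  colnames(masked) <- track_names
  structure(list(values = values, track_names = as.character(track_names),
                 masked = masked),
            class = "tgen_annotation")
}

#' @export
print.tgen_annotation <- function(x, ...) {
  cat("<tgen_annotation> ", nrow(x$values), " SNPs x ", ncol(x$values),
      " tracks (", sum(x$masked), " masked entries)\n", sep = "")
  invisible(x)
}

# coerce a matrix / NULL / tgen_annotation into a plain p x m value matrix
annotation_values <- function(A, p) {
  if (is.null(A)) return(matrix(0, p, 0))
  if (inherits(A, "tgen_annotation")) A <- A$values
  A <- as.matrix(A)
  if (nrow(A) != p) stop("annotation row count (", nrow(A), ") != number of SNPs (", p, ")")
  A
}

#' GWAS summary statistics
#'
#' @param records Data frame with columns `snp_id`, `a1` (effect allele),
#'   `a2` (other allele), `z` (per-SNP association z-score).
#' @param n_gwas GWAS sample size (positive integer).
#' @return A `tgen_gwas` list.
#' @export
gwas_summary <- function(records, n_gwas) {
  records <- tibble::as_tibble(records)
  required <- c("snp_id", "a1", "a2", "z")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("GWAS records missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (any(!is.finite(records$z))) stop("GWAS z-scores must be finite")
  if (any(toupper(records$a1) == toupper(records$a2))) stop("GWAS alleles must be distinct")
  n_gwas <- as.integer(n_gwas)
  if (is.na(n_gwas) || n_gwas < 1L) stop("n_gwas must be a positive integer")
  structure(list(records = records, n_gwas = n_gwas), class = "tgen_gwas")
}
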