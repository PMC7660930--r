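read_tsv_checked <- function(path, required, what, col_types = NULL) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  tbl <- readr::read_tsv(path, show_col_types = FALSE, col_types = col_types,
                         progress = FALSE)
  prb <- readr::problems(tbl)
  if (nrow(prb) > 0) {
    stop("malformed ", what, " rows at line(s) ",
         paste(unique(prb$row) + 1L, collapse = ", "), " in ", path)
  }
  missing_cols <- setdiff(required, names(tbl))
  if (length(missing_cols) > 0) {
    stop(what, " file ", path, " is missing mandatory header column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tbl
}

#' Read / write an expression matrix (genes x samples TSV)
#'
#' The first column is `gene_id`; remaining columns are samples. Gzip input
#' and output are handled transparently via the file extension.
#'
#' @param path File path (`.tsv` or `.tsv.gz`).
#' @return A tibble with `gene_id` and one numeric column per sample.
#' @export
read_expression_tsv <- function(path) {
  tbl <- read_tsv_checked(path, "gene_id", "expression")
  bad <- !vapply(tbl[-1], is.numeric, TRUE)
  if (any(bad)) stop("non-numeric expression column(s): ",
                     paste(names(tbl)[-1][bad], collapse = ", "))
  tbl
}

#' @rdname read_expression_tsv
#' @param expr Tibble as returned by [read_expression_tsv()].
#' @export
write_expression_tsv <- function(expr, path) {
  stopifnot("gene_id" %in% names(expr))
  readr::write_tsv(expr, path)
  invisible(path)
}

#' Extract one gene's expression vector from an expression table
#'
#' @param expr Tibble from [read_expression_tsv()].
#' @param gene_id Gene to extract.
#' @param sample_ids Optional sample order (defaults to table order).
#' @return A [expression_vector()].
#' @export
expression_for_gene <- function(expr, gene_id, sample_ids = NULL) {
  row <- which(expr$gene_id == gene_id)
  if (length(row) != 1) stop("gene ", gene_id, " not found exactly once")
  samples <- setdiff(names(expr), "gene_id")
  if (is.null(sample_ids)) sample_ids <- samples
  missing_s <- setdiff(sample_ids, samples)
  if (length(missing_s) > 0) {
    stop("samples absent from expression table: ",
         paste(missing_s, collapse = ", "))
  }
  expression_vector(gene_id, as.numeric(expr[row, sample_ids]), sample_ids)
}

#' Read / write GWAS summary statistics (TSV with SNP/A1/A2/Z/N header)
#'
#' @param path File path.
#' @return A [gwas_summary()].
#' @export
read_gwas_tsv <- function(path) {
  tbl <- read_tsv_checked(path, base::c("SNP", "A1", "A2", "Z", "N"), "GWAS")
  bad <- which(!is.finite(tbl$Z))
  if (length(bad) > 0) {
    stop("non-finite GWAS Z at line(s) ", paste(bad + 1L, collapse = ", "))
  }
  gwas_summary(tibble::tibble(snp_id = tbl$SNP, a1 = tbl$A1, a2 = tbl$A2,
                              z = tbl$Z),
               n_gwas = max(tbl$N))
}

#' @rdname read_gwas_tsv
#' @param gwas A [gwas_summary()].
#' @export
write_gwas_tsv <- function(gwas, path) {
  stopifnot(inherits(gwas, "tgen_gwas"))
  readr::write_tsv(tibble::tibble(SNP = gwas$records$snp_id,
                                  A1 = gwas$records$a1, A2 = gwas$records$a2,
                                  Z = gwas$records$z, N = gwas$n_gwas),
                   path)
  invisible(path)
}

#' Read / write BED-like annotation tracks
#'
#' On disk the intervals are BED-convention 0-based half-open
#' (`chrom`, `start`, `end`, `track`, `value`, `pvalue`); in memory they are
#' converted to 1-based inclusive coordinates, so a BED interval
#' `[99, 100)` covers exactly the 1-based SNP position 100.
#'
#' @param path File path.
#' @return Tibble with 1-based inclusive `start`/`end`.
#' @export
read_annotation_bed <- function(path) {
  tbl <- read_tsv_checked(path, base::c("chrom", "start", "end", "track",
                                        "value", "pvalue"), "annotation")
  if (any(tbl$end <= tbl$start)) {
    stop("empty/negative annotation interval at line(s) ",
         paste(which(tbl$end <= tbl$start) + 1L, collapse = ", "))
  }
  if (any(tbl$value < 0)) stop("annotation values must be non-negative")
  tbl$start <- tbl$start + 1L  # 0-based half-open -> 1-based inclusive
  tbl$chrom <- as.character(tbl$chrom)
  tbl
}

#' @rdname read_annotation_bed
#' @param tracks Tibble with 1-based inclusive `start`/`end` (as returned by
#'   [read_annotation_bed()]).
#' @export
write_annotation_bed <- function(tracks, path) {
  out <- tibble::as_tibble(tracks)
  out$start <- out$start - 1L  # back to BED 0-based half-open
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read / write per-tissue model stores
#'
#' A model store is a pair of TSV files per tissue: a weights table with one
#' row per (gene, SNP) — columns `gene`, `snp`, `chrom`, `pos`, `ref`, `alt`,
#' `beta`, `pps`, `train_mean` — and a per-gene sidecar with columns `gene`,
#' `tissue`, `method`, `cv_r2`, `cv_pvalue`, `n_snps`, `omega`
#' (comma-separated annotation coefficients, intercept first).
#'
#' @param models List of `tgen_model` objects (one tissue).
#' @param prefix Output path prefix; writes `<prefix>.weights.tsv` and
#'   `<prefix>.genes.tsv`.
#' @return (write) the prefix, invisibly; (read) a named list of
#'   `tgen_model`.
#' @export
write_model_store <- function(models, prefix) {
  if (inherits(models, "tgen_model")) models <- list(models)
  weights <- purrr::map_dfr(models, function(m) {
    tibble::tibble(gene = m$gene_id, snp = m$snps$snp_id,
                   chrom = m$snps$chrom, pos = m$snps$pos,
                   ref = m$snps$ref, alt = m$snps$alt,
                   beta = m$beta_hat, pps = m$pps,
                   train_mean = m$snps$train_mean)
  })
  genes <- purrr::map_dfr(models, function(m) {
    tibble::tibble(gene = m$gene_id, tissue = m$tissue,
                   method = m$method_tag, cv_r2 = m$cv_r2,
                   cv_pvalue = m$cv_pvalue, n_snps = nrow(m$snps),
                   omega = paste(format(m$omega_hat, digits = 17),
                                 collapse = ","))
  })
  readr::write_tsv(weights, paste0(prefix, ".weights.tsv"))
  readr::write_tsv(genes, paste0(prefix, ".genes.tsv"))
  invisible(prefix)
}

#' @rdname write_model_store
#' @export
read_model_store <- function(prefix) {
  weights <- read_tsv_checked(paste0(prefix, ".weights.tsv"),
                              base::c("gene", "snp", "chrom", "pos", "ref",
                                      "alt", "beta", "pps", "train_mean"),
                              "model weights")
  genes <- read_tsv_checked(paste0(prefix, ".genes.tsv"),
                            base::c("gene", "tissue", "method", "cv_r2",
                                    "cv_pvalue", "n_snps", "omega"),
                            "model sidecar")
  models <- purrr::pmap(genes, function(gene, tissue, method, cv_r2,
                                        cv_pvalue, n_snps, omega, ...) {
    w <- weights[weights$gene == gene, , drop = FALSE]
    if (nrow(w) != n_snps) {
      stop("model store mismatch for ", gene, ": sidecar says ", n_snps,
           " SNPs, weights table has ", nrow(w))
    }
    snps <- tibble::tibble(snp_id = w$snp, chrom = as.character(w$chrom),
                           pos = w$pos, ref = w$ref, alt = w$alt,
                           maf = NA_real_, train_mean = w$train_mean)
    om <- if (is.na(omega) || !nzchar(omega)) numeric(0) else
      as.numeric(strsplit(omega, ",")[[1]])
    new_tgen_model(gene_id = gene, tissue = tissue, snps = snps,
                   beta_hat = w$beta, pps = w$pps, omega_hat = om,
                   method_tag = method, cv_r2 = cv_r2, cv_pvalue = cv_pvalue)
  })
  names(models) <- genes$gene
  models
}

#' Write a cross-validation report table
#'
#' @param reports List of `tgen_cv_report`, or the tibble from
#'   [model_fdr_filter()].
#' @param path Output TSV path.
#' @param q FDR level used to mark kept models.
#' @return The gated tibble, invisibly.
#' @export
write_cv_report_tsv <- function(reports, path, q = 0.05) {
  tbl <- if (is.data.frame(reports)) tibble::as_tibble(reports) else
    model_fdr_filter(reports, q)
  readr::write_tsv(tbl, path)
  invisible(tbl)
}

#' Read / write genotype panels as VCF
#'
#' Reading uses the `DS` (dosage) FORMAT field when present, otherwise counts
#' alternative alleles in `GT`. Writing emits a minimal VCF 4.2 with both
#' `GT` (rounded) and `DS` fields; positions are 1-based as per VCF.
#'
#' @param path VCF file (`.vcf` or `.vcf.gz`).
#' @return A [genotype_panel()].
#' @export
read_vcf_panel <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  ds <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                 error = function(e) NULL)
  if (is.null(ds) || all(is.na(ds))) {
    gt <- vcfR::extract.gt(v, element = "GT")
    count_alt <- function(g) {
      ifelse(is.na(g), NA_real_,
             vapply(strsplit(gsub("\\|", "/", g), "/"),
                    function(a) sum(a == "1"), 0.0))
    }
    ds <- apply(gt, 2, count_alt)
    ds <- matrix(ds, nrow = nrow(gt), dimnames = dimnames(gt))
  }
  ids <- fix$ID
  ids[is.na(ids) | ids == "."] <- paste0(fix$CHROM, ":", fix$POS)[is.na(ids) | ids == "."]
  snps <- tibble::tibble(snp_id = ids, chrom = fix$CHROM,
                         pos = as.integer(fix$POS), ref = fix$REF,
                         alt = fix$ALT)
  genotype_panel(t(ds), snps, colnames(ds))
}

#' @rdname read_vcf_panel
#' @param panel A [genotype_panel()].
#' @export
write_vcf_panel <- function(panel, path) {
  stopifnot(inherits(panel, "tgen_panel"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(base::c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of ALT allele\">",
    paste(base::c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                  "INFO", "FORMAT", panel$sample_ids), collapse = "\t")), con)
  gt_codes <- base::c("0/0", "0/1", "1/1")
  for (j in seq_len(n_snps(panel))) {
    d <- panel$dosages[, j]
    gt <- ifelse(is.na(d), "./.", gt_codes[pmin(pmax(round(d), 0), 2) + 1])
    ds <- ifelse(is.na(d), ".", format(d, trim = TRUE, digits = 10))
    s <- panel$snps[j, ]
    writeLines(paste(base::c(s$chrom, s$pos, s$snp_id, s$ref, s$alt, ".",
                             "PASS", ".", "GT:DS", paste0(gt, ":", ds)),
                     collapse = "\t"), con)
  }
  invisible(path)
}
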