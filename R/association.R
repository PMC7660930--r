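#' Harmonize GWAS summary statistics to a fitted model
#'
#' Matches model SNPs to GWAS records by `snp_id` (falling back to
#' `chrom:pos` when the GWAS table carries those columns) and aligns the
#' allele coding: when the GWAS effect allele equals the model's alternative
#' allele the z-score is kept; when effect and other alleles are swapped the
#' sign is flipped; strand-ambiguous SNPs (A/T, C/G) and allele mismatches
#' are dropped with a recorded reason, and their model effects are excluded
#' from the downstream test.
#'
#' @param model A `tgen_model`.
#' @param gwas A [gwas_summary()].
#' @return A `tgen_aligned` list: `snp_ids` (model order), `beta` (model
#'   effects for retained SNPs), `z` (harmonized GWAS z-scores), `dropped`
#'   (tibble of `snp_id`, `reason`), `n_gwas`. `snp_sd`, `pred_sd`,
#'   `lambda_diag` are filled in by [build_lambda()].
#' @export
harmonize <- function(model, gwas) {
  stopifnot(inherits(model, "tgen_model"), inherits(gwas, "tgen_gwas"))
  rec <- gwas$records
  idx <- match(model$snps$snp_id, rec$snp_id)
  if (all(is.na(idx)) && all(base::c("chrom", "pos") %in% names(rec))) {
    idx <- match(paste(model$snps$chrom, model$snps$pos, sep = ":"),
                 paste(rec$chrom, rec$pos, sep = ":"))
  }
  keep <- logical(nrow(model$snps))
  z <- rep(NA_real_, nrow(model$snps))
  reasons <- rep(NA_character_, nrow(model$snps))
  ref <- toupper(model$snps$ref); alt <- toupper(model$snps$alt)
  for (i in seq_len(nrow(model$snps))) {
    j <- idx[i]
    if (is.na(j)) { reasons[i] <- "missing_in_gwas"; next }
    a1 <- toupper(rec$a1[j]); a2 <- toupper(rec$a2[j])
    if (is_ambiguous_pair(a1, a2) || is_ambiguous_pair(ref[i], alt[i])) {
      reasons[i] <- "ambiguous"; next
    }
    if (a1 == alt[i] && a2 == ref[i]) {
      z[i] <- rec$z[j]; keep[i] <- TRUE
    } else if (a1 == ref[i] && a2 == alt[i]) {
      z[i] <- -rec$z[j]; keep[i] <- TRUE
    } else {
      reasons[i] <- "allele_mismatch"
    }
  }
  if (!any(keep)) {
    stop("no model SNP could be harmonized to the GWAS; reasons: ",
         paste(utils::capture.output(print(table(reasons))), collapse = " "))
  }
  structure(list(snp_ids = model$snps$snp_id[keep],
                 beta = model$beta_hat[keep], z = z[keep],
                 dropped = tibble::tibble(snp_id = model$snps$snp_id[!keep],
                                          reason = reasons[!keep]),
                 n_gwas = gwas$n_gwas,
                 snp_sd = NULL, pred_sd = NULL, lambda_diag = NULL),
            class = "tgen_aligned")
}

#' Reference-panel scaling for the summary-statistics test
#'
#' Completes a harmonized model/GWAS pairing with the diagonal scaling
#' `Lambda`: per-SNP dosage standard deviations on the reference panel
#' divided by the standard deviation of the imputed expression on that panel
#' (the model restricted to the harmonized SNPs, empirical SD with
#' denominator n - 1).
#'
#' @param model A `tgen_model`.
#' @param reference A [genotype_panel()] containing the model SNPs.
#' @param aligned Optional `tgen_aligned` from [harmonize()]; when `NULL` all
#'   model SNPs are used with `z` left `NA` (useful for scaling diagnostics).
#' @return The completed `tgen_aligned` with `snp_sd`, `pred_sd`,
#'   `lambda_diag`.
#' @export
build_lambda <- function(model, reference, aligned = NULL) {
  stopifnot(inherits(model, "tgen_model"))
  if (is.null(aligned)) {
    aligned <- structure(list(snp_ids = model$snps$snp_id,
                              beta = model$beta_hat,
                              z = rep(NA_real_, nrow(model$snps)),
                              dropped = tibble::tibble(snp_id = character(),
                                                       reason = character()),
                              n_gwas = NA_integer_, snp_sd = NULL,
                              pred_sd = NULL, lambda_diag = NULL),
                         class = "tgen_aligned")
  }
  dos <- if (inherits(reference, "tgen_panel")) reference$dosages else as.matrix(reference)
  idx <- match(aligned$snp_ids, colnames(dos))
  present <- !is.na(idx)
  if (!all(present)) {
    warning(sum(!present), " harmonized SNP(s) absent from reference dropped")
    aligned$dropped <- dplyr::bind_rows(
      aligned$dropped,
      tibble::tibble(snp_id = aligned$snp_ids[!present],
                     reason = "missing_in_reference"))
    aligned$snp_ids <- aligned$snp_ids[present]
    aligned$beta <- aligned$beta[present]
    aligned$z <- aligned$z[present]
    idx <- idx[present]
  }
  sub <- restrict_model(model, aligned$snp_ids)
  pred <- predict_expression(sub, dos)
  pred_sd <- sd(pred)
  if (!is.finite(pred_sd) || pred_sd == 0) {
    stop("degenerate model: imputed expression has zero variance on the ",
         "reference panel")
  }
  aligned$snp_sd <- apply(dos[, idx, drop = FALSE], 2, sd)
  aligned$pred_sd <- pred_sd
  aligned$lambda_diag <- aligned$snp_sd / pred_sd
  aligned
}

# model restricted to a subset of SNP ids, preserving order of `ids`
restrict_model <- function(model, ids) {
  idx <- match(ids, model$snps$snp_id)
  stopifnot(!anyNA(idx))
  new_tgen_model(gene_id = model$gene_id, tissue = model$tissue,
                 snps = model$snps[idx, , drop = FALSE],
                 beta_hat = model$beta_hat[idx], pps = model$pps[idx],
                 omega_hat = model$omega_hat, method_tag = model$method_tag,
                 grid = model$grid, seed = model$seed,
                 cv_r2 = model$cv_r2, cv_pvalue = model$cv_pvalue,
                 flags = model$flags)
}

#' Gene-level association z-score from GWAS summary statistics
#'
#' Computes `z = sum_k beta_k lambda_k z_k` — the weighted sum of harmonized
#' per-SNP GWAS z-scores with weights `beta_hat * Lambda` — and its two-sided
#' normal p-value. This is the summary-statistics form of the z-score for the
#' regression coefficient of the trait on imputed expression.
#'
#' @param aligned A completed `tgen_aligned` (after [build_lambda()]).
#' @param beta_hat Optional replacement effect vector (defaults to the
#'   harmonized model effects stored in `aligned`).
#' @param gene_id,tissue Labels for the result row.
#' @return A one-row tibble: `gene_id`, `tissue`, `z`, `pvalue`,
#'   `n_snps_used`.
#' @export
gene_zscore <- function(aligned, beta_hat = NULL, gene_id = "gene",
                        tissue = "tissue") {
  stopifnot(inherits(aligned, "tgen_aligned"), !is.null(aligned$lambda_diag))
  beta <- beta_hat %||% aligned$beta
  stopifnot(length(beta) == length(aligned$z))
  z <- sum(beta * aligned$lambda_diag * aligned$z)
  if (!is.finite(z)) stop("non-finite gene z-score")
  tibble::tibble(gene_id = gene_id, tissue = tissue, z = z,
                 pvalue = 2 * pnorm(-abs(z)),
                 n_snps_used = length(aligned$z))
}

#' Bonferroni threshold over tested gene-tissue pairs
#'
#' @param n_gene_tissue_pairs Number of tested gene-tissue models.
#' @param alpha Family-wise error level (default 0.05).
#' @return `alpha / n_gene_tissue_pairs`.
#' @export
#' @examples
#' bonferroni_threshold(258039)  # the genome-wide per-pair threshold
bonferroni_threshold <- function(n_gene_tissue_pairs, alpha = 0.05) {
  n_gene_tissue_pairs <- as.numeric(n_gene_tissue_pairs)
  if (length(n_gene_tissue_pairs) != 1 || is.na(n_gene_tissue_pairs) ||
      n_gene_tissue_pairs < 1) {
    stop("n_gene_tissue_pairs must be a positive count")
  }
  alpha / n_gene_tissue_pairs
}

#' Run the summary-statistics association stage over a model store
#'
#' For every fitted gene-tissue model, harmonizes the GWAS z-scores, builds
#' the reference-panel scaling, and computes the gene-level z-score.
#' Significance is declared at the Bonferroni threshold `alpha / n_tested`
#' (over the pairs actually tested in this run) or, optionally, by
#' Benjamini-Hochberg. Per-gene failures (e.g. zero GWAS overlap) are
#' collected and do not stop the run.
#'
#' @param models List of `tgen_model` objects (typically the FDR-passing
#'   store).
#' @param gwas A [gwas_summary()].
#' @param reference A [genotype_panel()] used for SNP and imputed-expression
#'   standard deviations.
#' @param alpha Multiple-testing level (default 0.05).
#' @param adjust `"bonferroni"` (default) or `"BH"`.
#' @param band_map Optional tibble (`chrom`, `start`, `end`, `band`) for
#'   aggregating significant genes into cytogenetic bands; requires `genes`.
#' @param genes Optional tibble (`gene_id`, `chrom`, `tss`) locating genes
#'   for band aggregation.
#' @return A `tgen_twas` tibble (`gene_id`, `tissue`, `z`, `pvalue`,
#'   `n_snps_used`, `significant`) with attributes `failures` (tibble),
#'   `threshold`, and (when requested) `bands` (tibble of band, n_genes,
#'   genes).
#' @export
run_twas <- function(models, gwas, reference, alpha = 0.05,
                     adjust = base::c("bonferroni", "BH"), band_map = NULL,
                     genes = NULL) {
  adjust <- match.arg(adjust)
  if (inherits(models, "tgen_model")) models <- list(models)
  if (length(models) == 0) stop("no models supplied")
  rows <- list()
  failures <- list()
  for (m in models) {
    res <- tryCatch({
      aligned <- harmonize(m, gwas)
      aligned <- build_lambda(m, reference, aligned)
      gene_zscore(aligned, gene_id = m$gene_id, tissue = m$tissue)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <-
        tibble::tibble(gene_id = m$gene_id, tissue = m$tissue,
                       error = conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  if (length(rows) == 0) stop("association failed for every model")
  out <- dplyr::bind_rows(rows)
  if (adjust == "bonferroni") {
    thr <- bonferroni_threshold(nrow(out), alpha)
    out$significant <- out$pvalue < thr
  } else {
    thr <- alpha
    out$significant <- p.adjust(out$pvalue, method = "BH") <= alpha
  }
  attr(out, "threshold") <- thr
  attr(out, "adjust") <- adjust
  attr(out, "failures") <- if (length(failures)) dplyr::bind_rows(failures) else
    tibble::tibble(gene_id = character(), tissue = character(),
                   error = character())
  if (!is.null(band_map) && !is.null(genes)) {
    attr(out, "bands") <- aggregate_bands(out, genes, band_map)
  }
  class(out) <- base::c("tgen_twas", class(out))
  out
}

# group significant genes into user-supplied cytogenetic bands
aggregate_bands <- function(results, genes, band_map) {
  sig <- dplyr::filter(results, .data$significant)
  if (nrow(sig) == 0) {
    return(tibble::tibble(band = character(), n_genes = integer(),
                          genes = character()))
  }
  loc <- dplyr::inner_join(dplyr::distinct(sig, .data$gene_id),
                           tibble::as_tibble(genes), by = "gene_id")
  band_map <- tibble::as_tibble(band_map)
  loc$band <- NA_character_
  for (i in seq_len(nrow(loc))) {
    hit <- which(band_map$chrom == loc$chrom[i] &
                   band_map$start <= loc$tss[i] & band_map$end >= loc$tss[i])
    if (length(hit) > 0) loc$band[i] <- band_map$band[hit[1]]
  }
  loc |>
    dplyr::filter(!is.na(.data$band)) |>
    dplyr::group_by(.data$band) |>
    dplyr::summarise(n_genes = dplyr::n(),
                     genes = paste(sort(.data$gene_id), collapse = ","),
                     .groups = "drop")
}
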