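#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a fitted gene model into one row per SNP
#'
#' @param x A `tgen_model`.
#' @param ... Unused.
#' @return Tibble: `snp_id`, `chrom`, `pos`, `ref`, `alt`, `beta`, `pps`.
#' @method tidy tgen_model
#' @export
tidy.tgen_model <- function(x, ...) {
  tibble::tibble(snp_id = x$snps$snp_id, chrom = x$snps$chrom,
                 pos = x$snps$pos, ref = x$snps$ref, alt = x$snps$alt,
                 beta = x$beta_hat, pps = x$pps)
}

#' One-row summary of a fitted gene model
#'
#' @param x A `tgen_model`.
#' @param ... Unused.
#' @return Tibble with gene/tissue/method labels, SNP counts, the number of
#'   SNPs with PPS > 0.5, and cross-validation diagnostics when present.
#' @method glance tgen_model
#' @export
glance.tgen_model <- function(x, ...) {
  tibble::tibble(gene_id = x$gene_id, tissue = x$tissue,
                 method = x$method_tag, n_snps = nrow(x$snps),
                 n_selected = sum(x$pps > 0.5),
                 max_pps = if (length(x$pps)) max(x$pps) else NA_real_,
                 cv_r2 = x$cv_r2, cv_pvalue = x$cv_pvalue)
}

#' Tidy a cross-validation report
#'
#' @param x A `tgen_cv_report`.
#' @param ... Unused.
#' @return One-row tibble: `gene_id`, `method`, `r2`, `pvalue`, and per-fold
#'   R-squared values nested in a list column.
#' @method tidy tgen_cv_report
#' @export
tidy.tgen_cv_report <- function(x, ...) {
  tibble::tibble(gene_id = x$gene_id, method = x$method_tag, r2 = x$r2,
                 pvalue = x$pvalue, per_fold_r2 = list(x$per_fold_r2))
}

#' Plot per-SNP inclusion probabilities along the cis window
#'
#' @param object A `tgen_model`.
#' @param ... Unused.
#' @return A ggplot: PPS against genomic position, point size scaled by
#'   |beta|.
#' @method autoplot tgen_model
#' @export
autoplot.tgen_model <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$pps)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$pos, yend = 0),
                          linewidth = 0.3, colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(size = abs(.data$beta)), alpha = 0.8) +
    ggplot2::scale_size_continuous(name = "|beta|", range = base::c(0.5, 3)) +
    ggplot2::labs(x = "position (bp)", y = "posterior probability of selection",
                  title = paste0(object$gene_id, " [", object$method_tag, "]")) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot gene-level association results
#'
#' @param object A `tgen_twas` results table from [run_twas()].
#' @param ... Unused.
#' @return A ggplot of -log10 p-values per gene with the multiple-testing
#'   threshold drawn as a dashed line.
#' @method autoplot tgen_twas
#' @export
autoplot.tgen_twas <- function(object, ...) {
  thr <- attr(object, "threshold")
  d <- tibble::as_tibble(object)
  d$idx <- seq_len(nrow(d))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$idx, y = -log10(.data$pvalue),
                                  colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(thr), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = base::c(`TRUE` = "firebrick",
                                                  `FALSE` = "grey40")) +
    ggplot2::labs(x = "gene-tissue pair", y = "-log10 p") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the ELBO trace of a variational fit
#'
#' @param object A `tgen_vb_state` from [fit_single_theta()].
#' @param ... Unused.
#' @return A ggplot of the ELBO against iteration.
#' @method autoplot tgen_vb_state
#' @export
autoplot.tgen_vb_state <- function(object, ...) {
  d <- tibble::tibble(iteration = seq_along(object$elbo_trace),
                      elbo = object$elbo_trace)
  ggplot2::ggplot(d, ggplot2::aes(.data$iteration, .data$elbo)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(y = "evidence lower bound") +
    ggplot2::theme_minimal()
}
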