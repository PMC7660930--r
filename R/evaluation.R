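#' Deterministic k-fold split
#'
#' Randomly partitions `n` samples into `k` folds whose sizes differ by at
#' most one, deterministically under `seed`.
#'
#' @param n Number of samples.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return List of `k` integer index vectors (disjoint, exhaustive).
#' @export
kfold_split <- function(n, k = 5L, seed = 2020) {
  n <- as.integer(n); k <- as.integer(k)
  if (k > n) stop("k (", k, ") must not exceed n (", n, ")")
  if (k < 2L) stop("k must be at least 2")
  withr::local_seed(seed)
  idx <- sample.int(n)
  sizes <- rep(n %/% k, k) + base::c(rep(1L, n %% k), rep(0L, k - n %% k))
  unname(split(idx, rep(seq_len(k), times = sizes)))
}

#' Squared Pearson correlation between observed and imputed expression
#'
#' @param observed,predicted Equal-length numeric vectors (length >= 3).
#' @return Squared Pearson correlation; 0 (with attribute
#'   `zero_variance = TRUE`) when `predicted` has zero variance.
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted lengths differ")
  }
  if (length(observed) < 3) stop("need at least 3 observations")
  if (sd(predicted) == 0 || sd(observed) == 0) {
    return(structure(0, zero_variance = TRUE))
  }
  cor(observed, predicted)^2
}

#' Cross-validated imputation accuracy for one gene
#'
#' Splits samples into `k` folds, refits the chosen method on each training
#' set, predicts the held-out fold, pools all out-of-fold predictions, and
#' reports the squared correlation with the observed expression together with
#' a one-sided p-value for positive correlation (the model-significance
#' p-value fed to [model_fdr_filter()]).
#'
#' @inheritParams fit_model
#' @param k Number of folds (default 5).
#' @param seed Seed for the fold split and fold fits.
#' @return A `tgen_cv_report`: `gene_id`, `method_tag`, `folds`, `r2`,
#'   `pvalue`, `per_fold_r2`, and the pooled `predicted` vector (in sample
#'   order).
#' @export
cross_validate <- function(X, Y, A = NULL, method_tag = "tgen",
                           config = prior_config(), k = 5L, seed = 2020,
                           gene_id = "gene", tissue = "tissue", snps = NULL) {
  X <- as.matrix(X)
  if (!is.null(snps)) colnames(X) <- snps$snp_id
  if (is.null(colnames(X))) colnames(X) <- paste0("snp_", seq_len(ncol(X)))
  Y <- as.numeric(Y)
  n <- nrow(X)
  folds <- kfold_split(n, k, seed)
  predicted <- rep(NA_real_, n)
  per_fold_r2 <- rep(NA_real_, length(folds))
  for (f in seq_along(folds)) {
    test <- folds[[f]]
    train <- setdiff(seq_len(n), test)
    mod <- tryCatch(
      fit_model(X[train, , drop = FALSE], Y[train], A,
                method_tag = method_tag, config = config, gene_id = gene_id,
                tissue = tissue, snps = snps, seed = seed + f),
      error = function(e) stop("fold ", f, " fit failed: ",
                               conditionMessage(e), call. = FALSE))
    pred <- suppressWarnings(predict_expression(mod, X[test, , drop = FALSE]))
    predicted[test] <- pred
    if (length(test) >= 3) {
      per_fold_r2[f] <- as.numeric(r_squared(Y[test], pred))
    }
  }
  r2 <- as.numeric(r_squared(Y, predicted))
  pvalue <- cv_pvalue(Y, predicted, folds)
  structure(list(gene_id = gene_id, method_tag = method_tag, folds = folds,
                 r2 = r2, pvalue = pvalue, per_fold_r2 = per_fold_r2,
                 predicted = predicted),
            class = "tgen_cv_report")
}

# One-sided significance of positive correlation between observed and
# out-of-fold predicted expression. The correlation is tested within each
# fold — conditional on its training data a fold's predictions are a fixed
# vector independent of the held-out responses, so each per-fold p-value is
# exactly uniform under the null — and folds are combined by Stouffer's
# method. (A single pooled correlation across folds is negatively biased
# under the null because every sample's response also enters the other
# folds' training fits.) Folds too small to carry a correlation (< 3
# samples, e.g. leave-one-out) fall back to the pooled test; degenerate
# constant-prediction folds are skipped.
cv_pvalue <- function(Y, predicted, folds) {
  if (min(lengths(folds)) < 3) {
    if (sd(predicted) == 0 || sd(Y) == 0) return(1)
    return(cor.test(Y, predicted, alternative = "greater")$p.value)
  }
  zf <- base::c()
  for (f in folds) {
    if (sd(predicted[f]) == 0 || sd(Y[f]) == 0) next
    r <- cor(Y[f], predicted[f])
    df <- length(f) - 2L
    pf <- stats::pt(r * sqrt(df / (1 - r^2)), df, lower.tail = FALSE)
    zf <- base::c(zf, qnorm(pf, lower.tail = FALSE))
  }
  if (length(zf) == 0) return(1)
  pnorm(sum(zf) / sqrt(length(zf)), lower.tail = FALSE)
}

#' @export
print.tgen_cv_report <- function(x, ...) {
  cat("<tgen_cv_report> ", x$gene_id, " [", x$method_tag, "] ",
      length(x$folds), "-fold: R^2 = ", signif(x$r2, 3), ", p = ",
      signif(x$pvalue, 3), "\n", sep = "")
  invisible(x)
}

#' FDR gate on cross-validated gene models
#'
#' Benjamini-Hochberg adjustment of the model-significance p-values across
#' all candidate gene models (per tissue in the standard workflow); models
#' with adjusted p-value at or below `q` pass the gate and enter association
#' testing.
#'
#' @param reports List of `tgen_cv_report` objects, or a data frame with
#'   columns `gene_id`, `r2`, `pvalue`.
#' @param q FDR level (default 0.05).
#' @return Tibble with `gene_id`, `r2`, `pvalue`, `padj`, `kept`.
#' @export
model_fdr_filter <- function(reports, q = 0.05) {
  if (is.data.frame(reports)) {
    tbl <- tibble::as_tibble(reports)
  } else {
    tbl <- purrr::map_dfr(reports, function(r) {
      tibble::tibble(gene_id = r$gene_id, r2 = r$r2, pvalue = r$pvalue)
    })
  }
  if (nrow(tbl) == 0) {
    return(tibble::tibble(gene_id = character(), r2 = numeric(),
                          pvalue = numeric(), padj = numeric(),
                          kept = logical()))
  }
  if (any(tbl$pvalue < 0 | tbl$pvalue > 1, na.rm = TRUE)) {
    stop("invalid p-values in CV reports")
  }
  tbl$padj <- p.adjust(tbl$pvalue, method = "BH")
  tbl$kept <- tbl$padj <= q
  tbl
}
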