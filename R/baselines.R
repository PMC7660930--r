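#' Annotation-free spike-and-slab baseline (vb)
#'
#' The same variational machinery as the annotation-informed model, run with
#' an intercept-only inclusion prior (no annotation columns). Equivalent to
#' calling [fit_grid()] with `A = NULL`.
#'
#' @inheritParams fit_grid
#' @return A `tgen_model` with `method_tag = "vb"`.
#' @export
fit_vb_baseline <- function(X, Y, config = prior_config(), gene_id = "gene",
                            tissue = "tissue", snps = NULL, seed = 2020) {
  fit_grid(X, Y, A = NULL, config = config, gene_id = gene_id,
           tissue = tissue, snps = snps, method_tag = "vb",
           seed = seed)$model
}

# Elastic-net comparator: mixing parameter fixed at 0.5, penalty chosen by
# internal cross-validation (cv.glmnet, lambda.min). For p = 1 glmnet cannot
# run; an ordinary least-squares slope is used and the model flagged.
fit_elnt <- function(X, Y, gene_id = "gene", tissue = "tissue", snps = NULL,
                     seed = 2020, method_tag = "elnt") {
  X <- as.matrix(X)
  Y <- as.numeric(Y)
  p <- ncol(X)
  flags <- character()
  if (p >= 2) {
    withr::local_seed(seed)
    cvfit <- glmnet::cv.glmnet(X, Y, alpha = 0.5,
                               nfolds = min(10L, max(3L, nrow(X) %/% 3L)))
    beta_hat <- as.numeric(coef(cvfit, s = "lambda.min"))[-1]
  } else {
    xc <- X[, 1] - mean(X[, 1])
    beta_hat <- if (sum(xc^2) > 0) sum(xc * (Y - mean(Y))) / sum(xc^2) else 0
    flags <- "ols_fallback_p1"
  }
  if (is.null(snps)) {
    ids <- colnames(X) %||% paste0("snp_", seq_len(p))
    snps <- tibble::tibble(snp_id = ids, chrom = "1", pos = seq_len(p),
                           ref = "A", alt = "G", maf = NA_real_)
  }
  snps <- tibble::as_tibble(snps)
  snps$train_mean <- colMeans(X)
  new_tgen_model(gene_id = gene_id, tissue = tissue, snps = snps,
                 beta_hat = beta_hat, pps = as.numeric(beta_hat != 0),
                 omega_hat = numeric(0), method_tag = method_tag, seed = seed,
                 flags = flags)
}

#' Annotation-filtered comparator fits (vb.annot / elnt.annot)
#'
#' Drops cis-SNPs whose annotation values are non-positive on all listed
#' tracks, then fits the chosen base learner on the survivors: `"vb"` (the
#' spike-and-slab baseline) or `"elnt"` (elastic net with mixing parameter
#' 0.5 and cross-validated penalty).
#'
#' @inheritParams fit_grid
#' @param tracks Track names used for the positivity filter; defaults to all
#'   tracks in `A`.
#' @param base `"vb"` or `"elnt"`.
#' @return A `tgen_model` with `method_tag` `"vb.annot"` or `"elnt.annot"`,
#'   containing only the surviving SNPs. When every SNP is filtered the model
#'   has an empty SNP set and carries the flag `"all_snps_filtered"`.
#' @export
annotation_filter_fit <- function(X, Y, A, tracks = NULL,
                                  base = base::c("vb", "elnt"),
                                  config = prior_config(), gene_id = "gene",
                                  tissue = "tissue", snps = NULL,
                                  seed = 2020) {
  base <- match.arg(base)
  X <- as.matrix(X)
  stopifnot(inherits(A, "tgen_annotation"))
  if (is.null(tracks)) tracks <- A$track_names
  if (!all(tracks %in% A$track_names)) {
    stop("unknown annotation tracks: ",
         paste(setdiff(tracks, A$track_names), collapse = ", "))
  }
  tag <- paste0(base, ".annot")
  keep <- which(rowSums(A$values[, tracks, drop = FALSE] > 0) > 0)
  if (is.null(snps)) {
    ids <- colnames(X) %||% paste0("snp_", seq_len(ncol(X)))
    snps <- tibble::tibble(snp_id = ids, chrom = "1", pos = seq_len(ncol(X)),
                           ref = "A", alt = "G", maf = NA_real_)
  }
  snps <- tibble::as_tibble(snps)
  if (length(keep) == 0) {
    empty <- snps[0, ]
    empty$train_mean <- numeric(0)
    return(new_tgen_model(gene_id = gene_id, tissue = tissue, snps = empty,
                          beta_hat = numeric(0), pps = numeric(0),
                          omega_hat = numeric(0), method_tag = tag,
                          seed = seed, flags = "all_snps_filtered"))
  }
  Xk <- X[, keep, drop = FALSE]
  sk <- snps[keep, , drop = FALSE]
  if (base == "vb") {
    mod <- fit_grid(Xk, Y, A = NULL, config = config, gene_id = gene_id,
                    tissue = tissue, snps = sk, method_tag = tag,
                    seed = seed)$model
  } else {
    mod <- fit_elnt(Xk, Y, gene_id = gene_id, tissue = tissue, snps = sk,
                    seed = seed, method_tag = tag)
  }
  mod
}

#' Fit one gene with any of the shipped methods
#'
#' Dispatcher over the five imputation learners: `tgen`
#' (annotation-informed spike-and-slab), `vb` (annotation-free baseline),
#' `vb.annot`/`elnt.annot` (annotation positivity filter then base learner),
#' and `elnt` (elastic net, mixing parameter 0.5).
#'
#' @inheritParams fit_grid
#' @param method_tag One of `"tgen"`, `"vb"`, `"vb.annot"`, `"elnt"`,
#'   `"elnt.annot"`.
#' @return A `tgen_model`.
#' @export
fit_model <- function(X, Y, A = NULL,
                      method_tag = base::c("tgen", "vb", "vb.annot", "elnt",
                                           "elnt.annot"),
                      config = prior_config(), gene_id = "gene",
                      tissue = "tissue", snps = NULL, seed = 2020) {
  method_tag <- match.arg(method_tag)
  if (method_tag %in% base::c("tgen", "vb.annot", "elnt.annot") && is.null(A)) {
    stop("method '", method_tag, "' requires an annotation matrix")
  }
  switch(method_tag,
    tgen = fit_grid(X, Y, A, config = config, gene_id = gene_id,
                    tissue = tissue, snps = snps, method_tag = "tgen",
                    seed = seed)$model,
    vb = fit_vb_baseline(X, Y, config = config, gene_id = gene_id,
                         tissue = tissue, snps = snps, seed = seed),
    vb.annot = annotation_filter_fit(X, Y, A, base = "vb", config = config,
                                     gene_id = gene_id, tissue = tissue,
                                     snps = snps, seed = seed),
    elnt = fit_elnt(X, Y, gene_id = gene_id, tissue = tissue, snps = snps,
                    seed = seed),
    elnt.annot = annotation_filter_fit(X, Y, A, base = "elnt",
                                       config = config, gene_id = gene_id,
                                       tissue = tissue, snps = snps,
                                       seed = seed))
}
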