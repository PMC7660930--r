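log_dinvgamma <- function(x, shape, scale) {
  shape * log(scale) - lgamma(shape) - (shape + 1) * log(x) - scale / x
}

softmax <- function(lw) {
  w <- exp(lw - max(lw))
  w / sum(w)
}

#' Fit the annotation-informed model over the hyperparameter grid
#'
#' Runs [fit_single_theta()] at every grid point and combines the per-point
#' variational fits by posterior weights
#' `w_theta ∝ exp(ELBO(theta) + log prior(theta))`, with the prior density
#' taken from the inverse-gamma/inverse-gamma/gamma assumptions in
#' [prior_config()]. The posterior probability of selection is the weighted
#' average of the per-point inclusion probabilities,
#' `PPS_k = sum_theta w_theta alpha_k(theta)`, and the SNP effect estimate is
#' the posterior-mean `beta_hat_k = sum_theta w_theta alpha_k(theta)
#' mu_k(theta)` used in the prediction rule `Y_hat = X beta_hat`.
#'
#' @param X n x p dosage matrix (raw; centered internally, with training
#'   means stored in the returned model for later prediction).
#' @param Y Length-n adjusted expression vector.
#' @param A Optional p x m annotation matrix or [annotation_matrix()].
#' @param config A [prior_config()].
#' @param gene_id,tissue Labels stored in the model.
#' @param snps Optional SNP metadata tibble (as in [genotype_panel()]); when
#'   `NULL`, minimal records are fabricated from `colnames(X)`.
#' @param method_tag Label recorded on the model (default `"tgen"`).
#' @param seed Seed controlling any randomized choices (the default update
#'   schedule is deterministic; the seed is recorded for reproducibility).
#' @return A `tgen_grid_fit` with elements `states` (list of
#'   `tgen_vb_state`), `log_weights`, `weights`, `grid` (tibble of theta,
#'   ELBO, weight, convergence), and `model` (a `tgen_model`).
#' @export
fit_grid <- function(X, Y, A = NULL, config = prior_config(),
                     gene_id = "gene", tissue = "tissue", snps = NULL,
                     method_tag = "tgen", seed = 2020) {
  X <- as.matrix(X)
  p <- ncol(X)
  grid <- resolve_theta_grid(config, var(as.numeric(Y)))
  withr::local_seed(seed)

  states <- vector("list", nrow(grid))
  lw <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    st <- withCallingHandlers(
      fit_single_theta(X, Y, A,
                       theta = list(sigma2 = grid$sigma2[g],
                                    sigma_beta2 = grid$sigma_beta2[g],
                                    eta = grid$eta[g]),
                       tol = config$tol, max_iter = config$max_iter,
                       profile_sigma2 = config$profile_sigma2),
      warning = function(w) invokeRestart("muffleWarning"))
    states[[g]] <- st
    lw[g] <- st$elbo +
      log_dinvgamma(st$sigma2, config$a, config$b) +
      log_dinvgamma(grid$sigma_beta2[g], config$c, config$d) +
      dgamma(grid$eta[g], shape = config$a0, rate = config$b0, log = TRUE)
  }
  if (!any(vapply(states, `[[`, TRUE, "converged"))) {
    stop("no grid point converged; grid diagnostics: ",
         paste(sprintf("(sb2=%g, eta=%g, iters=%d)", grid$sigma_beta2,
                       grid$eta, vapply(states, `[[`, 1L, "iterations")),
               collapse = " "))
  }
  w <- softmax(lw)
  alpha_mat <- vapply(states, `[[`, numeric(p), "alpha")
  mu_mat <- vapply(states, `[[`, numeric(p), "mu")
  alpha_mat <- matrix(alpha_mat, nrow = p)
  mu_mat <- matrix(mu_mat, nrow = p)
  pps <- drop(alpha_mat %*% w)
  beta_hat <- drop((alpha_mat * mu_mat) %*% w)
  omega_mat <- vapply(states, `[[`, numeric(length(states[[1]]$omega_mean)),
                      "omega_mean")
  omega_hat <- drop(matrix(omega_mat, ncol = length(states)) %*% w)

  if (is.null(snps)) {
    ids <- colnames(X) %||% paste0("snp_", seq_len(p))
    snps <- tibble::tibble(snp_id = ids, chrom = "1", pos = seq_len(p),
                           ref = "A", alt = "G", maf = NA_real_)
  }
  snps <- tibble::as_tibble(snps)
  snps$train_mean <- colMeans(X)

  grid_tbl <- tibble::tibble(
    sigma2 = vapply(states, `[[`, 1.0, "sigma2"),
    sigma_beta2 = grid$sigma_beta2, eta = grid$eta,
    elbo = vapply(states, `[[`, 1.0, "elbo"),
    iterations = vapply(states, `[[`, 1L, "iterations"),
    converged = vapply(states, `[[`, TRUE, "converged"),
    log_weight = lw - max(lw) - log(sum(exp(lw - max(lw)))),
    weight = w)

  model <- new_tgen_model(gene_id = gene_id, tissue = tissue, snps = snps,
                          beta_hat = beta_hat, pps = pps,
                          omega_hat = omega_hat, method_tag = method_tag,
                          grid = grid_tbl, seed = seed)
  structure(list(states = states, log_weights = grid_tbl$log_weight,
                 weights = w, grid = grid_tbl, model = model),
            class = "tgen_grid_fit")
}

new_tgen_model <- function(gene_id, tissue, snps, beta_hat, pps, omega_hat,
                           method_tag, grid = NULL, seed = NA_integer_,
                           cv_r2 = NA_real_, cv_pvalue = NA_real_,
                           flags = character()) {
  stopifnot(length(beta_hat) == nrow(snps), length(pps) == nrow(snps))
  if (length(pps) > 0) stopifnot(all(pps >= -1e-12 & pps <= 1 + 1e-12))
  structure(list(gene_id = gene_id, tissue = tissue, snps = snps,
                 beta_hat = as.numeric(beta_hat), pps = as.numeric(pps),
                 omega_hat = as.numeric(omega_hat),
                 method_tag = method_tag, grid = grid, seed = seed,
                 cv_r2 = cv_r2, cv_pvalue = cv_pvalue, flags = flags),
            class = "tgen_model")
}

#' @export
print.tgen_model <- function(x, ...) {
  cat("<tgen_model> ", x$gene_id, " / ", x$tissue, " [", x$method_tag, "]\n",
      sep = "")
  cat("  ", nrow(x$snps), " SNPs; ", sum(x$pps > 0.5), " with PPS > 0.5\n",
      sep = "")
  if (!is.na(x$cv_r2)) {
    cat("  CV R^2 = ", signif(x$cv_r2, 3), " (p = ",
        signif(x$cv_pvalue, 3), ")\n", sep = "")
  }
  invisible(x)
}

#' Impute expression from a fitted model
#'
#' Applies the prediction rule `Y_hat = X_centered beta_hat`, centering each
#' SNP's dosages at the training means stored in the model. Model SNPs absent
#' from the panel contribute zero, with a warning.
#'
#' @param model A `tgen_model`.
#' @param panel A [genotype_panel()] (or bare dosage matrix with SNP ids as
#'   column names).
#' @return Numeric vector of imputed (centered) expression values, one per
#'   panel sample.
#' @export
predict_expression <- function(model, panel) {
  dos <- if (inherits(panel, "tgen_panel")) panel$dosages else as.matrix(panel)
  idx <- match(model$snps$snp_id, colnames(dos))
  missing <- is.na(idx)
  if (any(missing)) {
    warning(sum(missing), " model SNP(s) absent from panel contribute 0: ",
            paste(head(model$snps$snp_id[missing], 5), collapse = ", "))
  }
  if (all(missing) || nrow(model$snps) == 0) return(rep(0, nrow(dos)))
  Xm <- dos[, idx[!missing], drop = FALSE]
  Xm <- sweep(Xm, 2, model$snps$train_mean[!missing], "-")
  unname(drop(Xm %*% model$beta_hat[!missing]))
}
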