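#' Prior configuration for the hyperparameter grid
#'
#' The residual variance `sigma2`, the slab variance ratio `sigma_beta2`
#' (slab variance is `sigma_beta2 * sigma2`), and the annotation-coefficient
#' precision `eta` are treated as hyperparameters `theta`. Each carries a
#' prior — inverse-gamma IG(a, b) for `sigma2`, IG(c, d) for `sigma_beta2`,
#' Gamma(a0, b0) for `eta` — and inference averages over a grid of `theta`
#' values weighted by variational evidence plus prior density.
#'
#' The `"auto"` grid crosses `sigma_beta2` over `{0.001, 0.01, 0.1, 1}`
#' (log-spaced) with `eta` over `{1, 10}`; `sigma2` is initialized at half the
#' sample variance of the phenotype and profiled at its ELBO-maximizing value
#' during fitting (`profile_sigma2 = TRUE`).
#'
#' @param a,b Inverse-gamma shape/scale for `sigma2` (default 0.01, 0.01:
#'   weakly informative).
#' @param c,d Inverse-gamma shape/scale for `sigma_beta2`.
#' @param a0,b0 Gamma shape/rate for `eta`.
#' @param theta_grid `"auto"`, or a data frame with columns `sigma2`
#'   (`NA` to profile), `sigma_beta2`, `eta`.
#' @param tol Absolute ELBO convergence tolerance (default 1e-4).
#' @param max_iter Maximum coordinate-ascent iterations per grid point.
#' @param profile_sigma2 Update `sigma2` at its closed-form ELBO maximizer
#'   each iteration (default `TRUE`).
#' @return A `tgen_prior_config` list.
#' @export
prior_config <- function(a = 0.01, b = 0.01, c = 0.01, d = 0.01,
                         a0 = 0.01, b0 = 0.01, theta_grid = "auto",
                         tol = 1e-4, max_iter = 500L, profile_sigma2 = TRUE) {
  vals <- list(a = a, b = b, c = c, d = d, a0 = a0, b0 = b0)
  if (any(unlist(vals) <= 0)) stop("all prior hyperparameters must be positive")
  structure(base::c(vals, list(theta_grid = theta_grid, tol = tol,
                               max_iter = as.integer(max_iter),
                               profile_sigma2 = isTRUE(profile_sigma2))),
            class = "tgen_prior_config")
}

resolve_theta_grid <- function(config, y_var) {
  tg <- config$theta_grid
  if (is.character(tg) && identical(tg, "auto")) {
    tg <- expand.grid(sigma2 = NA_real_,
                      sigma_beta2 = base::c(0.001, 0.01, 0.1, 1),
                      eta = base::c(1, 10))
  }
  tg <- tibble::as_tibble(tg)
  stopifnot(all(base::c("sigma2", "sigma_beta2", "eta") %in% names(tg)),
            nrow(tg) >= 1)
  tg$sigma2[is.na(tg$sigma2)] <- max(0.5 * y_var, 1e-8)
  if (any(tg$sigma_beta2 <= 0) || any(tg$eta <= 0) || any(tg$sigma2 <= 0)) {
    stop("theta grid components must be positive")
  }
  tg
}

#' Logistic prior inclusion probability
#'
#' The prior probability that a SNP is an eQTL given its annotation row:
#' `sigmoid(intercept + A_row . slopes)`.
#'
#' @param A_row Annotation values for one SNP (length m).
#' @param omega Coefficient vector of length m + 1; first element is the
#'   intercept.
#' @return Probability in (0, 1).
#' @export
#' @examples
#' logistic_prior(numeric(0), 0)        # 0.5
#' logistic_prior(c(1, 2), c(-2, 1, 1)) # sigmoid(2)
logistic_prior <- function(A_row, omega) {
  stopifnot(all(is.finite(A_row)), all(is.finite(omega)),
            length(omega) == length(A_row) + 1L)
  unname(sigmoid(omega[1] + sum(A_row * omega[-1])))
}

# local bound slope of the Jaakkola-Jordan quadratic bound
jj_lambda <- function(xi) {
  out <- rep(0.125, length(xi))
  nz <- xi > 1e-6
  out[nz] <- tanh(xi[nz] / 2) / (4 * xi[nz])
  out
}

entropy_bern <- function(alpha) {
  a <- pmin(pmax(alpha, 1e-12), 1 - 1e-12)
  -(a * log(a) + (1 - a) * log(1 - a))
}

# ELBO of the full variational approximation; `fixed_prior` switches between
# the Jaakkola-Jordan bound with q(omega) Gaussian and an exact Bernoulli
# prior with known inclusion logits.
vb_elbo <- function(n, xx, resid, alpha, mu, s2, sigma2, sigma_beta2,
                    Aint, omega_mean, omega_cov, xi, eta,
                    fixed_prior_logit = NULL) {
  equad <- sum(resid^2) + sum(xx * (alpha * (s2 + mu^2) - (alpha * mu)^2))
  ll <- -n / 2 * log(2 * pi * sigma2) - equad / (2 * sigma2)
  slab <- sum(alpha * (1 + log(s2 / (sigma2 * sigma_beta2)) -
                         (s2 + mu^2) / (sigma2 * sigma_beta2))) / 2
  ent <- sum(entropy_bern(alpha))
  if (!is.null(fixed_prior_logit)) {
    l <- fixed_prior_logit
    prior <- sum(alpha * l + log(sigmoid(-l)))
    return(ll + slab + ent + prior)
  }
  lin <- drop(Aint %*% omega_mean)
  M <- omega_cov + tcrossprod(omega_mean)
  q2 <- rowSums((Aint %*% M) * Aint)
  lam <- jj_lambda(xi)
  jj <- sum(alpha * lin + log(sigmoid(xi)) - (lin + xi) / 2 -
              lam * (q2 - xi^2))
  d <- length(omega_mean)
  kl_omega <- 0.5 * (eta * (sum(diag(omega_cov)) + sum(omega_mean^2)) -
                       d - d * log(eta) - determinant(omega_cov)$modulus[1])
  ll + slab + ent + jj - kl_omega
}

#' Fit the spike-and-slab model at one hyperparameter setting
#'
#' Coordinate-ascent variational inference for the model
#' `Y = X beta + eps`, `eps ~ N(0, sigma2 I)`,
#' `beta_k | gamma_k = 1 ~ N(0, sigma_beta2 * sigma2)`,
#' `beta_k | gamma_k = 0 = 0`, `gamma_k ~ Bernoulli(pi_k)`,
#' `logit(pi_k) = omega_0 + A_k . omega`, `omega ~ N(0, eta^-1 I)`.
#'
#' Each iteration performs (i) a cyclic sweep over SNPs in stored (genomic)
#' order updating `(alpha_k, mu_k, s2_k)` in closed form, (ii) a Gaussian
#' update of `q(omega)` using the Jaakkola-Jordan quadratic bound of the
#' logistic term with local parameters `xi`, (iii) the closed-form `xi`
#' update, and (iv) optionally the closed-form ELBO-maximizing `sigma2`.
#' Every step ascends the same objective, so the recorded ELBO trace is
#' non-decreasing (to numerical precision).
#'
#' @param X n x p dosage (or generic design) matrix; centered internally.
#' @param Y Length-n phenotype vector; centered internally.
#' @param A Optional p x m annotation matrix or [annotation_matrix()]; `NULL`
#'   means intercept-only (the `vb` baseline model).
#' @param theta Named vector/list with `sigma2`, `sigma_beta2`, `eta`.
#' @param init Optional `tgen_vb_state` to warm-start from.
#' @param tol,max_iter Convergence tolerance on |ELBO change| and iteration
#'   cap.
#' @param profile_sigma2 Update `sigma2` each iteration at its ELBO maximizer.
#' @param update_omega Update `q(omega)`; set `FALSE` to keep the prior
#'   inclusion logits fixed at `fixed_prior_logit` (exact Bernoulli prior,
#'   no omega block).
#' @param fixed_prior_logit Length-p vector of fixed prior logits, used only
#'   when `update_omega = FALSE`.
#' @return A `tgen_vb_state`: `alpha`, `mu`, `s2`, `omega_mean`, `omega_cov`,
#'   `xi`, `elbo_trace`, `sigma2` (possibly profiled), `theta`, `converged`,
#'   `iterations`.
#' @export
fit_single_theta <- function(X, Y, A = NULL, theta,
                             init = NULL, tol = 1e-4, max_iter = 500L,
                             profile_sigma2 = TRUE, update_omega = TRUE,
                             fixed_prior_logit = NULL) {
  X <- as.matrix(X)
  Y <- as.numeric(Y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(n >= 2, p >= 1, length(Y) == n)
  if (!all(is.finite(X)) || !all(is.finite(Y))) stop("non-finite values in X or Y")
  theta <- as.list(theta)
  sigma2 <- theta$sigma2; sigma_beta2 <- theta$sigma_beta2; eta <- theta$eta
  stopifnot(sigma2 > 0, sigma_beta2 > 0, eta > 0)

  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- Y - mean(Y)
  Av <- annotation_values(A, p)
  Aint <- cbind(intercept = 1, Av)
  d <- ncol(Aint)
  xx <- colSums(Xc^2)

  if (is.null(init)) {
    alpha <- rep(0.1, p)
    mu <- rep(0, p)
    s2 <- sigma2 / (xx + 1 / sigma_beta2)
    omega_mean <- base::c(logit(0.1), rep(0, d - 1L))
    omega_cov <- diag(1 / eta, d)
    xi <- rep(1, p)
  } else {
    alpha <- init$alpha; mu <- init$mu; s2 <- init$s2
    omega_mean <- init$omega_mean; omega_cov <- init$omega_cov; xi <- init$xi
  }
  if (!update_omega && is.null(fixed_prior_logit)) {
    fixed_prior_logit <- drop(Aint %*% omega_mean)
  }
  if (update_omega) fixed_prior_logit <- NULL

  resid <- Yc - drop(Xc %*% (alpha * mu))
  order0 <- seq_len(p) - 1L  # cyclic, genomic order
  elbo_trace <- numeric(0)
  elbo_prev <- -Inf
  converged <- FALSE
  iter <- 0L

  for (iter in seq_len(max_iter)) {
    prior_logit <- if (update_omega) drop(Aint %*% omega_mean) else fixed_prior_logit
    vb_sweep_inplace(Xc, xx, prior_logit, sigma2, sigma_beta2,
                     alpha, mu, s2, resid, order0)

    if (update_omega) {
      lam <- jj_lambda(xi)
      Sinv <- diag(eta, d) + 2 * crossprod(Aint * lam, Aint)
      omega_cov <- chol2inv(chol(Sinv))
      omega_mean <- drop(omega_cov %*% crossprod(Aint, alpha - 0.5))
      M <- omega_cov + tcrossprod(omega_mean)
      xi <- sqrt(pmax(rowSums((Aint %*% M) * Aint), 1e-12))
    }

    if (profile_sigma2) {
      equad <- sum(resid^2) + sum(xx * (alpha * (s2 + mu^2) - (alpha * mu)^2))
      sigma2 <- (equad + sum(alpha * (s2 + mu^2)) / sigma_beta2) /
        (n + sum(alpha))
      sigma2 <- max(sigma2, 1e-10)
    }

    elbo <- vb_elbo(n, xx, resid, alpha, mu, s2, sigma2, sigma_beta2,
                    Aint, omega_mean, omega_cov, xi, eta,
                    fixed_prior_logit = fixed_prior_logit)
    elbo_trace <- base::c(elbo_trace, elbo)
    if (is.finite(elbo_prev) && abs(elbo - elbo_prev) < tol) {
      converged <- TRUE
      break
    }
    elbo_prev <- elbo
  }
  if (!converged) {
    warning("variational fit did not converge in ", max_iter, " iterations")
  }

  structure(list(alpha = alpha, mu = mu, s2 = s2,
                 omega_mean = omega_mean, omega_cov = omega_cov, xi = xi,
                 elbo_trace = elbo_trace, elbo = elbo_trace[length(elbo_trace)],
                 sigma2 = sigma2,
                 theta = list(sigma2 = theta$sigma2, sigma_beta2 = sigma_beta2,
                              eta = eta),
                 x_center = attr(Xc, "scaled:center"), y_center = mean(Y),
                 converged = converged, iterations = iter),
            class = "tgen_vb_state")
}
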