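# Independent oracles for the variational fits. Exact posterior inclusion
# probabilities by enumeration of all 2^p inclusion configurations, using the
# closed-form Gaussian marginal likelihood
#   Y | gamma ~ N(0, sigma2 (I + sigma_beta2 X_g X_g'))
# evaluated via the matrix determinant lemma / Woodbury identity. The prior
# over configurations is either a fixed common inclusion logit, or an
# intercept-only logistic prior integrated numerically over its
# N(0, 1/eta) prior on a fixed quadrature grid. No package internals are
# reused here beyond centering conventions.
oracle_pip <- function(X, Y, sigma2, sigma_beta2, eta = 1,
                       fixed_logit = NULL, nodes = 61) {
  n <- nrow(X); p <- ncol(X)
  stopifnot(p <= 12)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Yc <- Y - mean(Y)
  XtX <- crossprod(Xc); XtY <- crossprod(Xc, Yc); yy <- sum(Yc^2)
  logml <- function(idx) {
    q <- length(idx)
    if (q == 0) return(-0.5 * (n * log(2 * pi) + n * log(sigma2) + yy / sigma2))
    G <- diag(q) + sigma_beta2 * XtX[idx, idx, drop = FALSE]
    ld <- n * log(sigma2) + determinant(G)$modulus[1]
    quad <- (yy - sigma_beta2 * drop(t(XtY[idx]) %*% solve(G, XtY[idx]))) / sigma2
    -0.5 * (n * log(2 * pi) + ld + quad)
  }
  configs <- as.matrix(expand.grid(rep(list(0:1), p)))
  lm_g <- apply(configs, 1, function(g) logml(which(g == 1)))
  k <- rowSums(configs)
  if (!is.null(fixed_logit)) {
    lp <- lm_g + k * fixed_logit - p * log(1 + exp(fixed_logit))
    w <- exp(lp - max(lp)); w <- w / sum(w)
    return(unname(colSums(configs * w)))
  }
  sdw <- 1 / sqrt(eta)
  grid <- seq(-6, 6, length.out = nodes) * sdw
  wq <- dnorm(grid, 0, sdw); wq <- wq / sum(wq)
  lpmat <- matrix(NA_real_, length(lm_g), nodes)
  for (j in seq_len(nodes)) {
    lpmat[, j] <- lm_g + k * grid[j] - p * log(1 + exp(grid[j])) + log(wq[j])
  }
  W <- exp(lpmat - max(lpmat)); W <- W / sum(W)
  unname(colSums(configs * rowSums(W)))
}
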