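#' Restricted maximum likelihood fit of the strain mixed model
#'
#' Fits `y = X beta + u + e` with `Var(u) = sigma_g^2 K` (kinship-structured
#' genetic values) and `Var(e) = sigma_e^2 I`, profiling the restricted
#' likelihood over the variance ratio `delta = sigma_e^2 / sigma_g^2`. The
#' restricted likelihood is evaluated through the spectral decomposition of
#' the kinship projected onto the residual space of `X`; the optimum over
#' `ln delta` is located by a grid search with safeguarded Newton refinement
#' at every sign change of the derivative, and the global optimum over all
#' refined candidates and the grid endpoints is returned.
#'
#' @param y Numeric phenotype vector (one value per strain).
#' @param X Fixed-effect design matrix; `NULL` for intercept only.
#' @param K Kinship matrix (symmetric, positive semidefinite, unit
#'   diagonal), e.g. from [compute_kinship()].
#' @param ln_delta_range Search interval for `ln delta` (default `[-10, 10]`,
#'   the conventional mixed-model association default).
#' @param grid_points Number of grid points across `ln_delta_range`
#'   (default 100).
#' @return Object of class `variance_components`: list with `sigma_g2`,
#'   `sigma_e2`, `delta`, `reml_loglik`, `heritability`
#'   (`sigma_g2 / (sigma_g2 + sigma_e2)`), and `df` (residual degrees of
#'   freedom `n - rank(X)`).
#' @export
reml_fit <- function(y, X = NULL, K, ln_delta_range = c(-10, 10),
                     grid_points = 100L) {
  if (!is.null(names(y)) && !is.null(rownames(K))) {
    if (!all(rownames(K) %in% names(y)))
      stop("named phenotype vector does not cover the kinship strains",
           call. = FALSE)
    y <- y[rownames(K)]
  }
  y <- as.numeric(y)
  n <- length(y)
  K <- unclass(K)
  stopifnot(nrow(K) == n, ncol(K) == n)
  if (max(abs(K - t(K))) > 1e-8)
    stop("kinship matrix must be symmetric", call. = FALSE)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  q <- qr(X)$rank
  if (q < ncol(X)) stop("covariate design X is rank deficient", call. = FALSE)
  if (n - q < 2L) stop("too few residual degrees of freedom", call. = FALSE)
  evK <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(evK) < -1e-8)
    stop("kinship matrix is not positive semidefinite", call. = FALSE)
  sp <- reml_spectral(y, X, K)
  if (sp$ss < 1e-12 * max(1, sum(y^2)))
    stop("degenerate fit: phenotype is constant (or lies in span of X)",
         call. = FALSE)
  obj <- reml_objective(sp)
  ld <- seq(ln_delta_range[1], ln_delta_range[2], length.out = grid_points)
  dvals <- vapply(ld, function(l) obj$dloglik(exp(l)), numeric(1))
  cand <- exp(ln_delta_range)
  sign_change <- which(dvals[-length(dvals)] > 0 & dvals[-1] < 0)
  for (i in sign_change) {
    cand <- c(cand, newton_root(obj, exp(ld[i]), exp(ld[i + 1])))
  }
  ll <- vapply(cand, obj$loglik, numeric(1))
  delta <- cand[which.max(ll)]
  sigma_g2 <- sum(sp$eta2 / (sp$xi + delta)) / sp$m
  out <- list(
    sigma_g2 = sigma_g2,
    sigma_e2 = delta * sigma_g2,
    delta = delta,
    reml_loglik = max(ll),
    heritability = 1 / (1 + delta),
    df = sp$m
  )
  class(out) <- "variance_components"
  out
}

# Spectral pieces of the restricted likelihood: eigenvalues xi of S K S on
# the residual space of X (m = n - q of them) and squared rotated residuals
# eta^2. Decomposing S (K + I) S instead of S K S keeps the residual space
# (eigenvalues >= 1) numerically separated from span(X) (eigenvalues 0) even
# when K is nearly low rank; xi is recovered by subtracting 1.
reml_spectral <- function(y, X, K) {
  n <- length(y)
  q <- qr(X)$rank
  S <- diag(n) - X %*% solve(crossprod(X), t(X))
  es <- eigen(S %*% (K + diag(n)) %*% S, symmetric = TRUE)
  m <- n - q
  xi <- pmax(es$values[seq_len(m)] - 1, 0)
  eta <- drop(crossprod(es$vectors[, seq_len(m), drop = FALSE], y))
  list(xi = xi, eta2 = eta^2, m = m, ss = sum(eta^2))
}

reml_objective <- function(sp) {
  xi <- sp$xi; eta2 <- sp$eta2; m <- sp$m
  loglik <- function(delta) {
    w <- xi + delta
    0.5 * (m * log(m / (2 * pi)) - m - m * log(sum(eta2 / w)) - sum(log(w)))
  }
  dloglik <- function(delta) {
    w <- xi + delta
    a1 <- sum(eta2 / w); a2 <- sum(eta2 / w^2)
    0.5 * (m * a2 / a1 - sum(1 / w))
  }
  d2loglik <- function(delta) {
    w <- xi + delta
    a1 <- sum(eta2 / w); a2 <- sum(eta2 / w^2); a3 <- sum(eta2 / w^3)
    0.5 * (m * (a2^2 - 2 * a1 * a3) / a1^2 + sum(1 / w^2))
  }
  list(loglik = loglik, dloglik = dloglik, d2loglik = d2loglik)
}

# Newton iteration on the derivative of the restricted log-likelihood within
# a bracketing interval [lo, hi]; falls back to bisection whenever a Newton
# step leaves the bracket or the curvature is unusable.
newton_root <- function(obj, lo, hi, tol = 1e-10, max_iter = 60L) {
  x <- (lo + hi) / 2
  for (i in seq_len(max_iter)) {
    d1 <- obj$dloglik(x)
    if (abs(d1) < tol) break
    if (d1 > 0) lo <- x else hi <- x
    d2 <- obj$d2loglik(x)
    step_ok <- is.finite(d2) && d2 != 0
    x_new <- if (step_ok) x - d1 / d2 else NA_real_
    if (!step_ok || is.na(x_new) || x_new <= lo || x_new >= hi)
      x_new <- (lo + hi) / 2
    if (abs(x_new - x) < tol * max(1, abs(x))) { x <- x_new; break }
    x <- x_new
  }
  x
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf(
    "REML variance components: sigma_g2 = %.4g, sigma_e2 = %.4g, delta = %.4g\n",
    x$sigma_g2, x$sigma_e2, x$delta))
  cat(sprintf("  heritability (K scale) = %.3f, REML logLik = %.4f\n",
              x$heritability, x$reml_loglik))
  invisible(x)
}

#' Strain-level heritability implied by a REML fit
#'
#' `sigma_g2 / (sigma_g2 + sigma_e2)` is on the scale of the supplied
#' kinship matrix; for an identity-like K the two coincide, but an
#' identity-by-state kinship carries a large constant baseline shared by all
#' strains, which the intercept absorbs. The fraction of *strain-to-strain*
#' phenotypic variance that is genetic rescales `sigma_g2` by the Gower
#' factor of K (expected sample variance across strains of a unit-variance
#' genetic value under K).
#'
#' @param vc A `variance_components` object from [reml_fit()].
#' @param K The kinship matrix the fit used.
#' @return Estimated strain-level heritability in `[0, 1]`.
#' @export
heritability_estimate <- function(vc, K) {
  cf <- gower_factor(unclass(K))
  g <- vc$sigma_g2 * cf
  g / (g + vc$sigma_e2)
}
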