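#' Mixed-model association of strain phenotypes with each SNP
#'
#' For each SNP, the strain phenotype is regressed on the additive genotype
#' code under the kinship mixed model: the variance ratio `delta` is
#' estimated by REML (once under the null model in the default `"approx"`
#' mode; re-fitted per SNP with the SNP in the design in `"exact"` mode),
#' the data are rotated into the eigenbasis of `K + delta I`, and the SNP
#' coefficient is tested with a t statistic on `n - rank([X, snp])` degrees
#' of freedom. With `K = identity` both modes reduce exactly to the ordinary
#' least-squares t-test. Strains with a missing call are dropped for that
#' SNP only.
#'
#' The null-model delta is the default because with ~30 strains re-fitting
#' delta per marker measurably inflates type-I error (the marker overfits
#' the variance ratio), while the null-model approximation is near-perfectly
#' calibrated; see the methods vignette.
#'
#' @param y Strain phenotype vector (e.g. `slope_mean` from
#'   [summarize_strains()]), in `genotypes$strain_ids` order, or named by
#'   strain.
#' @param genotypes A filtered [genotype_matrix()] (see [filter_snps()]).
#' @param K Kinship matrix from [compute_kinship()], or `NULL` to compute it
#'   from `genotypes`.
#' @param X Optional covariate design (intercept added automatically when
#'   `NULL`).
#' @param mode `"approx"` (one null-model delta reused for every SNP, the
#'   default) or `"exact"` (re-fit REML per SNP).
#' @return Data frame with one row per SNP: `snp_id`, `chrom`, `pos`, `maf`
#'   (minor-allele strain fraction), `effect` (phenotype units per allele
#'   copy), `stat` (t), `p` (two-sided), `df`, `n_used`, `collinear` (flag;
#'   such rows carry `NA` p).
#' @export
snp_association <- function(y, genotypes, K = NULL, X = NULL,
                            mode = c("approx", "exact")) {
  mode <- match.arg(mode)
  calls <- genotypes$calls
  n <- nrow(calls)
  if (!is.null(names(y))) y <- y[genotypes$strain_ids]
  y <- as.numeric(y)
  stopifnot(length(y) == n)
  if (is.null(K)) K <- compute_kinship(genotypes)
  K <- unclass(K)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  null_delta <- if (mode == "approx") reml_fit(y, X, K)$delta else NA_real_
  eig_full <- eigen(K, symmetric = TRUE)
  m <- ncol(calls)
  maf <- effect <- stat <- p <- rep(NA_real_, m)
  dfs <- n_used <- rep(NA_integer_, m)
  collinear <- rep(FALSE, m)
  for (j in seq_len(m)) {
    x <- calls[, j]
    idx <- which(!is.na(x) & !is.na(y))
    nj <- length(idx)
    n_used[j] <- nj
    xs <- x[idx]
    f <- mean(xs) / 2
    maf[j] <- min(f, 1 - f)
    X2 <- cbind(X[idx, , drop = FALSE], snp = xs)
    rk <- qr(X2)$rank
    if (rk < ncol(X2) || nj - rk < 1L) {
      collinear[j] <- TRUE
      next
    }
    if (nj == n) {
      eg <- eig_full
      Ks <- K
    } else {
      Ks <- K[idx, idx, drop = FALSE]
      eg <- eigen(Ks, symmetric = TRUE)
    }
    delta <- if (mode == "exact") {
      fit <- tryCatch(reml_fit(y[idx], X2, Ks),
                      error = function(e) NULL)
      if (is.null(fit)) { collinear[j] <- TRUE; next }
      fit$delta
    } else null_delta
    w <- 1 / sqrt(pmax(eg$values + delta, 1e-12))
    yt <- w * drop(crossprod(eg$vectors, y[idx]))
    Xt <- w * crossprod(eg$vectors, X2)
    qr_t <- qr(Xt)
    beta <- qr.coef(qr_t, yt)
    res <- yt - Xt %*% beta
    df_j <- nj - qr_t$rank
    s2 <- sum(res^2) / df_j
    xtx_inv <- chol2inv(qr.R(qr_t))
    se <- sqrt(s2 * xtx_inv[ncol(X2), ncol(X2)])
    effect[j] <- beta[ncol(X2)]
    stat[j] <- effect[j] / se
    p[j] <- 2 * pt(-abs(stat[j]), df_j)
    dfs[j] <- df_j
  }
  data.frame(
    snp_id = genotypes$map$snp_id,
    chrom = genotypes$map$chrom,
    pos = genotypes$map$pos,
    maf = maf, effect = effect, stat = stat, p = p,
    df = dfs, n_used = n_used, collinear = collinear,
    stringsAsFactors = FALSE
  )
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param m Number of tests (> 0).
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 281300) # 1.777e-07, prints 1.8e-07 at 2 sf
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (length(m) != 1L || !is.finite(m) || m <= 0)
    stop("number of tests m must be a positive number", call. = FALSE)
  stopifnot(alpha > 0, alpha <= 1)
  alpha / m
}

#' Genomic inflation factor lambda_GC
#'
#' Ratio of the median observed 1-df chi-square statistic (obtained from the
#' two-sided p-values) to its null median; values near 1 indicate calibrated
#' tests.
#'
#' @param p Vector of two-sided p-values.
#' @return Scalar lambda_GC.
#' @export
genomic_inflation <- function(p) {
  p <- p[!is.na(p)]
  median(qchisq(p, df = 1, lower.tail = FALSE)) / qchisq(0.5, df = 1)
}
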