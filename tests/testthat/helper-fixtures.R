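# Shared fixtures and independent oracles, all built in code.

# Tiny genotype matrix from an explicit call matrix (strains x SNPs), all on
# one chromosome with 1e5-spaced positions.
toy_genotypes <- function(calls, chrom = "chr01") {
  ns <- ncol(calls)
  map <- data.frame(
    snp_id = sprintf("s%03d", seq_len(ns)),
    chrom = rep_len(chrom, ns),
    pos = seq_len(ns) * 100000L,
    allele_a = rep_len("A", ns), allele_b = rep_len("G", ns),
    stringsAsFactors = FALSE
  )
  genotype_matrix(calls, map)
}

# Strain-mean phenotypes for a panel: the standard front half of the pipeline.
strain_means <- function(genotypes, config) {
  su <- summarize_strains(simulate_phenotypes(genotypes, config))
  setNames(su$slope_mean, su$strain)
}

# Independent REML oracle: restricted log-likelihood via the determinant
# formula (no spectral shortcut), used to cross-check reml_fit.
direct_reml_loglik <- function(y, X, K, delta) {
  n <- length(y)
  V <- K + delta * diag(n)
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtVX, t(X) %*% Vi)
  m <- n - ncol(X)
  s2 <- drop(t(y) %*% P %*% y) / m
  -0.5 * (m * log(2 * pi * s2) + determinant(V)$modulus +
            determinant(XtVX)$modulus -
            determinant(crossprod(X))$modulus + m)
}

# Two-stage dense grid argmax of the restricted likelihood over ln delta,
# independent of the Newton refinement path.
grid_delta_oracle <- function(y, X, K, pts = 1000L) {
  ll_fun <- function(d) direct_reml_loglik(y, X, K, d)
  ld <- seq(-10, 10, length.out = pts)
  ll <- vapply(exp(ld), ll_fun, numeric(1))
  i <- which.max(ll)
  ld2 <- seq(ld[max(1, i - 2)], ld[min(pts, i + 2)], length.out = pts)
  ll2 <- vapply(exp(ld2), ll_fun, numeric(1))
  exp(ld2[which.max(ll2)])
}

# Reconstruct the z-score from a simulated summary-statistic record.
z_from_record <- function(rec) {
  -qnorm(rec$p_two_sided / 2) * sign(log(rec$effect))
}

# Equal-N four-study panel used by the planted-signal pipeline checks;
# lambda = 5/sqrt(N) gives each study a non-centrality of 5 at signal SNPs.
planted_studies <- function(n = 10000L) {
  data.frame(name = c("discovery", "repl_A", "repl_B", "repl_C"),
             n_samples = rep(as.integer(n), 4),
             ancestry = c("combined", "EA", "EA", "EA"),
             shares_signal = TRUE, stringsAsFactors = FALSE)
}

# Full pipeline on one simulated dataset: mouse association -> gene windows
# -> orthologs -> human screen -> per-gene minimum Fisher-combined log p.
run_planted_pipeline <- function(seed, n_snps = 2000L, effect = 0.8,
                                 causal_index = 905L) {
  cfg <- simulation_config(
    n_snps = n_snps, heritability = 0.5,
    causal_snps = data.frame(snp_index = causal_index, effect = effect),
    studies = planted_studies(), human_effect = 5 / sqrt(10000),
    seed = seed
  )
  ds <- simulate_dataset(cfg)
  gf <- filter_snps(ds$genotypes)
  y <- strain_means(ds$genotypes, cfg)
  assoc <- snp_association(y, gf, compute_kinship(ds$genotypes))
  top <- genes_near_snps(assoc, ds$homology$mouse_genes, 1e-3, 50000)
  orth <- map_orthologs(top, ds$homology$map)
  cand <- screen_candidates(ds$summary_stats, orth$human_genes, 1e-3, 50000)
  disc <- ds$summary_stats$discovery
  repl <- setdiff(names(ds$summary_stats), "discovery")
  gene_logp <- vapply(seq_len(nrow(orth$human_genes)), function(i) {
    g <- orth$human_genes[i, ]
    ids <- disc$snp_id[disc$chrom == g$chrom &
                         disc$pos >= g$start - 50000 &
                         disc$pos <= g$end + 50000]
    if (!length(ids)) return(NA_real_)
    min(vapply(ids, function(id) {
      r0 <- disc[disc$snp_id == id, ]
      d0 <- effect_direction(r0$effect, r0$effect_type)
      pv <- r0$p_two_sided
      for (st in repl) {
        r1 <- ds$summary_stats[[st]]
        r1 <- r1[r1$snp_id == id, ]
        if (nrow(r1)) {
          d1 <- effect_direction(r1$effect, r1$effect_type)
          if (d1 != 0) pv <- c(pv, one_sided_p(r1$p_two_sided, d1, d0))
        }
      }
      fisher_combine(pv)$log_combined_p
    }, numeric(1)))
  }, numeric(1))
  names(gene_logp) <- orth$human_genes$gene_id
  list(truth = ds$truth, candidates = cand, gene_logp = gene_logp)
}
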