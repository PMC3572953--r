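test_that("invalid configurations fail naming the offending field", {
  expect_error(simulation_config(n_strains = 2), "n_strains")
  expect_error(simulation_config(heritability = 1.5), "heritability")
  expect_error(simulation_config(ld_decay_rho = 1), "ld_decay_rho")
  expect_error(simulation_config(maf_distribution = c(0.6, 0.2)),
               "maf_distribution")
  expect_error(
    simulation_config(n_snps = 100,
                      causal_snps = data.frame(snp_index = 101, effect = 1)),
    "causal_snps")
  expect_error(
    simulation_config(studies = data.frame(name = "a", n_samples = 0,
                                           ancestry = "EA",
                                           shares_signal = TRUE)),
    "n_samples")
})

test_that("strain panel is inbred-coded, block-structured and seeded", {
  cfg <- simulation_config(n_strains = 31, n_snps = 1000,
                           block_length_snps = 50, seed = 7)
  g1 <- simulate_strain_panel(cfg)
  g2 <- simulate_strain_panel(cfg)
  expect_identical(g1$calls, g2$calls)
  expect_identical(dim(g1), c(31L, 1000L))
  expect_true(all(g1$calls %in% c(0, 2)))
  # every SNP in a block shares one strain partition
  block_of <- rep(seq_len(20), each = 50)
  for (b in unique(block_of)) {
    blk <- g1$calls[, block_of == b, drop = FALSE]
    expect_true(all(blk == blk[, 1]))
  }
  # different seed changes the panel
  g3 <- simulate_strain_panel(simulation_config(n_strains = 31, n_snps = 1000,
                                                block_length_snps = 50,
                                                seed = 8))
  expect_false(identical(g1$calls, g3$calls))
})

test_that("phenotypes are seeded and reduce correctly in the noise-free limit", {
  cfg <- simulation_config(n_snps = 200, seed = 2)
  g <- simulate_strain_panel(cfg)
  expect_identical(simulate_phenotypes(g, cfg), simulate_phenotypes(g, cfg))
  # one causal SNP, no other variation: strain means split 0.6 apart
  cfg0 <- simulation_config(
    n_snps = 200, slope_sd = 0, residual_sd_within_animal = 0,
    causal_snps = data.frame(snp_index = 42, effect = 0.6), seed = 2)
  su <- summarize_strains(simulate_phenotypes(g, cfg0))
  x <- g$calls[su$strain, 42]
  expect_equal(unname(su$slope_mean[x == 2] - su$slope_mean[x == 0][1]),
               rep(0.6, sum(x == 2)), tolerance = 1e-10)
  expect_equal(sd(su$slope_mean[x == 0]), 0, tolerance = 1e-12)
  # causal index out of range
  expect_error(simulate_phenotypes(
    g, simulation_config(n_snps = 500,
                         causal_snps = data.frame(snp_index = 400,
                                                  effect = 1), seed = 1)),
    "out of range")
})

test_that("zero heritability leaves only sampling noise between strains", {
  ratios <- vapply(1:20, function(s) {
    cfg <- simulation_config(n_snps = 100, heritability = 0, seed = 500 + s)
    g <- simulate_strain_panel(cfg)
    dr <- simulate_phenotypes(g, cfg)
    su <- summarize_strains(dr)
    slopes <- vapply(split(dr, dr$animal_id), function(a)
      fit_animal_slope(a$dose_mg_ml, a$resistance), numeric(1))
    # between-strain variance of means over total animal-slope variance,
    # discounted by the sampling contribution var_within/n
    n_per <- su$n_animals[1]
    (var(su$slope_mean) - mean(tapply(slopes, dr$strain[match(names(slopes),
      dr$animal_id)], var)) / n_per) / var(slopes)
  }, numeric(1))
  expect_lt(abs(mean(ratios)), 0.05)
})

test_that("realized strain-level heritability tracks the config over seeds", {
  for (h2 in c(0.2, 0.5, 0.8)) {
    real <- vapply(1:20, function(s) {
      cfg <- simulation_config(n_snps = 800, heritability = h2,
                               seed = 300 + s)
      g <- simulate_strain_panel(cfg)
      dr <- simulate_phenotypes(g, cfg)
      su <- summarize_strains(dr)
      var(attr(dr, "genetic_values")) / var(su$slope_mean)
    }, numeric(1))
    expect_lt(abs(mean(real) - h2), 0.15)
  }
})

test_that("null summary statistics are uniform and LD-free at rho = 0", {
  genes <- gene_intervals(sprintf("g%03d", 1:167),
                          rep(sprintf("chr%02d", 1:22), length.out = 167),
                          (1:167) * 2e6, (1:167) * 2e6 + 2e5,
                          species = "human")
  cfg <- simulation_config(
    ld_decay_rho = 0, human_effect = 0, seed = 31,
    studies = data.frame(name = "s1", n_samples = 5000L, ancestry = "EA",
                         shares_signal = FALSE))
  st <- simulate_summary_stats(genes, cfg, snps_per_gene = 30)[["s1"]]
  expect_gte(nrow(st), 5000)
  expect_gt(ks.test(st$p_two_sided, "punif")$p.value, 0.01)
  # OR and p are mutually consistent
  z <- z_from_record(st)
  expect_true(all(sign(log(st$effect)) == sign(z) | z == 0))
  # adjacent z uncorrelated
  r <- cor(z[-1], z[-length(z)])
  expect_lt(abs(r), 0.05)
})

test_that("a strong signal gene contains the study minimum p", {
  hits <- 0
  genes <- gene_intervals(sprintf("g%02d", 1:20), "chr01",
                          (1:20) * 2e6, (1:20) * 2e6 + 2e5,
                          species = "human")
  for (s in 1:20) {
    cfg <- simulation_config(
      human_effect = 6 / sqrt(4000), seed = 700 + s,
      studies = data.frame(name = "s1", n_samples = 4000L, ancestry = "EA",
                           shares_signal = TRUE))
    st <- simulate_summary_stats(genes, cfg, signal_genes = "g07",
                                 signal_sign = 1)[["s1"]]
    best <- st[which.min(st$p_two_sided), ]
    sig <- genes[genes$gene_id == "g07", ]
    if (best$chrom == sig$chrom && best$pos >= sig$start - 50000 &&
        best$pos <= sig$end + 50000) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("LD decay follows the configured autoregressive correlation", {
  genes <- gene_intervals("g1", "chr01", 1e6, 1e6 + 6e6, species = "human")
  cfg <- simulation_config(
    ld_decay_rho = 0.6, human_effect = 0, seed = 13,
    studies = data.frame(name = "s1", n_samples = 5000L, ancestry = "EA",
                         shares_signal = FALSE))
  st <- simulate_summary_stats(genes, cfg, snps_per_gene = 4000)[["s1"]]
  z <- z_from_record(st)
  expect_lt(abs(cor(z[-1], z[-length(z)]) - 0.6), 0.1)
})

test_that("truth record pins causal entities and directions", {
  cfg <- simulation_config(
    n_snps = 500, causal_snps = data.frame(snp_index = 250, effect = 0.8),
    seed = 5)
  ds <- simulate_dataset(cfg)
  tr <- ds$truth
  expect_identical(tr$causal_snps$snp_id, ds$genotypes$map$snp_id[250])
  expect_true(length(tr$causal_mouse_genes) >= 1)
  expect_true(all(tr$causal_human_genes %in% ds$homology$map$human_gene))
  expect_true(all(tr$study_directions %in% c(-1, 0, 1)))
  # causal mouse gene covers the causal SNP
  mg <- ds$homology$mouse_genes
  mg <- mg[mg$gene_id %in% tr$causal_mouse_genes, ]
  pos <- ds$genotypes$map$pos[250]
  chr <- ds$genotypes$map$chrom[250]
  expect_true(any(mg$chrom == chr & mg$start <= pos & mg$end >= pos))
})
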