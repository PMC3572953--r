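rec1 <- function(a1, a2, or = 0.92) {
  data.frame(ref_allele = a1, other_allele = a2, effect = or,
             effect_type = "OR", stringsAsFactors = FALSE)
}

test_that("allele harmonization follows the orientation truth table", {
  # reference pair G/T; every reconcilable configuration, hand-derived
  cases <- list(
    list(rec = c("G", "T"), flip = FALSE, amb = FALSE), # same
    list(rec = c("T", "G"), flip = TRUE,  amb = FALSE), # swapped
    list(rec = c("C", "A"), flip = FALSE, amb = FALSE), # strand complement
    list(rec = c("A", "C"), flip = TRUE,  amb = FALSE)  # complement+swap
  )
  for (cs in cases) {
    out <- harmonize_alleles(rec1(cs$rec[1], cs$rec[2]), "G", "T")
    expect_identical(out$flipped, cs$flip)
    expect_identical(out$ambiguous, cs$amb)
    expect_equal(out$effect, if (cs$flip) 1 / 0.92 else 0.92,
                 tolerance = 1e-12)
    expect_identical(c(out$ref_allele, out$other_allele), c("G", "T"))
  }
  # second reference pair A/G behaves identically
  for (cs in list(list(rec = c("A", "G"), flip = FALSE),
                  list(rec = c("G", "A"), flip = TRUE),
                  list(rec = c("T", "C"), flip = FALSE),
                  list(rec = c("C", "T"), flip = TRUE))) {
    out <- harmonize_alleles(rec1(cs$rec[1], cs$rec[2]), "A", "G")
    expect_identical(out$flipped, cs$flip)
  }
  # beta effects negate rather than reciprocate
  b <- data.frame(ref_allele = "T", other_allele = "G", effect = 0.3,
                  effect_type = "beta")
  expect_equal(harmonize_alleles(b, "G", "T")$effect, -0.3)
  # strand-ambiguous pairs flagged but resolved same-strand
  out <- harmonize_alleles(rec1("A", "T"), "A", "T")
  expect_true(out$ambiguous)
  expect_false(out$flipped)
  out <- harmonize_alleles(rec1("C", "G"), "G", "C")
  expect_true(out$ambiguous)
  expect_true(out$flipped)
  # irreconcilable
  expect_error(harmonize_alleles(rec1("A", "G"), "A", "C"),
               "irreconcilable")
})

test_that("one-sided conversion halves or complements", {
  expect_equal(one_sided_p(1.0, +1, +1), 0.5)
  expect_equal(one_sided_p(0.04, +1, +1), 0.02)
  expect_equal(one_sided_p(0.04, -1, +1), 0.98)
  # concordant and discordant conversions of the same p sum to 1
  p <- runif(50)
  expect_equal(one_sided_p(p, 1, 1) + one_sided_p(p, -1, 1), rep(1, 50))
  expect_error(one_sided_p(0.5, 0, 1), "direction")
  expect_error(one_sided_p(0.5, NA, 1), "direction")
  expect_error(one_sided_p(0, 1, 1))
})

test_that("Fisher combination has the chi-square closed form", {
  # single study: chi-square(2) upper tail at -2 ln p is p itself
  for (p in c(0.5, 0.05, 1e-4)) {
    expect_equal(fisher_combine(p)$combined_p, p, tolerance = 1e-12)
  }
  # k identical p-values against the closed form, k = 1..6
  for (k in 1:6) for (alpha in c(0.5, 0.05, 1e-4)) {
    got <- fisher_combine(rep(alpha, k))
    expect_identical(got$df, 2L * k)
    expect_equal(got$combined_p,
                 pchisq(-2 * k * log(alpha), 2 * k, lower.tail = FALSE),
                 tolerance = 1e-12)
    expect_equal(got$combined_p, exp(got$log_combined_p), tolerance = 1e-12)
  }
  # missing studies dropped with df reduced
  got <- fisher_combine(c(0.01, NA, 0.2, NA))
  expect_identical(got$n_studies_used, 2L)
  expect_identical(got$df, 4L)
  expect_error(fisher_combine(c(0.01, NA), allow_missing = FALSE), "missing")
  expect_error(fisher_combine(c(NA_real_, NA_real_)), "no p-values")
  expect_error(fisher_combine(c(0.1, 0)), "> 0")
  expect_error(fisher_combine(1.3), "<= 1")
})

test_that("Fisher combination is monotone and underflow-safe", {
  base <- c(0.03, 0.2, 0.08)
  p0 <- fisher_combine(base)$combined_p
  for (i in 1:3) {
    lowered <- base; lowered[i] <- lowered[i] / 10
    expect_lt(fisher_combine(lowered)$combined_p, p0)
  }
  tiny <- fisher_combine(rep(1e-300, 4))
  expect_true(is.finite(tiny$log_combined_p))
  expect_lt(tiny$log_combined_p, 0)
})

test_that("Fisher combined p is uniform under the null", {
  set.seed(14)
  sims <- replicate(10000, fisher_combine(runif(4))$combined_p)
  expect_gt(ks.test(sims, "punif")$p.value, 0.01)
})

test_that("weighted z meta reduces to Stouffer and stays standard normal", {
  expect_equal(weighted_z_meta(1.7, 800)$Z, 1.7)
  got <- weighted_z_meta(c(1.96, 1.96), c(500, 500))
  expect_equal(got$Z, 3.92 / sqrt(2), tolerance = 1e-12)
  # equal n equals the unweighted Stouffer statistic exactly
  z <- rnorm(5)
  expect_equal(weighted_z_meta(z, rep(123, 5))$Z, sum(z) / sqrt(5),
               tolerance = 1e-12)
  expect_error(weighted_z_meta(numeric(0), numeric(0)), "no studies")
  expect_error(weighted_z_meta(1, -5))
  set.seed(15)
  n <- c(500, 1200, 800, 3000, 90)
  Zs <- replicate(10000, weighted_z_meta(rnorm(5), n)$Z)
  expect_gt(ks.test(Zs, "pnorm")$p.value, 0.01)
})

test_that("report table matches an independent row-by-row recomputation", {
  set.seed(16)
  studies <- c("disc", "r1", "r2", "r3")
  snps <- sprintf("rs%04d", 1:12)
  rows <- list()
  for (s in studies) for (id in snps) {
    if (s != "disc" && runif(1) < 0.15) next # missing study results
    swap <- s != "disc" && runif(1) < 0.5
    rows[[length(rows) + 1]] <- data.frame(
      study = s, ancestry = "EA", snp_id = id, chrom = "4",
      pos = 1e6 + match(id, snps) * 1000,
      ref_allele = if (swap) "G" else "A",
      other_allele = if (swap) "A" else "G",
      p_two_sided = runif(1)^2,
      effect = exp(rnorm(1, 0, 0.1)), effect_type = "OR",
      n_samples = 1000L, stringsAsFactors = FALSE)
  }
  stats <- do.call(rbind, rows)
  tab <- build_table(stats, "disc")
  expect_identical(nrow(tab), 12L)
  for (i in seq_len(nrow(tab))) {
    id <- tab$snp_id[i]
    ref <- stats[stats$study == "disc" & stats$snp_id == id, ]
    dir_ref <- sign(log(ref$effect))
    expected <- ref$p_two_sided
    for (s in c("r1", "r2", "r3")) {
      rr <- stats[stats$study == s & stats$snp_id == id, ]
      if (nrow(rr) == 0) {
        expect_true(is.na(tab[[paste0("p_", s)]][i]))
        next
      }
      eff <- if (rr$ref_allele == ref$ref_allele) rr$effect else 1 / rr$effect
      p1 <- if (sign(log(eff)) == dir_ref) rr$p_two_sided / 2 else
        1 - rr$p_two_sided / 2
      expect_equal(tab[[paste0("p_", s)]][i], p1, tolerance = 1e-12)
      expected <- c(expected, p1)
    }
    expect_equal(tab$p_combined[i],
                 pchisq(-2 * sum(log(expected)), 2 * length(expected),
                        lower.tail = FALSE), tolerance = 1e-10)
    expect_identical(tab$nominal_replication[i],
                     sum(c(tab$p_disc[i], tab$p_r1[i], tab$p_r2[i],
                           tab$p_r3[i]) < 0.05, na.rm = TRUE) >= 3)
  }
  # per-study minimum flags point at actual minima
  for (s in studies) {
    col <- tab[[paste0("p_", s)]]
    marked <- grepl(s, tab$lowest_in, fixed = TRUE)
    expect_identical(which(marked), which(col == min(col, na.rm = TRUE)))
  }
  # reference study absent for a SNP
  stats2 <- stats[!(stats$study == "disc" & stats$snp_id == "rs0001"), ]
  tab2 <- build_table(stats2, "disc", snp_ids = snps)
  expect_true(tab2$direction_missing[tab2$snp_id == "rs0001"])
})
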