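#' Simulation configuration for the synthetic cross-species dataset
#'
#' Bundles every knob of the synthetic-data generator: the mouse strain panel
#' (strain count, animals phenotyped per strain and sex, SNP count, haplotype
#' block length, allele-frequency range), the genetic architecture of the AHR
#' slope phenotype (causal SNPs with per-allele effects, strain-level
#' heritability of the polygenic background, within-animal measurement noise),
#' and the human side (per-study sample sizes and ancestry labels, whether a
#' study carries the shared signal, and the autoregressive correlation of
#' neighbouring summary-statistic z-scores).
#'
#' Defaults describe the emulated study design: 31 inbred strains, 8 animals
#' per strain and sex, SNPs in ancestral haplotype blocks, and strain mean
#' slopes spanning roughly 0.4--1.7 resistance units per log10(mg/ml).
#'
#' @param n_strains Number of inbred strains (>= 3).
#' @param animals_per_strain Animals phenotyped per strain and sex.
#' @param n_snps Number of autosomal SNPs to simulate.
#' @param block_length_snps SNPs per ancestral haplotype block; all SNPs in a
#'   block share one biallelic strain partition.
#' @param maf_distribution Length-2 numeric, lower/upper bound of the uniform
#'   distribution the per-block strain allele frequency is drawn from.
#' @param causal_snps Data frame with columns `snp_index` (1-based) and
#'   `effect` (slope units per allele), or `NULL` for no causal SNP.
#' @param heritability Strain-level heritability of the polygenic background,
#'   in `[0, 1]`: fraction of strain-mean slope variance attributable to the
#'   kinship-structured genetic value.
#' @param residual_sd_within_animal SD of the resistance reading noise around
#'   an animal's latent dose-response line (resistance units).
#' @param slope_mean Population mean latent slope (resistance units per
#'   log10(mg/ml)).
#' @param slope_sd SD of strain latent slopes; together with `slope_mean`
#'   calibrated so 31 strains span roughly 0.4--1.7.
#' @param studies Data frame with columns `name`, `n_samples`, `ancestry`,
#'   `shares_signal` (logical), one row per human GWAS; may have zero rows.
#' @param ld_decay_rho First-order autoregressive correlation of neighbouring
#'   human z-scores, in `[0, 1)`.
#' @param human_effect Per-study non-centrality at signal-gene SNPs on the
#'   z-score scale divided by sqrt(n_samples) (lambda); mean shift is
#'   sqrt(N) * lambda.
#' @param seed Integer seed; all `simulate_*` output is a deterministic
#'   function of the config including this seed.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- simulation_config(n_strains = 10, n_snps = 200, seed = 1)
#' cfg$n_strains
#' @export
simulation_config <- function(n_strains = 31L,
                              animals_per_strain = 8L,
                              n_snps = 2000L,
                              block_length_snps = 10L,
                              maf_distribution = c(0.1, 0.5),
                              causal_snps = NULL,
                              heritability = 0.5,
                              residual_sd_within_animal = 0.05,
                              slope_mean = 1.0,
                              slope_sd = 0.3,
                              studies = default_studies(),
                              ld_decay_rho = 0.5,
                              human_effect = 0.15,
                              seed = 1L) {
  cfg <- list(
    n_strains = as.integer(n_strains),
    animals_per_strain = as.integer(animals_per_strain),
    n_snps = as.integer(n_snps),
    block_length_snps = as.integer(block_length_snps),
    maf_distribution = as.numeric(maf_distribution),
    causal_snps = causal_snps,
    heritability = as.numeric(heritability),
    residual_sd_within_animal = as.numeric(residual_sd_within_animal),
    slope_mean = as.numeric(slope_mean),
    slope_sd = as.numeric(slope_sd),
    studies = studies,
    ld_decay_rho = as.numeric(ld_decay_rho),
    human_effect = as.numeric(human_effect),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

#' Default human study panel for the simulator
#'
#' One multi-ancestry discovery study and three replication studies, mirroring
#' a discovery-plus-replication asthma GWAS design. Sample sizes are order of
#' magnitude only.
#'
#' @return Data frame with columns `name`, `n_samples`, `ancestry`,
#'   `shares_signal`.
#' @export
default_studies <- function() {
  data.frame(
    name = c("discovery", "repl_A", "repl_B", "repl_C"),
    n_samples = c(12000L, 1200L, 26000L, 1900L),
    ancestry = c("combined", "EA", "EA", "EA"),
    shares_signal = c(TRUE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

validate_config <- function(cfg) {
  fail <- function(field, why) {
    stop(sprintf("invalid simulation config: field '%s' %s", field, why),
         call. = FALSE)
  }
  if (is.na(cfg$n_strains) || cfg$n_strains < 3L)
    fail("n_strains", "must be >= 3")
  if (is.na(cfg$animals_per_strain) || cfg$animals_per_strain < 1L)
    fail("animals_per_strain", "must be >= 1")
  if (is.na(cfg$n_snps) || cfg$n_snps < 1L)
    fail("n_snps", "must be >= 1")
  if (is.na(cfg$block_length_snps) || cfg$block_length_snps < 1L)
    fail("block_length_snps", "must be >= 1")
  if (length(cfg$maf_distribution) != 2L ||
      any(!is.finite(cfg$maf_distribution)) ||
      cfg$maf_distribution[1] > cfg$maf_distribution[2] ||
      cfg$maf_distribution[1] < 0 || cfg$maf_distribution[2] > 1)
    fail("maf_distribution", "must be (low, high) within [0, 1]")
  if (!is.finite(cfg$heritability) ||
      cfg$heritability < 0 || cfg$heritability > 1)
    fail("heritability", "must lie in [0, 1]")
  if (!is.finite(cfg$ld_decay_rho) ||
      cfg$ld_decay_rho < 0 || cfg$ld_decay_rho >= 1)
    fail("ld_decay_rho", "must lie in [0, 1)")
  if (cfg$residual_sd_within_animal < 0)
    fail("residual_sd_within_animal", "must be >= 0")
  if (cfg$slope_sd < 0) fail("slope_sd", "must be >= 0")
  if (!is.null(cfg$causal_snps)) {
    cs <- cfg$causal_snps
    if (!is.data.frame(cs) || !all(c("snp_index", "effect") %in% names(cs)))
      fail("causal_snps", "must be a data frame with snp_index and effect")
    if (any(cs$snp_index < 1L | cs$snp_index > cfg$n_snps))
      fail("causal_snps", sprintf("snp_index out of range 1..%d", cfg$n_snps))
  }
  if (!is.null(cfg$studies) && nrow(cfg$studies) > 0) {
    st <- cfg$studies
    need <- c("name", "n_samples", "ancestry", "shares_signal")
    if (!all(need %in% names(st)))
      fail("studies", paste("must have columns", paste(need, collapse = ", ")))
    if (any(st$n_samples <= 0))
      fail("studies", "n_samples must be > 0 for every study")
  }
  invisible(cfg)
}
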