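# Seeded evaluation that restores the caller's RNG state afterwards, so the
# generator is reproducible without clobbering the session RNG.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate an inbred strain genotype panel
#'
#' Inbred laboratory strains descend from a small founder pool and are
#' homozygous genome-wide, so they share large ancestral haplotype blocks.
#' The generator mimics this: SNPs come in blocks that all carry one
#' biallelic strain partition, the partition is drawn from a family structure
#' (strains in the same family usually inherit the same ancestral allele),
#' and calls are coded 0/2 copies of allele B.
#'
#' @param config A [simulation_config()].
#' @param n_families Number of strain subfamilies generating kinship
#'   structure.
#' @param family_flip Probability that a strain's block allele differs from
#'   its family's ancestral allele (controls within- vs between-family
#'   similarity).
#' @return A [genotype_matrix()]; identical for identical configs.
#' @export
simulate_strain_panel <- function(config, n_families = 5L,
                                  family_flip = 0.15) {
  validate_config(config)
  with_seed(config$seed, {
    ns <- config$n_strains
    nsnp <- config$n_snps
    bl <- config$block_length_snps
    n_blocks <- ceiling(nsnp / bl)
    fam <- sample(rep_len(seq_len(n_families), ns))
    calls <- matrix(NA_real_, ns, nsnp)
    block_of <- rep(seq_len(n_blocks), each = bl, length.out = nsnp)
    for (b in seq_len(n_blocks)) {
      f <- runif(1, config$maf_distribution[1], config$maf_distribution[2])
      anc <- as.integer(runif(n_families) < f)
      allele <- anc[fam]
      flip <- runif(ns) < family_flip
      allele[flip] <- 1L - allele[flip]
      calls[, block_of == b] <- 2 * allele
    }
    n_chrom <- 19L
    blocks_per_chrom <- ceiling(n_blocks / n_chrom)
    chrom_of_block <- (seq_len(n_blocks) - 1L) %/% blocks_per_chrom + 1L
    chrom <- sprintf("chr%02d", chrom_of_block[block_of])
    pos <- integer(nsnp)
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      pos[idx] <- 100000L + (seq_along(idx) - 1L) * 30000L
    }
    map <- data.frame(
      snp_id = sprintf("msnp%06d", seq_len(nsnp)),
      chrom = chrom, pos = pos,
      allele_a = "A", allele_b = "G",
      stringsAsFactors = FALSE
    )
    geno <- genotype_matrix(calls, map,
                            sprintf("strain%0*d", max(2L, nchar(ns)),
                                    seq_len(ns)))
    attr(geno, "family") <- fam
    geno
  })
}

# Gower centering factor: expected sample variance across strains of a
# genetic value with covariance K, per unit sigma_g^2. Used to put the
# simulated variance components on the strain-mean variance scale.
gower_factor <- function(K) {
  n <- nrow(K)
  (sum(diag(K)) / n - sum(K) / n^2) * n / (n - 1)
}

#' Simulate per-animal methacholine dose-response tables
#'
#' Each animal receives a saline reading (dose 0) and readings at 1, 3, 10
#' and 30 mg/ml methacholine. Readings follow a latent linear dose-response
#' in log10(dose): the animal's latent slope is the strain latent slope
#' (population mean + causal SNP effects + a kinship-structured polygenic
#' value) plus animal-level noise, and each reading adds instrument noise of
#' SD `residual_sd_within_animal`. Variance components are scaled so that the
#' strain-level heritability of strain mean slopes equals
#' `config$heritability`.
#'
#' @param genotypes [genotype_matrix()] for the strain panel.
#' @param config A [simulation_config()]; causal SNP effects are the full
#'   slope difference between the two homozygote classes.
#' @return Data frame `strain`, `sex`, `animal_id`, `dose_mg_ml`,
#'   `resistance`; dose 0 marks the saline reading.
#' @export
simulate_phenotypes <- function(genotypes, config) {
  validate_config(config)
  ns <- nrow(genotypes$calls)
  if (!is.null(config$causal_snps) &&
      any(config$causal_snps$snp_index > ncol(genotypes$calls)))
    stop("causal snp_index out of range for this genotype matrix",
         call. = FALSE)
  with_seed(config$seed + 1L, {
    h2 <- config$heritability
    sv <- config$slope_sd^2
    latent <- rep(config$slope_mean, ns)
    if (!is.null(config$causal_snps)) {
      for (r in seq_len(nrow(config$causal_snps))) {
        x <- genotypes$calls[, config$causal_snps$snp_index[r]]
        x[is.na(x)] <- 0
        latent <- latent + (x / 2) * config$causal_snps$effect[r]
      }
    }
    gval <- numeric(ns)
    if (h2 > 0 && sv > 0) {
      K <- compute_kinship(genotypes)
      cf <- gower_factor(unclass(K))
      if (cf <= 0)
        stop("degenerate kinship: no genetic contrast between strains",
             call. = FALSE)
      sigma_g <- sqrt(h2 * sv / cf)
      L <- chol(unclass(K) + diag(1e-8, ns))
      gval <- sigma_g * as.vector(crossprod(L, rnorm(ns)))
      latent <- latent + gval
    }
    n_tot <- 2L * config$animals_per_strain
    sd_a <- config$slope_sd * sqrt((1 - h2) * n_tot)
    doses <- c(0, 1, 3, 10, 30)
    rows <- vector("list", ns * n_tot)
    k <- 0L
    for (s in seq_len(ns)) {
      for (sex in c("F", "M")) {
        for (a in seq_len(config$animals_per_strain)) {
          slope_a <- latent[s] + rnorm(1, 0, sd_a)
          baseline <- 0.5
          res <- baseline +
            ifelse(doses == 0, 0, slope_a * log10(pmax(doses, 1))) +
            rnorm(length(doses), 0, config$residual_sd_within_animal)
          k <- k + 1L
          rows[[k]] <- data.frame(
            strain = genotypes$strain_ids[s],
            sex = sex,
            animal_id = sprintf("%s_%s_%02d", genotypes$strain_ids[s], sex, a),
            dose_mg_ml = doses,
            resistance = pmax(res, 1e-3),
            stringsAsFactors = FALSE
          )
        }
      }
    }
    out <- do.call(rbind, rows)
    # realized components, retained for diagnostics and property tests
    attr(out, "genetic_values") <- setNames(gval, genotypes$strain_ids)
    attr(out, "strain_latent") <- setNames(latent, genotypes$strain_ids)
    out
  })
}

#' Simulate a mouse gene annotation and mouse-human homology map
#'
#' Mouse genes are tiled across the simulated SNP map (any causal SNP is
#' guaranteed to fall inside a gene); a configurable fraction of mouse genes
#' has a human ortholog, and a small fraction of mapped genes has two human
#' partners to exercise one-to-many homology. Human orthologs are laid out on
#' their own coordinate system, far enough apart that 50 kb windows never
#' bleed between genes.
#'
#' @param genotypes [genotype_matrix()] from [simulate_strain_panel()].
#' @param config A [simulation_config()].
#' @param n_genes Number of mouse genes to tile.
#' @param ortholog_rate Probability a mouse gene has a human ortholog
#'   (causal genes always map).
#' @param fanout_rate Probability a mapped mouse gene has a second human
#'   partner.
#' @return List with `map` (homology-map data frame), `mouse_genes` and
#'   `human_genes` ([gene_intervals()] tables), `causal_mouse_genes`,
#'   `causal_human_genes` (character vectors).
#' @export
simulate_homology_map <- function(genotypes, config, n_genes = 40L,
                                  ortholog_rate = 0.64, fanout_rate = 0.05) {
  validate_config(config)
  map <- genotypes$map
  nsnp <- nrow(map)
  hw <- max(2L, config$block_length_snps %/% 2L)
  with_seed(config$seed + 2L, {
    centers <- unique(round(seq(1 + hw, nsnp - hw, length.out = n_genes)))
    causal_idx <- if (is.null(config$causal_snps)) integer(0) else
      config$causal_snps$snp_index
    for (ci in causal_idx) {
      centers[which.min(abs(centers - ci))] <- ci
    }
    centers <- sort(unique(centers))
    lo <- pmax(centers - hw, 1L)
    hi <- pmin(centers + hw, nsnp)
    # keep each gene on one chromosome
    for (i in seq_along(centers)) {
      ch <- map$chrom[centers[i]]
      idx <- lo[i]:hi[i]
      idx <- idx[map$chrom[idx] == ch]
      lo[i] <- min(idx); hi[i] <- max(idx)
    }
    mouse_genes <- gene_intervals(
      sprintf("mgene%03d", seq_along(centers)),
      map$chrom[centers], map$pos[lo], map$pos[hi],
      species = "mouse"
    )
    causal_mouse <- unique(vapply(causal_idx, function(ci) {
      inside <- map$chrom[ci] == mouse_genes$chrom &
        map$pos[ci] >= mouse_genes$start & map$pos[ci] <= mouse_genes$end
      mouse_genes$gene_id[which(inside)[1]]
    }, character(1)))
    mapped <- runif(nrow(mouse_genes)) < ortholog_rate
    mapped[mouse_genes$gene_id %in% causal_mouse] <- TRUE
    second <- mapped & runif(nrow(mouse_genes)) < fanout_rate
    slot <- 0L
    pairs <- list()
    for (i in which(mapped)) {
      n_partners <- 1L + as.integer(second[i])
      for (k in seq_len(n_partners)) {
        slot <- slot + 1L
        h_chrom <- sprintf("chr%02d", (slot - 1L) %% 22L + 1L)
        h_start <- ((slot - 1L) %/% 22L) * 2e6 + 1e6
        pairs[[length(pairs) + 1L]] <- data.frame(
          mouse_gene = mouse_genes$gene_id[i],
          mouse_chrom = mouse_genes$chrom[i],
          mouse_start = mouse_genes$start[i],
          mouse_end = mouse_genes$end[i],
          human_gene = sprintf("hgene%03d", slot),
          human_chrom = h_chrom,
          human_start = h_start,
          human_end = h_start + 2e5,
          stringsAsFactors = FALSE
        )
      }
    }
    hmap <- do.call(rbind, pairs)
    human_genes <- gene_intervals(hmap$human_gene, hmap$human_chrom,
                                  hmap$human_start, hmap$human_end,
                                  species = "human")
    causal_human <- hmap$human_gene[hmap$mouse_gene %in% causal_mouse]
    list(map = hmap, mouse_genes = mouse_genes, human_genes = human_genes,
         causal_mouse_genes = causal_mouse,
         causal_human_genes = unique(causal_human))
  })
}

#' Simulate human GWAS summary statistics
#'
#' Per-study z-scores are drawn on the summary-statistic scale (no
#' individual-level genotypes): marginally standard normal under the null,
#' with a first-order autoregressive correlation `ld_decay_rho` between
#' neighbouring SNPs in map order standing in for linkage disequilibrium, and
#' a mean shift of `sqrt(n_samples) * config$human_effect * signal_sign` at
#' SNPs inside signal genes for studies with `shares_signal`. Two-sided
#' p-values and odds ratios are derived consistently from z
#' (`sign(log OR) = sign(z)`).
#'
#' @param human_genes [gene_intervals()] table of human genes; SNPs tile each
#'   gene plus 50 kb flanks.
#' @param config A [simulation_config()]; `config$studies` defines the study
#'   panel.
#' @param signal_genes Character vector of signal gene ids (typically the
#'   truth record's causal human genes).
#' @param signal_sign +1 or -1, shared true effect direction.
#' @param snps_per_gene SNPs simulated per gene region.
#' @return Named list (one element per study) of summary-statistic data
#'   frames with columns `study`, `ancestry`, `snp_id`, `chrom`, `pos`,
#'   `ref_allele`, `other_allele`, `p_two_sided`, `effect`, `effect_type`,
#'   `n_samples`.
#' @export
simulate_summary_stats <- function(human_genes, config,
                                   signal_genes = character(0),
                                   signal_sign = 1,
                                   snps_per_gene = 30L) {
  validate_config(config)
  studies <- config$studies
  if (is.null(studies) || nrow(studies) == 0L) return(list())
  if (any(studies$n_samples <= 0))
    stop("study with n_samples <= 0", call. = FALSE)
  genes <- human_genes[!duplicated(human_genes$gene_id), , drop = FALSE]
  with_seed(config$seed + 3L, {
    snp_rows <- lapply(seq_len(nrow(genes)), function(i) {
      g <- genes[i, ]
      pos <- round(seq(g$start - 50000, g$end + 50000,
                       length.out = snps_per_gene))
      data.frame(chrom = g$chrom, pos = pos, gene_id = g$gene_id,
                 stringsAsFactors = FALSE)
    })
    smap <- do.call(rbind, snp_rows)
    smap <- smap[order(smap$chrom, smap$pos), , drop = FALSE]
    smap <- smap[!duplicated(smap[c("chrom", "pos")]), , drop = FALSE]
    m <- nrow(smap)
    smap$snp_id <- sprintf("hsnp%05d", seq_len(m))
    bases <- c("A", "C", "G", "T")
    al <- t(vapply(seq_len(m), function(i) sample(bases, 2), character(2)))
    smap$ref_allele <- al[, 1]
    smap$other_allele <- al[, 2]
    in_signal <- smap$gene_id %in% signal_genes
    rho <- config$ld_decay_rho
    out <- list()
    for (s in seq_len(nrow(studies))) {
      lambda <- if (isTRUE(studies$shares_signal[s])) config$human_effect else 0
      n_s <- studies$n_samples[s]
      mu <- ifelse(in_signal, sqrt(n_s) * lambda * signal_sign, 0)
      z0 <- numeric(m)
      for (ch in unique(smap$chrom)) {
        idx <- which(smap$chrom == ch)
        e <- rnorm(length(idx))
        zc <- numeric(length(idx))
        zc[1] <- e[1]
        if (length(idx) > 1) {
          for (j in 2:length(idx))
            zc[j] <- rho * zc[j - 1] + sqrt(1 - rho^2) * e[j]
        }
        z0[idx] <- zc
      }
      z <- mu + z0
      p <- pmax(2 * pnorm(-abs(z)), .Machine$double.xmin)
      or <- exp(2 * z / sqrt(n_s))
      out[[studies$name[s]]] <- data.frame(
        study = studies$name[s],
        ancestry = studies$ancestry[s],
        snp_id = smap$snp_id,
        chrom = smap$chrom,
        pos = smap$pos,
        ref_allele = smap$ref_allele,
        other_allele = smap$other_allele,
        p_two_sided = p,
        effect = or,
        effect_type = "OR",
        n_samples = n_s,
        stringsAsFactors = FALSE
      )
    }
    out
  })
}

#' Simulate a complete cross-species dataset with recorded ground truth
#'
#' Runs the full generator: strain panel, dose-response phenotypes, mouse
#' gene annotation plus homology map, and per-study human summary statistics
#' sharing the causal gene's signal. The returned truth record pins down what
#' downstream stages should recover.
#'
#' @param config A [simulation_config()].
#' @inheritParams simulate_homology_map
#' @inheritParams simulate_summary_stats
#' @return List `genotypes`, `dose_response`, `homology` (list from
#'   [simulate_homology_map()]), `summary_stats` (list by study), `truth`
#'   (class `truth_record`).
#' @export
simulate_dataset <- function(config, n_genes = 40L, ortholog_rate = 0.64,
                             snps_per_gene = 30L) {
  validate_config(config)
  genotypes <- simulate_strain_panel(config)
  dose_response <- simulate_phenotypes(genotypes, config)
  homology <- simulate_homology_map(genotypes, config, n_genes = n_genes,
                                    ortholog_rate = ortholog_rate)
  sign <- with_seed(config$seed + 4L, sample(c(-1, 1), 1))
  stats <- simulate_summary_stats(homology$human_genes, config,
                                  signal_genes = homology$causal_human_genes,
                                  signal_sign = sign,
                                  snps_per_gene = snps_per_gene)
  causal <- config$causal_snps
  truth <- structure(list(
    causal_snps = if (is.null(causal)) data.frame(snp_id = character(0),
                                                  snp_index = integer(0),
                                                  effect = numeric(0))
      else data.frame(snp_id = genotypes$map$snp_id[causal$snp_index],
                      snp_index = causal$snp_index,
                      effect = causal$effect, stringsAsFactors = FALSE),
    causal_mouse_genes = homology$causal_mouse_genes,
    causal_human_genes = homology$causal_human_genes,
    study_directions = if (nrow(config$studies) > 0)
      setNames(ifelse(config$studies$shares_signal, sign, 0L),
               config$studies$name) else integer(0),
    seed = config$seed
  ), class = "truth_record")
  list(genotypes = genotypes, dose_response = dose_response,
       homology = homology, summary_stats = stats, truth = truth)
}
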