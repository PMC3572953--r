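#' Screen human summary statistics over ortholog gene windows
#'
#' A human gene becomes a candidate when at least one ancestry stream (each
#' study/ancestry analysis is an independent screen; streams are combined by
#' union) contains a SNP with a two-sided p-value strictly below
#' `p_threshold` within the gene body plus `window_bp` on either side.
#'
#' @param stats Named list of summary-statistic data frames, one per stream
#'   (columns `snp_id`, `chrom`, `pos`, `p_two_sided`).
#' @param ortholog_genes A [gene_intervals()] table of human genes to screen.
#' @param p_threshold Strict screening threshold (default 1e-3).
#' @param window_bp Window on either side of the gene body (default 50000).
#' @return Data frame of candidates: `gene_id`, `support_streams`
#'   (comma-separated), `min_p`, `min_snp`, `min_stream`, `n_snps_in_window`
#'   (across streams' union of SNP positions). Genes with no sub-threshold
#'   SNP are omitted; per-gene SNP coverage for all screened genes is
#'   attached as attribute `"coverage"`.
#' @export
screen_candidates <- function(stats, ortholog_genes, p_threshold = 1e-3,
                              window_bp = 50000) {
  stopifnot(p_threshold > 0, p_threshold <= 1, window_bp >= 0)
  if (is.data.frame(stats)) stats <- list(stream = stats)
  if (is.null(names(stats)) || any(names(stats) == ""))
    names(stats) <- paste0("stream", seq_along(stats))
  genes <- ortholog_genes[!duplicated(ortholog_genes$gene_id), , drop = FALSE]
  cov_rows <- list()
  cand_rows <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lo <- g$start - window_bp
    hi <- g$end + window_bp
    support <- character(0)
    min_p <- Inf; min_snp <- NA_character_; min_stream <- NA_character_
    snp_keys <- character(0)
    for (s in names(stats)) {
      st <- stats[[s]]
      inw <- st$chrom == g$chrom & st$pos >= lo & st$pos <= hi
      if (!any(inw)) next
      sub <- st[inw, , drop = FALSE]
      snp_keys <- union(snp_keys, paste(sub$chrom, sub$pos))
      j <- which.min(sub$p_two_sided)
      if (sub$p_two_sided[j] < min_p) {
        min_p <- sub$p_two_sided[j]
        min_snp <- sub$snp_id[j]
        min_stream <- s
      }
      if (sub$p_two_sided[j] < p_threshold) support <- c(support, s)
    }
    cov_rows[[i]] <- data.frame(gene_id = g$gene_id,
                                n_snps_in_window = length(snp_keys),
                                stringsAsFactors = FALSE)
    if (length(support) > 0) {
      cand_rows[[length(cand_rows) + 1L]] <- data.frame(
        gene_id = g$gene_id,
        support_streams = paste(support, collapse = ","),
        min_p = min_p, min_snp = min_snp, min_stream = min_stream,
        n_snps_in_window = length(snp_keys),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(cand_rows)) do.call(rbind, cand_rows) else
    data.frame(gene_id = character(0), support_streams = character(0),
               min_p = numeric(0), min_snp = character(0),
               min_stream = character(0), n_snps_in_window = integer(0),
               stringsAsFactors = FALSE)
  attr(out, "coverage") <- do.call(rbind, cov_rows)
  out
}

#' Strain minor-allele-count filter for a mouse region
#'
#' A mouse association peak is only trusted when every sub-threshold SNP in
#' the region rests on a minor allele observed in strictly more than
#' `min_count` strains (a minor allele in exactly 2 of 31 strains fails the
#' `> 2/31` criterion).
#'
#' @param assoc Association records from [snp_association()] (needs `chrom`,
#'   `pos`, `p`, `maf`, `n_used`).
#' @param region One-row [gene_intervals()] table (or any list with `chrom`,
#'   `start`, `end`).
#' @param min_count Strain count the minor allele must strictly exceed
#'   (default 2).
#' @param p_threshold Mouse nominal threshold defining the region's
#'   supporting SNPs (default 1e-3).
#' @return `TRUE`/`FALSE`, or `NA` with a warning when the region contains no
#'   mouse SNPs below the threshold.
#' @export
mouse_maf_filter <- function(assoc, region, min_count = 2L,
                             p_threshold = 1e-3) {
  inr <- assoc$chrom == region$chrom & assoc$pos >= region$start &
    assoc$pos <= region$end & !is.na(assoc$p) & assoc$p < p_threshold
  if (!any(inr)) {
    warning("region contains no mouse SNPs below the threshold; ",
            "minor-allele filter indeterminate")
    return(NA)
  }
  counts <- round(assoc$maf[inr] * assoc$n_used[inr])
  all(counts > min_count)
}

#' Genotype-phenotype concordance of one mouse SNP across strains
#'
#' Quantifies the "phenotype distribution matches the genotype distribution"
#' criterion as a rank-biserial correlation between the two homozygote
#' classes and the strain mean slopes (`2U/(n0*n2) - 1`, where `U` counts
#' allele-B-class strains outranking allele-A-class strains), with a Wilcoxon
#' rank-sum p-value between classes. The rank-biserial form reaches exactly
#' +-1 under perfect separation of the classes and 0 when the two classes
#' have identical slope distributions; the plain point-biserial correlation
#' is returned alongside.
#'
#' @param strain_summaries Output of [summarize_strains()].
#' @param snp_calls Named numeric vector (0/2 per strain) of calls at one
#'   SNP; names must cover `strain_summaries$strain`.
#' @return List with `score` (rank-biserial correlation in `[-1, 1]`,
#'   positive when allele-B strains have larger slopes), `rank_p` (Wilcoxon
#'   rank-sum p), `point_biserial`, and class sizes `n0`, `n2`.
#' @export
concordance_score <- function(strain_summaries, snp_calls) {
  x <- snp_calls[strain_summaries$strain]
  keep <- !is.na(x) & !is.na(strain_summaries$slope_mean)
  x <- x[keep]
  slopes <- strain_summaries$slope_mean[keep]
  if (length(unique(x)) < 2L)
    stop("monomorphic SNP: concordance undefined", call. = FALSE)
  n0 <- sum(x == 0)
  n2 <- sum(x == 2)
  wt <- suppressWarnings(wilcox.test(slopes[x == 2], slopes[x == 0],
                                     exact = FALSE, correct = FALSE))
  u2 <- unname(wt$statistic) # pairs where an allele-B strain outranks
  list(score = 2 * u2 / (n0 * n2) - 1,
       rank_p = wt$p.value,
       point_biserial = cor(x, slopes),
       n0 = n0, n2 = n2)
}

#' Count of supporting SNPs in a region
#'
#' Regional support: the number of SNPs with p-value strictly below the
#' threshold, used (per species/stream) as a count-based stand-in for "the
#' association is supported by a region of LD".
#'
#' @param x Numeric vector of p-values, or a data frame with a `p` or
#'   `p_two_sided` column.
#' @param p_threshold Strict threshold.
#' @return Integer count.
#' @export
regional_support <- function(x, p_threshold) {
  p <- if (is.data.frame(x)) {
    if ("p" %in% names(x)) x$p else x$p_two_sided
  } else as.numeric(x)
  sum(!is.na(p) & p < p_threshold)
}

#' Does a region pass the two-species regional-support criterion?
#'
#' @param mouse_count,human_count Supporting SNP counts from
#'   [regional_support()].
#' @param min_support Minimum count required in each species (default 2).
#' @return Logical.
#' @export
regional_support_pass <- function(mouse_count, human_count,
                                  min_support = 2L) {
  mouse_count >= min_support & human_count >= min_support
}
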