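COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Effect direction of a summary-statistic record
#'
#' @param effect Effect estimate (odds ratio or beta).
#' @param effect_type `"OR"` or `"beta"`.
#' @return -1, 0 or +1 (`sign(log OR)` or `sign(beta)`).
#' @export
effect_direction <- function(effect, effect_type) {
  ifelse(effect_type == "OR", sign(log(effect)), sign(effect))
}

#' Orient a summary-statistic record to a reference allele pair
#'
#' Replication effect directions are only comparable once every study reports
#' with respect to the same allele. The record's allele pair is matched to
#' the reference pair directly or through the strand complement; when the
#' record's reference allele corresponds to the reference study's *other*
#' allele, the effect is flipped once (OR to 1/OR, beta to -beta) and the
#' alleles swapped. Strand-ambiguous A/T and C/G SNPs are flagged (and by
#' convention resolved as same-strand matches), not dropped.
#'
#' @param record One-row data frame (or list) with `ref_allele`,
#'   `other_allele`, `effect`, `effect_type`.
#' @param ref_allele,ref_other Reference study's allele pair for this SNP.
#' @return The record with effect/alleles oriented to the reference, plus
#'   logical fields `flipped` and `ambiguous`.
#' @export
harmonize_alleles <- function(record, ref_allele, ref_other) {
  a1 <- toupper(record$ref_allele); a2 <- toupper(record$other_allele)
  r1 <- toupper(ref_allele); r2 <- toupper(ref_other)
  stopifnot(all(c(a1, a2, r1, r2) %in% names(COMPLEMENT)))
  ambiguous <- a1 == COMPLEMENT[[a2]]
  same <- (a1 == r1 && a2 == r2)
  swapped <- (a1 == r2 && a2 == r1)
  comp_same <- (COMPLEMENT[[a1]] == r1 && COMPLEMENT[[a2]] == r2)
  comp_swapped <- (COMPLEMENT[[a1]] == r2 && COMPLEMENT[[a2]] == r1)
  # ambiguous pairs match in several configurations; same-strand wins
  flip <- if (same) FALSE
    else if (swapped) TRUE
    else if (comp_same) FALSE
    else if (comp_swapped) TRUE
    else stop(sprintf(
      "irreconcilable alleles: record %s/%s vs reference %s/%s",
      a1, a2, r1, r2), call. = FALSE)
  out <- record
  if (flip) {
    out$effect <- if (record$effect_type == "OR") 1 / record$effect
                  else -record$effect
  }
  out$ref_allele <- r1
  out$other_allele <- r2
  out$flipped <- flip
  out$ambiguous <- ambiguous
  out
}

#' Direction-aware one-sided p-value for a replication study
#'
#' Converts a replication study's two-sided p-value to the one-sided p-value
#' for the alternative oriented by the discovery study's effect direction:
#' `p/2` when the directions agree, `1 - p/2` when they disagree — so an
#' effect in the opposite direction can never produce an inappropriately
#' small replication p-value.
#'
#' @param p_two Two-sided p-value(s) in `(0, 1]`.
#' @param study_direction,reference_direction Effect direction signs
#'   (+1/-1); see [effect_direction()].
#' @return One-sided p-value(s).
#' @examples
#' one_sided_p(0.04, +1, +1) # 0.02
#' one_sided_p(0.04, -1, +1) # 0.98
#' @export
one_sided_p <- function(p_two, study_direction, reference_direction) {
  if (any(is.na(study_direction)) || any(is.na(reference_direction)) ||
      any(study_direction == 0) || any(reference_direction == 0))
    stop("effect direction required (zero or missing direction)",
         call. = FALSE)
  stopifnot(all(p_two > 0 & p_two <= 1))
  n <- max(length(p_two), length(study_direction),
           length(reference_direction))
  p_two <- rep_len(p_two, n)
  agree <- rep_len(sign(study_direction), n) ==
    rep_len(sign(reference_direction), n)
  ifelse(agree, p_two / 2, 1 - p_two / 2)
}

#' Fisher's combined probability method
#'
#' Combines k independent p-values as `X^2 = -2 sum(ln p_i)`, referred to the
#' upper tail of a chi-square distribution with `2k` degrees of freedom. The
#' tail is computed on the log scale, so extremely small inputs survive
#' without underflow (`log_combined_p` stays finite even when `combined_p`
#' would round to zero in double precision).
#'
#' @param p Vector of p-values in `(0, 1]` (typically the discovery p as
#'   reported plus direction-aware one-sided replication p-values).
#' @param allow_missing Drop `NA` entries (studies without results) with the
#'   degrees of freedom reduced accordingly; if `FALSE`, `NA` is an error.
#' @return Object of class `meta_result`: `p_values`, `n_studies_used`,
#'   `fisher_chi2`, `df` (`2 * n_studies_used`), `combined_p`,
#'   `log_combined_p` (natural log).
#' @examples
#' fisher_combine(c(3.0e-2, 1.0e-3, 1.9e-1, 2.3e-2))$combined_p # 1.1e-4
#' @export
fisher_combine <- function(p, allow_missing = TRUE) {
  p_in <- p
  if (anyNA(p)) {
    if (!allow_missing) stop("missing p-value with allow_missing = FALSE",
                             call. = FALSE)
    p <- p[!is.na(p)]
  }
  if (length(p) == 0L)
    stop("no p-values left to combine", call. = FALSE)
  if (any(p <= 0))
    stop("p-values must be > 0 (log undefined at 0)", call. = FALSE)
  if (any(p > 1)) stop("p-values must be <= 1", call. = FALSE)
  chi2 <- -2 * sum(log(p))
  k <- length(p)
  logp <- pchisq(chi2, df = 2 * k, lower.tail = FALSE, log.p = TRUE)
  out <- list(
    p_values = p_in,
    n_studies_used = k,
    fisher_chi2 = chi2,
    df = 2L * k,
    combined_p = exp(logp),
    log_combined_p = logp
  )
  class(out) <- "meta_result"
  out
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf(
    "Fisher combination of %d p-value(s): X2 = %.4g on %d df, combined p = %.3g\n",
    x$n_studies_used, x$fisher_chi2, x$df, x$combined_p))
  invisible(x)
}

#' Sample-size-weighted z-score meta-analysis
#'
#' The discovery-style meta statistic: a linear combination of per-study z
#' statistics weighted by the square root of study sample size,
#' `Z = sum(sqrt(n_i) z_i) / sqrt(sum(n_i))`, assessed against the standard
#' normal.
#'
#' @param z Per-study z statistics.
#' @param n Per-study sample sizes (> 0), same length as `z`.
#' @return List with `Z` and two-sided `p`.
#' @export
weighted_z_meta <- function(z, n) {
  if (length(z) == 0L) stop("no studies supplied", call. = FALSE)
  stopifnot(length(z) == length(n), all(n > 0))
  Z <- sum(sqrt(n) * z) / sqrt(sum(n))
  list(Z = Z, p = 2 * pnorm(-abs(Z)))
}

#' Assemble a discovery-plus-replication report table
#'
#' For each requested SNP: the discovery (reference) study's two-sided
#' p-value enters as reported; each replication record is allele-harmonized
#' to the reference orientation and converted to a direction-aware one-sided
#' p-value; the per-SNP evidence is combined with [fisher_combine()] over the
#' studies with available results. Flags mark, per study, the SNP achieving
#' that study's smallest p-value among the tabled SNPs, and SNPs nominally
#' replicated (p < `alpha_nominal`) in at least `min_nominal` of the
#' available studies.
#'
#' @param stats Long-format data frame of per-study records: `study`,
#'   `snp_id`, `chrom`, `pos`, `ref_allele`, `other_allele`, `p_two_sided`,
#'   `effect`, `effect_type`.
#' @param reference_study Name of the discovery study whose effect direction
#'   orients the one-sided alternatives.
#' @param snp_ids SNPs to tabulate (default: all SNPs present for the
#'   reference study).
#' @param alpha_nominal Nominal replication threshold (default 0.05).
#' @param min_nominal Number of studies that must be nominally significant
#'   for the replication flag (default 3).
#' @return Data frame with one row per SNP: `snp_id`, `chrom`, `pos`,
#'   `ref_allele`, `other_allele`, one `p_<study>` column per study
#'   (one-sided for replication studies), `p_combined`, `n_studies`,
#'   `lowest_in` (comma-separated studies for which this SNP is the
#'   minimum), `nominal_replication` (logical), `direction_missing`
#'   (reference record absent).
#' @export
build_table <- function(stats, reference_study, snp_ids = NULL,
                        alpha_nominal = 0.05, min_nominal = 3L) {
  studies <- unique(stats$study)
  if (!reference_study %in% studies)
    stop("reference study not present in stats", call. = FALSE)
  repl <- setdiff(studies, reference_study)
  if (is.null(snp_ids))
    snp_ids <- unique(stats$snp_id[stats$study == reference_study])
  rows <- lapply(snp_ids, function(id) {
    recs <- stats[stats$snp_id == id, , drop = FALSE]
    ref <- recs[recs$study == reference_study, , drop = FALSE]
    pvals <- setNames(rep(NA_real_, length(studies)), studies)
    dir_missing <- nrow(ref) == 0L
    meta_info <- c(chrom = NA, pos = NA, a1 = NA_character_,
                   a2 = NA_character_)
    if (!dir_missing) {
      ref <- ref[1, ]
      ref_dir <- effect_direction(ref$effect, ref$effect_type)
      pvals[reference_study] <- ref$p_two_sided
      meta_info <- c(chrom = ref$chrom, pos = ref$pos,
                     a1 = ref$ref_allele, a2 = ref$other_allele)
      for (s in repl) {
        rec <- recs[recs$study == s, , drop = FALSE]
        if (nrow(rec) == 0L) next
        rec <- harmonize_alleles(rec[1, ], ref$ref_allele, ref$other_allele)
        d <- effect_direction(rec$effect, rec$effect_type)
        pvals[s] <- if (d == 0) NA_real_
          else one_sided_p(rec$p_two_sided, d, ref_dir)
      }
    } else {
      any_rec <- recs[1, ]
      meta_info <- c(chrom = any_rec$chrom, pos = any_rec$pos,
                     a1 = any_rec$ref_allele, a2 = any_rec$other_allele)
      for (s in repl) {
        rec <- recs[recs$study == s, , drop = FALSE]
        if (nrow(rec) > 0L) pvals[s] <- rec$p_two_sided[1]
      }
    }
    comb <- if (all(is.na(pvals))) list(combined_p = NA_real_,
                                        n_studies_used = 0L)
      else fisher_combine(unname(pvals), allow_missing = TRUE)
    out <- data.frame(snp_id = id, chrom = meta_info[["chrom"]],
                      pos = as.numeric(meta_info[["pos"]]),
                      ref_allele = meta_info[["a1"]],
                      other_allele = meta_info[["a2"]],
                      stringsAsFactors = FALSE)
    for (s in studies) out[[paste0("p_", s)]] <- pvals[[s]]
    out$p_combined <- comb$combined_p
    out$n_studies <- comb$n_studies_used
    out$nominal_replication <-
      sum(pvals < alpha_nominal, na.rm = TRUE) >= min_nominal
    out$direction_missing <- dir_missing
    out
  })
  tab <- do.call(rbind, rows)
  lowest <- vapply(seq_len(nrow(tab)), function(i) {
    hits <- character(0)
    for (s in studies) {
      col <- tab[[paste0("p_", s)]]
      if (!is.na(col[i]) && col[i] == min(col, na.rm = TRUE))
        hits <- c(hits, s)
    }
    paste(hits, collapse = ",")
  }, character(1))
  tab$lowest_in <- lowest
  tab
}
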