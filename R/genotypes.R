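#' Construct a strain genotype matrix
#'
#' Inbred strains are homozygous at essentially every site, so calls are coded
#' additively as 0 or 2 copies of allele B (code 1 is reserved for
#' heterozygotes but never produced by the simulator); `NA` marks missing.
#'
#' @param calls Numeric matrix, strains x SNPs, values in \{0, 2, NA\}.
#' @param map Data frame with one row per SNP: `snp_id`, `chrom`, `pos`
#'   (1-based), `allele_a`, `allele_b`; must be sorted by (chrom, pos).
#' @param strain_ids Character vector of strain names, one per row of `calls`.
#' @return Object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, map, strain_ids = rownames(calls)) {
  calls <- as.matrix(calls)
  if (is.null(strain_ids)) strain_ids <- paste0("strain", seq_len(nrow(calls)))
  stopifnot(nrow(map) == ncol(calls), length(strain_ids) == nrow(calls))
  if (anyDuplicated(map$snp_id))
    stop("duplicate snp_ids in map", call. = FALSE)
  bad <- !(calls %in% c(0, 2) | is.na(calls))
  if (any(bad))
    stop("genotype calls must be 0, 2 or NA", call. = FALSE)
  ord <- order(map$chrom, map$pos)
  if (!identical(ord, seq_len(nrow(map)))) {
    map <- map[ord, , drop = FALSE]
    calls <- calls[, ord, drop = FALSE]
  }
  rownames(calls) <- strain_ids
  colnames(calls) <- map$snp_id
  structure(list(calls = calls, map = map, strain_ids = strain_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d strains x %d SNPs, %d chromosome(s)\n",
              nrow(x$calls), ncol(x$calls), length(unique(x$map$chrom))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Drop monomorphic and singleton SNPs
#'
#' A strain survey carries no association information at SNPs where all
#' strains share one allele (monomorphic) or where the minor allele is seen in
#' exactly one strain (singleton); both are removed before association
#' testing. Counts dropped per reason are attached as attributes
#' `n_monomorphic` and `n_singleton`.
#'
#' @param genotypes A [genotype_matrix()].
#' @return Filtered `genotype_matrix`.
#' @export
filter_snps <- function(genotypes) {
  calls <- genotypes$calls
  if (ncol(calls) == 0L || nrow(calls) == 0L)
    stop("empty genotype matrix", call. = FALSE)
  n_b <- colSums(calls == 2, na.rm = TRUE)
  n_a <- colSums(calls == 0, na.rm = TRUE)
  minor_count <- pmin(n_a, n_b)
  mono <- minor_count == 0
  single <- minor_count == 1
  keep <- !(mono | single)
  out <- genotype_matrix(calls[, keep, drop = FALSE],
                         genotypes$map[keep, , drop = FALSE],
                         genotypes$strain_ids)
  attr(out, "n_monomorphic") <- sum(mono)
  attr(out, "n_singleton") <- sum(single)
  out
}

#' Identity-by-state kinship between strains
#'
#' Entry (i, j) is the fraction of SNPs, over those non-missing in both
#' strains, at which the two strains carry the same (homozygous) call — the
#' genetic-similarity matrix used to absorb population structure in the mixed
#' model. The diagonal is exactly 1.
#'
#' @param genotypes A [genotype_matrix()].
#' @return Symmetric strains x strains matrix of class `kinship_matrix` with
#'   unit diagonal, entries in `[0, 1]`.
#' @export
compute_kinship <- function(genotypes) {
  calls <- genotypes$calls
  n <- nrow(calls)
  obs <- !is.na(calls)
  g <- calls
  g[!obs] <- 0
  # same-call indicator decomposes over {0,2}: both 2, or both 0
  both2 <- (g == 2) %*% t(g == 2)
  both0 <- ((g == 0) & obs) %*% t((g == 0) & obs)
  overlap <- obs %*% t(obs)
  if (any(overlap == 0))
    stop("strain pair with zero overlapping genotyped SNPs", call. = FALSE)
  K <- (both2 + both0) / overlap
  diag(K) <- 1
  K <- (K + t(K)) / 2
  dimnames(K) <- list(genotypes$strain_ids, genotypes$strain_ids)
  class(K) <- c("kinship_matrix", "matrix", "array")
  K
}
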