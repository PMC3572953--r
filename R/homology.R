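#' Construct a normalized gene interval table
#'
#' Gene coordinates are 1-based inclusive. Coordinates supplied in descending
#' order (as minus-strand genes are sometimes printed) are swapped so that
#' `start <= end` always holds; downstream window arithmetic is strand
#' agnostic.
#'
#' @param gene_id Character vector of gene identifiers.
#' @param chrom Chromosome labels.
#' @param start,end 1-based inclusive coordinates (any order).
#' @param species `"mouse"` or `"human"`.
#' @param strand `"+"`, `"-"` or `"unknown"`; kept as annotation only.
#' @return Data frame of class `gene_intervals` with columns `gene_id`,
#'   `species`, `chrom`, `start`, `end`, `strand`; `start <= end` guaranteed.
#' @examples
#' gene_intervals("KCNIP4", "4", 21950417, 20730227, species = "human")
#' @export
gene_intervals <- function(gene_id, chrom, start, end,
                           species = "mouse", strand = "unknown") {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(start < 0 | end < 0, na.rm = TRUE))
    stop("negative coordinate in gene interval", call. = FALSE)
  swap <- !is.na(start) & !is.na(end) & start > end
  if (any(swap)) {
    tmp <- start[swap]
    start[swap] <- end[swap]
    end[swap] <- tmp
  }
  out <- data.frame(
    gene_id = as.character(gene_id),
    species = rep_len(as.character(species), length(gene_id)),
    chrom = as.character(chrom),
    start = start,
    end = end,
    strand = rep_len(as.character(strand), length(gene_id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("gene_intervals", "data.frame")
  out
}

#' Genes near nominally associated SNPs
#'
#' Selects genes lying within `window_bp` of at least one SNP whose
#' association p-value is strictly below `p_threshold` — the gene-window step
#' that turns a SNP-level strain survey into a candidate gene list. Distance
#' is zero for a SNP inside the gene body and the base-pair gap to the nearest
#' gene edge otherwise; the window boundary is inclusive.
#'
#' @param assoc Data frame of association records with columns `snp_id`,
#'   `chrom`, `pos`, `p` (as produced by [snp_association()]).
#' @param genes A [gene_intervals()] table.
#' @param p_threshold Strict upper bound on the SNP p-value (default 1e-3).
#' @param window_bp Window on either side of the gene body, in bp
#'   (default 50000).
#' @return Character vector of selected `gene_id`s (unique, in `genes` order).
#' @export
genes_near_snps <- function(assoc, genes, p_threshold = 1e-3,
                            window_bp = 50000) {
  stopifnot(window_bp >= 0, p_threshold > 0, p_threshold <= 1)
  hits <- assoc[!is.na(assoc$p) & assoc$p < p_threshold, , drop = FALSE]
  if (nrow(hits) == 0L) return(character(0))
  bad <- setdiff(unique(hits$chrom), unique(genes$chrom))
  # SNP chromosomes absent from the gene annotation are a coordinate-system
  # mismatch only when *no* chromosome label is shared
  if (length(intersect(unique(hits$chrom), unique(genes$chrom))) == 0L)
    stop("no shared chromosome labels between SNPs and genes; offending: ",
         paste(bad, collapse = ", "), call. = FALSE)
  sel <- vapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    on_chr <- hits$chrom == g$chrom
    if (!any(on_chr)) return(FALSE)
    pos <- hits$pos[on_chr]
    d <- ifelse(pos < g$start, g$start - pos,
                ifelse(pos > g$end, pos - g$end, 0))
    any(d <= window_bp)
  }, logical(1))
  unique(genes$gene_id[sel])
}

#' Map mouse genes to human orthologs through a homology map
#'
#' @param mouse_genes Character vector of mouse gene ids to map.
#' @param map Homology map data frame with columns `mouse_gene`,
#'   `mouse_chrom`, `mouse_start`, `mouse_end`, `human_gene`, `human_chrom`,
#'   `human_start`, `human_end` (1-based inclusive). One mouse gene may pair
#'   with several human genes and vice versa; all pairs are retained.
#' @return List with `human_genes` (a [gene_intervals()] table of the human
#'   partners, one row per homology pair, duplicates removed) and `dropped`
#'   (data frame `gene_id`, `reason` for query genes with no ortholog).
#' @export
map_orthologs <- function(mouse_genes, map) {
  mouse_genes <- unique(as.character(mouse_genes))
  if (is.null(map) || nrow(map) == 0L) {
    warning("empty homology map: no orthologs mapped")
    return(list(
      human_genes = gene_intervals(character(0), character(0), numeric(0),
                                   numeric(0), species = "human"),
      dropped = data.frame(gene_id = mouse_genes,
                           reason = rep("no ortholog", length(mouse_genes)),
                           stringsAsFactors = FALSE)
    ))
  }
  hit <- map[map$mouse_gene %in% mouse_genes, , drop = FALSE]
  hit <- hit[!duplicated(hit[c("mouse_gene", "human_gene")]), , drop = FALSE]
  missing <- setdiff(mouse_genes, hit$mouse_gene)
  hg <- gene_intervals(hit$human_gene, hit$human_chrom, hit$human_start,
                       hit$human_end, species = "human")
  hg$mouse_gene <- hit$mouse_gene
  list(
    human_genes = hg,
    dropped = data.frame(gene_id = missing,
                         reason = rep("no ortholog", length(missing)),
                         stringsAsFactors = FALSE)
  )
}

#' Genomic span in kilobases from printed coordinates
#'
#' Accepts coordinates in either order (descending order is common for genes
#' printed on the minus strand) and returns the absolute span in kb.
#'
#' @param coord_a,coord_b Non-negative 1-based coordinates.
#' @return Span `|coord_a - coord_b| / 1000` in kb.
#' @examples
#' gene_span_kb(21950417, 20730227) # 1220.19
#' @export
gene_span_kb <- function(coord_a, coord_b) {
  if (any(c(coord_a, coord_b) < 0))
    stop("negative coordinate", call. = FALSE)
  abs(coord_a - coord_b) / 1000
}
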