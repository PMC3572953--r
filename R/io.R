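# Tab-delimited interchange formats. All coordinates are 1-based inclusive;
# genotype calls are {0, 2, NA}; dose 0 marks the saline/baseline reading.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write / read the strain genotype format
#'
#' Header `snp_id chrom pos allele_a allele_b <strain...>`, one row per SNP,
#' calls in \{0, 2, NA\}.
#'
#' @param genotypes A [genotype_matrix()].
#' @param path File path.
#' @return `read_genotypes()` returns a [genotype_matrix()];
#'   `write_genotypes()` returns `path` invisibly.
#' @export
write_genotypes <- function(genotypes, path) {
  df <- cbind(genotypes$map,
              as.data.frame(t(genotypes$calls)))
  names(df) <- c(names(genotypes$map), genotypes$strain_ids)
  write_tsv(df, path)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  map_cols <- c("snp_id", "chrom", "pos", "allele_a", "allele_b")
  strains <- setdiff(names(df), map_cols)
  calls <- t(as.matrix(df[, strains, drop = FALSE]))
  genotype_matrix(calls, df[, map_cols], strains)
}

#' Write / read the per-animal dose-response format
#'
#' Columns `strain sex animal_id dose_mg_ml resistance`; dose 0 is the
#' saline reading.
#'
#' @param dose_response Data frame in the dose-response format.
#' @param path File path.
#' @export
write_dose_response <- function(dose_response, path) {
  write_tsv(dose_response, path)
  invisible(path)
}

#' @rdname write_dose_response
#' @export
read_dose_response <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(strain = "character", sex = "character",
                            animal_id = "character"))
}

#' Write / read human GWAS summary statistics
#'
#' Columns `study ancestry snp_id chrom pos ref_allele other_allele
#' p_two_sided effect effect_type n_samples`; all studies may share one
#' file. `read_summary_stats()` returns a named list split by study.
#'
#' @param stats Named list of per-study data frames (or one combined data
#'   frame).
#' @param path File path.
#' @export
write_summary_stats <- function(stats, path) {
  df <- if (is.data.frame(stats)) stats else do.call(rbind, stats)
  rownames(df) <- NULL
  write_tsv(df, path)
  invisible(path)
}

#' @rdname write_summary_stats
#' @export
read_summary_stats <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(chrom = "character"))
  out <- split(df, df$study)
  lapply(out, function(x) { rownames(x) <- NULL; x })
}

#' Write / read the mouse-human homology map
#'
#' Columns `mouse_gene mouse_chrom mouse_start mouse_end human_gene
#' human_chrom human_start human_end`, coordinates 1-based inclusive;
#' descending coordinate pairs are normalized on read.
#'
#' @param map Homology-map data frame.
#' @param path File path.
#' @export
write_homology_map <- function(map, path) {
  write_tsv(map, path)
  invisible(path)
}

#' @rdname write_homology_map
#' @export
read_homology_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(mouse_chrom = "character",
                                  human_chrom = "character"))
  for (side in c("mouse", "human")) {
    s <- df[[paste0(side, "_start")]]
    e <- df[[paste0(side, "_end")]]
    swap <- s > e
    df[[paste0(side, "_start")]] <- ifelse(swap, e, s)
    df[[paste0(side, "_end")]] <- ifelse(swap, s, e)
  }
  df
}

#' Write / read a ground-truth record
#'
#' @param truth A `truth_record` from [simulate_dataset()].
#' @param path JSON file path.
#' @export
write_truth <- function(truth, path) {
  obj <- unclass(truth)
  # named vectors must serialize as JSON objects, not bare arrays
  obj$study_directions <- as.list(obj$study_directions)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tr <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr$causal_mouse_genes <- as.character(unlist(tr$causal_mouse_genes))
  tr$causal_human_genes <- as.character(unlist(tr$causal_human_genes))
  dirs <- unlist(tr$study_directions)
  tr$study_directions <- if (is.null(dirs)) integer(0) else dirs
  class(tr) <- "truth_record"
  tr
}

#' Materialize a complete synthetic dataset on disk
#'
#' Generates the dataset deterministically from the config and writes every
#' interchange file: `genotypes.tsv`, `dose_response.tsv`,
#' `summary_stats.tsv` (omitted when the config has no studies),
#' `homology_map.tsv` and `truth.json`. Two calls with the same config
#' produce byte-identical files.
#'
#' @param config A [simulation_config()].
#' @param output_dir Directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_fixtures <- function(config, output_dir) {
  ok <- dir.exists(output_dir) || dir.create(output_dir, recursive = TRUE,
                                             showWarnings = FALSE)
  if (!ok || file.access(output_dir, 2) != 0)
    stop("cannot write to output directory: ", output_dir, call. = FALSE)
  ds <- simulate_dataset(config)
  paths <- c(
    genotypes = file.path(output_dir, "genotypes.tsv"),
    dose_response = file.path(output_dir, "dose_response.tsv"),
    homology_map = file.path(output_dir, "homology_map.tsv"),
    truth = file.path(output_dir, "truth.json")
  )
  write_genotypes(ds$genotypes, paths["genotypes"])
  write_dose_response(ds$dose_response, paths["dose_response"])
  write_homology_map(ds$homology$map, paths["homology_map"])
  write_truth(ds$truth, paths["truth"])
  if (length(ds$summary_stats) > 0) {
    paths <- c(paths,
               summary_stats = file.path(output_dir, "summary_stats.tsv"))
    write_summary_stats(ds$summary_stats, paths["summary_stats"])
  }
  invisible(paths)
}

#' Write per-strain phenotype summaries
#'
#' Columns `strain slope_mean slope_sem n_animals`.
#'
#' @param summaries Output of [summarize_strains()].
#' @param path File path.
#' @export
write_strain_summary <- function(summaries, path) {
  write_tsv(summaries, path)
  invisible(path)
}

#' Write association results
#'
#' Columns `snp_id chrom pos maf effect stat p` (plus bookkeeping columns).
#'
#' @param assoc Output of [snp_association()].
#' @param path File path.
#' @export
write_association <- function(assoc, path) {
  write_tsv(assoc, path)
  invisible(path)
}

#' @rdname write_association
#' @export
read_association <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(chrom = "character"))
}
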