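#' Airway hyperresponsiveness slope for one animal
#'
#' The AHR phenotype is the ordinary least-squares slope of respiratory
#' resistance on log10(methacholine dose). Baseline and saline rows (dose 0)
#' are excluded from the fit: the log of dose 0 is undefined and the
#' phenotype is defined over the methacholine challenge only.
#'
#' @param dose Numeric vector of doses in mg/ml (0 = saline/baseline).
#' @param resistance Resistance readings, same length as `dose`.
#' @return Slope in resistance units per log10(mg/ml).
#' @examples
#' fit_animal_slope(c(0, 1, 3, 10, 30),
#'                  c(0.5, 0.5, 0.88, 1.3, 1.68)) # about 0.8
#' @export
fit_animal_slope <- function(dose, resistance) {
  stopifnot(length(dose) == length(resistance))
  if (any(dose < 0, na.rm = TRUE))
    stop("negative methacholine dose", call. = FALSE)
  keep <- !is.na(dose) & !is.na(resistance) & dose > 0
  d <- dose[keep]
  r <- resistance[keep]
  if (length(unique(d)) < 2L)
    stop("need >= 2 distinct nonzero doses to fit a slope", call. = FALSE)
  x <- log10(d)
  sum((x - mean(x)) * (r - mean(r))) / sum((x - mean(x))^2)
}

#' Per-strain summary of animal AHR slopes
#'
#' Fits one slope per animal with [fit_animal_slope()] and summarizes per
#' strain: mean, SEM (sample SD of animal slopes / sqrt(n)), and animal
#' count. Sexes are pooled unless filtered.
#'
#' @param dose_response Data frame with columns `strain`, `sex`, `animal_id`,
#'   `dose_mg_ml`, `resistance` (the dose-response interchange format).
#' @param sex Optional `"F"` or `"M"` to restrict to one sex.
#' @return Data frame `strain`, `slope_mean`, `slope_sem`, `n_animals`; SEM
#'   is `NA` for single-animal strains.
#' @export
summarize_strains <- function(dose_response, sex = NULL) {
  df <- dose_response
  if (!is.null(sex)) df <- df[df$sex %in% sex, , drop = FALSE]
  if (nrow(df) == 0L) {
    warning("no animals after filtering; empty summary")
    return(data.frame(strain = character(0), slope_mean = numeric(0),
                      slope_sem = numeric(0), n_animals = integer(0)))
  }
  slopes <- vapply(split(df, df$animal_id), function(a)
    fit_animal_slope(a$dose_mg_ml, a$resistance), numeric(1))
  strain_of <- vapply(split(df$strain, df$animal_id), function(s)
    s[1], character(1))
  out <- do.call(rbind, lapply(split(slopes, strain_of), function(s) {
    data.frame(slope_mean = mean(s),
               slope_sem = if (length(s) > 1) sd(s) / sqrt(length(s))
                           else NA_real_,
               n_animals = length(s))
  }))
  out <- data.frame(strain = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(out$strain), , drop = FALSE]
}

#' Fold change in mean AHR slope across strains
#'
#' Ratio of the largest to the smallest strain mean slope — the headline
#' measure of how much baseline airway responsiveness varies across a strain
#' panel.
#'
#' @param summaries Output of [summarize_strains()], or any data frame with a
#'   `slope_mean` column of positive means.
#' @return `max(slope_mean) / min(slope_mean)`.
#' @examples
#' fold_change(data.frame(slope_mean = c(0.40, 1.67))) # 4.175, prints 4.2
#' @export
fold_change <- function(summaries) {
  m <- summaries$slope_mean
  if (any(!is.finite(m)) || any(m <= 0))
    stop("fold change undefined: nonpositive or missing strain mean",
         call. = FALSE)
  max(m) / min(m)
}
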