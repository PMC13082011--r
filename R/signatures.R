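#' The 20-gene ADCC signature
#'
#' Default gene list used to operationalize antibody-dependent cellular
#' cytotoxicity (ADCC) activity from bulk tumor transcriptomes.
#'
#' @return character vector of 20 gene symbols.
#' @export
adcc_signature <- function() {
  c("TNFRSF9", "TNF", "BCL2", "IL21R", "BIRC3", "IKZF2", "CCR7", "CD69",
    "MKI67", "CD226", "CLEC2B", "CXCR4", "TIA1", "TNFSF10", "GZMA",
    "TLR6", "TLR1", "CD244", "CD38", "TLR3")
}

#' Z-score expression within each dataset of origin
#'
#' Per gene and per dataset: subtract the mean and divide by the sample
#' standard deviation (denominator n - 1) across that dataset's samples, so
#' cohorts profiled on different platforms can be integrated. A gene with
#' zero variance within a dataset becomes an all-zero row there, with a
#' warning.
#'
#' @param expr numeric matrix, genes in rows, samples in columns, with
#'   dimnames.
#' @param dataset character/factor of dataset-of-origin labels, one per
#'   sample; each dataset must have >= 2 samples.
#' @param genes optional subset of genes to normalize (default all rows).
#' @return numeric matrix of the selected genes, Z-scored within dataset.
#' @export
zscore_within_dataset <- function(expr, dataset, genes = rownames(expr)) {
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expr must carry gene (row) and sample (column) names")
  }
  if (length(dataset) != ncol(expr)) {
    stop("dataset labels must match the number of samples")
  }
  absent <- setdiff(genes, rownames(expr))
  if (length(absent) == length(genes)) {
    stop("none of the requested genes are present in the matrix")
  }
  genes <- intersect(genes, rownames(expr))
  dataset <- factor(dataset)
  if (any(table(dataset) < 2L)) stop("each dataset needs >= 2 samples")
  out <- expr[genes, , drop = FALSE]
  n_const <- 0L
  for (d in levels(dataset)) {
    cols <- which(dataset == d)
    block <- out[, cols, drop = FALSE]
    mu <- rowMeans(block)
    sdv <- apply(block, 1L, stats::sd)
    const <- sdv == 0
    n_const <- n_const + sum(const)
    sdv[const] <- 1 # centered row is already all zero
    out[, cols] <- (block - mu) / sdv
  }
  if (n_const > 0L) {
    warning(sprintf("%d gene-dataset block(s) had zero variance; set to 0",
                    n_const))
  }
  out
}

#' ADCC signature score per sample
#'
#' The unweighted mean of the within-dataset Z-scored signature-gene values
#' per sample. Signature genes missing from the matrix are dropped with a
#' warning giving the count.
#'
#' @param normalized matrix from [zscore_within_dataset()].
#' @param signature character vector of signature genes (default
#'   [adcc_signature()]).
#' @return named numeric vector of per-sample scores.
#' @export
adcc_score <- function(normalized, signature = adcc_signature()) {
  present <- intersect(signature, rownames(normalized))
  if (!length(present)) stop("no signature genes present in the matrix")
  if (length(present) < length(signature)) {
    warning(sprintf("%d signature gene(s) missing from the matrix; dropped",
                    length(signature) - length(present)))
  }
  colMeans(normalized[present, , drop = FALSE])
}

#' Stratify tumors by NK-cell infiltration score
#'
#' Tumors are NK-high when their (precomputed, e.g. deconvolution-derived)
#' NK infiltration score strictly exceeds the cutoff, default 0.01; a score
#' exactly at the cutoff is NK-low — a convention this package fixes since
#' the boundary case is not otherwise standardized.
#'
#' @param nk_scores non-negative numeric vector.
#' @param cutoff threshold (default 0.01, strict `>`).
#' @return factor with levels `low`, `high`.
#' @export
nk_stratify <- function(nk_scores, cutoff = 0.01) {
  if (any(nk_scores < 0, na.rm = TRUE)) stop("NK scores must be >= 0")
  factor(ifelse(nk_scores > cutoff, "high", "low"), levels = c("low", "high"))
}

#' Chi-square test of NK stratum vs CE1 serostatus
#'
#' Builds the 2 x 2 NK-high/low by seropositive/seronegative table and
#' delegates to [arb_category_chisq()] (Pearson, no continuity correction).
#'
#' @param nk_labels factor from [nk_stratify()].
#' @param seropositive logical vector.
#' @return list as from [arb_category_chisq()], plus `table`.
#' @export
serostatus_nk_chisq <- function(nk_labels, seropositive) {
  tab <- table(nk = nk_labels,
               serostatus = factor(ifelse(seropositive, "seropositive",
                                          "seronegative"),
                                   levels = c("seronegative", "seropositive")))
  res <- arb_category_chisq(tab)
  res$table <- tab
  res
}

#' Serostatus-stratified correlation of ASPH with the ADCC score
#'
#' Spearman rank correlation of normalized ASPH expression with the ADCC
#' signature score, computed separately in the CE1-seropositive and
#' seronegative strata (delegating to [stratified_spearman()]).
#'
#' @param asph numeric vector of normalized ASPH expression per sample.
#' @param adcc numeric vector of ADCC scores per sample.
#' @param seropositive logical vector.
#' @return data.frame `stratum`, `rho`, `p`, `n`.
#' @export
stratified_asph_adcc <- function(asph, adcc, seropositive) {
  stratum <- factor(ifelse(seropositive, "seropositive", "seronegative"),
                    levels = c("seronegative", "seropositive"))
  stratified_spearman(asph, adcc, stratum)
}

#' Survival by CE1 serostatus within ASPH-high and ASPH-low tumors
#'
#' Tumors are split at the within-cohort median ASPH expression (samples
#' exactly at the median go to the low stratum); within each ASPH stratum,
#' Kaplan-Meier curves and the log-rank test compare seropositive vs
#' seronegative patients.
#'
#' @param asph numeric vector of (normalized) ASPH expression.
#' @param time,event survival follow-up and 0/1 event indicator.
#' @param seropositive logical vector.
#' @return list with elements `asph_high` and `asph_low`, each a
#'   `km_logrank` result, plus `asph_cutoff` and `stratum_sizes`.
#' @export
asph_sero_survival <- function(asph, time, event, seropositive) {
  cutoff <- stats::median(asph, na.rm = TRUE)
  high <- asph > cutoff
  sero <- factor(ifelse(seropositive, "seropositive", "seronegative"),
                 levels = c("seronegative", "seropositive"))
  run <- function(mask) {
    tryCatch(km_logrank(time[mask], event[mask], sero[mask]),
             error = function(e) {
               warning("survival comparison unavailable in one ASPH stratum: ",
                       conditionMessage(e))
               NULL
             })
  }
  list(asph_high = run(high),
       asph_low = run(!high),
       asph_cutoff = cutoff,
       stratum_sizes = c(high = sum(high), low = sum(!high)))
}
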