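#' Per-individual, per-group mean epitope binding signal
#'
#' Averages the epitope binding signal (EBS; the PhIP-seq enrichment Z-score
#' of a peptide, non-negative by construction) over the peptides of each
#' group for each individual. This is the group-level seroreactivity summary
#' behind the group EBS comparison and the diagnosis logistic model.
#'
#' @param ebs numeric matrix, individuals in rows, peptides in columns, with
#'   dimnames; values must be non-negative.
#' @param assignment data.frame from [assign_groups()] (`peptide_id`,
#'   `group`).
#' @param strict if TRUE (default), a matrix peptide absent from the
#'   assignment is an error; if FALSE such peptides are excluded with a
#'   warning giving the count. Assignments for peptides not in the matrix
#'   are always ignored with a warning.
#' @return data.frame `individual_id`, `group`, `mean_ebs`, `n_peptides`.
#'   Groups with no peptides get `mean_ebs = NA`.
#' @export
group_ebs_summary <- function(ebs, assignment, strict = TRUE) {
  .validate_ebs(ebs)
  pep <- colnames(ebs)
  extra <- setdiff(assignment$peptide_id, pep)
  if (length(extra)) {
    warning(sprintf("%d assignment(s) not present in the EBS matrix; ignored",
                    length(extra)))
  }
  missing <- setdiff(pep, assignment$peptide_id)
  if (length(missing)) {
    if (strict) {
      stop(sprintf("%d matrix peptide(s) missing from the assignment (e.g. '%s')",
                   length(missing), missing[1]))
    }
    warning(sprintf("%d unassigned matrix peptide(s) excluded", length(missing)))
    ebs <- ebs[, setdiff(pep, missing), drop = FALSE]
    pep <- colnames(ebs)
  }
  grp <- assignment$group[match(pep, assignment$peptide_id)]
  out <- lapply(peptide_groups(), function(g) {
    cols <- which(grp == g)
    data.frame(individual_id = rownames(ebs),
               group = g,
               mean_ebs = if (length(cols)) rowMeans(ebs[, cols, drop = FALSE])
                          else NA_real_,
               n_peptides = length(cols),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Antibody repertoire breadth (ARB)
#'
#' ARB is the normalized Shannon diversity of an individual's EBS across the
#' peptides of one group: with \eqn{P_i = EBS_i / \sum_j EBS_j} over the
#' \eqn{S} peptides of the group,
#' \deqn{ARB = -\sum_{i=1}^{S} P_i \ln P_i \,/\, \ln S,}
#' using the continuity convention \eqn{0 \ln 0 = 0}. ARB is 1 when
#' reactivity is spread evenly over all peptides of the group, 0 when it is
#' concentrated on a single peptide, and is undefined (NA, flagged) when the
#' individual has no signal in the group or the group has fewer than two
#' peptides. ARB is invariant to rescaling an individual's group EBS vector.
#'
#' @inheritParams group_ebs_summary
#' @param group one of the labels from [peptide_groups()], or any group
#'   label present in `assignment`.
#' @return data.frame `individual_id`, `group`, `arb`, `n_peptides`,
#'   `total_signal`, `defined`.
#' @examples
#' ebs <- matrix(c(1, 1, 1, 1), 1, 4,
#'               dimnames = list("id1", paste0("p", 1:4)))
#' asn <- data.frame(peptide_id = paste0("p", 1:4), group = "CE1_VP1")
#' compute_arb(ebs, asn, "CE1_VP1")$arb # exactly 1
#' @export
compute_arb <- function(ebs, assignment, group) {
  .validate_ebs(ebs)
  ids <- assignment$peptide_id[assignment$group == group]
  ids <- intersect(colnames(ebs), ids)
  if (!length(ids)) stop(sprintf("group '%s' has no peptides in the matrix", group))
  sub <- ebs[, ids, drop = FALSE]
  S <- length(ids)
  total <- rowSums(sub)
  arb <- rep(NA_real_, nrow(sub))
  defined <- total > 0 & S >= 2
  if (any(defined)) {
    p <- sub[defined, , drop = FALSE] / total[defined]
    plogp <- p * log(p)
    plogp[p == 0] <- 0 # 0 * log(0) := 0
    arb[defined] <- -rowSums(plogp) / log(S) + 0 # + 0 normalizes IEEE -0
  }
  data.frame(individual_id = rownames(ebs),
             group = group,
             arb = arb,
             n_peptides = S,
             total_signal = total,
             defined = defined,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Categorize ARB values into bins and the ARB > 0.5 indicator
#'
#' Default bins are the quartiles of the unit interval:
#' \[0, 0.25\], (0.25, 0.5\], (0.5, 0.75\], (0.75, 1\]. The binary
#' high-breadth indicator uses the strict inequality ARB > 0.5, the survival
#' stratification threshold.
#'
#' @param arb numeric vector of defined ARB values in \[0, 1\] (NA allowed,
#'   propagated).
#' @param edges increasing numeric vector of interior + outer bin edges;
#'   default `c(0, 0.25, 0.5, 0.75, 1)`. Intervals are left-open,
#'   right-closed except the first which includes its left edge.
#' @param indicator_cutoff cutoff for the binary indicator (default 0.5,
#'   strict `>`).
#' @return data.frame `arb`, `category` (ordered factor), `above_cutoff`.
#' @export
arb_category <- function(arb, edges = c(0, 0.25, 0.5, 0.75, 1),
                         indicator_cutoff = 0.5) {
  if (any(arb < min(edges) - 1e-12 | arb > max(edges) + 1e-12, na.rm = TRUE)) {
    stop("arb values outside the binning range")
  }
  category <- cut(arb, breaks = edges, include.lowest = TRUE,
                  ordered_result = TRUE)
  data.frame(arb = arb,
             category = category,
             above_cutoff = arb > indicator_cutoff)
}

#' CE1 seroreactivity score
#'
#' The CE1 seroreactivity of an individual is the mean EBS over a panel of
#' the 40 most reactive CE1-related peptides. In fixed-panel mode (default)
#' the supplied peptide list is taken as that panel, mirroring a panel
#' defined in prior work rather than recomputed per cohort. In data-driven
#' mode the `k` CE1 peptides with the highest cohort-mean EBS are selected
#' (ties broken by lexicographic peptide id) before averaging.
#' Seropositivity is `score > positivity_threshold`; the threshold for
#' "detectable" seroreactivity is not standardized and defaults to 0.
#'
#' @inheritParams group_ebs_summary
#' @param ce1_peptides character vector of CE1 peptide ids, all present in
#'   the matrix.
#' @param k panel size in data-driven mode (default 40).
#' @param positivity_threshold seropositive iff score strictly exceeds this
#'   (default 0).
#' @param mode `"fixed"` (default) or `"data_driven"`.
#' @return data.frame `individual_id`, `score`, `k_used`, `seropositive`.
#' @export
ce1_seroreactivity <- function(ebs, ce1_peptides, k = 40L,
                               positivity_threshold = 0,
                               mode = c("fixed", "data_driven")) {
  mode <- match.arg(mode)
  .validate_ebs(ebs)
  if (!length(ce1_peptides)) stop("ce1_peptides must be non-empty")
  if (k < 1L) stop("k must be >= 1")
  absent <- setdiff(ce1_peptides, colnames(ebs))
  if (length(absent)) {
    stop(sprintf("CE1 peptide(s) absent from the matrix (e.g. '%s')", absent[1]))
  }
  panel <- if (mode == "fixed") {
    ce1_peptides
  } else {
    if (k > length(ce1_peptides)) {
      warning(sprintf("k = %d exceeds the %d CE1 peptides; using all",
                      k, length(ce1_peptides)))
      k <- length(ce1_peptides)
    }
    mu <- colMeans(ebs[, ce1_peptides, drop = FALSE])
    ord <- order(-mu, ce1_peptides)
    ce1_peptides[ord][seq_len(k)]
  }
  score <- rowMeans(ebs[, panel, drop = FALSE])
  data.frame(individual_id = rownames(ebs),
             score = score,
             k_used = length(panel),
             seropositive = score > positivity_threshold,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

.validate_ebs <- function(ebs) {
  if (!is.matrix(ebs) || !is.numeric(ebs)) stop("ebs must be a numeric matrix")
  if (is.null(rownames(ebs)) || is.null(colnames(ebs))) {
    stop("ebs must carry individual (row) and peptide (column) names")
  }
  if (anyDuplicated(rownames(ebs)) || anyDuplicated(colnames(ebs))) {
    stop("duplicate individual or peptide identifiers")
  }
  if (anyNA(ebs) || any(ebs < 0)) {
    stop("EBS values must be non-negative and non-missing")
  }
  invisible(TRUE)
}
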