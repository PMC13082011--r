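#' Partition a peptide catalog into CE1-VP1, non-CE1 VP1 and non-VP1 groups
#'
#' Each peptide in the catalog tiles a stretch of an EV/RV polyprotein, in
#' 1-based closed residue coordinates. Polyprotein chain annotations (the
#' UniProt "Chain" convention) locate the VP1 capsid protein and, within it,
#' the CE1 consensus-epitope window. A peptide is assigned to
#' \code{CE1_VP1} when its interval shares at least \code{min_ce1_overlap}
#' residues with the CE1 window, \code{NON_CE1_VP1} when it intersects the
#' VP1 chain but not the CE1 window, and \code{NON_VP1} otherwise. The
#' result is always a partition: every peptide receives exactly one group.
#'
#' @param catalog data.frame with columns `peptide_id`, `accession`,
#'   `start`, `end` (1-based inclusive polyprotein coordinates) and
#'   optionally `strain`.
#' @param annotations data.frame with columns `accession`, `chain_name`
#'   (one of VP1, VP2, VP3, VP4, NONSTRUCTURAL), `start`, `end`, and for VP1
#'   rows optionally `ce1_start`, `ce1_end` (NA elsewhere).
#' @param min_ce1_overlap minimum number of shared residues with the CE1
#'   window required for the CE1_VP1 call (default 1).
#' @return data.frame with columns `peptide_id` and `group` (factor with
#'   levels CE1_VP1, NON_CE1_VP1, NON_VP1), one row per catalog peptide, in
#'   catalog order.
#' @examples
#' ann <- data.frame(accession = "P1", chain_name = "VP1",
#'                   start = 800, end = 1090, ce1_start = 860, ce1_end = 900)
#' cat <- data.frame(peptide_id = "pep1", accession = "P1",
#'                   start = 850, end = 905)
#' assign_groups(cat, ann)$group # CE1_VP1
#' @export
assign_groups <- function(catalog, annotations, min_ce1_overlap = 1L) {
  annotations <- validate_annotations(annotations)
  req <- c("peptide_id", "accession", "start", "end")
  miss <- setdiff(req, names(catalog))
  if (length(miss)) {
    stop("catalog is missing columns: ", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(catalog$peptide_id)) {
    stop("duplicate peptide_id in catalog")
  }
  if (any(catalog$start < 1L) || any(catalog$end < catalog$start)) {
    stop("peptide coordinates must satisfy 1 <= start <= end")
  }

  unknown <- !(catalog$accession %in% annotations$accession)
  if (any(unknown)) {
    stop(sprintf("peptide '%s' references unknown accession '%s'",
                 catalog$peptide_id[which(unknown)[1]],
                 catalog$accession[which(unknown)[1]]))
  }
  acc_len <- tapply(annotations$end, annotations$accession, max)
  too_far <- catalog$end > acc_len[catalog$accession]
  if (any(too_far)) {
    k <- which(too_far)[1]
    stop(sprintf("peptide '%s' extends beyond annotated polyprotein '%s' (end %d > %d)",
                 catalog$peptide_id[k], catalog$accession[k],
                 catalog$end[k], acc_len[[catalog$accession[k]]]))
  }

  vp1 <- annotations[annotations$chain_name == "VP1", , drop = FALSE]
  group <- character(nrow(catalog))
  for (k in seq_len(nrow(catalog))) {
    v <- vp1[vp1$accession == catalog$accession[k], , drop = FALSE]
    ps <- catalog$start[k]
    pe <- catalog$end[k]
    in_vp1 <- FALSE
    in_ce1 <- FALSE
    for (r in seq_len(nrow(v))) {
      if (.overlap_len(ps, pe, v$start[r], v$end[r]) >= 1L) in_vp1 <- TRUE
      if (!is.na(v$ce1_start[r]) &&
          .overlap_len(ps, pe, v$ce1_start[r], v$ce1_end[r]) >= min_ce1_overlap) {
        in_ce1 <- TRUE
      }
    }
    group[k] <- if (in_vp1 && in_ce1) "CE1_VP1"
                else if (in_vp1) "NON_CE1_VP1"
                else "NON_VP1"
  }
  data.frame(peptide_id = catalog$peptide_id,
             group = factor(group, levels = peptide_groups()),
             stringsAsFactors = FALSE)
}

#' Peptide group labels, in canonical order
#' @return character vector of the three group labels.
#' @export
peptide_groups <- function() c("CE1_VP1", "NON_CE1_VP1", "NON_VP1")

# Length of the intersection of two 1-based closed intervals.
.overlap_len <- function(a1, a2, b1, b2) {
  max(0L, min(a2, b2) - max(a1, b1) + 1L)
}

validate_annotations <- function(annotations) {
  req <- c("accession", "chain_name", "start", "end")
  miss <- setdiff(req, names(annotations))
  if (length(miss)) {
    stop("annotations are missing columns: ", paste(miss, collapse = ", "))
  }
  if (!all(c("ce1_start", "ce1_end") %in% names(annotations))) {
    annotations$ce1_start <- NA_integer_
    annotations$ce1_end <- NA_integer_
  }
  ok_chain <- c("VP1", "VP2", "VP3", "VP4", "NONSTRUCTURAL")
  if (!all(annotations$chain_name %in% ok_chain)) {
    stop("chain_name must be one of ", paste(ok_chain, collapse = ", "))
  }
  if (any(annotations$start < 1L) || any(annotations$end < annotations$start)) {
    stop("chain coordinates must satisfy 1 <= start <= end")
  }
  has_ce1 <- !is.na(annotations$ce1_start)
  if (any(has_ce1 & annotations$chain_name != "VP1")) {
    stop("CE1 window may only be annotated on a VP1 chain")
  }
  bad_win <- has_ce1 & (annotations$ce1_start > annotations$ce1_end |
                        annotations$ce1_start < annotations$start |
                        annotations$ce1_end > annotations$end)
  if (any(bad_win)) {
    stop("CE1 window must lie within its VP1 chain")
  }
  # chains of one accession must not overlap
  for (acc in unique(annotations$accession)) {
    a <- annotations[annotations$accession == acc, , drop = FALSE]
    a <- a[order(a$start), , drop = FALSE]
    if (nrow(a) > 1 && any(a$start[-1] <= a$end[-nrow(a)])) {
      stop(sprintf("overlapping chains in accession '%s'", acc))
    }
  }
  invisible(annotations)
}
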