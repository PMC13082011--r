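#' Fold-change enrichment of IP-MS protein intensities
#'
#' For each protein and each (cell line, antibody) intensity table, the
#' enrichment fold change over the control antibody is
#' \code{(target + pseudocount) / (control + pseudocount)}; a protein passes
#' when the fold change strictly exceeds `cutoff` (default 100, the
#' enriched-binder definition). The pseudocount (default 1 intensity unit)
#' keeps the ratio finite when the control intensity is zero, as happens
#' with missing DIA intensities.
#'
#' @param intensities data.frame with columns `cell_line`, `antibody`,
#'   `protein_id`, `target`, `control` (non-negative intensities). Proteins
#'   absent from a table are treated as intensity 0 when tables are
#'   combined upstream.
#' @param pseudocount positive pseudocount added to both intensities.
#' @param cutoff enrichment threshold (strict `>`), default 100.
#' @return the input with columns `fold_change` and `pass` appended.
#' @examples
#' tb <- data.frame(cell_line = "Huh7", antibody = "rB9",
#'                  protein_id = "P1", target = 10100, control = 100)
#' compute_fold_changes(tb)$fold_change # 10101/101 = 100.0099..., pass
#' @export
compute_fold_changes <- function(intensities, pseudocount = 1, cutoff = 100) {
  req <- c("cell_line", "antibody", "protein_id", "target", "control")
  miss <- setdiff(req, names(intensities))
  if (length(miss)) stop("intensities missing columns: ",
                         paste(miss, collapse = ", "))
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (any(intensities$target < 0) || any(intensities$control < 0)) {
    stop("intensities must be non-negative")
  }
  intensities$fold_change <- (intensities$target + pseudocount) /
    (intensities$control + pseudocount)
  intensities$pass <- intensities$fold_change > cutoff
  intensities
}

#' Intersect enrichment verdicts across cell lines
#'
#' A protein is enriched when it passes the fold-change filter in every cell
#' line (`cell_line_mode = "all"`, the default, matching enrichment "in both
#' cell lines"). Within one cell line, passing under either antibody counts
#' by default (`antibody_mode = "any"`, matching enrichment "by rB9 or
#' rB10"); `"all"` requires every antibody.
#'
#' @param verdicts output of [compute_fold_changes()] (columns `cell_line`,
#'   `antibody`, `protein_id`, `pass`).
#' @param cell_line_mode `"all"` (default) or `"any"` across cell lines.
#' @param antibody_mode `"any"` (default) or `"all"` across antibodies
#'   within a cell line.
#' @return character vector of enriched protein ids (sorted).
#' @export
intersect_enriched <- function(verdicts, cell_line_mode = c("all", "any"),
                               antibody_mode = c("any", "all")) {
  cell_line_mode <- match.arg(cell_line_mode)
  antibody_mode <- match.arg(antibody_mode)
  lines <- unique(verdicts$cell_line)
  universe <- unique(verdicts$protein_id)
  per_line <- lapply(lines, function(cl) {
    v <- verdicts[verdicts$cell_line == cl, , drop = FALSE]
    agg <- tapply(v$pass, v$protein_id,
                  if (antibody_mode == "any") any else all)
    names(agg)[!is.na(agg) & agg]
  })
  hits <- if (cell_line_mode == "all") Reduce(intersect, per_line, universe)
          else Reduce(union, per_line, character(0))
  sort(hits)
}

#' Cross-reference enriched proteins with a surface proteome list
#'
#' Set intersection on normalized identifiers: case is folded and, when
#' `strip_isoform = TRUE` (default), a trailing isoform suffix (`-2` in
#' `P12345-2`) is removed before matching, so isoform-level IP-MS ids match
#' canonical surface-proteome accessions.
#'
#' @param enriched character vector of enriched protein ids.
#' @param surface_list character vector of surface proteome ids.
#' @param strip_isoform strip `-<digits>` isoform suffixes before matching.
#' @return the retained (original, un-normalized) enriched ids, sorted.
#' @export
filter_surface <- function(enriched, surface_list, strip_isoform = TRUE) {
  if (!length(surface_list)) {
    warning("empty surface list: no candidates retained")
    return(character(0))
  }
  norm <- function(ids) {
    ids <- toupper(trimws(ids))
    if (strip_isoform) ids <- sub("-[0-9]+$", "", ids)
    ids
  }
  sort(enriched[norm(enriched) %in% norm(surface_list)])
}

#' Local alignment of the epitope query against a candidate protein
#'
#' Smith-Waterman local alignment under BLOSUM62 with affine gap penalties
#' (a gap of length k costs `gap_open + k * gap_ext`; defaults 11 and 1).
#' Besides the raw score, the report carries a bit score and a
#' Karlin-Altschul expect value \eqn{E = K m n e^{-\lambda S}} with the
#' standard gapped BLOSUM62 constants (K = 0.041, lambda = 0.267) and
#' m, n the query and subject lengths (no database-size correction: the
#' pipeline uses E only to rank candidates). Each aligned column is flagged
#' `identity`, `conserved` (different residues with BLOSUM62 score > 0),
#' `mismatch`, or `gap`.
#'
#' @param query amino-acid string (canonical 20-letter alphabet), e.g. the
#'   CE1 epitope peptide.
#' @param subject candidate protein sequence (same alphabet).
#' @param gap_open,gap_ext affine gap penalties (positive costs).
#' @param K,lambda Karlin-Altschul constants for the expect value.
#' @param query_name,subject_name identifiers carried into the report.
#' @return list of class `"alignment_report"`: `query_name`, `subject_name`,
#'   `raw_score`, `bit_score`, `expect`, `query_aligned`, `subject_aligned`
#'   (gapped strings), `flags` (per-column character vector), `query_range`,
#'   `subject_range` (1-based inclusive), `n_identity`, `n_conserved`.
#' @examples
#' rep <- align_query("CSESVPALTAVETGHTS", "CSESVPALTAVETGHTS")
#' rep$raw_score # 87, the sum of BLOSUM62 diagonal entries
#' @export
align_query <- function(query, subject, gap_open = 11L, gap_ext = 1L,
                        K = 0.041, lambda = 0.267,
                        query_name = "query", subject_name = "subject") {
  qi <- .aa_index(query, "query")
  si <- .aa_index(subject, "subject")
  res <- .sw_align_cpp(qi, si, .blosum62, as.integer(gap_open),
                       as.integer(gap_ext))
  qc <- strsplit(query, "")[[1]]
  sc <- strsplit(subject, "")[[1]]
  qa <- ifelse(res$q_pos > 0, qc[res$q_pos], "-")
  sa <- ifelse(res$s_pos > 0, sc[res$s_pos], "-")
  flags <- vapply(seq_along(qa), function(k) {
    if (qa[k] == "-" || sa[k] == "-") return("gap")
    if (qa[k] == sa[k]) return("identity")
    if (.blosum62[qa[k], sa[k]] > 0) "conserved" else "mismatch"
  }, character(1))
  structure(list(query_name = query_name,
                 subject_name = subject_name,
                 raw_score = res$score,
                 bit_score = (lambda * res$score - log(K)) / log(2),
                 expect = K * length(qi) * length(si) *
                   exp(-lambda * res$score),
                 query_aligned = paste(qa, collapse = ""),
                 subject_aligned = paste(sa, collapse = ""),
                 flags = flags,
                 query_range = c(res$q_start, res$q_end),
                 subject_range = c(res$s_start, res$s_end),
                 n_identity = sum(flags == "identity"),
                 n_conserved = sum(flags == "conserved")),
            class = "alignment_report")
}

#' @export
print.alignment_report <- function(x, ...) {
  glyph <- c(identity = "|", conserved = "+", mismatch = " ", gap = " ")
  cat(sprintf("%s vs %s: raw %d, bit %.1f, E = %.3g, subject %d-%d\n",
              x$query_name, x$subject_name, x$raw_score, x$bit_score,
              x$expect, x$subject_range[1], x$subject_range[2]))
  cat(" ", x$query_aligned, "\n ",
      paste(glyph[x$flags], collapse = ""), "\n ",
      x$subject_aligned, "\n", sep = "")
  invisible(x)
}

#' Rank surface candidates by alignment to the epitope query
#'
#' Aligns the query against each candidate sequence and sorts by ascending
#' expect value, ties by descending raw score, then lexicographic candidate
#' id. Candidates without a sequence are dropped with a warning.
#'
#' @param candidates character vector of candidate protein ids.
#' @param sequences named character vector (or `Biostrings::AAStringSet`) of
#'   candidate sequences.
#' @param query epitope query string.
#' @param ... passed to [align_query()].
#' @return list with `table` (data.frame `rank`, `protein_id`, `raw_score`,
#'   `bit_score`, `expect`, `n_identity`, `n_conserved`, `subject_start`,
#'   `subject_end`) and `alignments` (named list of alignment reports).
#' @export
rank_candidates <- function(candidates, sequences, query, ...) {
  if (methods::is(sequences, "AAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  if (!length(candidates)) {
    return(list(table = data.frame(rank = integer(0), protein_id = character(0),
                                   raw_score = integer(0), bit_score = numeric(0),
                                   expect = numeric(0), n_identity = integer(0),
                                   n_conserved = integer(0),
                                   subject_start = integer(0),
                                   subject_end = integer(0)),
                alignments = list()))
  }
  absent <- setdiff(candidates, names(sequences))
  if (length(absent)) {
    warning(sprintf("%d candidate(s) without a sequence dropped (e.g. '%s')",
                    length(absent), absent[1]))
    candidates <- setdiff(candidates, absent)
  }
  reports <- lapply(candidates, function(id) {
    align_query(query, sequences[[id]], subject_name = id, ...)
  })
  names(reports) <- candidates
  tab <- data.frame(protein_id = candidates,
                    raw_score = vapply(reports, `[[`, numeric(1), "raw_score"),
                    bit_score = vapply(reports, `[[`, numeric(1), "bit_score"),
                    expect = vapply(reports, `[[`, numeric(1), "expect"),
                    n_identity = vapply(reports, `[[`, numeric(1), "n_identity"),
                    n_conserved = vapply(reports, `[[`, numeric(1), "n_conserved"),
                    subject_start = vapply(reports, function(r) r$subject_range[1],
                                           numeric(1)),
                    subject_end = vapply(reports, function(r) r$subject_range[2],
                                         numeric(1)),
                    stringsAsFactors = FALSE)
  ord <- order(tab$expect, -tab$raw_score, tab$protein_id)
  tab <- tab[ord, , drop = FALSE]
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  list(table = tab, alignments = reports[tab$protein_id])
}

#' Run the full mimicry funnel
#'
#' Fold-change filtering per (cell line, antibody), intersection across cell
#' lines, surface-proteome cross-referencing, and alignment ranking against
#' the query — with the candidate count logged at each stage (the funnel is
#' monotone: enriched >= surface >= ranked).
#'
#' @inheritParams compute_fold_changes
#' @inheritParams intersect_enriched
#' @inheritParams filter_surface
#' @inheritParams rank_candidates
#' @return list `fold_changes`, `enriched`, `surface`, `ranking`, `counts`.
#' @export
mimicry_funnel <- function(intensities, surface_list, sequences, query,
                           pseudocount = 1, cutoff = 100,
                           cell_line_mode = "all", antibody_mode = "any",
                           strip_isoform = TRUE, ...) {
  fc <- compute_fold_changes(intensities, pseudocount = pseudocount,
                             cutoff = cutoff)
  enriched <- intersect_enriched(fc, cell_line_mode = cell_line_mode,
                                 antibody_mode = antibody_mode)
  surface <- filter_surface(enriched, surface_list,
                            strip_isoform = strip_isoform)
  ranking <- rank_candidates(surface, sequences, query, ...)
  list(fold_changes = fc, enriched = enriched, surface = surface,
       ranking = ranking,
       counts = c(proteins = length(unique(fc$protein_id)),
                  enriched = length(enriched), surface = length(surface),
                  ranked = nrow(ranking$table)))
}

#' Two-way ANOVA summary of dose-response competition readouts
#'
#' Two-way ANOVA of a readout (e.g. ELISA binding signal or growth index)
#' on condition and dose/time, with the interaction. Balanced designs use
#' the classical sums-of-squares decomposition; unbalanced designs use
#' Type-II sums of squares (via `car::Anova`).
#'
#' @param readout numeric response.
#' @param condition factor of competitor/antibody condition.
#' @param dose factor of dose or time point.
#' @param type `"II"` (default) or `"I"` sums of squares.
#' @return data.frame `term`, `sum_sq`, `df`, `F`, `p`.
#' @export
competition_summary <- function(readout, condition, dose, type = c("II", "I")) {
  type <- match.arg(type)
  dat <- data.frame(y = readout, condition = factor(condition),
                    dose = factor(dose))
  fit <- stats::lm(y ~ condition * dose, data = dat)
  if (type == "I") {
    a <- stats::anova(fit)
    out <- data.frame(term = rownames(a), sum_sq = a$`Sum Sq`, df = a$Df,
                      F = a$`F value`, p = a$`Pr(>F)`)
  } else {
    a <- car::Anova(fit, type = 2)
    out <- data.frame(term = rownames(a), sum_sq = a$`Sum Sq`, df = a$Df,
                      F = a$`F value`, p = a$`Pr(>F)`)
  }
  out <- out[out$term != "Residuals", , drop = FALSE]
  rownames(out) <- NULL
  out
}
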