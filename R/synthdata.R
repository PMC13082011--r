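# Synthetic-data generators. Each generator runs under its own seed (global
# RNG state is saved and restored) so identical specs give bit-identical
# outputs regardless of calling context.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 1 || x != round(x)) {
    stop(sprintf("field '%s' must be a positive integer count", name))
  }
  as.integer(x)
}

.check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    stop(sprintf("field '%s' must be in [%g, %g]", name, lo, hi))
  }
  as.numeric(x)
}

.check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("field '%s' must be > 0", name))
  }
  as.numeric(x)
}

#' Specification of a synthetic serology cohort
#'
#' Defaults emulate the larger of the two study cohorts: 686 healthy
#' individuals, 470 with chronic liver disease (CLD) and 761 with HCC, with
#' the 2,011-peptide EV/RV catalog partitioned 59 / 281 / 1,671 into
#' CE1-VP1, non-CE1 VP1 and non-VP1 groups. The generator encodes a
#' protective per-unit odds ratio of 0.9 for mean CE1-VP1 EBS on HCC
#' diagnosis, an additive CE1 EBS location shift of +1 in healthy
#' individuals, and a hazard ratio of 2 for HCC patients with CE1-VP1
#' ARB <= 0.5 relative to ARB > 0.5, with 30% independent censoring.
#'
#' @param n_healthy,n_cld,n_hcc cohort class sizes.
#' @param n_peptides_per_group integer triple: CE1-VP1, non-CE1 VP1,
#'   non-VP1 peptide counts.
#' @param ebs_location_shift additive shift applied to the nonzero CE1-VP1
#'   EBS entries of healthy individuals (result clamped at 0).
#' @param diagnosis_or_per_ebs_unit odds ratio per unit of mean CE1-VP1 EBS
#'   encoded into diagnosis sampling (> 0; < 1 is protective).
#' @param arb_hazard_ratio hazard multiplier for HCC patients with CE1-VP1
#'   ARB <= 0.5 vs > 0.5 (> 0).
#' @param censor_rate per-subject probability of independent censoring.
#' @param seed integer RNG seed.
#' @return list of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_healthy = 686L, n_cld = 470L, n_hcc = 761L,
                        n_peptides_per_group = c(59L, 281L, 1671L),
                        ebs_location_shift = 1,
                        diagnosis_or_per_ebs_unit = 0.9,
                        arb_hazard_ratio = 2,
                        censor_rate = 0.3,
                        seed = 1L) {
  if (length(n_peptides_per_group) != 3L) {
    stop("field 'n_peptides_per_group' must be a triple of counts")
  }
  spec <- list(
    n_healthy = .check_count(n_healthy, "n_healthy"),
    n_cld = .check_count(n_cld, "n_cld"),
    n_hcc = .check_count(n_hcc, "n_hcc"),
    n_peptides_per_group = vapply(seq_len(3), function(i)
      .check_count(n_peptides_per_group[i], "n_peptides_per_group"),
      integer(1)),
    ebs_location_shift = as.numeric(ebs_location_shift),
    diagnosis_or_per_ebs_unit =
      .check_positive(diagnosis_or_per_ebs_unit, "diagnosis_or_per_ebs_unit"),
    arb_hazard_ratio = .check_positive(arb_hazard_ratio, "arb_hazard_ratio"),
    censor_rate = .check_fraction(censor_rate, "censor_rate"),
    seed = .check_count(seed, "seed"))
  class(spec) <- "cohort_spec"
  spec
}

# Deterministic synthetic polyprotein layout shared by the serology
# generator: 1-based closed chain coordinates, CE1 window inside VP1.
.synthetic_annotations <- function(n_accessions = 5L) {
  acc <- sprintf("SYN%02d", seq_len(n_accessions))
  do.call(rbind, lapply(acc, function(a) {
    data.frame(accession = a,
               chain_name = c("VP4", "VP2", "VP3", "VP1", "NONSTRUCTURAL"),
               start = c(1L, 70L, 331L, 571L, 871L),
               end = c(69L, 330L, 570L, 870L, 2190L),
               ce1_start = c(NA, NA, NA, 700L, NA),
               ce1_end = c(NA, NA, NA, 740L, NA),
               stringsAsFactors = FALSE)
  }))
}

#' Generate a synthetic serology cohort
#'
#' Builds (a) a peptide catalog tiling synthetic polyproteins such that the
#' CE1-VP1 / non-CE1 VP1 / non-VP1 partition reproduces the requested group
#' sizes exactly, and (b) an individuals-by-peptides EBS matrix with
#' clinical metadata. EBS values are zero-inflated log-normal (non-negative,
#' right-skewed); each individual carries a latent CE1 reactivity effect so
#' mean CE1-VP1 EBS varies across individuals. Diagnosis labels are sampled
#' from a logistic model in mean CE1-VP1 EBS whose slope encodes the
#' requested odds ratio and whose intercept is solved numerically to hit the
#' requested HCC prevalence; non-HCC individuals are split healthy/CLD at
#' the requested proportions. The CE1-VP1 block of healthy individuals is
#' then location-shifted by `ebs_location_shift`. HCC survival times are
#' exponential with hazard multiplied by `arb_hazard_ratio` when the
#' individual's realized CE1-VP1 ARB is <= 0.5, with independent
#' exponential censoring calibrated to `censor_rate`.
#'
#' @param spec a [cohort_spec()].
#' @return list with `catalog`, `annotations`, `ebs` (matrix), `meta`
#'   (data.frame `individual_id`, `diagnosis`, `survival_time`, `event`),
#'   and `spec`.
#' @export
generate_serology_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    ann <- .synthetic_annotations()
    accs <- unique(ann$accession)
    pep_len <- 56L
    counts <- spec$n_peptides_per_group

    sample_starts <- function(n, ranges) {
      # ranges: list of c(lo, hi) inclusive start windows
      pool <- unlist(lapply(ranges, function(r) seq.int(r[1], r[2])))
      pool[sample.int(length(pool), n, replace = TRUE)]
    }
    mk <- function(n, ranges, tag) {
      if (n == 0L) return(NULL)
      acc <- accs[((seq_len(n) - 1L) %% length(accs)) + 1L]
      st <- sample_starts(n, ranges)
      data.frame(peptide_id = sprintf("%s_%04d", tag, seq_len(n)),
                 accession = acc, start = st, end = st + pep_len - 1L,
                 strain = paste0("strain_", acc),
                 stringsAsFactors = FALSE)
    }
    # start windows chosen so peptides of each group land in the intended
    # region of the shared chain layout (VP1 571-870, CE1 700-740)
    catalog <- rbind(
      mk(counts[1], list(c(700L - pep_len + 1L, 740L)), "ce1"),
      mk(counts[2], list(c(571L, 700L - pep_len), c(741L, 870L - pep_len + 1L)),
         "vp1"),
      mk(counts[3], list(c(1L, 571L - pep_len), c(871L, 2190L - pep_len + 1L)),
         "nvp"))

    n <- spec$n_healthy + spec$n_cld + spec$n_hcc
    ids <- sprintf("ind_%04d", seq_len(n))
    P <- nrow(catalog)
    is_ce1 <- seq_len(P) <= counts[1]

    # zero-inflated log-normal EBS; CE1 block broadly reactive, other
    # groups sparse (left-skewed breadth); latent per-individual CE1 effect
    u <- stats::rnorm(n, 0, 0.7)
    # reactivity is broad across CE1 peptides but sparse elsewhere, giving
    # the right-shifted CE1 ARB vs near-zero non-CE1 ARB distributions;
    # a per-individual Beta propensity spreads CE1 breadth across the unit
    # interval so the ARB > 0.5 split and all four ARB bins are populated
    q_ce1 <- stats::rbeta(n, 0.9, 0.9)
    prob <- matrix(rep(ifelse(is_ce1, 0, 0.015), each = n), n, P)
    prob[, is_ce1] <- q_ce1
    nonzero <- matrix(stats::rbinom(n * P, 1L, as.vector(prob)), n, P)
    mag <- matrix(stats::rlnorm(n * P, meanlog = 0.5, sdlog = 0.6), n, P)
    mag[, is_ce1] <- mag[, is_ce1, drop = FALSE] * exp(u)
    ebs <- nonzero * mag
    dimnames(ebs) <- list(ids, catalog$peptide_id)

    # diagnosis: logistic in mean CE1 EBS; intercept solved for prevalence
    x <- rowMeans(ebs[, is_ce1, drop = FALSE])
    beta <- log(spec$diagnosis_or_per_ebs_unit)
    target_prev <- spec$n_hcc / n
    a <- stats::uniroot(function(a) mean(stats::plogis(a + beta * x)) - target_prev,
                        interval = c(-30, 30), tol = 1e-10)$root
    hcc <- stats::rbinom(n, 1L, stats::plogis(a + beta * x)) == 1L
    diagnosis <- rep("CLD", n)
    diagnosis[hcc] <- "HCC"
    p_healthy <- spec$n_healthy / (spec$n_healthy + spec$n_cld)
    diagnosis[!hcc][stats::runif(sum(!hcc)) < p_healthy] <- "healthy"

    # healthy CE1 location shift (nonzero entries, clamped at 0)
    if (spec$ebs_location_shift != 0) {
      h <- diagnosis == "healthy"
      blk <- ebs[h, is_ce1, drop = FALSE]
      blk[blk > 0] <- pmax(0, blk[blk > 0] + spec$ebs_location_shift)
      ebs[h, is_ce1] <- blk
    }

    # HCC survival: exponential hazard on the realized CE1 ARB > 0.5 split
    asn <- data.frame(peptide_id = catalog$peptide_id,
                      group = rep(peptide_groups(), counts),
                      stringsAsFactors = FALSE)
    arb <- compute_arb(ebs, asn, "CE1_VP1")$arb
    time <- rep(NA_real_, n)
    event <- rep(NA_integer_, n)
    idx <- which(diagnosis == "HCC")
    if (length(idx)) {
      base_rate <- log(2) / 1095 # median ~3 years for high-breadth patients
      low <- is.na(arb[idx]) | arb[idx] <= 0.5
      rate <- base_rate * ifelse(low, spec$arb_hazard_ratio, 1)
      t_event <- stats::rexp(length(idx), rate)
      if (spec$censor_rate > 0) {
        c_rate <- rate * spec$censor_rate / (1 - spec$censor_rate)
        t_cens <- stats::rexp(length(idx), c_rate)
      } else {
        t_cens <- rep(Inf, length(idx))
      }
      time[idx] <- pmin(t_event, t_cens)
      event[idx] <- as.integer(t_event <= t_cens)
    }

    list(catalog = catalog,
         annotations = ann,
         ebs = ebs,
         meta = data.frame(individual_id = ids, diagnosis = diagnosis,
                           survival_time = time, event = event,
                           stringsAsFactors = FALSE),
         spec = spec)
  })
}

#' Specification of a synthetic IP-MS mimicry screen
#'
#' Defaults emulate the published funnel at desk scale: 2,000 background
#' proteins across two cell lines and two target antibodies, roughly 10%
#' of the background enriched and 10% on the surface-proteome list, with a
#' single spiked surface mimic carrying 80% of the query residues at
#' 500-fold enrichment.
#'
#' @param n_background_proteins number of background proteins.
#' @param n_spiked_surface_mimics number of planted surface mimics.
#' @param mimic_identity_fraction fraction of query residues conserved in
#'   each planted mimic, in (0, 1].
#' @param enrichment_fold_spiked target/control intensity ratio of the
#'   mimics (> 0; the published filter keeps > 100).
#' @param intensity_noise_cv log-scale coefficient of variation of the
#'   intensity noise (fold-change noise uses half of it).
#' @param background_enriched_fraction fraction of background proteins that
#'   are strongly enriched in every table (funnel realism).
#' @param surface_fraction fraction of background proteins also present on
#'   the surface list.
#' @param seed integer RNG seed.
#' @return list of class `"mimicry_spec"`.
#' @export
mimicry_spec <- function(n_background_proteins = 2000L,
                         n_spiked_surface_mimics = 1L,
                         mimic_identity_fraction = 0.8,
                         enrichment_fold_spiked = 500,
                         intensity_noise_cv = 0.2,
                         background_enriched_fraction = 0.1,
                         surface_fraction = 0.1,
                         seed = 1L) {
  spec <- list(
    n_background_proteins = .check_count(n_background_proteins,
                                         "n_background_proteins"),
    n_spiked_surface_mimics = .check_count(n_spiked_surface_mimics,
                                           "n_spiked_surface_mimics"),
    mimic_identity_fraction = .check_fraction(mimic_identity_fraction,
                                              "mimic_identity_fraction",
                                              lo = 1e-9),
    enrichment_fold_spiked = .check_positive(enrichment_fold_spiked,
                                             "enrichment_fold_spiked"),
    intensity_noise_cv = .check_fraction(intensity_noise_cv,
                                         "intensity_noise_cv", hi = Inf),
    background_enriched_fraction =
      .check_fraction(background_enriched_fraction,
                      "background_enriched_fraction"),
    surface_fraction = .check_fraction(surface_fraction, "surface_fraction"),
    seed = .check_count(seed, "seed"))
  class(spec) <- "mimicry_spec"
  spec
}

#' The CE1 epitope query peptide
#'
#' The modified CE1 peptide used for antibody generation and as the mimicry
#' query. The leading cysteine is a conjugation residue; stripping it is
#' available as an option but off by default.
#'
#' @param strip_leading_cys drop the leading C (default FALSE).
#' @return single amino-acid string.
#' @export
ce1_query <- function(strip_leading_cys = FALSE) {
  q <- "CSESVPALTAVETGHTS"
  if (strip_leading_cys) substring(q, 2L) else q
}

#' Generate synthetic IP-MS tables, candidate sequences and a surface list
#'
#' Produces per-cell-line, per-antibody intensity tables (target vs control)
#' for background proteins and planted surface mimics; the mimics carry a
#' query-matching subsequence at the requested identity fraction, planted at
#' a uniformly random internal offset in an otherwise random sequence, and
#' always appear on the surface list. Background fold changes are
#' concentrated below the enrichment cutoff except for a designated
#' strongly-enriched fraction (which keeps the downstream surface/alignment
#' stages non-trivial); mimic fold changes equal `enrichment_fold_spiked` up
#' to mild multiplicative noise.
#'
#' @param spec a [mimicry_spec()].
#' @param query epitope query string (default [ce1_query()]).
#' @return list with `intensities` (data.frame `cell_line`, `antibody`,
#'   `protein_id`, `target`, `control`), `sequences` (named character),
#'   `surface_list`, `spiked_ids`, and `spec`.
#' @export
generate_ipms_tables <- function(spec, query = ce1_query()) {
  stopifnot(inherits(spec, "mimicry_spec"))
  qlen <- nchar(query)
  n_match <- round(spec$mimic_identity_fraction * qlen)
  if (n_match < 1L) {
    stop("field 'mimic_identity_fraction' produces an empty mimic subsequence")
  }
  with_seed(spec$seed, {
    nb <- spec$n_background_proteins
    ns <- spec$n_spiked_surface_mimics
    bg_ids <- sprintf("BG%05d", seq_len(nb))
    sp_ids <- sprintf("MIMIC%02d", seq_len(ns))
    ids <- c(bg_ids, sp_ids)

    enriched_bg <- stats::runif(nb) < spec$background_enriched_fraction
    fold_bg_enriched <- exp(stats::rnorm(nb, log(300), 0.3))
    cv <- spec$intensity_noise_cv

    tabs <- list()
    for (cl in c("CL1", "CL2")) {
      base <- stats::rlnorm(nb + ns, meanlog = log(1e5), sdlog = 1)
      for (ab in c("rB9", "rB10")) {
        control <- base * stats::rlnorm(nb + ns, 0, cv)
        fold <- c(ifelse(enriched_bg, fold_bg_enriched,
                         stats::rlnorm(nb, 0, 1)),
                  rep(spec$enrichment_fold_spiked, ns))
        target <- control * fold * stats::rlnorm(nb + ns, 0, cv / 2)
        tabs[[paste(cl, ab)]] <- data.frame(cell_line = cl, antibody = ab,
                                            protein_id = ids,
                                            target = target,
                                            control = control,
                                            stringsAsFactors = FALSE)
      }
    }
    intensities <- do.call(rbind, tabs)
    rownames(intensities) <- NULL

    rand_seq <- function(len) {
      paste(sample(.aa_alphabet, len, replace = TRUE), collapse = "")
    }
    lens <- sample(300:800, nb + ns, replace = TRUE)
    sequences <- vapply(lens, rand_seq, character(1))
    names(sequences) <- ids
    qc <- strsplit(query, "")[[1]]
    for (k in seq_len(ns)) {
      id <- sp_ids[k]
      len <- lens[nb + k]
      offset <- sample.int(len - qlen + 1L, 1L)
      window <- sample(.aa_alphabet, qlen, replace = TRUE)
      keep <- sample.int(qlen, n_match)
      window[keep] <- qc[keep]
      s <- strsplit(sequences[[id]], "")[[1]]
      s[offset:(offset + qlen - 1L)] <- window
      sequences[[id]] <- paste(s, collapse = "")
    }

    surface_list <- c(sp_ids,
                      bg_ids[stats::runif(nb) < spec$surface_fraction])
    list(intensities = intensities, sequences = sequences,
         surface_list = sort(surface_list), spiked_ids = sp_ids,
         spec = spec)
  })
}

#' Specification of a synthetic tumor expression cohort
#'
#' Defaults emulate the 97-patient integrative cohort: two datasets of
#' origin (an array-like and an RNA-seq-like set), roughly half the tumors
#' CE1-seropositive, a positive ASPH-ADCC rank correlation confined to the
#' seropositive stratum, higher NK-high prevalence among seropositive
#' tumors, and a survival benefit of seropositivity confined to ASPH-high
#' tumors.
#'
#' @param n_tumors number of tumor samples.
#' @param n_seropositive number of CE1-seropositive tumors (<= n_tumors).
#' @param adcc_asph_rho_pos target Spearman correlation between ASPH and
#'   the ADCC score in the seropositive stratum, in \[-1, 1\].
#' @param adcc_asph_rho_neg same, seronegative stratum.
#' @param nk_high_fraction_pos fraction of NK-high tumors among
#'   seropositive samples.
#' @param nk_high_fraction_neg fraction of NK-high tumors among
#'   seronegative samples.
#' @param sero_benefit_hr hazard ratio of seropositive vs seronegative
#'   within ASPH-high tumors (1 = no benefit; applies only in ASPH-high).
#' @param censor_rate per-subject probability of independent censoring.
#' @param seed integer RNG seed.
#' @return list of class `"expression_spec"`.
#' @export
expression_spec <- function(n_tumors = 97L, n_seropositive = 48L,
                            adcc_asph_rho_pos = 0.3,
                            adcc_asph_rho_neg = 0,
                            nk_high_fraction_pos = 0.6,
                            nk_high_fraction_neg = 0.3,
                            sero_benefit_hr = 0.5,
                            censor_rate = 0.3,
                            seed = 1L) {
  n_tumors <- .check_count(n_tumors, "n_tumors")
  n_seropositive <- .check_count(n_seropositive, "n_seropositive")
  if (n_seropositive > n_tumors) {
    stop("field 'n_seropositive' must not exceed 'n_tumors'")
  }
  spec <- list(
    n_tumors = n_tumors,
    n_seropositive = n_seropositive,
    adcc_asph_rho_pos = .check_fraction(adcc_asph_rho_pos,
                                        "adcc_asph_rho_pos", lo = -1),
    adcc_asph_rho_neg = .check_fraction(adcc_asph_rho_neg,
                                        "adcc_asph_rho_neg", lo = -1),
    nk_high_fraction_pos = .check_fraction(nk_high_fraction_pos,
                                           "nk_high_fraction_pos"),
    nk_high_fraction_neg = .check_fraction(nk_high_fraction_neg,
                                           "nk_high_fraction_neg"),
    sero_benefit_hr = .check_positive(sero_benefit_hr, "sero_benefit_hr"),
    censor_rate = .check_fraction(censor_rate, "censor_rate"),
    seed = .check_count(seed, "seed"))
  class(spec) <- "expression_spec"
  spec
}

#' Generate a synthetic tumor expression cohort
#'
#' Builds a genes-by-samples matrix containing an ASPH row and the 20 ADCC
#' signature genes, with per-sample NK infiltration scores, CE1
#' seroreactivity values, survival follow-up and a dataset-of-origin label.
#' Within each serostatus stratum, ASPH and the latent ADCC activity are
#' drawn from a Gaussian copula whose latent Pearson correlation
#' \eqn{r = 2\sin(\pi\rho/6)} yields the requested population Spearman
#' \eqn{\rho}; ADCC genes load on the latent activity with small
#' independent noise, and each dataset gets its own per-gene offsets and
#' scale so the within-dataset Z-scoring step is genuinely exercised. NK
#' scores straddle the 0.01 cutoff at the requested per-stratum NK-high
#' fractions; survival encodes a seropositivity benefit only among tumors
#' above the median latent ASPH level.
#'
#' @param spec an [expression_spec()].
#' @return list with `expr` (matrix, genes x samples), `meta` (data.frame
#'   `sample_id`, `dataset`, `nk_score`, `ce1_score`, `seropositive`,
#'   `survival_time`, `event`), and `spec`.
#' @export
generate_expression_cohort <- function(spec) {
  stopifnot(inherits(spec, "expression_spec"))
  with_seed(spec$seed, {
    n <- spec$n_tumors
    ids <- sprintf("tumor_%03d", seq_len(n))
    seropos <- rep(FALSE, n)
    seropos[sample.int(n, spec$n_seropositive)] <- TRUE
    dataset <- rep(c("set1_array", "set2_rnaseq"), length.out = n)

    z_asph <- numeric(n)
    z_act <- numeric(n)
    for (s in c(TRUE, FALSE)) {
      rho <- if (s) spec$adcc_asph_rho_pos else spec$adcc_asph_rho_neg
      r <- 2 * sin(pi * rho / 6)
      i <- which(seropos == s)
      z1 <- stats::rnorm(length(i))
      z2 <- r * z1 + sqrt(1 - r^2) * stats::rnorm(length(i))
      z_asph[i] <- z1
      z_act[i] <- z2
    }

    genes <- adcc_signature()
    offsets <- matrix(stats::rnorm(length(genes) * 2, 6, 1.5),
                      nrow = length(genes),
                      dimnames = list(genes, c("set1_array", "set2_rnaseq")))
    scale_d <- c(set1_array = 1, set2_rnaseq = 1.8)
    expr <- matrix(0, nrow = length(genes) + 1L, ncol = n,
                   dimnames = list(c("ASPH", genes), ids))
    for (d in unique(dataset)) {
      cols <- which(dataset == d)
      expr["ASPH", cols] <- (8 + z_asph[cols]) * scale_d[[d]]
      for (g in genes) {
        expr[g, cols] <- (offsets[g, d] + z_act[cols] +
                            stats::rnorm(length(cols), 0, 0.3)) * scale_d[[d]]
      }
    }

    nk_high <- stats::runif(n) < ifelse(seropos, spec$nk_high_fraction_pos,
                                        spec$nk_high_fraction_neg)
    nk_score <- ifelse(nk_high, stats::runif(n, 0.02, 0.3),
                       stats::runif(n, 0, 0.0095))
    ce1_score <- ifelse(seropos, stats::rlnorm(n, 1, 0.5), 0)

    asph_high <- z_asph > stats::median(z_asph)
    base_rate <- log(2) / 1095
    rate <- base_rate * ifelse(asph_high & seropos, spec$sero_benefit_hr, 1)
    t_event <- stats::rexp(n, rate)
    if (spec$censor_rate > 0) {
      t_cens <- stats::rexp(n, rate * spec$censor_rate / (1 - spec$censor_rate))
    } else {
      t_cens <- rep(Inf, n)
    }

    list(expr = expr,
         meta = data.frame(sample_id = ids, dataset = dataset,
                           nk_score = nk_score, ce1_score = ce1_score,
                           seropositive = seropos,
                           survival_time = pmin(t_event, t_cens),
                           event = as.integer(t_event <= t_cens),
                           stringsAsFactors = FALSE),
         spec = spec)
  })
}
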