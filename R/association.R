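#' Logistic regression of HCC diagnosis on serological reactivity
#'
#' Maximum-likelihood logistic fit (via [stats::glm()]) of a binary HCC
#' indicator on a per-individual EBS summary, optionally adjusted for
#' covariates. The odds ratio is reported on two scales: per unit of the
#' predictor and per standard deviation of the predictor, since published
#' per-EBS odds ratios do not always state the scaling.
#'
#' @param x numeric predictor (e.g. per-individual mean CE1-VP1 EBS).
#' @param diagnosis character/factor of diagnosis classes; `hcc_label`
#'   (default "HCC") defines the event, everything else is the reference.
#' @param covariates optional data.frame of adjustment covariates.
#' @param hcc_label label identifying the event class.
#' @return list of class `"logistic_fit"` with elements `coefficient`,
#'   `odds_ratio` (per unit), `odds_ratio_per_sd`, `se`, `p_value` (Wald,
#'   two-sided), `converged`, `separation`, `n_used`, `fit` (the glm
#'   object).
#' @export
fit_diagnosis_logistic <- function(x, diagnosis, covariates = NULL,
                                   hcc_label = "HCC") {
  y <- as.integer(as.character(diagnosis) == hcc_label)
  keep <- !is.na(x) & !is.na(y)
  if (!is.null(covariates)) keep <- keep & stats::complete.cases(covariates)
  x <- x[keep]; y <- y[keep]
  if (sum(y) == 0L || sum(y) == length(y)) {
    stop("need at least one event and one non-event")
  }
  if (stats::sd(x) == 0) stop("constant predictor")
  dat <- data.frame(.y = y, .x = x)
  form <- .y ~ .x
  if (!is.null(covariates)) {
    dat <- cbind(dat, covariates[keep, , drop = FALSE])
    form <- stats::reformulate(c(".x", colnames(covariates)), response = ".y")
  }
  fit <- suppressWarnings(stats::glm(form, family = stats::binomial(), data = dat))
  co <- summary(fit)$coefficients
  beta <- co[".x", "Estimate"]
  se <- co[".x", "Std. Error"]
  # quasi-complete separation: fitted probabilities pinned at both machine
  # extremes with an exploded Wald standard error
  eps <- 1e-10
  separation <- any(fit$fitted.values > 1 - eps) &&
    any(fit$fitted.values < eps) && se > 50
  if (separation) {
    warning("possible complete separation: coefficient estimate unreliable")
  }
  structure(list(coefficient = beta,
                 odds_ratio = exp(beta),
                 odds_ratio_per_sd = exp(beta * stats::sd(x)),
                 se = se,
                 p_value = co[".x", "Pr(>|z|)"],
                 converged = fit$converged,
                 separation = separation,
                 n_used = length(y),
                 fit = fit),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat(sprintf("logistic fit (n = %d%s)\n", x$n_used,
              if (x$converged) "" else ", NOT converged"))
  cat(sprintf("  OR per unit: %.4f (per SD: %.4f), Wald p = %.4g\n",
              x$odds_ratio, x$odds_ratio_per_sd, x$p_value))
  invisible(x)
}

#' Two-sided two-sample t test on group means
#'
#' Independent two-sample t test (Student by default, matching "two-tailed
#' unpaired Student's t-test"; Welch optionally) comparing a quantity
#' between two groups, with the effect direction reported.
#'
#' @param values numeric vector.
#' @param group two-level factor/character of the same length.
#' @param var_equal TRUE for Student (default), FALSE for Welch.
#' @return data.frame `group1`, `group2`, `mean1`, `mean2`, `t`, `df`, `p`,
#'   `direction` (sign of mean1 - mean2).
#' @export
compare_group_means <- function(values, group, var_equal = TRUE) {
  group <- factor(group)
  if (nlevels(group) != 2L) stop("exactly two groups required")
  tt <- stats::t.test(values ~ group, var.equal = var_equal)
  m <- tapply(values, group, mean)
  data.frame(group1 = levels(group)[1], group2 = levels(group)[2],
             mean1 = unname(m[1]), mean2 = unname(m[2]),
             t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value,
             direction = sign(unname(m[1]) - unname(m[2])))
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson chi-square without continuity correction on a diagnosis-class by
#' ARB-category (or any r x c) count table; df = (r-1)(c-1). All expected
#' counts must be positive.
#'
#' @param table matrix/table of non-negative counts.
#' @return list `statistic`, `df`, `p_value`, `expected`.
#' @export
arb_category_chisq <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected <= 0)) stop("all expected counts must be > 0 (zero margin)")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic),
       df = unname(ct$parameter),
       p_value = ct$p.value,
       expected = ct$expected)
}

#' Kaplan-Meier curves and log-rank test across strata
#'
#' Product-limit survival estimates per stratum and the standard
#' (hypergeometric-variance) log-rank test across two or more strata, via
#' the survival package. Records with missing time, event or stratum are
#' dropped with a message giving the count. The p-value is the chi-square
#' upper tail on k - 1 degrees of freedom (two-sided convention).
#'
#' @param time non-negative follow-up times.
#' @param event 0/1 event indicator (1 = death/event).
#' @param stratum stratum labels (>= 2 levels with >= 1 subject each).
#' @return list of class `"km_logrank"`: `curves` (data.frame `stratum`,
#'   `time`, `n_risk`, `n_event`, `surv`), `statistic`, `df`, `p_value`,
#'   `n_used`, `n_dropped`.
#' @export
km_logrank <- function(time, event, stratum) {
  keep <- !(is.na(time) | is.na(event) | is.na(stratum))
  n_dropped <- sum(!keep)
  if (n_dropped) message(sprintf("km_logrank: dropped %d record(s) with missing data",
                                 n_dropped))
  time <- time[keep]; event <- event[keep]
  stratum <- factor(stratum[keep])
  stratum <- droplevels(stratum)
  if (any(time < 0)) stop("survival times must be >= 0")
  if (nlevels(stratum) < 2L) stop("need >= 2 strata with data")
  dat <- data.frame(time = time, event = event, stratum = stratum)
  sf <- survival::survfit(survival::Surv(time, event) ~ stratum, data = dat)
  sm <- summary(sf, censored = TRUE)
  curves <- data.frame(stratum = sub("^stratum=", "", as.character(sm$strata)),
                       time = sm$time, n_risk = sm$n.risk,
                       n_event = sm$n.event, surv = sm$surv,
                       stringsAsFactors = FALSE)
  if (sum(event) == 0) {
    warning("all subjects censored in every stratum; log-rank statistic 0")
    stat <- 0; p <- 1
  } else {
    sd_ <- survival::survdiff(survival::Surv(time, event) ~ stratum, data = dat)
    stat <- sd_$chisq
    p <- stats::pchisq(stat, df = nlevels(stratum) - 1L, lower.tail = FALSE)
  }
  structure(list(curves = curves, statistic = stat,
                 df = nlevels(stratum) - 1L, p_value = p,
                 n_used = sum(keep), n_dropped = n_dropped),
            class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat(sprintf("log-rank chi-square = %.3f on %d df, p = %.4g (n = %d)\n",
              x$statistic, x$df, x$p_value, x$n_used))
  invisible(x)
}

#' Spearman rank correlation within strata
#'
#' Spearman rank correlation (mid-ranks for ties) of two quantities within
#' each level of a stratum label, with a two-sided p-value from the
#' t-approximation (optionally exact for small strata without ties).
#' Strata with fewer than 3 complete pairs return NA with a warning.
#'
#' @param x,y numeric vectors.
#' @param stratum stratum labels.
#' @param exact_max use the exact null distribution when a stratum has at
#'   most this many pairs and no ties (default 0 = never).
#' @return data.frame `stratum`, `rho`, `p`, `n`.
#' @export
stratified_spearman <- function(x, y, stratum, exact_max = 0L) {
  stratum <- factor(stratum)
  out <- lapply(levels(stratum), function(s) {
    i <- which(stratum == s & !is.na(x) & !is.na(y))
    if (length(i) < 3L) {
      warning(sprintf("stratum '%s' has < 3 complete pairs; rho undefined", s))
      return(data.frame(stratum = s, rho = NA_real_, p = NA_real_,
                        n = length(i)))
    }
    use_exact <- length(i) <= exact_max &&
      !anyDuplicated(x[i]) && !anyDuplicated(y[i])
    ct <- suppressWarnings(stats::cor.test(x[i], y[i], method = "spearman",
                                           exact = use_exact))
    data.frame(stratum = s, rho = unname(ct$estimate), p = ct$p.value,
               n = length(i))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment utility
#'
#' Thin wrapper over [stats::p.adjust()] provided for convenience; no
#' analysis in this package applies it by default, matching the unadjusted
#' per-test reporting of the underlying analyses.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
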