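#!/usr/bin/env Rscript
# Serology layer: partition the peptide catalog, compute per-group EBS
# summaries and the CE1-VP1 antibody repertoire breadth (ARB), then run the
# cohort association analyses - group-mean comparison, diagnosis logistic
# model, ARB-category chi-square and ARB-stratified survival.
# Requires results/data/ from 01_simulate_cohorts.R.

suppressPackageStartupMessages(library(mimiscan))
write_tsv <- mimiscan:::write_tsv

catalog <- mimiscan:::read_tsv("results/data/catalog.tsv")
annotations <- mimiscan:::read_tsv("results/data/annotations.tsv")
ebs <- read_ebs_matrix("results/data/ebs.tsv")
meta <- mimiscan:::read_tsv("results/data/meta.tsv")

assignment <- assign_groups(catalog, annotations)
write_tsv(assignment, "results/assignments.tsv")
cat("partition:", paste(names(table(assignment$group)),
                        table(assignment$group), collapse = ", "), "\n")

gsum <- group_ebs_summary(ebs, assignment)
write_tsv(gsum, "results/group_ebs_summary.tsv")
ce1_mean <- gsum$mean_ebs[gsum$group == "CE1_VP1"]
nonce1_mean <- gsum$mean_ebs[gsum$group == "NON_CE1_VP1"]
tt <- compare_group_means(c(ce1_mean, nonce1_mean),
                          rep(c("CE1_VP1", "NON_CE1_VP1"), each = nrow(meta)))
cat(sprintf("CE1 vs non-CE1 mean EBS: %.2f vs %.2f (t = %.1f, p = %.3g)\n",
            tt$mean1, tt$mean2, tt$t, tt$p))

fit <- fit_diagnosis_logistic(ce1_mean, meta$diagnosis)
cat(sprintf("HCC diagnosis OR per unit CE1 EBS: %.3f (per SD %.3f), p = %.3g\n",
            fit$odds_ratio, fit$odds_ratio_per_sd, fit$p_value))

arb <- compute_arb(ebs, assignment, "CE1_VP1")
cats <- arb_category(arb$arb)
arb$category <- as.character(cats$category)
arb$above_cutoff <- cats$above_cutoff
write_tsv(arb, "results/arb_ce1_vp1.tsv")
cat(sprintf("CE1-VP1 ARB: %d/%d defined, %.0f%% above 0.5\n",
            sum(arb$defined), nrow(arb),
            100 * mean(arb$above_cutoff, na.rm = TRUE)))

chisq <- arb_category_chisq(table(meta$diagnosis, arb$category))
cat(sprintf("diagnosis x ARB-category chi-square: %.1f on %d df, p = %.3g\n",
            chisq$statistic, chisq$df, chisq$p_value))

hcc <- meta$diagnosis == "HCC" & arb$defined
km <- km_logrank(meta$survival_time[hcc], meta$event[hcc],
                 ifelse(arb$above_cutoff[hcc], "ARB>0.5", "ARB<=0.5"))
write_tsv(km$curves, "results/km_curves_arb.tsv")
cat(sprintf("HCC survival by ARB>0.5: log-rank chi-square %.1f, p = %.3g (n = %d)\n",
            km$statistic, km$p_value, km$n_used))

jsonlite::write_json(
  list(t_test = as.list(tt),
       logistic = list(odds_ratio = fit$odds_ratio, p = fit$p_value),
       chisq = list(statistic = chisq$statistic, p = chisq$p_value),
       logrank = list(statistic = km$statistic, p = km$p_value)),
  "results/serology_associations.json", auto_unbox = TRUE, pretty = TRUE,
  digits = NA)
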