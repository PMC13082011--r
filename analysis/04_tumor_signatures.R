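#!/usr/bin/env Rscript
# Tumor-transcriptome layer: within-dataset Z-scoring, the 20-gene ADCC
# signature score, NK-infiltration stratification at the 0.01 cutoff, and
# the CE1-serostatus-stratified correlation and survival analyses.
# Requires results/data/ from 01_simulate_cohorts.R.

suppressPackageStartupMessages(library(mimiscan))

expr <- read_expression_matrix("results/data/expression.tsv")
meta <- mimiscan:::read_tsv("results/data/expression_meta.tsv")

norm <- zscore_within_dataset(expr, meta$dataset)
score <- adcc_score(norm)
nk <- nk_stratify(meta$nk_score)
seropos <- meta$ce1_score > 0

chisq <- serostatus_nk_chisq(nk, seropos)
cat(sprintf("NK-high fraction: %.0f%% seropositive vs %.0f%% seronegative (chi-square p = %.3g)\n",
            100 * mean(nk[seropos] == "high"),
            100 * mean(nk[!seropos] == "high"), chisq$p_value))

sp <- stratified_asph_adcc(norm["ASPH", ], score, seropos)
for (i in seq_len(nrow(sp))) {
  cat(sprintf("ASPH-ADCC Spearman, %s: rho = %.2f, p = %.3g (n = %d)\n",
              sp$stratum[i], sp$rho[i], sp$p[i], sp$n[i]))
}

surv <- asph_sero_survival(norm["ASPH", ], meta$survival_time, meta$event,
                           seropos)
cat(sprintf("survival by serostatus, ASPH-high: p = %.3g; ASPH-low: p = %.3g\n",
            surv$asph_high$p_value, surv$asph_low$p_value))

out <- data.frame(sample_id = meta$sample_id, adcc_score = score,
                  nk_stratum = as.character(nk), seropositive = seropos,
                  asph_normalized = norm["ASPH", ])
mimiscan:::write_tsv(out, "results/signature_scores.tsv")
jsonlite::write_json(
  list(nk_chisq = list(statistic = chisq$statistic, p = chisq$p_value),
       spearman = sp,
       survival = list(asph_high_p = surv$asph_high$p_value,
                       asph_low_p = surv$asph_low$p_value)),
  "results/tumor_signatures.json", auto_unbox = TRUE, pretty = TRUE,
  digits = NA)
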