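#!/usr/bin/env Rscript
# Simulate every input stream of the study at its default conditions:
# a TIGER-LC-sized serology cohort (686 healthy / 470 CLD / 761 HCC over
# the 59 / 281 / 1,671 peptide partition), a two-cell-line IP-MS screen
# with one planted CE1 surface mimic, and a 97-tumor expression cohort
# with matched serology. Inputs are written under results/data/.

suppressPackageStartupMessages(library(mimiscan))

seed <- 20240901L
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

cohort <- generate_serology_cohort(cohort_spec(seed = seed))
write_tsv <- mimiscan:::write_tsv
write_tsv(cohort$catalog, "results/data/catalog.tsv")
write_tsv(cohort$annotations, "results/data/annotations.tsv")
write_ebs_matrix(cohort$ebs, "results/data/ebs.tsv")
write_tsv(cohort$meta, "results/data/meta.tsv")
cat(sprintf("serology cohort: %d individuals x %d peptides (%s)\n",
            nrow(cohort$ebs), ncol(cohort$ebs),
            paste(names(table(cohort$meta$diagnosis)),
                  table(cohort$meta$diagnosis), collapse = ", ")))

ipms <- generate_ipms_tables(mimicry_spec(seed = seed))
write_tsv(ipms$intensities, "results/data/intensities.tsv")
write_fasta(ipms$sequences, "results/data/candidates.fasta")
write_surface_list(ipms$surface_list, "results/data/surface_list.txt")
cat(sprintf("IP-MS screen: %d proteins, %d on the surface list, mimic %s\n",
            length(ipms$sequences), length(ipms$surface_list),
            ipms$spiked_ids[1]))

bundle <- generate_expression_cohort(expression_spec(seed = seed))
write_expression_matrix(bundle$expr, "results/data/expression.tsv")
write_tsv(bundle$meta, "results/data/expression_meta.tsv")
cat(sprintf("expression cohort: %d tumors (%d seropositive) x %d genes\n",
            ncol(bundle$expr), sum(bundle$meta$seropositive),
            nrow(bundle$expr)))
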