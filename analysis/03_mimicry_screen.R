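#!/usr/bin/env Rscript
# Molecular-mimicry screen: fold-change enrichment (>100 over control) per
# cell line, intersection across cell lines, surface-proteome filtering,
# and BLOSUM62 Smith-Waterman ranking against the CE1 epitope query.
# Requires results/data/ from 01_simulate_cohorts.R.

suppressPackageStartupMessages(library(mimiscan))

intensities <- mimiscan:::read_tsv("results/data/intensities.tsv")
surface <- read_surface_list("results/data/surface_list.txt")
sequences <- read_fasta("results/data/candidates.fasta")

funnel <- mimicry_funnel(intensities, surface, sequences, ce1_query())
cat(sprintf("funnel: %d proteins -> %d enriched (>100-fold, both lines) -> %d surface -> ranked\n",
            funnel$counts[["proteins"]], funnel$counts[["enriched"]],
            funnel$counts[["surface"]]))

mimiscan:::write_tsv(funnel$ranking$table, "results/mimicry_ranking.tsv")
top <- funnel$ranking$alignments[[1]]
cat(sprintf("top candidate: %s (raw %d, E = %.2g, %d identities, %d conserved)\n",
            top$subject_name, top$raw_score, top$expect, top$n_identity,
            top$n_conserved))
sink("results/mimicry_alignments.txt")
for (r in funnel$ranking$alignments) print(r)
sink()
print(top)
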