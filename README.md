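# mimiscan

Antiviral antibody repertoire breadth and molecular-mimicry screening for
liver cancer serology.

Enterovirus/rhinovirus (EV/RV) infections leave lifelong antibody
repertoires. Antibodies against CE1 — a consensus epitope in the VP1 capsid
protein — are associated with reduced hepatocellular carcinoma (HCC) risk
and better survival, plausibly because they cross-react with aspartate
β-hydroxylase (ASPH) on tumor cells and recruit NK-cell-mediated ADCC.
`mimiscan` implements that investigation's computational pipeline for
biostatisticians and computational immunologists: serology partitioning and
breadth statistics, cohort association analyses, IP-MS mimicry screening,
and tumor-transcriptome ADCC signature analyses, plus seeded synthetic-data
generators so everything runs and is tested without restricted cohort data.

## The statistics at the core

**Antibody repertoire breadth (ARB).** For an individual's epitope binding
signals (EBS, PhIP-seq enrichment Z-scores) over the S peptides of a group,
with P<sub>i</sub> = EBS<sub>i</sub> / Σ<sub>j</sub> EBS<sub>j</sub>:

    ARB = − Σ P_i ln P_i / ln S        (0·ln 0 := 0)

the normalized Shannon diversity: 1 = evenly spread reactivity, 0 = a
single reactive peptide; undefined when the group signal is zero or S = 1.
Survival analyses stratify HCC patients at ARB > 0.5.

**Peptide partition.** Peptides are CE1-VP1 if their 1-based closed
interval shares ≥ 1 residue with the CE1 window inside the VP1 chain,
non-CE1 VP1 if they intersect VP1 only, non-VP1 otherwise.

**Mimicry funnel.** IP-MS fold change FC = (target + 1)/(control + 1) with
a strict > 100 enrichment cutoff per cell line (either target antibody
counts); enriched proteins are intersected with a surface proteome list and
ranked against the CE1 query `CSESVPALTAVETGHTS` by Smith–Waterman /
BLOSUM62 local alignment (gap open 11, extend 1) using the Karlin–Altschul
expect value E = K·m·n·e^(−λS). Aligned columns with different residues but
BLOSUM62 score > 0 are called conserved substitutions.

**Tumor signatures.** Expression is Z-scored within each dataset; ADCC
activity is the mean Z of 20 signature genes; tumors are NK-high when the
precomputed NK score exceeds 0.01; correlations (Spearman) and survival
(Kaplan–Meier + log-rank) are stratified by CE1 serostatus and median ASPH.

## Worked example

The `analysis/` scripts run the whole study on synthetic cohorts
(defaults mirror a 1,917-person serology cohort over the 59 / 281 / 1,671
peptide partition, a 2,000-protein IP-MS screen with one planted mimic, and
a 97-tumor expression cohort):

```sh
Rscript analysis/01_simulate_cohorts.R
Rscript analysis/02_serology_associations.R
Rscript analysis/03_mimicry_screen.R
Rscript analysis/04_tumor_signatures.R
```

which prints (abridged):

```
partition: CE1_VP1 59, NON_CE1_VP1 281, NON_VP1 1671
CE1 vs non-CE1 mean EBS: 1.45 vs 0.03 (t = 38.5, p = 4.12e-274)
HCC diagnosis OR per unit CE1 EBS: 0.823 (per SD 0.730), p = 6.22e-08
CE1-VP1 ARB: 1875/1917 defined, 84% above 0.5
HCC survival by ARB>0.5: log-rank chi-square 24.7, p = 6.61e-07 (n = 730)
funnel: 2001 proteins -> 189 enriched (>100-fold, both lines) -> 14 surface -> ranked
top candidate: MIMIC01 (raw 73, E = 8.4e-07, 14 identities, 1 conserved)
 CSESVPALTAVETGHTS
 |||+|| || |||||||
 CSETVPVLTWVETGHTS
ASPH-ADCC Spearman, seropositive: rho = 0.29, p = 0.0493 (n = 48)
ASPH-ADCC Spearman, seronegative: rho = -0.08, p = 0.589 (n = 49)
```

Reading the output: the generated catalog reproduces the published group
sizes exactly; the diagnosis odds ratio per unit CE1 EBS is protective
(< 1; here the encoded odds ratio 0.9 combines with the healthy cohort's
EBS shift); high CE1 breadth predicts survival; the planted surface mimic
is recovered at rank 1 with its alignment shown (`|` identity, `+`
conserved substitution); and the ASPH–ADCC correlation appears only in
CE1-seropositive tumors. Tables land under `results/`.

The same end-to-end run is available as one call from a single config:

```r
library(mimiscan)
cfg <- demo_config()           # inst/extdata/demo_config.yaml
run_pipeline(cfg, outdir = "results/demo")
```

which writes every intermediate table plus `run_report.json` (per-stage
parameters, record counts, warnings, timings) and is byte-reproducible for
a fixed seed.

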