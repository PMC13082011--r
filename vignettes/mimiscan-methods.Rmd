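---
title: "Methods: antibody repertoire breadth and CE1 mimicry screening"
author: "mimiscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: antibody repertoire breadth and CE1 mimicry screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimiscan)
```

## The scientific problem

Enteroviruses and rhinoviruses (EV/RV) elicit lifelong antibody repertoires
in essentially everyone. A consensus epitope within the VP1 capsid protein,
called CE1, draws an unusually strong and broad antibody response, and that
response is associated with a reduced risk of hepatocellular carcinoma
(HCC) and better survival in HCC patients. The proposed mechanism is
molecular mimicry: anti-CE1 antibodies cross-react with aspartate
β-hydroxylase (ASPH), a transmembrane protein aberrantly expressed on HCC
cells, and recruit NK-cell-mediated antibody-dependent cellular
cytotoxicity (ADCC) against the tumor.

`mimiscan` implements the computational side of that investigation as a
reusable, tested pipeline:

1. **catalog** — partition a phage-display peptide catalog into CE1-VP1,
   non-CE1 VP1 and non-VP1 groups from polyprotein chain annotations;
2. **repertoire** — per-individual group summaries of the epitope binding
   signal (EBS), the antibody repertoire breadth (ARB) statistic, and CE1
   seroreactivity scores;
3. **association** — the cohort statistics (logistic diagnosis model,
   group-mean t tests, breadth-category chi-square, Kaplan–Meier/log-rank);
4. **mimicry** — IP-MS fold-change filtering, surface-proteome
   cross-referencing and BLOSUM62 local-alignment ranking of candidate
   CE1 mimics;
5. **signatures** — tumor-transcriptome ADCC signature scoring with NK and
   serostatus stratification;
6. **synthetic data** — seeded generators for every input, so the whole
   pipeline is exercisable and testable without restricted-access cohort
   data.

## Models and statistics

### Peptide partition

Peptides and protein chains live in 1-based closed residue coordinates on
their source polyprotein (the UniProt "Chain" convention; all file headers
state this). A peptide is **CE1-VP1** when its interval shares at least
`min_ce1_overlap` residues (default 1) with the CE1 window annotated inside
VP1; **non-CE1 VP1** when it intersects VP1 but not the window; **non-VP1**
otherwise. One shared residue suffices both for "overlaps CE1" and for
"lies in VP1" for boundary-spanning peptides; both thresholds are the
minimal reading of "overlap" and are exposed as configuration. The
assignment is always a partition, and the test suite checks it against a
brute-force per-residue set-intersection oracle, including one-residue
boundary cases.

### Antibody repertoire breadth

For one individual and one peptide group with $S$ peptides, let
$P_i = \mathrm{EBS}_i / \sum_j \mathrm{EBS}_j$. Then

$$\mathrm{ARB} = \frac{-\sum_{i=1}^{S} P_i \ln P_i}{\ln S},$$

the Shannon entropy of the reactivity proportions normalized by its
maximum, with the continuity convention $0 \ln 0 = 0$. ARB is 1 for
perfectly even reactivity, 0 when one peptide carries all signal, and is
invariant to rescaling the individual's EBS vector. When the group signal
is zero, or $S = 1$, breadth has no meaning and the value is flagged
undefined (NA) rather than forced to 0; downstream analyses drop undefined
individuals and log the count. The survival stratification uses the strict
indicator ARB > 0.5, and the four default category bins are the quartiles
of the unit interval — the published figure labels its bins only "as
indicated", so the quartile edges are a disclosed assumption and are
configurable.

### CE1 seroreactivity

The score is the mean EBS over a 40-peptide panel of the most reactive
CE1-related peptides. The default is *fixed-panel* mode — the supplied list
is the panel, because the published panel originates in prior work rather
than being recomputed per cohort. A *data-driven* mode selects the `k`
peptides with highest cohort-mean EBS (ties broken lexicographically).
"Detectable" seroreactivity has no published cutoff; `seropositivity
threshold` defaults to score > 0 and is prominently configurable.

### Cohort statistics

All tests are two-sided. The diagnosis model is a maximum-likelihood
logistic regression of the HCC indicator on a per-individual EBS summary
(`stats::glm`), reporting the odds ratio both per unit and per standard
deviation of the predictor, since the published per-EBS scaling is not
stated. Quasi-complete separation is flagged, never silently returned.
Group comparisons use the unpaired Student t test (Welch optional);
category tables use the Pearson chi-square without continuity correction;
survival uses the product-limit estimator and the standard
hypergeometric-variance log-rank (survival package), with the p-value from
the $\chi^2_{k-1}$ upper tail. Spearman correlations use mid-ranks and the
t-approximation (exact optionally for small tie-free strata). No
multiple-testing correction is applied by default, matching per-test
reporting; a Benjamini–Hochberg utility is provided.

### Mimicry screen

Protein intensities from immunoprecipitation–mass-spectrometry are compared
between target and control antibodies as
$\mathrm{FC} = (t + c_0)/(c + c_0)$ with pseudocount $c_0 = 1$ intensity
unit (DIA intensities can be missing/zero; the source analysis is silent on
zeros). A protein is enriched when FC strictly exceeds 100. Across the two
antibodies within a cell line the default is *any* (matching enrichment "by
either antibody"); across cell lines the default is *all* (enriched "in
both cell lines"); both are switches. Enriched proteins are intersected
with a surface-proteome list on case-folded, isoform-stripped identifiers.

Surviving candidates are ranked by Smith–Waterman local alignment of the
CE1 query (`CSESVPALTAVETGHTS`) under BLOSUM62 with affine gaps (open 11,
extend 1; a length-$k$ gap costs $11 + k$). Local alignment is the only
flavor under which a 17-mer query against a several-hundred-residue protein
produces the short homology block the screen looks for; the published
analysis used a web alignment tool without stating parameters, so these
defaults are disclosed assumptions. The expect value is the Karlin–Altschul
form $E = K m n e^{-\lambda S}$ with standard gapped BLOSUM62 constants
($K = 0.041$, $\lambda = 0.267$) and $m, n$ the query and subject lengths —
no database-size correction, because the screen uses $E$ only to *rank*
candidates, not to claim absolute significance. Ranking is by ascending
$E$, ties by descending raw score, then lexicographic id. Each aligned
column is flagged identity, conserved (different residues with BLOSUM62
score > 0), mismatch, or gap. The dynamic programming core is implemented
in C++ (Gotoh recurrences) with a deterministic traceback (diagonal > up >
left; gaps closed as early as possible); tests verify score equality
against an independently written memoized recursion, full path enumeration
on tiny instances, and `Biostrings::pairwiseAlignment`.

The query retains the leading cysteine of the printed peptide by default
(`strip_leading_cys = FALSE`): it is a conjugation residue, but stripping
it changes scores and is therefore opt-in.

### Tumor signatures

Expression is Z-scored per gene *within each dataset of origin* (sample
standard deviation, $n - 1$) before integration; zero-variance blocks
become zeros with a warning. "Inferred ADCC activity" is operationalized as
the unweighted mean of the 20 signature genes' Z-scores — the source lists
the genes and the normalization but not the aggregation, so the mean is the
minimal choice (replaceable by median or a principal component). NK
stratification is strict: score > 0.01 is high, a score exactly at the
cutoff is low. The ASPH median split assigns samples exactly at the median
to the low stratum. Both boundary conventions are fixed here because no
published convention exists.

## What the synthetic data emulate

The generators define the study conditions under a fixed seed and are
bit-reproducible:

- **Serology** (`cohort_spec`): defaults mirror the larger clinical cohort
  — 686 healthy, 470 chronic liver disease, 761 HCC — over the published
  59 / 281 / 1,671 peptide partition, which the generated catalog
  reproduces *exactly* by construction. EBS values are zero-inflated
  log-normal: non-negative and right-skewed, the shape implied by
  enrichment Z-scores thresholded at zero. Reactivity is broad across CE1
  peptides but sparse elsewhere, reproducing the right-shifted CE1 ARB
  distribution (most individuals > 0.5) versus near-zero non-CE1 breadth;
  a per-individual Beta(0.9, 0.9) reactivity propensity spreads CE1
  breadth over the unit interval so all four ARB bins and both survival
  arms are populated. Diagnosis is sampled from a logistic model in mean
  CE1 EBS whose slope encodes the protective odds ratio (default 0.9 per
  unit) and whose intercept is solved numerically for the requested HCC
  prevalence; the additive CE1 shift (+1) in healthy individuals is applied
  afterwards to nonzero entries, clamped at zero. HCC survival is
  exponential — the simplest model the log-rank analysis can recover — with
  hazard doubled (default) for ARB ≤ 0.5 and a baseline median of three
  years; censoring is independent exponential calibrated so each subject is
  censored with the requested probability (default 0.3).
- **IP-MS** (`mimicry_spec`): two cell lines × two target antibodies, 2,000
  background proteins with log-normal intensities around $10^5$. Background
  fold changes are log-normal around 1 (essentially never > 100) except for
  a designated 10% strongly-enriched fraction, and 10% of background
  proteins sit on the surface list — both keep the downstream funnel
  non-trivial, echoing the published 1454-enriched → 47-surface narrative
  at desk scale. The planted mimic carries the query subsequence at the
  requested identity fraction (default 0.8) at a uniformly random internal
  offset, with non-matching residues uniform over the 20 canonical amino
  acids, and is enriched 500-fold (fold-change noise uses half the
  intensity CV so the encoded fold is preserved through the filter).
- **Expression** (`expression_spec`): defaults mirror the 97-patient
  integrative cohort split across an array-like and an RNA-seq-like
  dataset with different per-gene offsets and scales, so within-dataset
  Z-scoring is genuinely exercised. Within each serostatus stratum, ASPH
  and a latent ADCC activity are drawn from a Gaussian copula with latent
  Pearson correlation $r = 2\sin(\pi\rho/6)$, which makes the *population
  Spearman* equal the requested $\rho$ (default 0.3 in seropositive, 0 in
  seronegative tumors — magnitudes consistent with the marginally
  significant published correlation at this sample size); the 20 signature
  genes load on the activity with small independent noise. NK scores
  straddle the 0.01 cutoff at per-stratum NK-high fractions (defaults
  0.6 / 0.3), and survival encodes a seropositivity benefit (hazard ratio
  0.5) confined to tumors above the median latent ASPH level.

What the generators do **not** emulate: raw sequencing reads or spectra,
antibody affinity maturation, peptide-to-peptide correlation induced by
shared strain ancestry, batch effects beyond dataset offset/scale, and
non-exponential survival. Passing tests therefore demonstrate that the
statistics recover effects *encoded under these idealized conditions* —
they do not certify performance on real cohort data, where EBS
distributions, censoring mechanisms and confounding are richer.

## Numerical choices and degenerate inputs

- $0 \ln 0 := 0$ in the entropy; ARB undefined (not 0) for zero signal or
  $S = 1$.
- The logistic intercept is solved by `uniroot` on $[-30, 30]$ at tolerance
  $10^{-10}$; separation is flagged when fitted probabilities reach both
  machine extremes with an exploded Wald standard error.
- Alignment tie-breaks are fully deterministic (end cell: highest score,
  then smallest row-major index; traceback: diagonal > up > left).
- Chi-square requires all expected counts positive; zero margins error.
- All-censored survival inputs return statistic 0 with a warning rather
  than an error.
- Z-scoring is idempotent to $10^{-10}$; constant genes produce zero rows
  with a warning.

## Problem sizes

The test suite and the acceptance script run everything on synthetic
cohorts sized to the package's own reproducibility budget: the full
1,917-individual × 2,011-peptide cohort for single analyses; 100–200
replicates at reduced non-informative peptide panels (59 CE1 + 10 others)
for effect-recovery checks, since only the CE1 block carries the encoded
effects; 200 random pairs for alignment-oracle equivalence; and 1,000
replicates at $n = 200$ for type-I-error calibration. These sizes give
Monte-Carlo error well inside every asserted tolerance.

## Known limitations

- The CE1 window coordinates per real polyprotein are not bundled; users
  of real catalogs must supply chain annotations with the window.
- The E-value constants are fixed, not estimated from the scoring system;
  rankings are meaningful, absolute E-values are nominal.
- The seropositivity cutoff and the ARB category edges are conventions of
  this package where the source leaves them open; both are configuration.
- Cox modeling, competing risks, xCell deconvolution and batch correction
  beyond within-dataset Z-scoring are out of scope.
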