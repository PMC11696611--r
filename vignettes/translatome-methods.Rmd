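---
title: "Methods: polysome-profiling translatome classification, codon bias and motif enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polysome-profiling translatome classification, codon bias and motif enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(translatome)
```

## The analysis in one paragraph

Polysome profiling fractionates cytosolic mRNAs by ribosome load: a *total*
cytosolic fraction, a *light* polysomal fraction (1–3 ribosomes) and a
*heavy* polysomal fraction (>3 ribosomes). Comparing a knockout (KO) against
control (CTL) animals fraction by fraction separates transcriptional from
translational control: a transcript whose abundance shifts in a polysomal
fraction but not in the total pool has changed its ribosome engagement, not
its expression. `translatome` tests each fraction with a negative-binomial
(NB) GLM likelihood-ratio test, integrates the three calls into regulation
categories, and then asks two sequence-level questions about the
post-transcriptionally controlled set: is it biased toward the
wobble-uridine (U34) codons AAA/GAA/CAA whose decoding depends on
Elongator-initiated tRNA modification, and do the encoded proteins
preferentially carry runs of ≥5 hydrophilic residues, a motif associated
with aggregation when U34-dependent decoding fails. Small utilities cover
the LC-MS readouts of that tRNA-modification axis (modification/nucleoside
ratios and ¹³C m+2 isotopologue enrichment).

## Differential abundance model

For gene $i$ in sample $j$ with size factor $s_j$, counts are modelled as

$$y_{ij} \sim \mathrm{NB}\big(\mu_{ij},\ \phi_i\big), \qquad
\mu_{ij} = s_j \exp\!\big(\beta_{0i} + \beta_{1i}\,x_j\big),$$

with $x_j = 1$ for KO samples, $\mathrm{Var}(y) = \mu + \phi\mu^2$, and the
reported effect $\log_2\!\mathrm{FC} = \beta_{1i}/\ln 2$. The null
$\beta_{1i} = 0$ is compared to the full model by the likelihood-ratio
statistic $\Lambda_i = 2(\ell_{\text{full}} - \ell_{\text{null}})$, clipped
at zero and referred to $\chi^2_1$.

**Normalisation.** Median-of-ratios size factors: each sample's median
ratio to the per-gene geometric-mean reference over genes expressed in all
samples, rescaled to geometric mean 1. The method is exactly reproducible
by hand on small matrices, which is why it was preferred over TMM.

**Fitting.** At fixed $\phi_i$ the two-group model separates into
independent one-parameter problems (one rate per group, and one pooled rate
for the null), each solved by Fisher scoring on $\eta = \log\lambda$ with a
step cap of 5 and convergence at $|\Delta\eta| < 10^{-10}$ (50 iterations
maximum). A group with all-zero counts has its MLE at $\lambda = 0$ with
log-likelihood contribution 0; genes that fail to converge are reported
with `p = NA` and excluded from the BH family, so phantom tests never
deflate the adjusted values of the rest.

**Dispersion.** Per gene, a method-of-moments estimate on
size-factor-scaled counts, with the within-group sum of squares pooled over
both groups ($n-2$ denominator):
$\hat\phi_i^{\text{raw}} = \max\{0, (s_i^2 - m_i)/m_i^2\}$. Raw estimates
are then shrunk toward a mean–dispersion trend, keeping weight 0.3 on the
per-gene estimate and giving 0.7 to the trend, with a floor of $10^{-8}$.
The trend is a plain local average (lowess, `f = 0.5`, **no** robustness
iterations) of $\hat\phi^{\text{raw}}$ against $\log m$: the moment
estimator is strongly right-skewed at small $n$, so robustness iterations
would chase its median and systematically understate the dispersion. With
5 replicates per group the per-gene estimate is noisy, and the strong pull
to the trend is precisely what keeps the plug-in $\chi^2_1$ reference
calibrated (the test suite checks an all-null false-positive rate of
$0.05 \pm 0.01$ at $p < 0.05$ on 10,000 genes); weighting the per-gene
estimate more heavily makes the test anticonservative. This transparent
estimator deliberately replaces the Cox–Reid/empirical-Bayes machinery of
the established NB engines: it is oracle-testable line by line, and
adequate at the scale this package targets.

**Calls.** Significance requires both $|\mathrm{FC}| \ge$ `fc_threshold`
(inclusive) and FDR $<$ `fdr_threshold` (strict). Two presets are used:
polysome fractions (1.2, 0.2) and conventional whole-tissue RNA-seq
(2.0, 0.05). The BH adjustment is the standard step-up procedure applied to
the converged tests only.

Statistical power at these settings depends on the multiplicity context:
on an isolated family of planted 2-fold effects the suite requires ≥80%
sensitivity, while the same effects embedded in a predominantly null genome
are detected at a lower rate because the BH cutoff tightens — a behaviour
shared by the established NB engines on identical matrices, not a property
of this implementation.

## Fraction integration

With per-fraction significance flags $(T, L, H)$:

| total | light or heavy | category |
|---|---|---|
| no | yes | post_transcriptional |
| yes | no | transcriptional |
| yes | yes | mix |
| no | no | unchanged |

`unchanged` is an explicit fourth category so that the table is total and
the classifier is a partition — every tested gene receives exactly one
label. A gene filtered out of one fraction but tested in another is treated
as not significant in the missing fraction and flagged via `tested_*`
columns rather than dropped. Direction agreement between fractions is
diagnosed (`direction_consistent`) but never required for a category,
since the category definitions are stated purely in terms of differential
abundance.

## Codon-usage enrichment

Codons are counted as in-frame, non-overlapping triplets; stop codons and
codons containing `N` are excluded, and set-level frequencies pool counts
across genes (not per-gene means). Two statistics are computed because the
enrichment question can be read both ways: a per-codon Pearson $\chi^2$ on
the 2×2 table (codon vs rest; set vs background), 1 df, no continuity
correction, BH-adjusted across the 61 sense codons, with `enriched` set
when the set frequency exceeds background at FDR < 0.05; and an omnibus
61-cell goodness-of-fit $\chi^2$ of the set counts against the background
proportions. Background codons with zero probability are merged into an
"other" cell for the omnibus; observed mass in that cell is impossible
under the null and yields an infinite statistic, which is reported as such
rather than masked. The background is the whole transcriptome *including*
the test set, matching the natural reading of "against the whole
transcriptome"; an exclusive background can be obtained by subtracting the
set counts. The FDR cut of 0.05 on the flags is a package default, not an
extracted value. The U34 annotation defaults to {AAA, GAA, CAA} — the
A-ending codons of Lys/Glu/Gln read by the U34-modified tRNAs — and can be
extended with {AAG, GAG, CAG} for U:G wobble.

## Hydrophilic-run motif

The motif is a maximal run of at least `min_run = 5` consecutive
hydrophilic residues. The default alphabet {D, E, K, R, H, N, Q, S, T}
(charged plus polar-uncharged side chains) is a documented modelling choice
— the motif's originating literature defines it only by reference, so the
alphabet is configurable. Runs are maximal by construction (a run of 7 is
one motif, not three overlapping windows), positions are reported 1-based
inclusive in the R convention, and `X` is never hydrophilic. Prevalence is
reported both unrounded and as the nearest-integer display percentage
(282 of 2288 → 12.33%, displayed 12%). Enrichment against a background
proteome is an exact two-sided Fisher test on the presence/absence 2×2
table — a deliberate replacement of rank-based motif-enrichment software:
the scientific claim is over-representation of motif-bearing proteins,
which the exact test answers directly and reproducibly.

## Synthetic-data generator

The generator produces the study conditions the pipeline is validated
under, with all draws derived from a single seed (one stream per operation,
offset by operation, so enlarging one stage never perturbs another):

* **Design.** 2,000 genes, 5 replicates per group; 10% of genes
  post-transcriptional, 10% transcriptional, 5% mix, the rest unchanged.
  Effects are $\pm 1$ on the $\log_2$ scale (random sign per gene) placed
  on KO relative to CTL: light+heavy for post-transcriptional genes,
  total-only for transcriptional genes, total+heavy for mix genes —
  the simplest realisation consistent with the category definitions.
* **Counts.** $y \sim \mathrm{NB}$ with log-normal gene baselines
  (median ≈ 100 counts, $\sigma_{\log} = 1.2$), gene-wise dispersions
  log-normal with mean `dispersion_mean` = 0.1 (a typical bulk RNA-seq
  value), and log-normal library-size factors with CV 0.2 so that
  normalisation is exercised non-trivially. Fractions are conditionally
  independent given the gene baseline — a documented simplification; real
  fractions from one animal share biological noise.
* **Codon usage.** CDS are drawn codon-by-codon from a base distribution in
  which hydrophilic-residue codons are down-weighted (factor 0.3 against a
  uniform 61-codon background), putting the per-residue hydrophilic
  frequency near 0.20 so that *chance* penta-hydrophilic runs occur in
  roughly 5–15% of proteins — the order observed in real proteomes. Under a
  uniform codon model ~46% of residues would be hydrophilic and nearly
  every protein would carry a run, collapsing the motif analysis. U34-
  enriched genes (the post-transcriptional set) multiply the AAA/GAA/CAA
  probabilities by `u34_codon_boost` = 3 and renormalise, so their expected
  U34 frequency follows the closed form $bq/(1+(b-1)q)$ checked in the
  tests.
* **Motifs.** A fraction `hydrophilic_run_prob` = 0.12 of the
  post-transcriptional genes receives one planted run of exactly five
  hydrophilic residues, encoded at CDS level at a random internal position;
  every planted gene is motif-positive under the scanner (closure checked
  in the tests).

What the generator does **not** emulate — isoform structure, positional or
GC bias, correlated fractions, batch effects, outlier samples — bounds what
green tests mean: they validate the statistical machinery under the stated
model, not robustness to the full messiness of sequencing data.

## Problem sizes and runtime choices

The validation suite uses 10,000 genes for null calibration, 2,000-gene
fixtures for end-to-end category recovery, and 200–1,000 random cases for
each oracle comparison (BH, Pearson $\chi^2$, motif scanning, translation).
These sizes put Monte-Carlo error comfortably inside the asserted
tolerances while keeping the whole suite around a minute on one core; the
NB fitter is vectorised across genes, so the per-fraction test of a
10,000-gene matrix takes well under a second.

## Known limitations

* Gene-level only: one CDS represents a gene; isoform choice is the
  caller's responsibility.
* The dispersion estimator trades efficiency for transparency; with very
  few genes (< 10 expressed) no trend is fit and raw moment estimates are
  used as-is.
* The omnibus codon statistic becomes infinite when the set uses a codon
  the background lacks; at transcriptome scale this does not occur, but
  tiny toy backgrounds can trigger it.
* `mix` requires total plus a polysomal fraction; no attempt is made to
  subdivide by direction or magnitude.
* The LC-MS utilities start from integrated peak areas; peak picking,
  integration and isotope-pattern deconvolution are upstream of this
  package. The natural-abundance m+2 baseline is provided as a diagnostic
  and is off by default, matching the convention of reporting uncorrected
  relative ratios.
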