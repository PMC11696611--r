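# translatome

Polysome-profiling translatome analysis for two-group (KO vs CTL) designs:
negative-binomial differential abundance per fraction, integration of the
total / light-polysomal / heavy-polysomal fractions into regulation
categories, wobble-uridine (U34) codon-usage enrichment, penta-hydrophilic
protein-motif prevalence, and LC-MS nucleoside ratio utilities. It is aimed
at groups analysing sucrose-gradient polysome fractionation RNA-seq who want
a transparent, fully testable chain from count tables to the biological
readouts of the tRNA-modification / codon-decoding axis.

## The model

Counts for gene *i*, sample *j* follow a negative binomial with
Var = μ + φμ², mean

&nbsp;&nbsp;&nbsp;&nbsp;μ<sub>ij</sub> = s<sub>j</sub> · exp(β₀ᵢ + β₁ᵢ·1[KO]),

with median-of-ratios size factors s<sub>j</sub> and per-gene dispersion φᵢ
(method of moments, shrunk to a mean–dispersion trend). β₁ᵢ = 0 is tested by
a likelihood-ratio statistic against χ²₁; log₂FC = β₁ᵢ/ln 2; BH-adjusted
p-values are thresholded at |FC| ≥ 1.2 and FDR < 0.2 per fraction (the
engine is reusable at the conventional |FC| ≥ 2, FDR < 0.05 for whole-tissue
RNA-seq). The three per-fraction calls (T, L, H) map onto categories:

* polysomal but not total → **post-transcriptional**
* total only → **transcriptional**
* total and polysomal → **mix**
* none → **unchanged**

The post-transcriptional set is then tested for codon bias (per-codon
Pearson χ² against the whole-transcriptome background, BH over the 61 sense
codons, U34 codons AAA/GAA/CAA flagged) and for prevalence and Fisher-exact
enrichment of maximal runs of ≥5 hydrophilic residues (D,E,K,R,H,N,Q,S,T) in
the encoded proteins. See `vignettes/translatome-methods.Rmd` for the full
account.

## Worked example

The numbered scripts under `analysis/` run the whole study on the seeded
synthetic fixture (2,000 genes, 5 KO vs 5 CTL per fraction, ground truth
included) and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_data.R
Rscript analysis/02_differential_abundance.R
Rscript analysis/03_classify_regulation.R
Rscript analysis/04_codon_bias.R
Rscript analysis/05_motif_prevalence.R
Rscript analysis/06_nucleoside_ratios.R
```

Stage 2–5 output on the default seed:

```
total  fraction: 2000 genes tested, 326 significant (153 up, 173 down)
light  fraction: 2000 genes tested, 226 significant (114 up, 112 down)
heavy  fraction: 2000 genes tested, 302 significant (150 up, 152 down)

post_transcriptional      transcriptional                  mix            unchanged
                 270                  219                  107                 1404
Balanced accuracy vs ground truth: 0.856

Enriched codons (FDR < 0.05):
 codon freq_set freq_background       fdr  u34
   CAA   0.0169         0.00886 6.69e-106 TRUE
   AAA   0.0171         0.00862 1.52e-119 TRUE
   GAA   0.0167         0.00870 8.36e-106 TRUE

Motif prevalence in post-transcriptional set: 68 of 270 (25.2%, display 25%)
Whole-proteome background: 203 of 2000 (10.2%)
Fisher exact enrichment: OR = 2.98, p = 8.7e-11
```

Reading: the classifier recovers the planted regulation structure
(balanced accuracy 0.856 over the four categories), the three U34 codons
planted into the post-transcriptional genes are exactly the codons flagged
enriched against the transcriptome background, and the planted hydrophilic
runs raise motif prevalence in that set roughly 2.5-fold over the
background proteome.

The same chain runs on real data by replacing stage 1: load each fraction
with `read_counts()` (genes × samples TSV plus a sample→group map) and the
CDS with `read_fasta()`, then `run_pipeline(counts = ..., transcripts =
...)` executes stages 2–5 in one call.

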