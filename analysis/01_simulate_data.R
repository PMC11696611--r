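#!/usr/bin/env Rscript
# Stage 1: generate the synthetic polysome-profiling study.
#
# Writes a seeded fixture — transcriptome FASTA, three fraction count tables
# (total cytosolic, light polysomal, heavy polysomal; 5 KO vs 5 CTL), and
# the ground-truth regulation labels — under results/synthetic_data/.

suppressPackageStartupMessages(library(translatome))

cfg <- sim_config(seed = 1L)   # default study conditions
ds <- simulate_dataset(cfg)
out <- "results/synthetic_data"
write_dataset(ds, cfg, out)

cat("Simulated", cfg$n_genes, "genes x", 2L * cfg$n_reps_per_group,
    "samples per fraction ->", out, "\n")
print(table(ds$truth$true_category))
cat(sum(ds$truth$has_planted_motif), "genes carry a planted",
    "penta-hydrophilic run;",
    sum(ds$truth$u34_enriched), "are U34-codon enriched\n")
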