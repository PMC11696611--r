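#!/usr/bin/env Rscript
# Stage 4: codon-usage bias of the post-transcriptionally regulated genes.
#
# Compares pooled codon frequencies of the post-transcriptional set against
# the whole synthetic transcriptome by per-codon chi-squared tests (BH over
# the 61 sense codons) plus an omnibus goodness-of-fit statistic, flagging
# the wobble-uridine codons AAA/GAA/CAA.

suppressPackageStartupMessages(library(translatome))

tx <- read_fasta("results/synthetic_data/transcriptome.fasta")
calls <- utils::read.delim("results/regulation_calls.tsv")
post <- intersect(calls$gene_id[calls$category == "post_transcriptional"],
                  tx$gene_id)
cat("Post-transcriptional set:", length(post), "genes\n")

res <- codon_chi2(codon_usage(tx, post), codon_usage(tx))
utils::write.table(res$table, "results/codon_enrichment.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

enr <- res$table[res$table$enriched, c("codon", "freq_set",
                                       "freq_background", "fdr", "u34")]
cat("Enriched codons (FDR < 0.05):\n")
print(enr, row.names = FALSE, digits = 3)
cat(sprintf("Omnibus chi2 = %.1f on %d df (p = %.3g)\n",
            res$global_chi2, res$global_df, res$global_p))
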