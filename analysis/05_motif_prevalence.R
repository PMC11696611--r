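#!/usr/bin/env Rscript
# Stage 5: penta-hydrophilic motif prevalence and enrichment.
#
# Translates the CDS set, scans every protein for maximal runs of >= 5
# hydrophilic residues (D,E,K,R,H,N,Q,S,T), reports prevalence in the
# post-transcriptionally regulated set, and tests enrichment against the
# whole synthetic proteome with a two-sided Fisher exact test.

suppressPackageStartupMessages(library(translatome))

tx <- add_proteins(read_fasta("results/synthetic_data/transcriptome.fasta"))
calls <- utils::read.delim("results/regulation_calls.tsv")
post <- calls$gene_id[calls$category == "post_transcriptional"]

scan <- scan_motif_table(tx)
utils::write.table(scan, "results/motif_results.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

set_scan <- scan[scan$gene_id %in% post, ]
prev <- motif_prevalence(set_scan)
cat(sprintf("Motif prevalence in post-transcriptional set: %d of %d (%.1f%%, display %d%%)\n",
            prev$n_positive, prev$n_total, prev$percent,
            prev$display_percent))
bg_prev <- motif_prevalence(scan)
cat(sprintf("Whole-proteome background: %d of %d (%.1f%%)\n",
            bg_prev$n_positive, bg_prev$n_total, bg_prev$percent))

fish <- motif_fisher(set_scan, scan)
cat(sprintf("Fisher exact enrichment: OR = %.2f, p = %.3g\n",
            fish$odds_ratio, fish$p))
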