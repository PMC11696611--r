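#!/usr/bin/env Rscript
# Stage 3: integrate the three fractions into regulation categories.
#
# A gene significant in a polysomal fraction but not in total is controlled
# post-transcriptionally; total-only is transcriptional; total plus a
# polysomal fraction is mix; the remainder is unchanged. Scores recovery
# against the generator's ground truth.

suppressPackageStartupMessages(library(translatome))

de <- lapply(c(total = "total", light = "light", heavy = "heavy"),
             function(f) {
               utils::read.delim(file.path("results", paste0("de_", f, ".tsv")))
             })
calls <- classify_regulation(de$total, de$light, de$heavy)
utils::write.table(calls, "results/regulation_calls.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat("Regulation categories over", nrow(calls), "tested genes:\n")
print(table(calls$category))

truth <- utils::read.delim("results/synthetic_data/truth.tsv")
merged <- merge(calls, truth, by = "gene_id")
cat(sprintf("Balanced accuracy vs ground truth: %.3f\n",
            balanced_accuracy(merged$category, merged$true_category)))
cat(sprintf("%d significant genes change direction between fractions\n",
            sum(!merged$direction_consistent)))
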