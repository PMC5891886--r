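#!/usr/bin/env Rscript
# Expression-ratio classification: the >= 2-unit signed difference between
# epithelial and stromal TRIM28 IHC scores defines the high ratio group.

suppressMessages(library(stromanet))

out_dir <- "results/workflow"
ihc <- read_ihc_table(file.path(out_dir, "ihc_scores.csv"))

res <- classify_cohort(ihc)
write_ihc_table(res$cases, file.path(out_dir, "groups.csv"))

message(sprintf("classified %d cases: %d high ratio, %d low ratio",
                sum(res$counts), res$counts["high"], res$counts["low"]))
print(table(epithelium = res$cases$epithelium_score,
            stroma = res$cases$stroma_score))
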