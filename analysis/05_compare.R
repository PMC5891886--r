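#!/usr/bin/env Rscript
# Endpoint-level comparisons: Welch t tests of every endpoint (i) between
# epithelium and stroma within each ratio group and (ii) between ratio
# groups within each compartment, plus the box-plot summary statistics the
# comparisons are usually displayed with.

suppressMessages(library(stromanet))

out_dir <- "results/workflow"
values <- read_reduced_table(file.path(out_dir, "reduced.csv"))
groups <- read_ihc_table(file.path(out_dir, "groups.csv"))
qc <- read.csv(file.path(out_dir, "qc_report.csv"))
values <- values[!values$case_id %in% unique(qc$case_id[!qc$passed]), ]

comp <- compare_all(values, groups, alpha = 0.05)
box <- boxplot_summaries(values, groups)

write.csv(comp, file.path(out_dir, "comparisons.csv"), row.names = FALSE)
write.csv(box, file.path(out_dir, "boxplot_summaries.csv"), row.names = FALSE)

sig <- comp[!is.na(comp$significant) & comp$significant, ]
message(sprintf("%d of %d endpoint contrasts significant at p < 0.05",
                nrow(sig), nrow(comp)))
if (nrow(sig)) {
  print(sig[order(sig$p_value),
            c("endpoint", "stratum_a", "stratum_b", "p_value")][
              seq_len(min(10, nrow(sig))), ])
}
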