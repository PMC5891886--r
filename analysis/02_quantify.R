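#!/usr/bin/env Rscript
# RPPA quantification: replicate averaging, ssDNA normalization per dilution
# step, dilution-series reduction with a linearity flag, and the
# negative-control QC screen that drops cases indistinguishable from the
# no-primary-antibody slide.

suppressMessages(library(stromanet))

out_dir <- "results/workflow"
spots <- read_spot_table(file.path(out_dir, "spots.csv"))

q <- quantify_rppa(spots, qc_alpha = 0.05, slope_tolerance = 0.3)

write_reduced_table(q$values, file.path(out_dir, "reduced.csv"))
write.csv(q$qc, file.path(out_dir, "qc_report.csv"), row.names = FALSE)
write.csv(q$flags, file.path(out_dir, "reduction_flags.csv"),
          row.names = FALSE)

message(sprintf("reduced %d case x compartment units, detection floor %.3g",
                nrow(q$values), q$detection_floor))
message(sprintf("non-linear dilution series: %d of %d reduced values",
                sum(!q$flags$linearity_ok, na.rm = TRUE), nrow(q$flags)))
message("QC-excluded case(s): ",
        if (length(q$excluded_cases)) paste(q$excluded_cases, collapse = ", ")
        else "none")
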