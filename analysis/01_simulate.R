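#!/usr/bin/env Rscript
# Generate the study-design synthetic cohort: 19 cases (10 high / 9 low
# expression ratio), 30 endpoints in 4-point 2-fold dilution series per
# compartment, one case at the negative-control floor, and planted shared /
# group-exclusive correlation blocks. Writes the raw tables the rest of the
# workflow consumes.

suppressMessages(library(stromanet))

seed <- 17L
out_dir <- "results/workflow"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

spec <- default_cohort_spec(seed = seed)
sim <- generate_cohort(spec)

write_spot_table(sim$spots, file.path(out_dir, "spots.csv"))
write_ihc_table(sim$ihc, file.path(out_dir, "ihc_scores.csv"))
write.csv(sim$truth, file.path(out_dir, "truth.csv"), row.names = FALSE)

message(sprintf("wrote %d spot records for %d cases (%d endpoints)",
                nrow(sim$spots), length(unique(sim$spots$case_id)),
                spec$n_endpoints))
message(sprintf("planted %d correlation pairs (%s)", nrow(sim$truth),
                paste(names(table(sim$truth$scope)),
                      table(sim$truth$scope), sep = "=", collapse = ", ")))
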