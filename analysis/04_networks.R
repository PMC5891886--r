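#!/usr/bin/env Rscript
# Differential correlation networks: per ratio group and compartment,
# Spearman edges at rho >= 0.75 and p <= 0.01 on QC-passed cases; edges
# present in both groups of a compartment are shared and excluded, each
# group's exclusive edges form its differential network, subgrouped by
# seeded modularity maximization and exported as GEXF.

suppressMessages(library(stromanet))

seed <- 17L
out_dir <- "results/workflow"
values <- read_reduced_table(file.path(out_dir, "reduced.csv"))
groups <- read_ihc_table(file.path(out_dir, "groups.csv"))
qc <- read.csv(file.path(out_dir, "qc_report.csv"))

excluded <- unique(qc$case_id[!qc$passed])
values <- values[!values$case_id %in% excluded, ]
rg <- groups$ratio_group[match(values$case_id, groups$case_id)]
endpoints <- setdiff(names(values), c("case_id", "compartment"))

edge_sets <- list()
for (comp in c("epithelium", "stroma")) {
  for (g in c("high", "low")) {
    sel <- values$compartment == comp & rg == g
    m <- as.matrix(values[sel, endpoints])
    edge_sets[[paste(g, comp)]] <- significant_edges(
      m, group = paste0(g, "_ratio"), compartment = comp)
  }
}

offset <- 0L
all_edges <- list()
for (comp in c("epithelium", "stroma")) {
  part <- shared_and_exclusive(edge_sets[[paste("high", comp)]],
                               edge_sets[[paste("low", comp)]])
  message(sprintf("%s: %d shared, %d high-exclusive, %d low-exclusive edges",
                  comp, nrow(part$shared), nrow(part$exclusive_a$edges),
                  nrow(part$exclusive_b$edges)))
  for (side in c("exclusive_a", "exclusive_b")) {
    es <- part[[side]]
    g <- build_network(es)
    sub <- detect_subgroups(g, seed = seed + offset); offset <- offset + 1L
    if (igraph::vcount(g) > 0) {
      igraph::V(g)$community <- unname(sub$membership[igraph::V(g)$name])
    }
    key <- paste0(es$group, ".", comp)
    export_network(g, file.path(out_dir, paste0("network_", key, ".gexf")),
                   format = "gexf")
    message(sprintf("  %s: %d nodes, %d subgroups", key,
                    igraph::vcount(g), sub$n_subgroups))
    ed <- es$edges
    if (nrow(ed)) { ed$status <- "exclusive"; ed$group <- es$group
                    ed$compartment <- comp }
    all_edges[[key]] <- ed
  }
  sh <- part$shared
  if (nrow(sh)) { sh$status <- "shared"; sh$compartment <- comp }
  all_edges[[paste0("shared.", comp)]] <- sh
}

edges_flat <- do.call(rbind, lapply(all_edges, function(d)
  if (is.null(d) || nrow(d) == 0) NULL else
    data.frame(endpoint_a = d$endpoint_a, endpoint_b = d$endpoint_b,
               status = d$status, compartment = d$compartment,
               group = if ("group" %in% names(d)) d$group else "both",
               rho = if ("rho" %in% names(d)) d$rho else d$rho_a)))
write.csv(edges_flat, file.path(out_dir, "edges.csv"), row.names = FALSE)
message("edge tables written to ", file.path(out_dir, "edges.csv"))
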