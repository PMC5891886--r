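#' Validated pipeline configuration
#'
#' Collects the inputs and thresholds of a full run: either a
#' [cohort_spec()] to simulate, or paths/data frames for a spot table and an
#' IHC score table; the significance thresholds (`rho_min = 0.75`,
#' `p_max = 0.01` for edges; `alpha = 0.05` for group comparisons;
#' `qc_alpha = 0.05` for the negative-control screen;
#' `slope_tolerance = 0.3` for dilution linearity); the root seed; the
#' output directory and network export format. Validation happens here,
#' before any computation.
#'
#' @param simulate optional [cohort_spec()]; when given, `spots`/`ihc` are
#'   generated from it.
#' @param spots,ihc spot table / IHC table (data frame or file path);
#'   ignored when `simulate` is given.
#' @param rho_min,p_max,alpha,qc_alpha,slope_tolerance thresholds.
#' @param abs_rho filter edges on |rho| instead of signed rho.
#' @param var_equal pooled-variance t tests instead of Welch.
#' @param seed root RNG seed; every stochastic stage derives from it.
#' @param out_dir output directory (created if missing); `NULL` = no files
#'   written.
#' @param format network export format, `"graphml"` or `"gexf"`.
#' @return validated config list.
#' @export
pipeline_config <- function(simulate = NULL, spots = NULL, ihc = NULL,
                            rho_min = 0.75, p_max = 0.01, alpha = 0.05,
                            qc_alpha = 0.05, slope_tolerance = 0.3,
                            abs_rho = FALSE, var_equal = FALSE,
                            seed = 1L, out_dir = NULL,
                            format = c("graphml", "gexf")) {
  format <- match.arg(format)
  if (is.null(simulate) && (is.null(spots) || is.null(ihc))) {
    stop("either a simulate spec or both spots and ihc inputs are required",
         call. = FALSE)
  }
  if (!is.null(simulate) && !inherits(simulate, "cohort_spec")) {
    stop("simulate must be a cohort_spec", call. = FALSE)
  }
  check01 <- function(x, name, lo = 0, hi = 1) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= lo || x > hi) {
      stop("invalid ", name, ": must be in (", lo, ", ", hi, "]",
           call. = FALSE)
    }
  }
  check01(rho_min, "rho_min")
  check01(p_max, "p_max")
  check01(alpha, "alpha")
  check01(qc_alpha, "qc_alpha")
  if (!is.numeric(slope_tolerance) || slope_tolerance < 0) {
    stop("invalid slope_tolerance", call. = FALSE)
  }
  list(simulate = simulate, spots = spots, ihc = ihc,
       rho_min = rho_min, p_max = p_max, alpha = alpha,
       qc_alpha = qc_alpha, slope_tolerance = slope_tolerance,
       abs_rho = abs_rho, var_equal = var_equal,
       seed = as.integer(seed), out_dir = out_dir, format = format)
}

#' Run the full quantify - classify - network - compare pipeline
#'
#' Stages, mirroring the study workflow: (1) RPPA quantification with ssDNA
#' normalization, dilution reduction and negative-control QC; (2) IHC ratio
#' classification into high/low groups; (3) per group x compartment
#' thresholded Spearman edge sets on QC-passed cases, partitioned into
#' shared and exclusive edges; (4) differential networks from the exclusive
#' edges with seeded modularity subgroups, exported to GraphML/GEXF;
#' (5) endpoint comparisons between compartments within each group and
#' between groups within each compartment, with box-plot summaries. All
#' tables and a machine-readable `report.json` are written to
#' `config$out_dir` when set; the report's counts are recomputed from the
#' emitted edge tables, never cached.
#'
#' @param config a [pipeline_config()].
#' @return invisible list: `report`, plus the stage outputs (`quant`,
#'   `groups`, `edge_sets`, `partitions`, `networks`, `subgroups`,
#'   `comparisons`, `boxplots`).
#' @export
run_pipeline <- function(config) {
  log_lines <- character(0)
  say <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  if (!is.null(config$simulate)) {
    say("stage simulate: generating synthetic cohort (seed ",
        config$simulate$seed, ")")
    sim <- generate_cohort(config$simulate)
    spots <- sim$spots
    ihc <- sim$ihc
  } else {
    spots <- if (is.character(config$spots)) read_spot_table(config$spots)
             else validate_spot_table(config$spots)
    ihc <- if (is.character(config$ihc)) read_ihc_table(config$ihc)
           else config$ihc
  }

  say("stage quantify: ", length(unique(spots$case_id)), " cases")
  quant <- quantify_rppa(spots, qc_alpha = config$qc_alpha,
                         slope_tolerance = config$slope_tolerance)
  say("stage quantify: excluded ", length(quant$excluded_cases),
      " case(s) by negative-control QC")

  say("stage classify")
  groups <- classify_cohort(ihc)

  values <- quant$values
  keep <- !values$case_id %in% quant$excluded_cases
  values <- values[keep, , drop = FALSE]
  rg <- groups$cases$ratio_group[match(values$case_id, groups$cases$case_id)]
  endpoints <- setdiff(names(values), c("case_id", "compartment"))

  say("stage network: thresholded Spearman edges (rho >= ", config$rho_min,
      ", p <= ", config$p_max, ")")
  edge_sets <- list()
  for (comp in c("epithelium", "stroma")) {
    for (g in c("high", "low")) {
      sel <- values$compartment == comp & rg == g
      m <- as.matrix(values[sel, endpoints, drop = FALSE])
      rownames(m) <- values$case_id[sel]
      edge_sets[[paste0(g, "_ratio.", comp)]] <-
        significant_edges(m, group = paste0(g, "_ratio"),
                          compartment = comp,
                          rho_min = config$rho_min, p_max = config$p_max,
                          abs_rho = config$abs_rho)
    }
  }
  partitions <- list(
    epithelium = shared_and_exclusive(edge_sets[["high_ratio.epithelium"]],
                                      edge_sets[["low_ratio.epithelium"]]),
    stroma = shared_and_exclusive(edge_sets[["high_ratio.stroma"]],
                                  edge_sets[["low_ratio.stroma"]])
  )

  networks <- list()
  subgroups <- list()
  offset <- 0L
  for (comp in c("epithelium", "stroma")) {
    for (side in c("exclusive_a", "exclusive_b")) {
      es <- partitions[[comp]][[side]]
      key <- paste0(es$group, ".", comp)
      g <- build_network(es)
      sub <- detect_subgroups(g, seed = config$seed + offset)
      offset <- offset + 1L
      if (igraph::vcount(g) > 0L) {
        igraph::V(g)$community <- unname(sub$membership[igraph::V(g)$name])
      }
      networks[[key]] <- g
      subgroups[[key]] <- sub
      say("stage network: ", key, " - ", igraph::ecount(g),
          " exclusive edges, ", sub$n_subgroups, " subgroup(s)")
    }
  }

  say("stage compare: both contrast families, alpha = ", config$alpha)
  comparisons <- compare_all(values, groups$cases,
                             alpha = config$alpha,
                             var_equal = config$var_equal)
  boxplots <- boxplot_summaries(values, groups$cases)

  edge_tables <- lapply(names(edge_sets), function(key) {
    es <- edge_sets[[key]]
    comp <- es$compartment
    shared_keys <- paste(partitions[[comp]]$shared$endpoint_a,
                         partitions[[comp]]$shared$endpoint_b, sep = "~")
    ed <- es$edges
    ed$status <- ifelse(paste(ed$endpoint_a, ed$endpoint_b, sep = "~") %in%
                          shared_keys, "shared", "exclusive")
    ed$group <- es$group
    ed$compartment <- comp
    ed
  })
  names(edge_tables) <- names(edge_sets)

  report <- list(
    seed = config$seed,
    thresholds = list(rho_min = config$rho_min, p_max = config$p_max,
                      alpha = config$alpha, qc_alpha = config$qc_alpha,
                      slope_tolerance = config$slope_tolerance),
    group_sizes = as.list(groups$counts),
    qc_excluded = as.list(quant$excluded_cases),
    cases_in_network = as.list(tapply(values$case_id, rg, function(x)
      length(unique(x)))[c("high", "low")]),
    n_pairs_evaluated = edge_sets[[1L]]$n_pairs_evaluated,
    shared_edges = lapply(partitions, function(p) nrow(p$shared)),
    exclusive_edges = lapply(edge_tables, function(t)
      sum(t$status == "exclusive")),
    n_subgroups = lapply(subgroups, function(s) s$n_subgroups),
    n_significant_comparisons = sum(comparisons$significant, na.rm = TRUE),
    version = as.character(utils::packageVersion("stromanet"))
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$out_dir, f)
    write_reduced_table(quant$values, out("reduced.csv"))
    utils::write.csv(quant$qc, out("qc_report.csv"), row.names = FALSE)
    write_ihc_table(groups$cases, out("groups.csv"))
    all_edges <- do.call(rbind, edge_tables)
    rownames(all_edges) <- NULL
    utils::write.csv(all_edges, out("edges.csv"), row.names = FALSE)
    for (key in names(networks)) {
      ext <- if (config$format == "graphml") "graphml" else "gexf"
      export_network(networks[[key]], out(paste0("network_", key, ".", ext)),
                     format = config$format)
    }
    utils::write.csv(comparisons, out("comparisons.csv"), row.names = FALSE)
    utils::write.csv(boxplots, out("boxplot_summaries.csv"),
                     row.names = FALSE)
    jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    writeLines(log_lines, out("run.log"))
    say("outputs written to ", config$out_dir)
  }

  invisible(list(report = report, quant = quant, groups = groups,
                 edge_sets = edge_sets, partitions = partitions,
                 networks = networks, subgroups = subgroups,
                 edge_tables = edge_tables,
                 comparisons = comparisons, boxplots = boxplots))
}
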