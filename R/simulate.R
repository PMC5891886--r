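# run code with a local RNG state so generation never disturbs the caller's seed
with_local_seed <- function(seed, code) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic RPPA + IHC cohort
#'
#' Describes a two-group cohort with planted correlation structure: group
#' sizes, endpoint panel, dilution design, log-normal intensity noise, ssDNA
#' loading variation, a negative-control noise floor, the cohort's paired
#' IHC score distribution, cases forced to the noise floor (to exercise QC
#' exclusion), and correlation blocks that are shared between the ratio
#' groups or exclusive to one. Planted `rho` values are Spearman targets;
#' the generator embeds them in a Gaussian copula with latent Pearson
#' correlation `2 sin(pi rho / 6)`.
#'
#' @param n_cases_high,n_cases_low group sizes (defaults 10 and 9).
#' @param n_endpoints size of the antibody panel (default 30).
#' @param dilution_steps number of 2-fold dilution points (default 4:
#'   undiluted, 1:2, 1:4, 1:8).
#' @param correlation_blocks list of blocks, each
#'   `list(endpoints = <indices>, rho = <Spearman target in (0,1)>,
#'   scope = "shared"|"high_only"|"low_only",
#'   compartment = "epithelium"|"stroma")`.
#' @param noise_sd_log SD of multiplicative log-normal spot noise
#'   (default 0.15).
#' @param biological_sd_log SD of the per-case log-abundance variation the
#'   copula drives (default 0.5).
#' @param ssdna_loading_range range of the per-case-x-compartment loading
#'   factor (default 0.7 to 1.4).
#' @param negative_control_mean_sd mean and SD of negative-control spot
#'   intensities (default 2, 0.5 scanner units, against endpoint signals of
#'   order 500).
#' @param ihc_pair_distribution data frame of paired
#'   `epithelium_score`/`stroma_score` rows, one per case, whose ratio
#'   classification must yield exactly the stated group sizes.
#' @param qc_fail_cases case ids (of the generated `case_01`, ... sequence)
#'   whose endpoint spots are generated at the negative-control floor.
#' @param seed integer RNG seed; all generation flows from it.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_cases_high = 10L, n_cases_low = 9L,
                        n_endpoints = 30L, dilution_steps = 4L,
                        correlation_blocks = list(),
                        noise_sd_log = 0.15, biological_sd_log = 0.5,
                        ssdna_loading_range = c(0.7, 1.4),
                        negative_control_mean_sd = c(2, 0.5),
                        ihc_pair_distribution = NULL,
                        qc_fail_cases = character(0),
                        seed = 1L) {
  stopifnot(n_cases_high >= 1L, n_cases_low >= 1L, n_endpoints >= 2L,
            dilution_steps >= 2L, noise_sd_log > 0, biological_sd_log > 0,
            length(ssdna_loading_range) == 2L, all(ssdna_loading_range > 0),
            ssdna_loading_range[1] <= ssdna_loading_range[2])
  for (b in correlation_blocks) {
    stopifnot(all(c("endpoints", "rho", "scope", "compartment") %in% names(b)))
    if (!b$scope %in% c("shared", "high_only", "low_only")) {
      stop("unknown block scope: ", b$scope, call. = FALSE)
    }
    if (!b$compartment %in% c("epithelium", "stroma")) {
      stop("unknown block compartment: ", b$compartment, call. = FALSE)
    }
    if (b$rho <= 0 || b$rho >= 1) {
      stop("block target rho must be in (0, 1)", call. = FALSE)
    }
    if (any(b$endpoints < 1 | b$endpoints > n_endpoints)) {
      stop("block endpoints outside the panel", call. = FALSE)
    }
  }
  spec <- list(
    n_cases_high = as.integer(n_cases_high),
    n_cases_low = as.integer(n_cases_low),
    n_endpoints = as.integer(n_endpoints),
    dilution_steps = as.integer(dilution_steps),
    correlation_blocks = correlation_blocks,
    noise_sd_log = noise_sd_log,
    biological_sd_log = biological_sd_log,
    ssdna_loading_range = ssdna_loading_range,
    negative_control_mean_sd = negative_control_mean_sd,
    ihc_pair_distribution = ihc_pair_distribution,
    qc_fail_cases = qc_fail_cases,
    seed = as.integer(seed)
  )
  class(spec) <- "cohort_spec"
  # fail early on an inconsistent correlation structure
  for (g in c("high", "low")) {
    for (comp in c("epithelium", "stroma")) {
      group_sigma(spec, g, comp)
    }
  }
  spec
}

# Spearman target -> latent Pearson correlation of the Gaussian copula
latent_rho <- function(rho_spearman) 2 * sin(pi * rho_spearman / 6)

# latent correlation matrix for one group x compartment; validates
# disjointness of the applicable blocks and positive definiteness
group_sigma <- function(spec, group, compartment) {
  p <- spec$n_endpoints
  sigma <- diag(p)
  used <- integer(0)
  scopes <- c("shared", paste0(group, "_only"))
  for (b in spec$correlation_blocks) {
    if (!b$scope %in% scopes || b$compartment != compartment) next
    idx <- as.integer(b$endpoints)
    if (any(idx %in% used)) {
      stop("correlation blocks overlap for the ", group, " group in the ",
           compartment, " compartment", call. = FALSE)
    }
    used <- c(used, idx)
    sigma[idx, idx] <- latent_rho(b$rho)
    diag(sigma) <- 1
  }
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    stop("implied correlation matrix is not positive definite ",
         "(blocks overlap or rho too high)", call. = FALSE)
  }
  list(sigma = sigma, chol = ch)
}

#' Draw one group's latent endpoint matrix
#'
#' Samples `n_cases` rows from the Gaussian copula latent scale with the
#' given planted blocks (as in [cohort_spec()], ignoring scope/compartment).
#' Useful for fast simulation studies of the correlation-network stage
#' alone: Spearman correlations are invariant under the monotone map to
#' intensities, so network behaviour on latents equals behaviour on the
#' full synthetic intensities.
#'
#' @param n_cases rows to draw.
#' @param n_endpoints panel size.
#' @param blocks list of `list(endpoints = <indices>, rho = <target>)`.
#' @param seed RNG seed.
#' @return numeric matrix `n_cases` x `n_endpoints` with endpoint column
#'   names.
#' @export
simulate_endpoint_matrix <- function(n_cases, n_endpoints, blocks = list(),
                                     seed = 1L) {
  sigma <- diag(n_endpoints)
  for (b in blocks) {
    idx <- as.integer(b$endpoints)
    sigma[idx, idx] <- latent_rho(b$rho)
    diag(sigma) <- 1
  }
  ch <- tryCatch(chol(sigma), error = function(e) {
    stop("implied correlation matrix is not positive definite", call. = FALSE)
  })
  m <- with_local_seed(seed, {
    matrix(rnorm(n_cases * n_endpoints), n_cases, n_endpoints) %*% ch
  })
  colnames(m) <- endpoint_names(n_endpoints)
  m
}

endpoint_names <- function(p) sprintf("EP%02d", seq_len(p))

#' Generate a full synthetic cohort
#'
#' Produces everything the pipeline consumes, deterministically for a fixed
#' seed: a long-format spot table (endpoint spots in 2-fold dilution series
#' with multiplicative log-normal noise, flat ssDNA loading spots, and
#' negative-control rows), an IHC score table, and a ground-truth ledger of
#' every planted pair. Per case and compartment, latent abundances come from
#' a Gaussian copula whose correlation matrix embeds the blocks for that
#' case's ratio group; latents map to log-normal intensities scaled by a
#' per-case loading factor. Cases in `qc_fail_cases` get endpoint spots
#' drawn from the negative-control distribution, so exactly those cases
#' fail the downstream QC screen.
#'
#' @param spec a [cohort_spec()].
#' @return list with `spots`, `ihc`, `truth` (data frames) and `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n_cases <- spec$n_cases_high + spec$n_cases_low
  ihc <- spec$ihc_pair_distribution
  if (is.null(ihc)) {
    # degenerate default: saturated high pairs then flat low pairs
    ihc <- data.frame(
      epithelium_score = c(rep(3L, spec$n_cases_high), rep(2L, spec$n_cases_low)),
      stroma_score = c(rep(0L, spec$n_cases_high), rep(2L, spec$n_cases_low))
    )
  }
  if (nrow(ihc) != n_cases) {
    stop("ihc_pair_distribution must have one row per case", call. = FALSE)
  }
  case_ids <- sprintf("case_%02d", seq_len(n_cases))
  ihc <- data.frame(case_id = case_ids,
                    epithelium_score = as.integer(ihc$epithelium_score),
                    stroma_score = as.integer(ihc$stroma_score),
                    stringsAsFactors = FALSE)
  group <- expression_ratio_class(ihc$epithelium_score, ihc$stroma_score)
  if (sum(group == "high") != spec$n_cases_high ||
      sum(group == "low") != spec$n_cases_low) {
    stop("ihc_pair_distribution classifies into ",
         sum(group == "high"), " high / ", sum(group == "low"),
         " low, not the specified group sizes", call. = FALSE)
  }
  bad_qc <- setdiff(spec$qc_fail_cases, case_ids)
  if (length(bad_qc) > 0L) {
    stop("unknown qc_fail_cases: ", paste(bad_qc, collapse = ", "),
         call. = FALSE)
  }

  p <- spec$n_endpoints
  eps <- endpoint_names(p)
  steps <- seq_len(spec$dilution_steps) - 1L
  nc_mean <- spec$negative_control_mean_sd[1]
  nc_sd <- spec$negative_control_mean_sd[2]

  out <- with_local_seed(spec$seed, {
    log_mu <- rnorm(p, mean = log(500), sd = 0.5)  # per-endpoint base level
    spot_rows <- list()
    for (comp in c("epithelium", "stroma")) {
      # latent abundances per group share that group's planted correlation
      log_abund <- matrix(NA_real_, n_cases, p)
      for (g in c("high", "low")) {
        sel <- which(group == g)
        ch <- group_sigma(spec, g, comp)$chol
        z <- matrix(rnorm(length(sel) * p), length(sel), p) %*% ch
        log_abund[sel, ] <- sweep(spec$biological_sd_log * z, 2L, log_mu, "+")
      }
      loading <- runif(n_cases, spec$ssdna_loading_range[1],
                       spec$ssdna_loading_range[2])
      for (i in seq_len(n_cases)) {
        at_floor <- case_ids[i] %in% spec$qc_fail_cases
        n_spot <- p * length(steps)
        d <- rep(2^steps, times = p)
        ep_rep <- rep(eps, each = length(steps))
        raw <- if (at_floor) {
          pmax(rnorm(n_spot, nc_mean, nc_sd), 0.01)
        } else {
          true <- exp(rep(log_abund[i, ], each = length(steps)))
          loading[i] * true / d * exp(rnorm(n_spot, 0, spec$noise_sd_log))
        }
        ss_raw <- loading[i] * 100 * exp(rnorm(length(steps), 0,
                                               spec$noise_sd_log))
        nc_raw <- pmax(rnorm(length(steps), nc_mean, nc_sd), 0.01)
        spot_rows[[length(spot_rows) + 1L]] <- data.frame(
          case_id = case_ids[i],
          compartment = comp,
          stain = c(ep_rep, rep("ssDNA", length(steps)),
                    rep("negative_control", length(steps))),
          dilution_step = c(rep(steps, times = p), steps, steps),
          replicate = 1L,
          raw_intensity = c(raw, ss_raw, nc_raw),
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, spot_rows)
  })

  truth <- do.call(rbind, lapply(spec$correlation_blocks, function(b) {
    prs <- utils::combn(sort(as.integer(b$endpoints)), 2L)
    data.frame(endpoint_a = eps[prs[1L, ]], endpoint_b = eps[prs[2L, ]],
               scope = b$scope, compartment = b$compartment,
               target_rho = b$rho, stringsAsFactors = FALSE)
  }))
  if (is.null(truth)) {
    truth <- data.frame(endpoint_a = character(0), endpoint_b = character(0),
                        scope = character(0), compartment = character(0),
                        target_rho = numeric(0))
  }

  list(spots = out, ihc = ihc, truth = truth, spec = spec)
}

#' The default study-design cohort specification
#'
#' A 19-case cohort mirroring the study design the package emulates:
#' 10 high- and 9 low-ratio cases with the reference IHC score distribution
#' ([trim28_ihc_cohort()]), a 30-endpoint panel printed as 4-point 2-fold
#' dilution series, one high-ratio case generated at the negative-control
#' floor (so QC excludes it and 9 + 9 cases enter the network stage), and
#' per compartment one shared correlation block (5 endpoints, rho 0.8) plus
#' one block exclusive to each ratio group (5 endpoints each, rho 0.9).
#'
#' @param seed integer RNG seed.
#' @return a [cohort_spec()].
#' @export
default_cohort_spec <- function(seed = 1L) {
  blocks <- list()
  for (comp in c("epithelium", "stroma")) {
    blocks <- c(blocks, list(
      list(endpoints = 1:5, rho = 0.8, scope = "shared", compartment = comp),
      list(endpoints = 6:10, rho = 0.9, scope = "high_only", compartment = comp),
      list(endpoints = 11:15, rho = 0.9, scope = "low_only", compartment = comp)
    ))
  }
  ihc <- trim28_ihc_cohort()
  cohort_spec(
    n_cases_high = 10L, n_cases_low = 9L, n_endpoints = 30L,
    dilution_steps = 4L, correlation_blocks = blocks,
    ihc_pair_distribution = ihc[, c("epithelium_score", "stroma_score")],
    qc_fail_cases = "case_02",  # a (3,1) high-ratio case -> 9 + 9 after QC
    seed = seed
  )
}
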