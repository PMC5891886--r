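#' Compare one endpoint between two strata
#'
#' Independent-samples t test, Welch (unequal variances) by default at
#' n around 9-10 per stratum; `var_equal = TRUE` gives the pooled-variance
#' convention. Two-sided p, flagged significant at `alpha`.
#'
#' @param values_a,values_b numeric samples (>= 2 values each).
#' @param alpha significance level (default 0.05).
#' @param var_equal pooled-variance t test instead of Welch.
#' @return one-row data frame: `mean_a`, `mean_b`, `t_statistic`, `df`,
#'   `p_value`, `significant`. Samples that cannot be tested (undersized or
#'   zero variance in both) yield NA statistics and `significant = NA`.
#' @export
compare_endpoint <- function(values_a, values_b, alpha = 0.05,
                             var_equal = FALSE) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  untestable <- length(values_a) < 2L || length(values_b) < 2L ||
    (var(values_a) == 0 && var(values_b) == 0)
  if (untestable) {
    return(data.frame(
      mean_a = if (length(values_a)) mean(values_a) else NA_real_,
      mean_b = if (length(values_b)) mean(values_b) else NA_real_,
      t_statistic = NA_real_, df = NA_real_, p_value = NA_real_,
      significant = NA
    ))
  }
  ht <- t.test(values_a, values_b, var.equal = var_equal)
  data.frame(
    mean_a = mean(values_a),
    mean_b = mean(values_b),
    t_statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    significant = ht$p.value < alpha
  )
}

#' Compare every endpoint across the study's two contrast families
#'
#' Contrast `"compartment_within_group"` tests epithelium vs stroma
#' separately inside each ratio group (the within-group compartment
#' comparison); `"group_within_compartment"` tests high vs low ratio cases
#' separately inside each compartment. One row per endpoint per stratum
#' pair. Both use [compare_endpoint()].
#'
#' @param values wide data frame from [quantify_rppa()]`$values` (columns
#'   `case_id`, `compartment`, then endpoints).
#' @param groups data frame with `case_id` and `ratio_group` (`"high"` /
#'   `"low"`), e.g. [classify_cohort()]`$cases`.
#' @param contrast one or both of `"compartment_within_group"`,
#'   `"group_within_compartment"`.
#' @param alpha,var_equal passed to [compare_endpoint()].
#' @return data frame with `endpoint`, `stratum_a`, `stratum_b` and the
#'   test columns; zero rows for an empty `contrast`.
#' @export
compare_all <- function(values, groups,
                        contrast = c("compartment_within_group",
                                     "group_within_compartment"),
                        alpha = 0.05, var_equal = FALSE) {
  if (length(contrast) == 0L) {
    return(data.frame(endpoint = character(0), stratum_a = character(0),
                      stratum_b = character(0), mean_a = numeric(0),
                      mean_b = numeric(0), t_statistic = numeric(0),
                      df = numeric(0), p_value = numeric(0),
                      significant = logical(0)))
  }
  contrast <- match.arg(contrast, several.ok = TRUE)
  if (!all(values$case_id %in% groups$case_id)) {
    stop("cases in the reduced table lack a ratio-group label", call. = FALSE)
  }
  rg <- groups$ratio_group[match(values$case_id, groups$case_id)]
  if (any(!rg %in% c("high", "low"))) {
    stop("unknown stratum label: ",
         paste(unique(rg[!rg %in% c("high", "low")]), collapse = ", "),
         call. = FALSE)
  }
  endpoints <- setdiff(names(values), c("case_id", "compartment"))
  rows <- list()
  one <- function(ep, sel_a, sel_b, lab_a, lab_b) {
    res <- compare_endpoint(values[[ep]][sel_a], values[[ep]][sel_b],
                            alpha = alpha, var_equal = var_equal)
    cbind(data.frame(endpoint = ep, stratum_a = lab_a, stratum_b = lab_b,
                     stringsAsFactors = FALSE), res)
  }
  if ("compartment_within_group" %in% contrast) {
    for (g in c("high", "low")) {
      for (ep in endpoints) {
        rows[[length(rows) + 1L]] <- one(
          ep,
          rg == g & values$compartment == "epithelium",
          rg == g & values$compartment == "stroma",
          paste0(g, "_ratio.epithelium"), paste0(g, "_ratio.stroma")
        )
      }
    }
  }
  if ("group_within_compartment" %in% contrast) {
    for (comp in c("epithelium", "stroma")) {
      for (ep in endpoints) {
        rows[[length(rows) + 1L]] <- one(
          ep,
          rg == "high" & values$compartment == comp,
          rg == "low" & values$compartment == comp,
          paste0("high_ratio.", comp), paste0("low_ratio.", comp)
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Box-plot summary statistics for one sample
#'
#' Median, mean, 25th/75th percentiles (linear interpolation between order
#' statistics, `stats::quantile` type 7) and the minimum and maximum - the
#' quantities a box-plot with a mean diamond displays.
#'
#' @param values non-empty numeric vector.
#' @return one-row data frame: `median`, `mean`, `q25`, `q75`, `minimum`,
#'   `maximum`, `n`.
#' @export
boxplot_summary <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("empty sample", call. = FALSE)
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  data.frame(median = q[2L], mean = mean(values), q25 = q[1L], q75 = q[3L],
             minimum = min(values), maximum = max(values),
             n = length(values))
}

#' Box-plot summaries per endpoint and stratum
#'
#' @inheritParams compare_all
#' @return data frame: `endpoint`, `stratum`, summary columns.
#' @export
boxplot_summaries <- function(values, groups) {
  rg <- groups$ratio_group[match(values$case_id, groups$case_id)]
  endpoints <- setdiff(names(values), c("case_id", "compartment"))
  strata <- paste0(rg, "_ratio.", values$compartment)
  rows <- list()
  for (st in sort(unique(strata))) {
    for (ep in endpoints) {
      v <- values[[ep]][strata == st]
      v <- v[is.finite(v)]
      if (length(v) == 0L) next
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(endpoint = ep, stratum = st, stringsAsFactors = FALSE),
        boxplot_summary(v)
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
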