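#' @importFrom stats coef lm median pt qt quantile rnorm runif sd t.test var
NULL

RESERVED_STAINS <- c("ssDNA", "negative_control", "total_protein")
SPOT_COLUMNS <- c("case_id", "compartment", "stain", "dilution_step",
                  "replicate", "raw_intensity")

#' Normalize a spot intensity to its matching ssDNA intensity
#'
#' RPPA spot intensities scale with the amount of cellular material deposited;
#' dividing each antibody spot by the ssDNA stain intensity of the
#' corresponding spot corrects for loading / cell number. Vectorized.
#'
#' @param spot_intensity nonnegative spot intensity (scanner units).
#' @param ssdna_intensity positive ssDNA intensity for the corresponding spot.
#' @param label optional spot label used in error messages.
#' @return `spot_intensity / ssdna_intensity`.
#' @export
normalize_to_ssdna <- function(spot_intensity, ssdna_intensity, label = NULL) {
  bad <- !is.finite(ssdna_intensity) | ssdna_intensity <= 0
  if (any(bad)) {
    where <- if (is.null(label)) which(bad)[1L] else label[bad][1L]
    stop("non-positive ssDNA normalizer for spot ", where, call. = FALSE)
  }
  if (any(spot_intensity < 0, na.rm = TRUE)) {
    stop("negative spot intensity", call. = FALSE)
  }
  spot_intensity / ssdna_intensity
}

#' Reduce a normalized dilution series to one abundance value
#'
#' Each lysate is printed as a 2-fold dilution curve (undiluted, 1:2, 1:4,
#' 1:8). After ssDNA normalization the series is collapsed to a single value:
#' the geometric mean of `dilution_factor * normalized_intensity` over points
#' above the detection floor. On an ideal 2-fold series every product equals
#' the undiluted value, so the reduction returns it exactly. A linearity flag
#' records whether the fitted slope of `log2(intensity)` against
#' `-log2(dilution_factor)` is within `slope_tolerance` of 1 (a flat,
#' saturated series has slope near 0 and is flagged).
#'
#' @param dilution_factor positive dilution factors (1, 2, 4, 8 for a 2-fold
#'   4-point curve); must be distinct.
#' @param intensity nonnegative normalized intensities, same length.
#' @param slope_tolerance maximum absolute deviation of the log-log slope
#'   from 1 still considered linear (default 0.3).
#' @param detection_floor intensities at or below this value are excluded
#'   from the reduction (default 0).
#' @return list with `value` (NA if fewer than 2 usable points),
#'   `linearity_ok`, `n_points_used`.
#' @export
reduce_dilution_series <- function(dilution_factor, intensity,
                                   slope_tolerance = 0.3,
                                   detection_floor = 0) {
  stopifnot(length(dilution_factor) == length(intensity))
  if (any(dilution_factor <= 0)) stop("dilution factors must be positive", call. = FALSE)
  if (anyDuplicated(dilution_factor)) stop("dilution factors must be distinct", call. = FALSE)
  usable <- is.finite(intensity) & intensity > detection_floor & intensity > 0
  n <- sum(usable)
  if (n < 2L) {
    return(list(value = NA_real_, linearity_ok = NA, n_points_used = n))
  }
  d <- dilution_factor[usable]
  y <- intensity[usable]
  value <- exp(mean(log(d * y)))
  slope <- unname(coef(lm(log2(y) ~ I(-log2(d))))[2L])
  list(value = value,
       linearity_ok = abs(slope - 1) <= slope_tolerance,
       n_points_used = n)
}

#' Screen a case against the negative-control slide
#'
#' A case passes quality control when its spot intensities are significantly
#' above the no-primary-antibody control: one-sided Welch t test of
#' case > control. Cases that fail are excluded from all downstream network
#' analysis.
#'
#' @param case_values spot intensities for the case (one per endpoint).
#' @param negative_control_values control-slide spot intensities.
#' @param qc_alpha significance level (default 0.05).
#' @return list with `test_statistic`, `p_value`, `passed`.
#' @export
qc_case_vs_negative_control <- function(case_values, negative_control_values,
                                        qc_alpha = 0.05) {
  if (length(case_values) < 2L || length(negative_control_values) < 2L) {
    stop("each sample needs at least 2 values", call. = FALSE)
  }
  degenerate <- var(case_values) == 0 && var(negative_control_values) == 0
  if (degenerate) {
    # identical-constant inputs carry no evidence above control
    return(list(test_statistic = NA_real_, p_value = 1, passed = FALSE))
  }
  ht <- t.test(case_values, negative_control_values, alternative = "greater")
  passed <- ht$p.value < qc_alpha &&
    mean(case_values) > mean(negative_control_values)
  list(test_statistic = unname(ht$statistic),
       p_value = ht$p.value,
       passed = passed)
}

#' Read a long-format RPPA spot table
#'
#' Expects columns `case_id`, `compartment`, `stain`, `dilution_step`,
#' `replicate`, `raw_intensity`. `compartment` is `epithelium` or `stroma`;
#' `stain` is an endpoint name or one of the reserved stains `ssDNA`,
#' `negative_control`, `total_protein`; `dilution_step` is 0..3 meaning
#' dilution factor `2^step`. Delimiter is inferred from the extension
#' (`.tsv`/`.txt` = tab, otherwise comma).
#'
#' @param path file path.
#' @return validated data frame of spot records.
#' @export
read_spot_table <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  validate_spot_table(df, where = path)
}

validate_spot_table <- function(df, where = "spot table") {
  missing_cols <- setdiff(SPOT_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing column(s) in ", where, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!is.numeric(df$raw_intensity)) {
    stop("non-numeric raw_intensity in ", where, call. = FALSE)
  }
  bad <- which(!is.finite(df$raw_intensity) | df$raw_intensity < 0)
  if (length(bad) > 0L) {
    stop("invalid raw_intensity (negative or missing) in ", where,
         " at row ", bad[1L], call. = FALSE)
  }
  bad_step <- which(!df$dilution_step %in% 0:3)
  if (length(bad_step) > 0L) {
    stop("dilution_step outside 0..3 in ", where, " at row ", bad_step[1L],
         call. = FALSE)
  }
  bad_comp <- which(!df$compartment %in% c("epithelium", "stroma"))
  if (length(bad_comp) > 0L) {
    stop("unknown compartment in ", where, " at row ", bad_comp[1L],
         call. = FALSE)
  }
  key <- paste(df$case_id, df$compartment, df$stain, df$dilution_step,
               df$replicate)
  dup <- which(duplicated(key))
  if (length(dup) > 0L) {
    stop("duplicate spot record in ", where, " at row ", dup[1L],
         call. = FALSE)
  }
  df
}

#' @rdname read_spot_table
#' @param spots validated spot-record data frame.
#' @export
write_spot_table <- function(spots, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  utils::write.table(spots, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Quantify an RPPA spot table into per-endpoint abundance values
#'
#' Full quantification pass: replicate spots are averaged (arithmetic mean),
#' every endpoint spot is divided by the ssDNA intensity at the same dilution
#' step (nearest step with a warning when absent), each case x compartment x
#' endpoint dilution curve is reduced with [reduce_dilution_series()] using a
#' detection floor of `2 * median(negative-control intensity)`, and each
#' case x compartment is screened against its negative-control spots with
#' [qc_case_vs_negative_control()]. A case is excluded entirely when either
#' of its compartments fails QC.
#'
#' @param spots long-format spot data frame (see [read_spot_table()]).
#' @param qc_alpha QC significance level (default 0.05).
#' @param slope_tolerance linearity tolerance passed to the reduction.
#' @return list with
#'   \describe{
#'     \item{values}{wide data frame, one row per case x compartment
#'       (`case_id`, `compartment`, then one column per endpoint).}
#'     \item{flags}{long data frame of `linearity_ok` / `n_points_used` per
#'       reduced value.}
#'     \item{qc}{per case x compartment QC report.}
#'     \item{excluded_cases}{case ids failing QC in any compartment.}
#'     \item{detection_floor}{the floor applied.}
#'   }
#' @export
quantify_rppa <- function(spots, qc_alpha = 0.05, slope_tolerance = 0.3) {
  spots <- validate_spot_table(spots)
  # replicate averaging
  agg <- stats::aggregate(
    raw_intensity ~ case_id + compartment + stain + dilution_step,
    data = spots, FUN = mean
  )
  is_nc <- agg$stain == "negative_control"
  if (!any(is_nc)) stop("no negative_control rows in spot table", call. = FALSE)
  if (!any(agg$stain == "ssDNA")) stop("no ssDNA rows in spot table", call. = FALSE)
  floor_value <- 2 * median(agg$raw_intensity[is_nc])

  endpoints <- sort(setdiff(unique(agg$stain), RESERVED_STAINS))
  units <- unique(agg[agg$stain %in% endpoints, c("case_id", "compartment")])
  units <- units[order(units$case_id, units$compartment), , drop = FALSE]

  ssdna <- agg[agg$stain == "ssDNA", ]
  flags <- vector("list", nrow(units))
  values <- matrix(NA_real_, nrow(units), length(endpoints),
                   dimnames = list(NULL, endpoints))
  for (i in seq_len(nrow(units))) {
    cid <- units$case_id[i]; comp <- units$compartment[i]
    ss <- ssdna[ssdna$case_id == cid & ssdna$compartment == comp, ]
    if (nrow(ss) == 0L) {
      stop("no ssDNA spots for ", cid, " ", comp, call. = FALSE)
    }
    sub <- agg[agg$case_id == cid & agg$compartment == comp &
                 agg$stain %in% endpoints, ]
    if (!all(unique(sub$dilution_step) %in% ss$dilution_step)) {
      warning("ssDNA spot missing at some dilution steps for ", cid, " ",
              comp, "; nearest step used", call. = FALSE)
    }
    fl <- lapply(endpoints, function(ep) {
      pts <- sub[sub$stain == ep, ]
      if (nrow(pts) == 0L) {
        return(data.frame(endpoint = ep, value = NA_real_,
                          linearity_ok = NA, n_points_used = 0L))
      }
      ss_idx <- match(pts$dilution_step, ss$dilution_step)
      if (anyNA(ss_idx)) {
        # fall back to the nearest available ssDNA dilution step
        ss_idx <- vapply(pts$dilution_step, function(k) {
          which.min(abs(ss$dilution_step - k))
        }, integer(1))
      }
      norm <- normalize_to_ssdna(pts$raw_intensity,
                                 ss$raw_intensity[ss_idx],
                                 label = paste(cid, comp, ep, pts$dilution_step))
      norm_floor <- floor_value / ss$raw_intensity[ss_idx]
      usable <- norm > norm_floor
      red <- reduce_dilution_series(2^pts$dilution_step[usable],
                                    norm[usable],
                                    slope_tolerance = slope_tolerance)
      data.frame(endpoint = ep, value = red$value,
                 linearity_ok = red$linearity_ok,
                 n_points_used = red$n_points_used)
    })
    fl <- do.call(rbind, fl)
    fl$case_id <- cid; fl$compartment <- comp
    flags[[i]] <- fl
    values[i, ] <- fl$value[match(endpoints, fl$endpoint)]
  }
  flags <- do.call(rbind, flags)

  # QC: per-endpoint mean raw intensity vs this unit's negative-control spots
  qc <- lapply(seq_len(nrow(units)), function(i) {
    cid <- units$case_id[i]; comp <- units$compartment[i]
    sub <- agg[agg$case_id == cid & agg$compartment == comp, ]
    case_vals <- tapply(sub$raw_intensity[sub$stain %in% endpoints],
                        sub$stain[sub$stain %in% endpoints], mean)
    nc_vals <- sub$raw_intensity[sub$stain == "negative_control"]
    rep <- qc_case_vs_negative_control(as.numeric(case_vals), nc_vals,
                                       qc_alpha = qc_alpha)
    data.frame(case_id = cid, compartment = comp,
               test_statistic = rep$test_statistic,
               p_value = rep$p_value, passed = rep$passed)
  })
  qc <- do.call(rbind, qc)
  excluded <- sort(unique(qc$case_id[!qc$passed]))

  list(
    values = cbind(units, as.data.frame(values), row.names = NULL),
    flags = flags[, c("case_id", "compartment", "endpoint", "value",
                      "linearity_ok", "n_points_used")],
    qc = qc,
    excluded_cases = excluded,
    detection_floor = floor_value
  )
}

#' Read / write the reduced wide abundance table
#'
#' @param reduced wide data frame as produced by [quantify_rppa()]`$values`.
#' @param path file path (CSV).
#' @export
write_reduced_table <- function(reduced, path) {
  utils::write.csv(reduced, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reduced_table
#' @export
read_reduced_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("case_id", "compartment") %in% names(df))) {
    stop("missing case_id/compartment columns in ", path, call. = FALSE)
  }
  df
}
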