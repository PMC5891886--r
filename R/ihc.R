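#' Ordinal IHC score scale
#'
#' Nuclear staining intensity is scored on the conventional four-level ordinal
#' scale: 0 = absent, 1 = weak, 2 = moderate, 3 = strong. Scores are assessed
#' separately for the epithelial and stromal compartments of each case.
#'
#' @name ihc-scale
#' @keywords internal
NULL

assert_ihc_score <- function(score, what = "score") {
  if (length(score) == 0L) {
    stop(what, " is empty", call. = FALSE)
  }
  bad <- !is.numeric(score) | is.na(score) | score != as.integer(score) |
    score < 0 | score > 3
  if (any(bad)) {
    stop(
      "invalid ", what, " (must be an integer in 0..3): ",
      paste(utils::head(score[bad], 5L), collapse = ", "),
      call. = FALSE
    )
  }
  as.integer(score)
}

#' Classify an epithelium:stroma expression ratio from paired IHC scores
#'
#' A case is assigned to the *high* ratio group when the epithelial score
#' exceeds the stromal score by at least 2 ordinal units; a difference of 1 or
#' 0 units puts it in the *low* group. The difference is signed: a case whose
#' stromal score exceeds its epithelial score is always *low*.
#'
#' @param epithelium_score,stroma_score integer ordinal scores in `0:3`
#'   (vectors are recycled pairwise in the usual way; lengths must match).
#' @return character vector of `"high"` / `"low"`, one element per pair.
#' @examples
#' expression_ratio_class(3, 1) # "high"
#' expression_ratio_class(2, 1) # "low"
#' expression_ratio_class(0, 3) # "low" (signed difference)
#' @export
expression_ratio_class <- function(epithelium_score, stroma_score) {
  e <- assert_ihc_score(epithelium_score, "epithelium_score")
  s <- assert_ihc_score(stroma_score, "stroma_score")
  if (length(e) != length(s)) {
    stop("epithelium and stroma score vectors differ in length", call. = FALSE)
  }
  ifelse(e - s >= 2L, "high", "low")
}

#' Classify a cohort of paired IHC scores into ratio groups
#'
#' Applies [expression_ratio_class()] per case and tabulates group sizes.
#'
#' @param cases data frame with columns `case_id`, `epithelium_score`,
#'   `stroma_score`; case ids must be unique.
#' @return list with `cases` (the input plus a `ratio_group` column) and
#'   `counts` (named integer vector with elements `high` and `low`).
#' @export
classify_cohort <- function(cases) {
  required <- c("case_id", "epithelium_score", "stroma_score")
  missing_cols <- setdiff(required, names(cases))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(cases) == 0L) stop("empty cohort", call. = FALSE)
  if (anyDuplicated(cases$case_id)) {
    stop("duplicate case_id: ",
         paste(unique(cases$case_id[duplicated(cases$case_id)]), collapse = ", "),
         call. = FALSE)
  }
  cases$ratio_group <- expression_ratio_class(cases$epithelium_score,
                                              cases$stroma_score)
  counts <- c(high = sum(cases$ratio_group == "high"),
              low  = sum(cases$ratio_group == "low"))
  stopifnot(sum(counts) == nrow(cases))
  list(cases = cases, counts = counts)
}

#' Reference 19-case IHC score cohort
#'
#' The packaged 19-case colorectal cohort of paired epithelial/stromal TRIM28
#' scores. The high-ratio pairs are as enumerated in the source results
#' ((3,0) x1, (3,1) x6, (2,0) x3); the nine low-ratio pairs are completed
#' uniquely from the published score marginals (epithelium: 8 strong,
#' 9 moderate, 2 weak; stroma: 2 moderate, 12 weak, 5 absent) together with
#' the two described low-group cases (one strong-epithelium case, one
#' absent-stroma case). It is a faithful reconstruction of the published
#' distribution, not the authors' per-case pairing, and classifies 10 high /
#' 9 low.
#'
#' @return data frame with columns `case_id`, `epithelium_score`,
#'   `stroma_score` (19 rows).
#' @export
trim28_ihc_cohort <- function() {
  pairs <- rbind(
    matrix(c(3L, 0L), 1, 2),                     # high: strong epi, absent stroma
    matrix(rep(c(3L, 1L), 6), ncol = 2, byrow = TRUE),
    matrix(rep(c(2L, 0L), 3), ncol = 2, byrow = TRUE),
    matrix(c(3L, 2L), 1, 2),                     # low: the strong-epithelium case
    matrix(c(2L, 2L), 1, 2),
    matrix(rep(c(2L, 1L), 5), ncol = 2, byrow = TRUE),
    matrix(c(1L, 1L), 1, 2),
    matrix(c(1L, 0L), 1, 2)                      # low: the absent-stroma case
  )
  data.frame(
    case_id = sprintf("case_%02d", seq_len(nrow(pairs))),
    epithelium_score = pairs[, 1],
    stroma_score = pairs[, 2],
    stringsAsFactors = FALSE
  )
}

#' Read / write IHC score tables
#'
#' Plain CSV with columns `case_id`, `epithelium_score`, `stroma_score`
#' (plus `ratio_group` on write after classification).
#'
#' @param path file path.
#' @export
read_ihc_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("case_id", "epithelium_score", "stroma_score")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  assert_ihc_score(df$epithelium_score, "epithelium_score")
  assert_ihc_score(df$stroma_score, "stroma_score")
  df
}

#' @rdname read_ihc_table
#' @param cases data frame of scores (optionally with `ratio_group`).
#' @export
write_ihc_table <- function(cases, path) {
  utils::write.csv(cases, path, row.names = FALSE)
  invisible(path)
}
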