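test_that("ssDNA normalization is a plain quotient and scale invariant", {
  expect_identical(normalize_to_ssdna(100, 50), 2)
  expect_identical(normalize_to_ssdna(0, 50), 0)
  set.seed(71)
  for (i in 1:20) {
    a <- runif(1, 0, 100); b <- runif(1, 0.1, 50); c <- runif(1, 0.01, 1000)
    expect_equal(normalize_to_ssdna(c * a, c * b), normalize_to_ssdna(a, b))
  }
  expect_error(normalize_to_ssdna(10, 0), "non-positive ssDNA")
  expect_error(normalize_to_ssdna(10, -1), "non-positive ssDNA")
  expect_error(normalize_to_ssdna(-1, 1), "negative spot")
})

test_that("dilution reduction recovers an ideal 2-fold series exactly", {
  red <- reduce_dilution_series(c(1, 2, 4, 8), c(8, 4, 2, 1))
  expect_equal(red$value, 8)
  expect_true(red$linearity_ok)
  expect_identical(red$n_points_used, 4L)
})

test_that("a flat (saturated) series is flagged non-linear but still reduced", {
  red <- reduce_dilution_series(c(1, 2, 4, 8), rep(5, 4))
  expect_false(red$linearity_ok)
  expect_identical(red$n_points_used, 4L)
  expect_true(is.finite(red$value))
})

test_that("fewer than two usable points yields a missing value", {
  red <- reduce_dilution_series(c(1, 2, 4, 8), c(6, 0, 0, 0))
  expect_true(is.na(red$value))
  expect_identical(red$n_points_used, 1L)
  red2 <- reduce_dilution_series(c(1, 2, 4, 8), c(6, 5, 0.5, 0.4),
                                 detection_floor = 1)
  expect_identical(red2$n_points_used, 2L)
  expect_error(reduce_dilution_series(c(1, 1, 4, 8), c(8, 4, 2, 1)),
               "distinct")
  expect_error(reduce_dilution_series(c(-1, 2), c(1, 1)), "positive")
})

test_that("reduction of a noisy series concentrates around the true level", {
  # intensity = A / d * exp(eps), eps ~ N(0, 0.05^2), A = 8
  set.seed(2026)
  hits <- replicate(1000, {
    d <- c(1, 2, 4, 8)
    y <- 8 / d * exp(rnorm(4, 0, 0.05))
    v <- reduce_dilution_series(d, y)$value
    v >= 7.2 && v <= 8.8
  })
  expect_gte(mean(hits), 0.95)
})

test_that("negative-control QC separates signal from floor", {
  set.seed(5)
  nc <- rnorm(30)
  expect_false(qc_case_vs_negative_control(nc, nc)$passed)
  sep <- qc_case_vs_negative_control(nc + 10 * sd(nc), nc)
  expect_true(sep$passed)
  # zero-variance identical inputs: convention p = 1, not an error
  deg <- qc_case_vs_negative_control(rep(2, 6), rep(2, 6))
  expect_identical(deg$p_value, 1)
  expect_false(deg$passed)
  expect_error(qc_case_vs_negative_control(1, 1:5), "at least 2")
})

test_that("QC type-I error respects its nominal level", {
  set.seed(90)
  alpha <- 0.05
  n_rep <- 2000
  passes <- replicate(n_rep, {
    qc_case_vs_negative_control(rnorm(30), rnorm(30), qc_alpha = alpha)$passed
  })
  se <- sqrt(alpha * (1 - alpha) / n_rep)
  expect_lte(mean(passes), alpha + 2 * se)
})

test_that("QC exclusion count is monotone in qc_alpha", {
  set.seed(17)
  cases <- replicate(40, rnorm(30, mean = runif(1, 0, 0.6)),
                     simplify = FALSE)
  nc <- rnorm(30)
  excluded <- function(alpha) {
    sum(!vapply(cases, function(cv)
      qc_case_vs_negative_control(cv, nc, qc_alpha = alpha)$passed, TRUE))
  }
  alphas <- c(0.001, 0.01, 0.05, 0.2)
  counts <- vapply(alphas, excluded, integer(1))
  expect_true(all(diff(counts) <= 0)) # stricter alpha excludes more
})

test_that("spot tables round-trip and malformed files are rejected by row", {
  spots <- tiny_spot_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_spot_table(spots, path)
  back <- read_spot_table(path)
  expect_equal(back, spots)
  expect_identical(nrow(read_spot_table(path)), nrow(spots))

  bad <- spots; bad$raw_intensity[3] <- -1
  write_spot_table(bad, path)
  expect_error(read_spot_table(path), "row 3")

  dup <- rbind(spots, spots[2, ])
  write_spot_table(dup, path)
  expect_error(read_spot_table(path), "duplicate spot record")

  short <- withr::local_tempfile(lines = "a,b\n1,2", fileext = ".csv")
  expect_error(read_spot_table(short), "missing column")
})

test_that("quantification normalizes, reduces and screens a tiny cohort", {
  # clean 2-fold curves; expected reduced value = undiluted top / ssdna
  spots <- tiny_spot_table()
  q <- quantify_rppa(spots)
  expect_identical(q$values$case_id, "c1")
  expect_equal(q$values$AKT, 4)
  expect_equal(q$values$ERK, 2)
  expect_equal(q$values$STAT3, 5)
  expect_true(all(q$flags$linearity_ok))
  expect_identical(q$qc$passed, TRUE)
  expect_identical(q$excluded_cases, character(0))
})

test_that("replicate spots are averaged before normalization", {
  spots <- tiny_spot_table()
  rep2 <- spots[spots$stain == "AKT", ]
  rep2$replicate <- 2L
  rep2$raw_intensity <- rep2$raw_intensity * 3 # mean becomes 2x the original
  q <- quantify_rppa(rbind(spots, rep2))
  expect_equal(q$values$AKT, 2 * 8 / 2)
})

test_that("quantification is invariant to rescaling a sample and its ssDNA", {
  spots <- rbind(tiny_spot_table(),
                 tiny_spot_table(case = "c2",
                                 tops = c(AKT = 12, ERK = 3, P38 = 7,
                                          JNK = 2.5, STAT3 = 9, SRC = 4)))
  q1 <- quantify_rppa(spots)
  scaled <- spots
  sel <- scaled$case_id == "c2" & scaled$stain != "negative_control"
  scaled$raw_intensity[sel] <- scaled$raw_intensity[sel] * 7.3
  q2 <- quantify_rppa(scaled)
  eps <- c("AKT", "ERK", "P38", "JNK", "STAT3", "SRC")
  expect_equal(q2$values[, eps], q1$values[, eps])
})

test_that("a missing ssDNA dilution step falls back to the nearest with a warning", {
  spots <- tiny_spot_table()
  spots <- spots[!(spots$stain == "ssDNA" & spots$dilution_step == 3), ]
  expect_warning(q <- quantify_rppa(spots), "nearest step")
  expect_true(is.finite(q$values$AKT))
})

test_that("reduced tables round-trip", {
  spots <- tiny_spot_table()
  q <- quantify_rppa(spots)
  path <- withr::local_tempfile(fileext = ".csv")
  write_reduced_table(q$values, path)
  back <- read_reduced_table(path)
  expect_equal(back$AKT, q$values$AKT)
})
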