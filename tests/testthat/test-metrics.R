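test_that("balanced error rate averages the two per-class error rates", {
  truth <- c(rep("responsive", 4), rep("progressive", 2))
  pred <- truth
  expect_equal(balanced_error_rate(truth, pred), 0)
  # 1 of 4 responsive and 1 of 2 progressive misclassified
  pred2 <- c("progressive", "responsive", "responsive", "responsive",
             "responsive", "progressive")
  expect_equal(balanced_error_rate(truth, pred2), (0.25 + 0.5) / 2)
  # single-class truth: the present class's error rate alone
  expect_equal(balanced_error_rate(rep("responsive", 3),
                                   rep("progressive", 3)), 1)
  expect_equal(balanced_error_rate("progressive", "progressive"), 0)
  expect_gbm_error(balanced_error_rate(character(0), character(0)),
                   "gbm_metric_error")
  expect_gbm_error(balanced_error_rate("responsive", "stable"),
                   "gbm_metric_error")
})

test_that("temporal weights decay linearly before the decision", {
  expect_equal(temporal_weight(0), 1)
  expect_equal(temporal_weight(11), 0.5)
  expect_equal(temporal_weight(1), 1 - 0.5 / 11)
  expect_equal(temporal_weight(c(0, 2, 22)), c(1, 1 - 1 / 11, 0))
  expect_gbm_error(temporal_weight(-1), "gbm_metric_error")
})

test_that("weighted BER normalises its weights", {
  # constant series -> that constant
  s <- ber_series(offset = c(2, 0, -3), ber = rep(0.31, 3), n = c(1, 9, 4))
  expect_equal(weighted_ber(s), 0.31)
  # all-zero series -> 0
  expect_equal(weighted_ber(ber_series(-2:2, rep(0, 5), rep(3, 5))), 0)
  # offsets without data contribute nothing
  s2 <- ber_series(c(0, -1, -2), c(0.2, NA, 0.6), c(5, 0, 5))
  w <- temporal_weight(c(0, 2))
  expect_equal(weighted_ber(s2), sum(5 * w * c(0.2, 0.6)) / sum(5 * w))
  # single-offset series collapses to its BER
  expect_equal(weighted_ber(ber_series(-4, 0.37, 7)), 0.37)
  # counts scale out
  s3 <- ber_series(c(1, 0, -5), c(0.1, 0.4, 0.9), c(2, 6, 3))
  s3x <- ber_series(c(1, 0, -5), c(0.1, 0.4, 0.9), c(2, 6, 3) * 13)
  expect_equal(weighted_ber(s3), weighted_ber(s3x))
  # empty series errors
  expect_gbm_error(weighted_ber(ber_series(0, NA, 0)), "gbm_metric_error")
})

test_that("weighted BER is monotone in every single entry", {
  set.seed(11)
  for (rep in 1:20) {
    k <- sample(3:10, 1)
    offs <- sample(-11:5, k)
    ber <- runif(k)
    n <- sample(1:20, k, replace = TRUE)
    s <- ber_series(offs, ber, n)
    i <- sample(k, 1)
    bumped <- ber
    bumped[i] <- min(1, ber[i] + runif(1, 0, 1 - ber[i]))
    s2 <- ber_series(offs, bumped, n)
    expect_gte(weighted_ber(s2), weighted_ber(s) - 1e-12)
  }
})

test_that("weighted BER matches a direct evaluation of the weighting formula", {
  # independent oracle: explicit loop over offsets
  oracle <- function(offs, ber, n) {
    num <- 0; den <- 0
    for (j in seq_along(offs)) {
      if (is.na(ber[j])) next
      wt <- if (offs[j] >= 0) 1 else 1 - (0.5 / 11) * (-offs[j])
      wp <- n[j] / sum(n)
      num <- num + wp * wt * ber[j]
      den <- den + wp * wt
    }
    num / den
  }
  set.seed(7)
  for (rep in 1:50) {
    k <- sample(1:17, 1)
    offs <- sample(-11:5, k)
    ber <- round(runif(k), 3)
    n <- sample(1:29, k, replace = TRUE)
    expect_equal(weighted_ber(ber_series(offs, ber, n)),
                 oracle(offs, ber, n), tolerance = 1e-12)
  }
})

test_that("offset labels render and parse in all accepted spellings", {
  offs <- c(5, 1, 0, -1, -11)
  labs <- format_offset_label(offs)
  expect_equal(labs, c("L+5", "L+1", "L", "L-1", "L-11"))
  expect_equal(parse_offset_label(labs), offs)
  expect_equal(parse_offset_label(c("L + 2", "L − 3", "*L*")), c(2, -3, 0))
  expect_gbm_error(parse_offset_label("M-1"), "gbm_label_error")
})

test_that("wBER is recoverable from transcribed per-offset tables", {
  ber_path <- withr::local_tempfile(fileext = ".csv")
  cnt_path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("offset,clfA,clfB", "L+1,0,0.5", "L,0.2,0.1", "L-1,,1"),
             ber_path)
  writeLines(c("offset,n", "L+1,2", "L,10", "L-1,4"), cnt_path)
  w <- wber_from_tables(ber_path, cnt_path)
  expect_named(w, c("clfA", "clfB"))
  expect_equal(unname(w["clfA"]),
               weighted_ber(ber_series(c(1, 0), c(0, 0.2), c(2, 10))))
  expect_equal(unname(w["clfB"]),
               weighted_ber(ber_series(c(1, 0, -1), c(0.5, 0.1, 1), c(2, 10, 4))))

  # offset missing from the counts table is an error
  writeLines(c("offset,n", "L+1,2", "L,10"), cnt_path)
  expect_gbm_error(wber_from_tables(ber_path, cnt_path), "gbm_label_error")

  # an empty classifier column is an error naming the column
  writeLines(c("offset,n", "L+1,2", "L,10", "L-1,4"), cnt_path)
  writeLines(c("offset,clfA,empty", "L+1,0,", "L,0.2,", "L-1,,"), ber_path)
  err <- tryCatch(wber_from_tables(ber_path, cnt_path),
                  error = conditionMessage)
  expect_match(err, "empty")
})
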