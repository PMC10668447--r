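test_that("group fences match brute-force linear-interpolation quartiles", {
  f <- group_fences(c(1, 2, 3, 4, 5), "m", NA, "controls")
  expect_equal(f$q1, 2)
  expect_equal(f$q3, 4)
  expect_equal(f$lower, -1)
  expect_equal(f$upper, 7)
  # constant group collapses to zero-width fences
  fc <- group_fences(rep(3.3, 6))
  expect_equal(fc$lower, 3.3)
  expect_equal(fc$upper, 3.3)
  # oracle agreement and ordering properties on random vectors
  set.seed(31)
  for (i in 1:1000) {
    x <- round(rnorm(sample(2:25, 1), sd = sample(c(0.5, 5, 50), 1)), 2)
    f <- group_fences(x)
    o <- oracle_fences(x)
    expect_equal(f$lower, unname(o["lower"]), tolerance = 1e-12)
    expect_equal(f$upper, unname(o["upper"]), tolerance = 1e-12)
    expect_true(f$lower <= min(f$q1, oracle_quantile(x, 0.5)))
    expect_true(f$upper >= f$q3)
    expect_true(f$iqr >= 0)
  }
})

test_that("fences on fewer than two values are undefined with a warning", {
  expect_warning(f <- group_fences(3, "m", "axes", "patients"), "fewer than 2")
  expect_true(is.na(f$lower))
  expect_equal(f$n, 1)
})

test_that("the atypicality flag is the conjunction of two strict Tukey rules", {
  fc <- list(lower = -1, upper = 7)
  fp <- list(lower = 0, upper = 8)
  expect_true(atypical_flag(10, fc, fp)) # beyond both uppers
  expect_false(atypical_flag(7.5, fc, fp)) # outlier for controls only
  expect_false(atypical_flag(-0.5, fc, fp)) # outlier for patients only
  expect_false(atypical_flag(7, fc, fp)) # exactly on a fence: strict
  expect_false(atypical_flag(8, fc, fp))
  expect_true(is.na(atypical_flag(NA_real_, fc, fp)))
})

test_that("identical players give an all-zero summary matrix", {
  fx <- make_fixture_cohort()
  clone <- lapply(seq_along(fx$sessions), function(i) {
    s <- fx$sessions[[3]] # copy one typical patient everywhere
    player_session(paste0("p", i), if (i <= 2) "control" else "patient",
      s$trials, s$frames,
      validate = FALSE
    )
  })
  m <- build_summary_matrix(compute_metrics(clone))
  expect_true(all(m$values == 0, na.rm = TRUE))
})

test_that("the constructed atypical player is flagged and only they are", {
  fx <- make_fixture_cohort()
  m <- build_summary_matrix(compute_metrics(fx$sessions))
  expect_equal(dim(m$values), c(6, 14))
  row <- m$values["patient_4", ]
  expect_setequal(names(row)[!is.na(row) & row > 0], fx$expected_flagged)
  others <- m$values[rownames(m$values) != "patient_4", ]
  expect_true(all(others == 0, na.rm = TRUE))
  # per-level metric cells are means of Booleans over non-missing levels
  expect_true(all(m$values >= 0 & m$values <= 1, na.rm = TRUE))
})

test_that("when the groups coincide the rule reduces to single-group Tukey", {
  set.seed(32)
  vals <- c(rnorm(9), 6) # one clear outlier
  metrics <- tibble::tibble(
    player_id = c(paste0("c", 1:10), paste0("p", 1:10)),
    group = rep(c("control", "patient"), each = 10),
    metric = "head_lat", level = "axes",
    value = rep(vals, 2)
  )
  m <- build_summary_matrix(metrics)
  f <- oracle_fences(vals)
  single <- vals < f["lower"] | vals > f["upper"]
  expect_equal(unname(m$values[paste0("c", 1:10), "head_lat"]), as.numeric(single))
  expect_equal(unname(m$values[paste0("p", 1:10), "head_lat"]), as.numeric(single))
})

test_that("permuting player order permutes matrix rows only", {
  fx <- make_fixture_cohort()
  m1 <- build_summary_matrix(compute_metrics(fx$sessions))
  m2 <- build_summary_matrix(compute_metrics(rev(fx$sessions)))
  expect_equal(m2$values[rownames(m1$values), ], m1$values)
})

test_that("missing levels are dropped from the averaging denominator", {
  # player with two levels, flagged on one -> cell value 0.5, not 0.25
  mk <- function(id, grp, v1, v2 = NULL) {
    tibble::tibble(
      player_id = id, group = grp, metric = "head_lat",
      level = if (is.null(v2)) "axes" else c("axes", "depth"),
      value = c(v1, v2)
    )
  }
  metrics <- dplyr::bind_rows(
    mk("c1", "control", 0, 0), mk("c2", "control", 0.5, 0.5),
    mk("p1", "patient", 0, 0), mk("p2", "patient", 0.4, 0.6),
    mk("p4", "patient", 0.2, 0.3),
    mk("p3", "patient", 30) # one level only, extreme on it
  )
  m <- build_summary_matrix(metrics)
  expect_equal(unname(m$values["p3", "head_lat"]), 1) # 1 of 1 level, not 1 of 2
})

test_that("mean atypicality averages non-missing cells", {
  fx <- make_fixture_cohort()
  m <- build_summary_matrix(compute_metrics(fx$sessions))
  ma <- mean_atypicality(m)
  expect_equal(ma$mean_atypicality[ma$player_id == "control_1"], 0)
  p4 <- m$values["patient_4", ]
  expect_equal(
    ma$mean_atypicality[ma$player_id == "patient_4"],
    mean(p4, na.rm = TRUE)
  )
  # 14 cells, two equal to 1, rest 0 -> 2/14
  fake <- m
  fake$values["patient_1", ] <- c(1, 1, rep(0, 12))
  ma2 <- mean_atypicality(fake)
  expect_equal(ma2$mean_atypicality[ma2$player_id == "patient_1"], 2 / 14)
})

test_that("leave-one-out fences exclude the evaluated player", {
  # value extreme vs others but dominating its own group's quartiles
  metrics <- tibble::tibble(
    player_id = c(paste0("c", 1:5), paste0("p", 1:3)),
    group = rep(c("control", "patient"), c(5, 3)),
    metric = "head_lat", level = "axes",
    value = c(0, 0.2, -0.1, 0.1, 0, 0.1, -0.2, 50)
  )
  with_self <- build_summary_matrix(metrics)
  loo <- build_summary_matrix(metrics, leave_one_out = TRUE)
  # including self, 50 inflates the patient IQR; held out it cannot
  expect_equal(unname(loo$values["p3", "head_lat"]), 1)
  expect_gte(
    unname(loo$values["p3", "head_lat"]),
    unname(with_self$values["p3", "head_lat"])
  )
})

test_that("atypicality artefacts are written and re-readable", {
  fx <- make_fixture_cohort()
  m <- build_summary_matrix(compute_metrics(fx$sessions))
  td <- withr::local_tempdir()
  paths <- write_atypicality(m, td)
  sm <- readr::read_csv(paths$summary_matrix, show_col_types = FALSE)
  expect_equal(nrow(sm), 6)
  expect_true(all(metric_names()$metric %in% names(sm)))
  js <- jsonlite::read_json(paths$summary)
  p4 <- Filter(function(x) x$player_id == "patient_4", js)[[1]]
  expect_setequal(unlist(p4$flagged_metrics), fx$expected_flagged)
})
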