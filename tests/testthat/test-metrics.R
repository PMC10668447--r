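trial_row <- function(lat, vert, ecc, correct, rt, level = "axes", idx = 0L) {
  tibble::tibble(
    level = level, trial_index = idx,
    target_lateral = lat, target_vertical = vert, target_ecc = ecc,
    selected_lateral = ifelse(correct, lat, -99),
    selected_vertical = ifelse(correct, vert, 0),
    correct = correct, rt_s = rt
  )
}

test_that("accuracy is percent correct and missing (not zero) when empty", {
  tr <- trial_row(rep(25, 8), 0, 25, c(rep(TRUE, 6), FALSE, FALSE), 1)
  expect_equal(accuracy_for_level(tr), 75)
  expect_equal(accuracy_for_level(trial_row(25, 0, 25, TRUE, 1)), 100)
  expect_equal(accuracy_for_level(trial_row(rep(25, 18), 0, 25, FALSE, 1)), 0)
  expect_true(is.na(accuracy_for_level(empty_trials())))
})

test_that("RT trimming applies strict single-pass Tukey fences", {
  # zero-IQR data flags nothing (strict inequalities)
  t1 <- trim_rt_outliers(c(2, 2, 2, 2))
  expect_equal(unname(t1$fences), c(2, 2))
  expect_true(all(t1$keep))
  # type-7 quartiles of (2,2,2,100): Q3 = 26.5, upper fence 63.25
  t2 <- trim_rt_outliers(c(2, 2, 2, 100))
  expect_equal(unname(t2$fences["upper"]), 63.25)
  expect_equal(t2$outlier, c(FALSE, FALSE, FALSE, TRUE))
  expect_equal(mean(t2$kept), 2)
  # empty input gives an empty result
  expect_length(trim_rt_outliers(numeric())$kept, 0)
})

test_that("flagged fractions match a brute-force quantile oracle", {
  set.seed(21)
  for (i in 1:200) {
    rts <- rlnorm(sample(c(5, 8, 20, 200), 1), meanlog = 0.5, sdlog = 0.6)
    f <- oracle_fences(rts)
    expect_identical(
      trim_rt_outliers(rts)$outlier,
      rts < f["lower"] | rts > f["upper"]
    )
  }
})

test_that("trimming is single-pass: re-trimming the kept set may flag anew", {
  # the contract is one application of the rule, not a fixed point
  rts <- c(1, 1.1, 1.2, 1.3, 6, 40)
  first <- trim_rt_outliers(rts)
  expect_equal(sum(first$outlier), 1)
  second <- trim_rt_outliers(first$kept)
  expect_gt(sum(second$outlier), 0) # fences recomputed on the kept set differ
})

test_that("per-level RT uses correct trials only and propagates missing", {
  tr <- dplyr::bind_rows(
    trial_row(25, 0, 25, TRUE, 1),
    trial_row(25, 0, 25, TRUE, 2, idx = 1L),
    trial_row(25, 0, 25, TRUE, 3, idx = 2L),
    trial_row(25, 0, 25, FALSE, 60, idx = 3L)
  )
  expect_equal(rt_for_level(tr), 2)
  all_wrong <- trial_row(rep(25, 4), 0, 25, FALSE, 5)
  expect_true(is.na(rt_for_level(all_wrong)))
})

test_that("raycast means use search-phase frames only", {
  fr <- tibble::tibble(
    level = "axes", trial_index = 0L, time_s = seq(0.1, 0.6, 0.1),
    phase = c("cue", "cue", "array", "array", "array", "array"),
    head_lat = c(99, 99, -10, 10, -10, 10),
    head_vert = c(99, 99, 5, 5, 5, 5),
    ctrl_lat = c(99, 99, 2, 2, 2, 2),
    ctrl_vert = 0
  )
  expect_equal(raycast_mean(fr, "headset", "lateral", "axes"), 0)
  expect_equal(raycast_mean(fr, "headset", "vertical", "axes"), 5)
  expect_equal(raycast_mean(fr, "controller", "lateral", "axes"), 2)
  expect_true(is.na(raycast_mean(fr, "headset", "lateral", "depth")))
})

test_that("quadrant preference signs mean right/up advantage is positive", {
  # accuracy: right 80% vs left 60% -> +20
  tr <- dplyr::bind_rows(
    trial_row(rep(25, 5), 0, 25, c(TRUE, TRUE, TRUE, TRUE, FALSE), 1),
    trial_row(rep(-25, 5), 0, 25, c(TRUE, TRUE, TRUE, FALSE, FALSE), 1)
  )
  expect_equal(spatial_preference(tr, "lr", "accuracy"), 20)
  # RT: left 3 s vs right 2 s -> +1 (right preference)
  tr2 <- dplyr::bind_rows(
    trial_row(rep(25, 3), 0, 25, TRUE, 2),
    trial_row(rep(-25, 3), 0, 25, TRUE, 3)
  )
  expect_equal(spatial_preference(tr2, "lr", "rt"), 1)
  # up/down mirrors the rule
  tr3 <- dplyr::bind_rows(
    trial_row(0, rep(25, 3), 25, TRUE, 2),
    trial_row(0, rep(-25, 3), 25, TRUE, 4)
  )
  expect_equal(spatial_preference(tr3, "ud", "rt"), 2)
  # a side without usable trials gives a missing score
  expect_true(is.na(spatial_preference(trial_row(25, 0, 25, TRUE, 1), "lr", "accuracy")))
})

test_that("eccentricity preference is positive for a central advantage", {
  tr <- dplyr::bind_rows(
    trial_row(rep(12.5, 10), 0, 12.5, c(rep(TRUE, 9), FALSE), 1),
    trial_row(rep(25, 10), 0, 25, c(rep(TRUE, 7), rep(FALSE, 3)), 2),
    trial_row(rep(37.5, 10), 0, 37.5, c(rep(TRUE, 5), rep(FALSE, 5)), 3)
  )
  expect_equal(eccentricity_preference(tr, "ecc25", "accuracy"), 20)
  expect_equal(eccentricity_preference(tr, "ecc37", "accuracy"), 20)
  expect_equal(eccentricity_preference(tr, "ecc25", "rt"), 1)
  expect_equal(eccentricity_preference(tr, "ecc37", "rt"), 1)
  withr::local_options(neglectvr.ecc_sign = -1)
  expect_equal(eccentricity_preference(tr, "ecc25", "accuracy"), -20)
})

test_that("the metric vector has 14 metrics and matches its parts", {
  fx <- make_fixture_cohort()
  s <- fx$sessions[[6]] # the constructed atypical patient
  mv <- compute_metric_vector(s)
  expect_setequal(unique(mv$metric), metric_names()$metric)
  expect_equal(nrow(metric_names()), 14)
  # compositional check against the individual operations
  tr <- s$trials
  expect_equal(
    mv$value[mv$metric == "accuracy" & mv$level == "axes"],
    accuracy_for_level(tr)
  )
  expect_equal(
    mv$value[mv$metric == "rt" & mv$level == "axes"],
    rt_for_level(tr)
  )
  expect_equal(
    mv$value[mv$metric == "head_lat" & mv$level == "axes"],
    raycast_mean(s$frames, "headset", "lateral", "axes")
  )
  expect_equal(
    mv$value[mv$metric == "acc_lr"],
    spatial_preference(tr, "lr", "accuracy")
  )
  expect_equal(
    mv$value[mv$metric == "rt_ecc25"],
    eccentricity_preference(tr, "ecc25", "rt")
  )
})

test_that("an empty session yields an all-missing vector with a warning", {
  s <- player_session("empty", "control")
  expect_warning(mv <- compute_metric_vector(s), "no analysable levels")
  expect_true(all(is.na(mv$value)))
  expect_setequal(unique(mv$metric), metric_names()$metric[metric_names()$kind == "pooled"])
})

test_that("tutorial trials are excluded from every metric", {
  tut <- trial_row(rep(25, 4), 0, 25, FALSE, 9, level = "tutorial")
  ax <- trial_row(rep(25, 4), 0, 25, TRUE, 1, level = "axes")
  s <- player_session("p", "patient", dplyr::bind_rows(tut, ax))
  mv <- compute_metric_vector(s)
  expect_false("tutorial" %in% mv$level)
  expect_equal(mv$value[mv$metric == "accuracy" & mv$level == "axes"], 100)
})

test_that("accuracy conserves counts per level", {
  fx <- make_fixture_cohort()
  for (s in fx$sessions) {
    tr <- s$trials
    expect_equal(sum(tr$correct) + sum(!tr$correct), nrow(tr))
  }
})

test_that("fixture cohort metrics equal the hand-computed table", {
  fx <- make_fixture_cohort()
  m <- compute_metrics(fx$sessions)
  joined <- dplyr::inner_join(
    m, fx$expected_metrics,
    by = c("player_id", "metric", "level"), suffix = c("", "_exp")
  )
  expect_equal(nrow(joined), nrow(fx$expected_metrics))
  expect_equal(joined$value, joined$value_exp, tolerance = 1e-12)
})
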