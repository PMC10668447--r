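test_that("agent parameter validation rejects impossible values", {
  expect_error(agent_params(contralesional_miss_slope = 1.5))
  expect_error(agent_params(base_dwell = 0))
  expect_error(agent_params(frame_rate = -1))
})

test_that("a noiseless agent finding the target immediately is deterministic", {
  ag <- agent_params(
    dwell_noise_sd = 0, orientation_noise_sd = 0, motor_noise_sd = 0,
    cue_noise_sd = 0, selection_error_rate = 0, temperature = 1e-6,
    frame_rate = 10
  )
  lvl <- level_config("axes", c(12.5, 25, 37.5, 50), 2L, 1)
  g <- game_config(list(lvl))
  # with a near-zero temperature the agent always inspects the element
  # nearest straight-ahead first; repeat until that element is the target
  set.seed(5)
  for (i in 1:20) {
    out <- simulate_trial(ag, lvl, g)
    first <- out$frames[out$frames$phase == "array", ][1, ]
    t <- out$trial
    if (t$correct && t$rt_s < ag$base_dwell + ag$motor_time + 1e-9) {
      # found at the first inspection: RT is exactly dwell + motor time
      expect_equal(t$rt_s, ag$base_dwell + ag$motor_time)
    }
    expect_lte(
      abs(nrow(out$frames[out$frames$phase == "array", ]) - t$rt_s * ag$frame_rate),
      1
    )
  }
})

test_that("a forced-miss agent gives up and selects a distractor", {
  ag <- agent_params(
    neglect_side = "left", contralesional_miss_slope = 1,
    give_up_after = 16, selection_error_rate = 0, frame_rate = 5
  )
  lvl <- level_config("axes", c(12.5, 25, 37.5, 50), 2L, 1)
  g <- game_config(list(lvl))
  set.seed(6)
  found_left_target <- FALSE
  for (i in 1:40) {
    out <- simulate_trial(ag, lvl, g)
    t <- out$trial
    if (t$target_lateral <= -12.5) {
      # any leftward target is missed with probability 1 -> give-up
      expect_false(t$correct)
      expect_false(t$selected_lateral == t$target_lateral &&
        t$selected_vertical == t$target_vertical)
      found_left_target <- TRUE
    }
  }
  expect_true(found_left_target)
})

test_that("frame bookkeeping matches the reaction time", {
  ag <- agent_params(frame_rate = 30)
  lvl <- level_config("stimuli", 15, 8L, 1)
  g <- game_config(list(lvl))
  set.seed(7)
  for (i in 1:10) {
    out <- simulate_trial(ag, lvl, g)
    n_arr <- sum(out$frames$phase == "array")
    expect_lte(abs(n_arr - out$trial$rt_s * ag$frame_rate), 1)
  }
})

test_that("sessions are byte-identical under the same seed", {
  g <- mini_game()
  a <- simulate_session(fast_agent(), g, seed = 99, player_id = "x")
  b <- simulate_session(fast_agent(), g, seed = 99, player_id = "x")
  expect_identical(a, b)
  c <- simulate_session(fast_agent(), g, seed = 100, player_id = "x")
  expect_false(identical(a$trials, c$trials))
})

test_that("sessions respect level durations and the free-viewing contract", {
  g <- game_config(list(
    level_config("axes", c(12.5, 25, 37.5, 50), 2L, 0.3),
    level_config("free_viewing", numeric(), 0L, 0.1, has_trials = FALSE)
  ))
  s <- simulate_session(fast_agent(), g, seed = 12)
  ax <- s$trials[s$trials$level == "axes", ]
  expect_gt(nrow(ax), 0)
  # gameplay time reaches the minimum duration
  expect_gte(max(s$frames$time_s[s$frames$level == "axes"]), 0.3 * 60)
  fv <- s$frames[s$frames$level == "free_viewing", ]
  expect_gt(nrow(fv), 0)
  expect_true(all(fv$phase == "free"))
  expect_false("free_viewing" %in% s$trials$level)
})

test_that("an unbiased agent's headset lateral mean is near zero", {
  s <- simulate_session(fast_agent(), mini_game(1), seed = 13)
  expect_lt(abs(raycast_mean(s$frames, "headset", "lateral")), 1.5)
})

test_that("injected lateral bias is recovered by the headset lateral mean", {
  g <- game_config(list(level_config("axes", c(12.5, 25, 37.5, 50), 2L, 4)))
  for (b in c(5, 20)) {
    ag <- agent_params(lateral_bias = b, frame_rate = 10)
    s <- simulate_session(ag, g, seed = 140 + b)
    tr100 <- s$trials[seq_len(min(100, nrow(s$trials))), ]
    fr <- s$frames[s$frames$trial_index %in% tr100$trial_index, ]
    expect_lt(abs(raycast_mean(fr, "headset", "lateral") - b), 2)
  }
})

test_that("mirroring the bias sign mirrors lateral means and LR scores", {
  g <- mini_game(1)
  right <- simulate_session(agent_params(lateral_bias = 15, frame_rate = 5), g, seed = 77)
  left <- simulate_session(agent_params(lateral_bias = -15, frame_rate = 5), g, seed = 77)
  mr <- raycast_mean(right$frames, "headset", "lateral")
  ml <- raycast_mean(left$frames, "headset", "lateral")
  expect_gt(mr, 5)
  expect_lt(ml, -5)
  expect_lt(abs(mr + ml), 6) # approximate antisymmetry in distribution
})

test_that("a right-favouring agent yields positive LR preference scores", {
  g <- game_config(list(level_config("axes", c(12.5, 25, 37.5, 50), 2L, 4)))
  # accuracy route: misses accumulate into the left hemifield
  acc_agent <- agent_params(
    neglect_side = "left", contralesional_miss_slope = 0.02, frame_rate = 5
  )
  mv1 <- compute_metric_vector(simulate_session(acc_agent, g, seed = 3))
  expect_gt(mv1$value[mv1$metric == "acc_lr"], 0)
  # speed route: rightward scan start plus leftward dwell slowing
  rt_agent <- agent_params(
    lateral_bias = 15, neglect_side = "left", contralesional_rt_slope = 0.08,
    dwell_noise_sd = 0.05, temperature = 25, frame_rate = 5
  )
  mv2 <- compute_metric_vector(simulate_session(rt_agent, g, seed = 3))
  expect_gt(mv2$value[mv2$metric == "rt_lr"], 0)
})

test_that("cohort simulation is deterministic and respects group sizes", {
  spec <- cohort_spec(
    n_controls = 3, n_patients = 4, game = mini_game(0.15),
    master_seed = 5,
    control_gen = null_control_gen, patient_gen = null_patient_gen
  )
  c1 <- simulate_cohort(spec)
  c2 <- simulate_cohort(spec)
  expect_identical(c1, c2)
  expect_length(c1, 7)
  expect_equal(sum(vapply(c1, function(s) s$group, "") == "control"), 3)
  expect_length(simulate_cohort(cohort_spec(0, 0, master_seed = 1)), 0)
})

test_that("the fixture cohort passes the full pipeline without warnings", {
  fx <- make_fixture_cohort()
  expect_no_warning({
    m <- compute_metrics(fx$sessions)
    mat <- build_summary_matrix(m)
  })
  expect_equal(dim(mat$values), c(6, 14))
})
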