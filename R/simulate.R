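#' Generative gameplay simulator
#'
#' A behavioural agent model that emulates the statistical structure the
#' analysis assumes, so every pipeline stage is testable without clinical
#' data: cue/array trial structure, spherical array grids, orientation
#' traces at the tracking rate, lateralised orienting bias, hemifield
#' accuracy deficits, reaction-time slowing, and give-up distractor
#' selections.
#'
#' The scan-path model is the simulator's own: at each step the agent
#' inspects an uninspected element with probability proportional to
#' `exp(-d / temperature)`, where `d` is the angular distance from the
#' agent's *effective origin* — the current orientation shifted by
#' `(lateral_bias, vertical_bias)`. Inspecting the target detects it with
#' probability `1 - contralesional_miss_slope x (degrees into the neglected
#' hemifield)`. The head tracks the inspected element with a fixed gain
#' about the agent's preferred direction (seated players orient mostly with
#' the eyes), so the headset lateral mean recovers `lateral_bias`. If the
#' target is not detected after `give_up_after` inspections the agent gives
#' up and selects the inspected distractor nearest its preferred direction.
#'
#' All randomness flows through R's global RNG (Mersenne-Twister);
#' [simulate_session()] seeds it once per session and
#' [simulate_cohort()] derives one child seed per player from the master
#' seed, so fixtures never drift.
#'
#' @name simulator
NULL

#' Agent parameters
#'
#' @param lateral_bias Rightward orienting preference, degrees (positive =
#'   right).
#' @param vertical_bias Upward orienting preference, degrees.
#' @param neglect_side Hemifield where misses and slowing accumulate
#'   (`"left"` or `"right"`); only relevant when a slope below is nonzero.
#' @param contralesional_miss_slope Extra miss probability per degree of
#'   target eccentricity into the neglected hemifield.
#' @param contralesional_rt_slope Extra dwell (seconds per degree) for
#'   elements inspected in the neglected hemifield.
#' @param base_dwell Mean dwell per inspected element, seconds.
#' @param dwell_noise_sd Dwell noise SD, seconds.
#' @param orientation_noise_sd Per-frame orientation noise SD, degrees.
#' @param give_up_after Inspections before giving up and selecting a
#'   distractor.
#' @param selection_error_rate Probability of selecting a neighbour instead
#'   of the detected target.
#' @param frame_rate Tracking rate in Hz (default 90).
#' @param temperature Scan-path softmax temperature, degrees; larger =
#'   weaker spatial guidance.
#' @param head_gain,ctrl_gain Fraction of the gaze shift carried by the
#'   head / controller about the preferred direction.
#' @param motor_time,motor_noise_sd Selection (motor) time constant and
#'   noise, seconds.
#' @param cue_time,cue_noise_sd Cue-selection time constant and noise,
#'   seconds.
#'
#' @return An `agent_params` list.
#' @export
agent_params <- function(lateral_bias = 0, vertical_bias = 0,
                         neglect_side = c("left", "right"),
                         contralesional_miss_slope = 0,
                         contralesional_rt_slope = 0,
                         base_dwell = 0.35, dwell_noise_sd = 0.1,
                         orientation_noise_sd = 2,
                         give_up_after = 16, selection_error_rate = 0.02,
                         frame_rate = 90, temperature = 75,
                         head_gain = 0.25, ctrl_gain = 0.25,
                         motor_time = 0.4, motor_noise_sd = 0.1,
                         cue_time = 0.8, cue_noise_sd = 0.2) {
  neglect_side <- match.arg(neglect_side)
  stopifnot(
    contralesional_miss_slope >= 0, contralesional_miss_slope <= 1,
    selection_error_rate >= 0, selection_error_rate <= 1,
    base_dwell > 0, dwell_noise_sd >= 0, frame_rate > 0,
    give_up_after >= 1, temperature > 0
  )
  structure(
    list(
      lateral_bias = lateral_bias, vertical_bias = vertical_bias,
      neglect_side = neglect_side,
      contralesional_miss_slope = contralesional_miss_slope,
      contralesional_rt_slope = contralesional_rt_slope,
      base_dwell = base_dwell, dwell_noise_sd = dwell_noise_sd,
      orientation_noise_sd = orientation_noise_sd,
      give_up_after = as.integer(give_up_after),
      selection_error_rate = selection_error_rate,
      frame_rate = frame_rate, temperature = temperature,
      head_gain = head_gain, ctrl_gain = ctrl_gain,
      motor_time = motor_time, motor_noise_sd = motor_noise_sd,
      cue_time = cue_time, cue_noise_sd = cue_noise_sd
    ),
    class = "agent_params"
  )
}

# degrees into the neglected hemifield (0 on the intact side)
neglect_depth <- function(lateral, side) {
  if (side == "left") pmax(0, -lateral) else pmax(0, lateral)
}

# per-level element machinery, precomputed once per session
level_setup <- function(level, game) {
  if (level$name == "axes") {
    list(type = "axes", eccs = level$ring_eccentricities)
  } else {
    grid <- build_spherical_grid(level$ring_eccentricities, game$grid$within_ring_spacing)
    list(
      type = "ring", grid = grid,
      ring_idx = split(seq_len(nrow(grid)), grid$ring),
      k = level$elements_per_ring[[1]]
    )
  }
}

# array elements for one trial; returns a list of parallel vectors
trial_elements <- function(setup) {
  if (setup$type == "axes") {
    e <- setup$eccs
    if (stats::runif(1) < 0.5) {
      list(lateral = c(e, -e), vertical = rep(0, 2 * length(e)), ecc = c(e, e))
    } else {
      list(lateral = rep(0, 2 * length(e)), vertical = c(e, -e), ecc = c(e, e))
    }
  } else {
    idx <- unlist(lapply(setup$ring_idx, function(ix) ix[sample.int(length(ix), min(setup$k, length(ix)))]),
      use.names = FALSE
    )
    list(
      lateral = setup$grid$lateral[idx],
      vertical = setup$grid$vertical[idx],
      ecc = setup$grid$ring[idx]
    )
  }
}

#' Simulate one cue/array trial
#'
#' Uses the current state of R's RNG; see [simulate_session()] for seeded
#' use.
#'
#' @param agent An [agent_params()].
#' @param level A [level_config()] with trials.
#' @param game A [game_config()] (grid parameters).
#' @param trial_index 0-based trial index.
#' @param t0 Level clock at trial start, seconds.
#'
#' @return List with `trial` (one-row trial tibble), `frames` (frame
#'   tibble, cue then array phase), and `duration` (cue + array + motor
#'   time, seconds).
#' @export
simulate_trial <- function(agent, level, game, trial_index = 0L, t0 = 0) {
  stopifnot(level$has_trials)
  raw <- sim_trial_raw(agent, level_setup(level, game), level$name, trial_index, t0)
  list(
    trial = tibble::as_tibble(raw$trial),
    frames = tibble::as_tibble(raw$frames),
    duration = raw$duration
  )
}

# hot path: plain lists, no tibble construction
sim_trial_raw <- function(agent, setup, level_name, trial_index = 0L, t0 = 0) {
  el <- trial_elements(setup)
  n <- length(el$lateral)
  target <- sample.int(n, 1)

  # -- scan path ---------------------------------------------------------
  cur <- c(0, 0)
  remaining <- seq_len(n)
  order <- integer(0)
  found <- FALSE
  max_steps <- min(agent$give_up_after, n)
  for (step in seq_len(max_steps)) {
    o_lat <- cur[1] + agent$lateral_bias
    o_vert <- cur[2] + agent$vertical_bias
    d <- sqrt((el$lateral[remaining] - o_lat)^2 + (el$vertical[remaining] - o_vert)^2)
    w <- exp(-(d - min(d)) / agent$temperature) # stabilised softmax weights
    pick <- remaining[sample.int(length(remaining), 1, prob = w)]
    order <- c(order, pick)
    remaining <- setdiff(remaining, pick)
    cur <- c(el$lateral[pick], el$vertical[pick])
    if (pick == target) {
      miss_p <- min(1, agent$contralesional_miss_slope *
        neglect_depth(el$lateral[target], agent$neglect_side))
      if (stats::runif(1) >= miss_p) {
        found <- TRUE
        break
      }
    }
    if (!length(remaining)) break
  }

  # -- selection ---------------------------------------------------------
  if (found) {
    selected <- if (n > 1 && stats::runif(1) < agent$selection_error_rate) {
      sample(setdiff(seq_len(n), target), 1)
    } else {
      target
    }
  } else {
    cands <- setdiff(order, target)
    if (!length(cands)) cands <- order
    d_pref <- sqrt((el$lateral[cands] - agent$lateral_bias)^2 +
      (el$vertical[cands] - agent$vertical_bias)^2)
    selected <- cands[which.min(d_pref)]
  }
  correct <- selected == target

  # -- timing ------------------------------------------------------------
  dwell <- pmax(0.05, agent$base_dwell +
    stats::rnorm(length(order), 0, agent$dwell_noise_sd) +
    agent$contralesional_rt_slope *
      neglect_depth(el$lateral[order], agent$neglect_side))
  motor <- max(0.05, agent$motor_time + stats::rnorm(1, 0, agent$motor_noise_sd))
  rt <- sum(dwell) + motor
  cue_rt <- max(0.2, agent$cue_time + stats::rnorm(1, 0, agent$cue_noise_sd))

  # -- frames ------------------------------------------------------------
  n_cue <- max(1L, round(cue_rt * agent$frame_rate))
  n_arr <- max(1L, round(rt * agent$frame_rate))
  # distribute array frames over inspections in proportion to dwell
  share <- dwell / sum(dwell)
  counts <- floor(share * n_arr)
  rem <- n_arr - sum(counts)
  if (rem > 0) {
    top <- order(share * n_arr - counts, decreasing = TRUE)[seq_len(rem)]
    counts[top] <- counts[top] + 1L
  }
  looked <- rep(order, times = counts)
  nz <- agent$orientation_noise_sd
  ntot <- n_cue + n_arr
  frames <- list(
    level = rep(level_name, ntot),
    trial_index = rep(as.integer(trial_index), ntot),
    time_s = t0 + c(
      seq_len(n_cue) / agent$frame_rate,
      cue_rt + seq_len(n_arr) / agent$frame_rate
    ),
    phase = c(rep("cue", n_cue), rep("array", n_arr)),
    head_lat = c(
      stats::rnorm(n_cue, 0, nz),
      agent$lateral_bias + agent$head_gain * el$lateral[looked] +
        stats::rnorm(n_arr, 0, nz)
    ),
    head_vert = c(
      stats::rnorm(n_cue, 0, nz),
      agent$vertical_bias + agent$head_gain * el$vertical[looked] +
        stats::rnorm(n_arr, 0, nz)
    ),
    ctrl_lat = c(
      stats::rnorm(n_cue, 0, nz),
      agent$lateral_bias + agent$ctrl_gain * el$lateral[looked] +
        stats::rnorm(n_arr, 0, nz)
    ),
    ctrl_vert = c(
      stats::rnorm(n_cue, 0, nz),
      agent$vertical_bias + agent$ctrl_gain * el$vertical[looked] +
        stats::rnorm(n_arr, 0, nz)
    )
  )

  trial <- list(
    level = level_name,
    trial_index = as.integer(trial_index),
    target_lateral = el$lateral[target],
    target_vertical = el$vertical[target],
    target_ecc = el$ecc[target],
    selected_lateral = el$lateral[selected],
    selected_vertical = el$vertical[selected],
    correct = correct,
    rt_s = rt
  )
  list(trial = trial, frames = frames, duration = cue_rt + rt)
}

#' Simulate a full gameplay session
#'
#' Trials are generated per level until the level's minimum duration is
#' reached (a level ends only when the current element is selected); the
#' free-viewing level emits orientation frames only. Deterministic given
#' `seed`.
#'
#' @param agent An [agent_params()].
#' @param game A [game_config()]; default [default_game_config()].
#' @param seed Integer seed for this session.
#' @param player_id,group Session labels.
#' @return A [player_session()].
#' @export
simulate_session <- function(agent, game = default_game_config(), seed = 1,
                             player_id = "sim", group = "control") {
  set.seed(seed, kind = "Mersenne-Twister")
  trials <- list()
  frames <- list()
  for (level in game$levels) {
    if (level$has_trials) {
      setup <- level_setup(level, game)
      t <- 0
      idx <- 0L
      while (t < level$min_duration * 60) {
        out <- sim_trial_raw(agent, setup, level$name, trial_index = idx, t0 = t)
        trials[[length(trials) + 1L]] <- out$trial
        frames[[length(frames) + 1L]] <- out$frames
        t <- t + out$duration
        idx <- idx + 1L
      }
    } else {
      frames[[length(frames) + 1L]] <- as.list(free_viewing_frames(agent, level))
    }
  }
  bind_col_lists <- function(rows, proto) {
    if (!length(rows)) {
      return(proto)
    }
    cols <- lapply(stats::setNames(names(proto), names(proto)), function(cn) {
      unlist(lapply(rows, `[[`, cn), use.names = FALSE)
    })
    tibble::as_tibble(cols)
  }
  player_session(
    player_id = player_id, group = group,
    trials = bind_col_lists(trials, empty_trials()),
    frames = bind_col_lists(frames, empty_frames()),
    validate = FALSE
  )
}

# slow wandering orientation around the preferred direction
free_viewing_frames <- function(agent, level) {
  n <- max(1L, round(level$min_duration * 60 * agent$frame_rate))
  wander <- function(bias, sd_step = 0.5, sd_range = 15) {
    x <- stats::filter(stats::rnorm(n, 0, sd_step), 0.995, method = "recursive")
    bias + as.numeric(x) / max(1e-9, stats::sd(x)) * sd_range / 3 +
      stats::rnorm(n, 0, agent$orientation_noise_sd)
  }
  tibble::tibble(
    level = level$name,
    trial_index = NA_integer_,
    time_s = seq_len(n) / agent$frame_rate,
    phase = "free",
    head_lat = wander(agent$lateral_bias),
    head_vert = wander(agent$vertical_bias),
    ctrl_lat = wander(agent$lateral_bias),
    ctrl_vert = wander(agent$vertical_bias)
  )
}

#' Cohort specification
#'
#' @param n_controls,n_patients Group sizes (the study cohort is 9 + 13).
#' @param game A [game_config()].
#' @param master_seed Master seed; one child seed per player is derived
#'   from it.
#' @param control_gen,patient_gen Functions `(i)` returning an
#'   [agent_params()] for the i-th player of the group, called with the
#'   player's child RNG stream active. Defaults: [default_control_agent()]
#'   and [default_patient_agent()].
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_controls = 9, n_patients = 13,
                        game = default_game_config(), master_seed = 1,
                        control_gen = default_control_agent,
                        patient_gen = default_patient_agent) {
  stopifnot(n_controls >= 0, n_patients >= 0)
  structure(
    list(
      n_controls = as.integer(n_controls), n_patients = as.integer(n_patients),
      game = game, master_seed = as.integer(master_seed),
      control_gen = control_gen, patient_gen = patient_gen
    ),
    class = "cohort_spec"
  )
}

#' Default agent generators
#'
#' Controls draw a small inter-individual orienting idiosyncrasy
#' (`lateral_bias`, `vertical_bias` ~ Normal(0, 1.5 deg)) and mild dwell
#' variation. Patients mirror the study's clinical mix: 3 of 13 with a
#' left-neglect-like profile (rightward bias 10-25 deg, contralesional
#' miss and slowing gradients) and the remainder with generalised slowing
#' and larger idiosyncratic variability but no lateralised deficit.
#'
#' @param i Player index within the group (1-based).
#' @param n_neglect Number of neglect-like patients (first `n_neglect`
#'   indices).
#' @return An [agent_params()].
#' @export
default_control_agent <- function(i) {
  agent_params(
    lateral_bias = stats::rnorm(1, 0, 1.5),
    vertical_bias = stats::rnorm(1, 0, 1.5),
    base_dwell = 0.35 * stats::runif(1, 0.8, 1.3)
  )
}

#' @rdname default_control_agent
#' @export
default_patient_agent <- function(i, n_neglect = 3) {
  if (i <= n_neglect) {
    agent_params(
      lateral_bias = stats::runif(1, 10, 25),
      vertical_bias = stats::rnorm(1, 0, 2),
      neglect_side = "left",
      contralesional_miss_slope = stats::runif(1, 0.01, 0.025),
      contralesional_rt_slope = stats::runif(1, 0.02, 0.05),
      base_dwell = 0.35 * stats::runif(1, 1.5, 3),
      give_up_after = 12
    )
  } else {
    agent_params(
      lateral_bias = stats::rnorm(1, 0, 3),
      vertical_bias = stats::rnorm(1, 0, 3),
      base_dwell = 0.35 * stats::runif(1, 1, 2.5),
      dwell_noise_sd = 0.15
    )
  }
}

#' Simulate a cohort of sessions
#'
#' Child seeds are derived deterministically from `master_seed` (one
#' `sample.int` draw per player under the master stream); agent parameters
#' are drawn under the player's child stream, then the session is
#' simulated. Two cohorts from the same spec are identical.
#'
#' @param spec A [cohort_spec()].
#' @return List of [player_session()] objects (controls first), with
#'   player ids `control_01`, ..., `patient_01`, ...
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_controls + spec$n_patients
  if (!n) {
    return(list())
  }
  set.seed(spec$master_seed, kind = "Mersenne-Twister")
  child_seeds <- sample.int(.Machine$integer.max - 1L, n)
  sessions <- vector("list", n)
  for (i in seq_len(n)) {
    is_control <- i <= spec$n_controls
    j <- if (is_control) i else i - spec$n_controls
    set.seed(child_seeds[[i]], kind = "Mersenne-Twister")
    agent <- if (is_control) spec$control_gen(j) else spec$patient_gen(j)
    sessions[[i]] <- simulate_session(
      agent, spec$game,
      seed = child_seeds[[i]] %% (.Machine$integer.max - 1L) + 1L,
      player_id = sprintf("%s_%02d", if (is_control) "control" else "patient", j),
      group = if (is_control) "control" else "patient"
    )
  }
  sessions
}
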