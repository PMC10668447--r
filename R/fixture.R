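#' Hand-constructed regression fixture cohort
#'
#' A tiny cohort (2 controls, 4 patients, 8 trials each on a single axes
#' level) whose metric values and atypicality flags were worked out by hand
#' and ship alongside the sessions as an expected-output table. Player
#' `patient_4` is built to be atypical: right-shifted raycasts (+30 deg),
#' accuracy 25%, slowed RT, and right-favouring spatial preference.
#' Patients 1-3 miss one down-quadrant target; controls are error-free.
#'
#' @return A list:
#' * `sessions` — list of 6 [player_session()] objects,
#' * `expected_metrics` — tibble (`player_id`, `metric`, `level`, `value`)
#'   of hand-computed metric values,
#' * `expected_flagged` — character vector of the metrics on which
#'   `patient_4` is atypical by construction.
#' @export
make_fixture_cohort <- function() {
  # eight targets: three right, two left, one up, two down;
  # eccentricities 12.5 (x3), 25 (x4), 37.5 (x1)
  targets <- tibble::tibble(
    trial_index = 0:7,
    lat = c(12.5, -12.5, 25, -25, 0, 0, 37.5, 0),
    vert = c(0, 0, 0, 0, 25, -25, 0, -12.5),
    ecc = c(12.5, 12.5, 25, 25, 25, 25, 37.5, 12.5)
  )

  build_trials <- function(correct, rt_correct, rt_wrong, wrong_sel = c(12.5, 0)) {
    tibble::tibble(
      level = "axes",
      trial_index = targets$trial_index,
      target_lateral = targets$lat,
      target_vertical = targets$vert,
      target_ecc = targets$ecc,
      selected_lateral = ifelse(correct, targets$lat, wrong_sel[1]),
      selected_vertical = ifelse(correct, targets$vert, wrong_sel[2]),
      correct = correct,
      rt_s = ifelse(correct, rt_correct, rt_wrong)
    )
  }
  build_frames <- function(lat) {
    tibble::tibble(
      level = "axes",
      trial_index = 0L,
      time_s = seq(0.1, 1, by = 0.1),
      phase = c("cue", "cue", rep("array", 8)),
      head_lat = c(0, 0, rep(lat, 8)),
      head_vert = 0,
      ctrl_lat = c(0, 0, rep(lat, 8)),
      ctrl_vert = 0
    )
  }
  all_ok <- rep(TRUE, 8)
  miss_down <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, TRUE) # t5 missed
  only_right <- c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)

  sessions <- list(
    player_session("control_1", "control", build_trials(all_ok, 1.0, NA), build_frames(0)),
    player_session("control_2", "control", build_trials(all_ok, 1.2, NA), build_frames(0)),
    player_session("patient_1", "patient", build_trials(miss_down, 2, 3), build_frames(0)),
    player_session("patient_2", "patient", build_trials(miss_down, 2, 3), build_frames(0)),
    player_session("patient_3", "patient", build_trials(miss_down, 2, 3), build_frames(0)),
    player_session("patient_4", "patient", build_trials(only_right, 5, 6), build_frames(30))
  )

  # hand-computed expected values (see the methods vignette for the
  # arithmetic); raycast verticals are 0 everywhere and omitted for brevity
  exp_one <- function(id, acc, rt, hlat, acc_lr, acc_ud, acc_e25, acc_e37,
                      rt_lr, rt_ud, rt_e25, rt_e37) {
    tibble::tibble(
      player_id = id,
      metric = c(
        "accuracy", "rt", "head_lat", "ctrl_lat",
        "acc_lr", "acc_ud", "acc_ecc25", "acc_ecc37",
        "rt_lr", "rt_ud", "rt_ecc25", "rt_ecc37"
      ),
      level = c(rep("axes", 4), rep(NA_character_, 8)),
      value = c(acc, rt, hlat, hlat, acc_lr, acc_ud, acc_e25, acc_e37, rt_lr, rt_ud, rt_e25, rt_e37)
    )
  }
  expected_metrics <- dplyr::bind_rows(
    exp_one("control_1", 100, 1.0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    exp_one("control_2", 100, 1.2, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    exp_one("patient_1", 87.5, 2, 0, 0, 50, 25, -25, 0, 0, 0, 0),
    exp_one("patient_2", 87.5, 2, 0, 0, 50, 25, -25, 0, 0, 0, 0),
    exp_one("patient_3", 87.5, 2, 0, 0, 50, 25, -25, 0, 0, 0, 0),
    exp_one(
      "patient_4", 25, 5, 30, 200 / 3, 0, 100 / 3 - 25, 25,
      NA, NA, 0, NA
    )
  )

  list(
    sessions = sessions,
    expected_metrics = expected_metrics,
    expected_flagged = c(
      "accuracy", "rt", "head_lat", "ctrl_lat",
      "acc_lr", "acc_ecc25", "acc_ecc37"
    )
  )
}
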