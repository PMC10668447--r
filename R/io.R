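#' Session I/O
#'
#' Sessions are serialised as two flat CSV tables sharing `player_id`:
#'
#' * `trials.csv`: `player_id, group, level, trial_index, target_lateral,
#'   target_vertical, target_ecc, selected_lateral, selected_vertical,
#'   correct, rt_s`
#' * `frames.csv`: `player_id, level, trial_index, time_s, phase, head_lat,
#'   head_vert, ctrl_lat, ctrl_vert`
#'
#' Files are UTF-8 CSV with a header row and `.` decimal separator. Unknown
#' columns are preserved and round-tripped. `trial_index` is 0-based on
#' disk (human-facing reports are 1-based).
#'
#' @name session-io
NULL

#' Read player sessions from trial and frame tables
#'
#' @param trials_path Path to `trials.csv`.
#' @param frames_path Optional path to `frames.csv` (or a `.jsonl` file with
#'   one frame object per line); `NULL` gives sessions without frames.
#' @param demographics_path Optional path to a demographics CSV keyed by
#'   `player_id`; matched rows are attached to each session as a list.
#' @param validate Validate each session on construction.
#'
#' @return A list of [player_session()] objects, ordered by first appearance
#'   in the trial table (then by frame table for frame-only players).
#' @export
read_sessions <- function(trials_path, frames_path = NULL,
                          demographics_path = NULL, validate = TRUE) {
  trials <- readr::read_csv(trials_path, show_col_types = FALSE, progress = FALSE)
  need <- c("player_id", "group", TRIAL_COLS)
  miss <- setdiff(need, names(trials))
  if (length(miss)) {
    stop("trials table ", trials_path, " is missing columns: ",
      paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  frames <- if (!is.null(frames_path)) read_frames(frames_path) else NULL
  demo <- if (!is.null(demographics_path)) {
    readr::read_csv(demographics_path, show_col_types = FALSE, progress = FALSE)
  } else {
    NULL
  }

  ids <- unique(c(trials$player_id, if (!is.null(frames)) frames$player_id))
  lapply(ids, function(id) {
    tr <- dplyr::filter(trials, .data$player_id == id)
    grp <- if (nrow(tr)) tr$group[[1]] else "control"
    fr <- if (!is.null(frames)) {
      dplyr::select(dplyr::filter(frames, .data$player_id == id), -"player_id")
    } else {
      empty_frames()
    }
    dm <- if (!is.null(demo) && id %in% as.character(demo$player_id)) {
      as.list(demo[as.character(demo$player_id) == id, , drop = FALSE][1, ])
    } else {
      NULL
    }
    player_session(
      player_id = id, group = grp,
      trials = dplyr::select(tr, -"player_id", -"group"),
      frames = fr, demographics = dm, validate = validate
    )
  })
}

read_frames <- function(path) {
  if (grepl("\\.jsonl$", path)) {
    fr <- jsonlite::stream_in(file(path), verbose = FALSE)
    fr <- tibble::as_tibble(fr)
  } else {
    fr <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  miss <- setdiff(c("player_id", FRAME_COLS), names(fr))
  if (length(miss)) {
    stop("frames table ", path, " is missing columns: ",
      paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  fr
}

#' Write player sessions to trial and frame tables
#'
#' @param sessions List of [player_session()] objects.
#' @param trials_path,frames_path Output CSV paths (`frames_path = NULL`
#'   skips frames).
#' @return Invisibly, a named list of the paths written.
#' @export
write_sessions <- function(sessions, trials_path, frames_path = NULL) {
  stopifnot(all(vapply(sessions, inherits, logical(1), "player_session")))
  trials <- purrr::map_dfr(sessions, function(s) {
    if (!nrow(s$trials)) {
      return(tibble::tibble())
    }
    dplyr::mutate(s$trials, player_id = s$player_id, group = s$group, .before = 1)
  })
  if (!nrow(trials)) trials <- dplyr::mutate(empty_trials(), player_id = character(), group = character(), .before = 1)
  readr::write_csv(trials, trials_path, progress = FALSE)
  out <- list(trials = trials_path)
  if (!is.null(frames_path)) {
    frames <- purrr::map_dfr(sessions, function(s) {
      if (!nrow(s$frames)) {
        return(tibble::tibble())
      }
      dplyr::mutate(s$frames, player_id = s$player_id, .before = 1)
    })
    if (!nrow(frames)) frames <- dplyr::mutate(empty_frames(), player_id = character(), .before = 1)
    readr::write_csv(frames, frames_path, progress = FALSE)
    out$frames <- frames_path
  }
  invisible(out)
}

#' Read a patient demographics table
#'
#' Columns mirror the clinical intake table: `player_id, age, sex,
#' days_since_injury, days_in_rehab, diagnosis, hemisphere, fim_motor,
#' fim_cognition, fim_total, neglect_present, neglected_hemispace, clox,
#' slct, alberts`. A copy of the study's 13-patient intake table ships with
#' the package (`system.file("extdata", "table2_demographics.csv",
#' package = "neglectvr")`).
#'
#' @param path CSV path.
#' @return A tibble, one row per patient.
#' @export
read_demographics <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Descriptive summary of a patient demographics table
#'
#' Medians use linear-interpolation (type-7) quantiles, the package-wide
#' convention; the IQR is Q3 - Q1 under the same rule.
#'
#' @param demo A demographics tibble from [read_demographics()].
#' @return A one-row tibble: `n`, `median_age`, `age_iqr`,
#'   `mean_days_since_injury`, `sd_days_since_injury`,
#'   `mean_days_in_rehab`, `sd_days_in_rehab`, `n_neglect`,
#'   `neglect_prevalence_pct`, `fim_motor_median`, `fim_motor_iqr`,
#'   `fim_cognition_median`, `fim_cognition_iqr`.
#' @export
demographics_summary <- function(demo) {
  q <- function(x, p) unname(stats::quantile(x, p, type = 7, na.rm = TRUE))
  iqr <- function(x) q(x, 0.75) - q(x, 0.25)
  tibble::tibble(
    n = nrow(demo),
    median_age = q(demo$age, 0.5),
    age_iqr = iqr(demo$age),
    mean_days_since_injury = mean(demo$days_since_injury),
    sd_days_since_injury = stats::sd(demo$days_since_injury),
    mean_days_in_rehab = mean(demo$days_in_rehab),
    sd_days_in_rehab = stats::sd(demo$days_in_rehab),
    n_neglect = sum(demo$neglect_present),
    neglect_prevalence_pct = 100 * mean(demo$neglect_present),
    fim_motor_median = q(demo$fim_motor, 0.5),
    fim_motor_iqr = iqr(demo$fim_motor),
    fim_cognition_median = q(demo$fim_cognition, 0.5),
    fim_cognition_iqr = iqr(demo$fim_cognition)
  )
}
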