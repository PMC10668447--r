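#' Player gameplay sessions
#'
#' A `player_session` bundles one player's full gameplay: a trial table, a
#' frame (raycast) table, the group label, and optional demographics. Trials
#' record the cue/array structure — on each trial a central cue is selected,
#' the search array appears, and the trial ends when any element (target or
#' distractor) is selected. Frames record the headset and controller
#' orientation angles at the tracking rate, tagged with the trial phase
#' (`"cue"`, `"array"`, or `"free"` for the free-viewing level).
#'
#' @name player-session
NULL

TRIAL_COLS <- c(
  "level", "trial_index", "target_lateral", "target_vertical", "target_ecc",
  "selected_lateral", "selected_vertical", "correct", "rt_s"
)
FRAME_COLS <- c(
  "level", "trial_index", "time_s", "phase",
  "head_lat", "head_vert", "ctrl_lat", "ctrl_vert"
)

#' Construct a player session
#'
#' @param player_id Unique player identifier (coerced to character).
#' @param group `"patient"` or `"control"`.
#' @param trials Tibble with columns `level`, `trial_index` (0-based),
#'   `target_lateral`, `target_vertical`, `target_ecc`, `selected_lateral`,
#'   `selected_vertical`, `correct` (logical), `rt_s` (seconds, cue-to-
#'   selection interval of the array phase).
#' @param frames Tibble with columns `level`, `trial_index`, `time_s`
#'   (seconds since level start), `phase` (`"cue"`, `"array"`, `"free"`),
#'   `head_lat`, `head_vert`, `ctrl_lat`, `ctrl_vert` (degrees).
#' @param demographics Optional named list (age, sex, days_since_injury, ...).
#' @param validate Run [validate_session()]? Default `TRUE`.
#'
#' @return A `player_session` object.
#' @export
player_session <- function(player_id, group, trials = empty_trials(),
                           frames = empty_frames(), demographics = NULL,
                           validate = TRUE) {
  group <- match.arg(group, c("patient", "control"))
  s <- structure(
    list(
      player_id = as.character(player_id),
      group = group,
      trials = tibble::as_tibble(trials),
      frames = tibble::as_tibble(frames),
      demographics = demographics
    ),
    class = "player_session"
  )
  if (validate) validate_session(s)
  s
}

#' Empty trial / frame tables with the canonical schema
#' @return A zero-row tibble.
#' @export
empty_trials <- function() {
  tibble::tibble(
    level = character(), trial_index = integer(),
    target_lateral = numeric(), target_vertical = numeric(),
    target_ecc = numeric(),
    selected_lateral = numeric(), selected_vertical = numeric(),
    correct = logical(), rt_s = numeric()
  )
}

#' @rdname empty_trials
#' @export
empty_frames <- function() {
  tibble::tibble(
    level = character(), trial_index = integer(), time_s = numeric(),
    phase = character(),
    head_lat = numeric(), head_vert = numeric(),
    ctrl_lat = numeric(), ctrl_vert = numeric()
  )
}

#' Validate a player session
#'
#' Checks the schemas, that completed trials have positive reaction times,
#' that `correct` agrees with the selected and target positions, and that
#' frame times are non-decreasing within each level.
#'
#' @param session A [player_session()].
#' @param tol Position-match tolerance in degrees for the correctness check.
#' @return `session`, invisibly; errors describe the offending rows.
#' @export
validate_session <- function(session, tol = 1e-6) {
  stopifnot(inherits(session, "player_session"))
  tr <- session$trials
  fr <- session$frames
  miss_t <- setdiff(TRIAL_COLS, names(tr))
  if (length(miss_t)) {
    stop("trial table is missing columns: ", paste(miss_t, collapse = ", "), call. = FALSE)
  }
  miss_f <- setdiff(FRAME_COLS, names(fr))
  if (length(miss_f)) {
    stop("frame table is missing columns: ", paste(miss_f, collapse = ", "), call. = FALSE)
  }
  if (nrow(tr)) {
    if (any(tr$trial_index < 0)) stop("trial_index must be non-negative", call. = FALSE)
    done <- !is.na(tr$rt_s)
    if (any(tr$rt_s[done] <= 0)) {
      stop(
        "rt_s must be positive for completed trials (rows ",
        paste(which(done & tr$rt_s <= 0), collapse = ", "), ")",
        call. = FALSE
      )
    }
    sel <- !is.na(tr$selected_lateral) & !is.na(tr$selected_vertical)
    hit <- sel &
      abs(tr$selected_lateral - tr$target_lateral) < tol &
      abs(tr$selected_vertical - tr$target_vertical) < tol
    bad <- which(tr$correct != hit & sel)
    if (length(bad)) {
      stop(
        "`correct` disagrees with selected/target positions at trial rows ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
  }
  if (nrow(fr)) {
    ok <- fr |>
      dplyr::group_by(.data$level) |>
      dplyr::summarise(mono = !is.unsorted(.data$time_s), .groups = "drop")
    if (!all(ok$mono)) {
      stop(
        "frame times must be non-decreasing within a level (level ",
        paste(ok$level[!ok$mono], collapse = ", "), ")",
        call. = FALSE
      )
    }
  }
  invisible(session)
}

#' @export
print.player_session <- function(x, ...) {
  cat(
    sprintf(
      "<player_session> %s (%s): %d trials, %d frames, levels: %s\n",
      x$player_id, x$group, nrow(x$trials), nrow(x$frames),
      paste(unique(c(x$trials$level, x$frames$level)), collapse = ", ")
    )
  )
  invisible(x)
}

#' @export
format.player_session <- function(x, ...) {
  sprintf("player_session(%s, %s)", x$player_id, x$group)
}
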