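#' Game and level configuration
#'
#' A game is an ordered list of levels played for a fixed minimum duration
#' each; a level ends only when the current element is selected (no
#' time-out). Level geometry is a subset of a spherical grid (2-m radius,
#' rings at multiples of 12.5 degrees eccentricity, 15-degree within-ring
#' spacing).
#'
#' @name game-config
NULL

LEVEL_NAMES <- c("tutorial", "axes", "stimuli", "depth", "full_field", "free_viewing")

#' Construct a level configuration
#'
#' @param name Level name, one of `"tutorial"`, `"axes"`, `"stimuli"`,
#'   `"depth"`, `"full_field"`, `"free_viewing"`.
#' @param ring_eccentricities Eccentricities (degrees) of the concentric
#'   rings holding array elements; empty for `free_viewing`.
#' @param elements_per_ring Number of elements drawn per ring on each trial.
#' @param min_duration Minimum level duration in minutes (> 0).
#' @param depth_radii Radii (metres) of the presentation surfaces; the depth
#'   level uses exactly `c(2, 4)`, all others `2`.
#' @param has_trials Does the level present cue/array trials? `FALSE` only
#'   for free viewing.
#'
#' @return A `level_config` list.
#' @export
level_config <- function(name, ring_eccentricities, elements_per_ring,
                         min_duration, depth_radii = 2, has_trials = TRUE) {
  name <- match.arg(name, LEVEL_NAMES)
  if (min_duration <= 0) stop("`min_duration` must be positive", call. = FALSE)
  if (name == "depth" && !setequal(depth_radii, c(2, 4))) {
    stop("the depth level uses exactly two surfaces at radii 2 and 4 m", call. = FALSE)
  }
  structure(
    list(
      name = name,
      ring_eccentricities = as.numeric(ring_eccentricities),
      elements_per_ring = as.integer(elements_per_ring),
      min_duration = min_duration,
      depth_radii = as.numeric(depth_radii),
      has_trials = isTRUE(has_trials)
    ),
    class = "level_config"
  )
}

#' Construct a game configuration
#'
#' @param levels List of [level_config()] objects, in play order.
#' @param radial_spacing Ring-system radial spacing in degrees (default 12.5).
#' @param within_ring_spacing Within-ring polar spacing in degrees (default 15).
#' @param radius Near-surface radius in metres (default 2).
#'
#' @return A `game_config` list.
#' @export
game_config <- function(levels, radial_spacing = 12.5, within_ring_spacing = 15,
                        radius = 2) {
  stopifnot(length(levels) > 0, all(vapply(levels, inherits, logical(1), "level_config")))
  structure(
    list(
      levels = stats::setNames(levels, vapply(levels, `[[`, character(1), "name")),
      grid = list(
        radial_spacing = radial_spacing,
        within_ring_spacing = within_ring_spacing,
        radius = radius
      )
    ),
    class = "game_config"
  )
}

#' The default (shorter, six-level) game preset
#'
#' Level set and minimum durations: tutorial 0.5 min, axes 3.0 min, stimuli
#' 4.5 min, depth 6.0 min, full field 4.5 min, free viewing 1.0 min — a
#' 19.5-minute minimum game. Eight-element levels use a single ring whose
#' eccentricity is configurable (default 15 degrees); the axes level places
#' its eight elements on the horizontal or vertical axis at +/-12.5, 25,
#' 37.5 and 50 degrees; the full-field level uses four concentric rings at
#' 12.5, 25, 37.5 and 50 degrees.
#'
#' @param single_ring_ecc Eccentricity (degrees) of the single ring used by
#'   the tutorial, stimuli and depth levels.
#' @return A [game_config()] object.
#' @export
default_game_config <- function(single_ring_ecc = 15) {
  game_config(list(
    level_config("tutorial", single_ring_ecc, 8L, 0.5),
    level_config("axes", c(12.5, 25, 37.5, 50), 2L, 3.0),
    level_config("stimuli", single_ring_ecc, 8L, 4.5),
    level_config("depth", single_ring_ecc, 8L, 6.0, depth_radii = c(2, 4)),
    level_config("full_field", c(12.5, 25, 37.5, 50), 6L, 4.5),
    level_config("free_viewing", numeric(), 0L, 1.0, has_trials = FALSE)
  ))
}

#' Total minimum duration of a game
#'
#' @param game A [game_config()] object.
#' @return Sum of the per-level minimum durations, in minutes.
#' @export
total_min_duration <- function(game) {
  stopifnot(inherits(game, "game_config"))
  sum(vapply(game$levels, `[[`, numeric(1), "min_duration"))
}

#' Read / write a game configuration as JSON
#'
#' The JSON mirrors the game-preset concept: a `levels` array with `name`,
#' `ring_eccentricities`, `elements_per_ring`, `min_duration_min`,
#' `depth_radii_m`, `has_trials`, plus a `grid` object.
#'
#' @param path File path.
#' @param game A [game_config()] object.
#' @return `read_game_config()` returns a [game_config()];
#'   `write_game_config()` returns `path` invisibly.
#' @export
read_game_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  levels <- lapply(raw$levels, function(l) {
    level_config(
      name = l$name,
      ring_eccentricities = unlist(l$ring_eccentricities),
      elements_per_ring = unlist(l$elements_per_ring),
      min_duration = l$min_duration_min,
      depth_radii = if (is.null(l$depth_radii_m)) 2 else unlist(l$depth_radii_m),
      has_trials = isTRUE(l$has_trials)
    )
  })
  game_config(
    levels,
    radial_spacing = raw$grid$radial_spacing,
    within_ring_spacing = raw$grid$within_ring_spacing,
    radius = raw$grid$radius
  )
}

#' @rdname read_game_config
#' @export
write_game_config <- function(game, path) {
  stopifnot(inherits(game, "game_config"))
  out <- list(
    levels = unname(lapply(game$levels, function(l) {
      list(
        name = l$name,
        ring_eccentricities = l$ring_eccentricities,
        elements_per_ring = l$elements_per_ring,
        min_duration_min = l$min_duration,
        depth_radii_m = l$depth_radii,
        has_trials = l$has_trials
      )
    })),
    grid = game$grid
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.game_config <- function(x, ...) {
  cat("<game_config> ", length(x$levels), " levels, ",
    format(total_min_duration(x)), " min minimum\n",
    sep = ""
  )
  for (l in x$levels) {
    cat(
      sprintf(
        "  %-12s %4.1f min  %s\n", l$name, l$min_duration,
        if (l$has_trials) {
          paste0(
            "rings {", paste(l$ring_eccentricities, collapse = ", "),
            "} deg x ", l$elements_per_ring, "/ring"
          )
        } else "free viewing (no trials)"
      )
    )
  }
  invisible(x)
}
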