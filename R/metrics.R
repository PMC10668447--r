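#' Attention metrics
#'
#' Fourteen metrics per player, in three primary categories: accuracy (%),
#' reaction time (s), and raycast orientation (degrees) for the headset and
#' the controller. Six primary metrics are computed per game level:
#'
#' * `accuracy` — percent correct trials
#' * `rt` — mean RT of correct trials after within-player Tukey trimming
#' * `head_lat`, `head_vert`, `ctrl_lat`, `ctrl_vert` — mean headset /
#'   controller orientation angles over search (array) frames
#'
#' Eight spatial-preference difference scores pool trials across levels:
#' left/right and up/down quadrant contrasts and two adjacent-eccentricity
#' contrasts (12.5 vs 25.0 and 25.0 vs 37.5 degrees), each for accuracy
#' (delta %) and RT (delta s). Subtraction order makes positive quadrant
#' scores a right/up preference for both measures; positive eccentricity
#' scores are a central advantage (configurable, see
#' [eccentricity_preference()]).
#'
#' The tutorial level is excluded from all metrics; the free-viewing level
#' contributes raycast metrics only.
#'
#' @name attention-metrics
NULL

#' Names and kinds of the 14 attention metrics
#'
#' @return A tibble with columns `metric`, `kind` (`"per_level"` or
#'   `"pooled"`), `unit`, and `label` (the conventional latitude/longitude
#'   label used in clinical figures).
#' @export
metric_names <- function() {
  tibble::tibble(
    metric = c(
      "accuracy", "rt", "head_lat", "head_vert", "ctrl_lat", "ctrl_vert",
      "acc_lr", "acc_ud", "acc_ecc25", "acc_ecc37",
      "rt_lr", "rt_ud", "rt_ecc25", "rt_ecc37"
    ),
    kind = c(rep("per_level", 6), rep("pooled", 8)),
    unit = c(
      "%", "s", "deg", "deg", "deg", "deg",
      "delta%", "delta%", "delta%", "delta%",
      "deltas", "deltas", "deltas", "deltas"
    ),
    label = c(
      "accuracy", "RT", "headset latitude M", "headset longitude M",
      "controller latitude M", "controller longitude M",
      "accuracy LR", "accuracy UD", "accuracy 25.0 deg diff.",
      "accuracy 37.5 deg diff.",
      "RT LR", "RT UD", "RT 25.0 deg diff.", "RT 37.5 deg diff."
    )
  )
}

# levels entering performance metrics (tutorial never analysed)
analysis_levels <- function(x) setdiff(unique(x), "tutorial")

#' Tukey quartiles and fences
#'
#' Quartiles use linear interpolation (type 7), the convention that
#' reproduces the study cohort's printed IQRs; the method is configurable
#' package-wide via `options(neglectvr.quantile_type = )`.
#'
#' @param x Numeric vector (NAs dropped).
#' @param k Fence multiplier (default 1.5).
#' @return Named list: `q1`, `q3`, `iqr`, `lower`, `upper`, `n`.
#' @export
tukey_fences <- function(x, k = 1.5) {
  x <- x[!is.na(x)]
  type <- getOption("neglectvr.quantile_type", 7L)
  qs <- unname(stats::quantile(x, c(0.25, 0.75), type = type, names = FALSE))
  iqr <- qs[2] - qs[1]
  list(
    q1 = qs[1], q3 = qs[2], iqr = iqr,
    lower = qs[1] - k * iqr, upper = qs[2] + k * iqr, n = length(x)
  )
}

#' Flag reaction-time outliers within a player
#'
#' A trial RT is an outlier when it lies strictly beyond the player's own
#' Tukey fences (`rt < Q1 - 1.5 IQR` or `rt > Q3 + 1.5 IQR`), computed over
#' the supplied RTs in a single pass (no iterative re-fencing). Strict
#' inequalities mean zero-IQR data flags nothing. Trimming is applied
#' separately per level for level metrics and once over all pooled trials
#' for spatial-preference scores.
#'
#' @param rts Numeric vector of correct-trial RTs in seconds.
#' @return A list of class `rt_trim`: `input_rts`, `outlier` (logical, the
#'   outlier Booleans), `keep` (`!outlier`), `fences` (lower, upper), `kept`
#'   (the surviving RTs).
#' @examples
#' trim_rt_outliers(c(2, 2, 2, 100))$kept # 100 s flagged, mean 2 s remains
#' @export
trim_rt_outliers <- function(rts) {
  if (!length(rts)) {
    return(structure(
      list(
        input_rts = numeric(), outlier = logical(), keep = logical(),
        fences = c(lower = NA_real_, upper = NA_real_), kept = numeric()
      ),
      class = "rt_trim"
    ))
  }
  f <- tukey_fences(rts)
  outlier <- rts < f$lower | rts > f$upper
  structure(
    list(
      input_rts = rts, outlier = outlier, keep = !outlier,
      fences = c(lower = f$lower, upper = f$upper),
      kept = rts[!outlier]
    ),
    class = "rt_trim"
  )
}

#' Per-level accuracy
#'
#' @param trials Trial tibble (rows of one level for one player).
#' @return `100 * n_correct / n_trials`, or `NA` for an empty table —
#'   missing, never zero.
#' @export
accuracy_for_level <- function(trials) {
  if (!nrow(trials)) {
    return(NA_real_)
  }
  100 * mean(trials$correct)
}

#' Per-level mean reaction time
#'
#' Mean RT over correct trials after within-player outlier trimming
#' ([trim_rt_outliers()]); missing when no correct trial survives.
#'
#' @param trials Trial tibble (one level, one player).
#' @return Seconds, or `NA`.
#' @export
rt_for_level <- function(trials) {
  rts <- trials$rt_s[trials$correct & !is.na(trials$rt_s)]
  kept <- trim_rt_outliers(rts)$kept
  if (!length(kept)) {
    return(NA_real_)
  }
  mean(kept)
}

#' Mean raycast orientation angle
#'
#' Arithmetic mean of the chosen angle over search-phase frames (`"array"`
#' frames, plus `"free"` frames from the free-viewing level); cue-phase
#' frames are excluded.
#'
#' @param frames Frame tibble.
#' @param source `"headset"` or `"controller"`.
#' @param axis `"lateral"` or `"vertical"`.
#' @param level Optional level name to filter on.
#' @return Degrees, or `NA` if no qualifying frames.
#' @export
raycast_mean <- function(frames, source = c("headset", "controller"),
                         axis = c("lateral", "vertical"), level = NULL) {
  source <- match.arg(source)
  axis <- match.arg(axis)
  col <- paste0(
    if (source == "headset") "head_" else "ctrl_",
    if (axis == "lateral") "lat" else "vert"
  )
  keep <- frames$phase %in% c("array", "free")
  if (!is.null(level)) keep <- keep & frames$level == level
  vals <- frames[[col]][keep]
  if (!length(vals)) {
    return(NA_real_)
  }
  mean(vals)
}

#' Quadrant spatial-preference score
#'
#' Trials are pooled across analysed levels and split by the quadrant of
#' the target ([assign_quadrant()]); tie ("axis") targets are excluded.
#' Subtraction order fixes the sign convention so that positive scores are
#' a right (LR) or up (UD) preference for both measures: accuracy is
#' right - left / up - down, RT is left - right / down - up. RT side means
#' use pooled trimming (one trim over all pooled correct trials, then the
#' split).
#'
#' @param trials Pooled trial tibble for one player (tutorial excluded).
#' @param contrast `"lr"` or `"ud"`.
#' @param measure `"accuracy"` (delta %) or `"rt"` (delta s).
#' @return Numeric score, or `NA` when either side has no usable trials.
#' @export
spatial_preference <- function(trials, contrast = c("lr", "ud"),
                               measure = c("accuracy", "rt")) {
  contrast <- match.arg(contrast)
  measure <- match.arg(measure)
  quad <- assign_quadrant(trials$target_lateral, trials$target_vertical)
  sides <- if (contrast == "lr") c("right", "left") else c("up", "down")
  pos <- trials[quad == sides[1], , drop = FALSE]
  neg <- trials[quad == sides[2], , drop = FALSE]
  if (measure == "accuracy") {
    a_pos <- accuracy_for_level(pos)
    a_neg <- accuracy_for_level(neg)
    if (is.na(a_pos) || is.na(a_neg)) {
      return(NA_real_)
    }
    return(a_pos - a_neg)
  }
  # pooled trimming before the contrast split
  kept <- pooled_kept_rts(trials)
  quad_k <- assign_quadrant(kept$target_lateral, kept$target_vertical)
  rt_pos <- kept$rt_s[quad_k == sides[1]]
  rt_neg <- kept$rt_s[quad_k == sides[2]]
  if (!length(rt_pos) || !length(rt_neg)) {
    return(NA_real_)
  }
  # positive = faster on the right/up side
  mean(rt_neg) - mean(rt_pos)
}

# correct trials surviving one pooled within-player trim
pooled_kept_rts <- function(trials) {
  ok <- trials$correct & !is.na(trials$rt_s)
  sub <- trials[ok, , drop = FALSE]
  if (!nrow(sub)) {
    return(sub)
  }
  sub[trim_rt_outliers(sub$rt_s)$keep, , drop = FALSE]
}

#' Eccentricity spatial-preference score
#'
#' Contrasts trials whose target eccentricity matches the two members of an
#' adjacent ring pair, pooled across levels. With the default sign
#' convention positive scores are a central advantage: accuracy is
#' central - peripheral, RT is peripheral - central. Set
#' `options(neglectvr.ecc_sign = -1)` to flip.
#'
#' @param trials Pooled trial tibble for one player.
#' @param pair `"ecc25"` (12.5 vs 25.0 deg) or `"ecc37"` (25.0 vs 37.5 deg).
#' @param measure `"accuracy"` or `"rt"`.
#' @param tol Eccentricity match tolerance in degrees.
#' @return Numeric score, or `NA` when either eccentricity has no usable
#'   trials.
#' @export
eccentricity_preference <- function(trials, pair = c("ecc25", "ecc37"),
                                    measure = c("accuracy", "rt"), tol = 0.25) {
  pair <- match.arg(pair)
  measure <- match.arg(measure)
  eccs <- if (pair == "ecc25") c(12.5, 25.0) else c(25.0, 37.5)
  sgn <- getOption("neglectvr.ecc_sign", 1)
  central <- trials[abs(trials$target_ecc - eccs[1]) <= tol, , drop = FALSE]
  periph <- trials[abs(trials$target_ecc - eccs[2]) <= tol, , drop = FALSE]
  if (measure == "accuracy") {
    a_c <- accuracy_for_level(central)
    a_p <- accuracy_for_level(periph)
    if (is.na(a_c) || is.na(a_p)) {
      return(NA_real_)
    }
    return(sgn * (a_c - a_p))
  }
  kept <- pooled_kept_rts(trials)
  rt_c <- kept$rt_s[abs(kept$target_ecc - eccs[1]) <= tol]
  rt_p <- kept$rt_s[abs(kept$target_ecc - eccs[2]) <= tol]
  if (!length(rt_c) || !length(rt_p)) {
    return(NA_real_)
  }
  sgn * (mean(rt_p) - mean(rt_c))
}

#' Compute the full metric vector for one player
#'
#' Assembles the six per-level metrics for every analysed level present in
#' the session (tutorial excluded; free viewing contributes raycast metrics
#' only) and the eight pooled spatial-preference scores. Every cell needs
#' at least one qualifying observation, otherwise it is missing (`NA`),
#' never zero-imputed.
#'
#' @param session A [player_session()].
#' @return A tibble with columns `player_id`, `group`, `metric`, `level`
#'   (`NA` for pooled metrics), `value`. Rows are emitted for every metric
#'   x analysed level combination so missingness is explicit.
#' @export
compute_metric_vector <- function(session) {
  stopifnot(inherits(session, "player_session"))
  tr <- session$trials[session$trials$level != "tutorial", , drop = FALSE]
  fr <- session$frames[session$frames$level != "tutorial", , drop = FALSE]
  levels <- analysis_levels(c(tr$level, fr$level))
  if (!length(levels) && !nrow(tr)) {
    warning("session ", session$player_id, " has no analysable levels; all metrics missing",
      call. = FALSE
    )
  }

  per_level <- purrr::map_dfr(levels, function(lv) {
    t_lv <- tr[tr$level == lv, , drop = FALSE]
    tibble::tibble(
      metric = c("accuracy", "rt", "head_lat", "head_vert", "ctrl_lat", "ctrl_vert"),
      level = lv,
      value = c(
        accuracy_for_level(t_lv),
        rt_for_level(t_lv),
        raycast_mean(fr, "headset", "lateral", lv),
        raycast_mean(fr, "headset", "vertical", lv),
        raycast_mean(fr, "controller", "lateral", lv),
        raycast_mean(fr, "controller", "vertical", lv)
      )
    )
  })
  pooled <- tibble::tibble(
    metric = c(
      "acc_lr", "acc_ud", "acc_ecc25", "acc_ecc37",
      "rt_lr", "rt_ud", "rt_ecc25", "rt_ecc37"
    ),
    level = NA_character_,
    value = c(
      spatial_preference(tr, "lr", "accuracy"),
      spatial_preference(tr, "ud", "accuracy"),
      eccentricity_preference(tr, "ecc25", "accuracy"),
      eccentricity_preference(tr, "ecc37", "accuracy"),
      spatial_preference(tr, "lr", "rt"),
      spatial_preference(tr, "ud", "rt"),
      eccentricity_preference(tr, "ecc25", "rt"),
      eccentricity_preference(tr, "ecc37", "rt")
    )
  )
  dplyr::bind_rows(per_level, pooled) |>
    dplyr::mutate(
      player_id = session$player_id, group = session$group,
      .before = 1
    )
}

#' Compute metrics for a whole cohort
#'
#' @param sessions List of [player_session()] objects.
#' @return Long tibble, the row-bound [compute_metric_vector()] of every
#'   session.
#' @export
compute_metrics <- function(sessions) {
  purrr::map_dfr(sessions, compute_metric_vector)
}
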