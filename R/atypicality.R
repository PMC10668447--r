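#' Double-reference Tukey-fence atypicality
#'
#' The normative model: for each attention metric (and game level, for the
#' per-level metrics), quartiles and Tukey fences are estimated separately
#' in the control and the patient reference groups. A player's value is
#' *atypical* (Boolean 1) when it lies strictly beyond the 1.5 x IQR fences
#' of BOTH reference distributions:
#'
#' \deqn{B = [(M < Q1_c - 1.5\,IQR_c) \lor (M > Q3_c + 1.5\,IQR_c)] \land
#'           [(M < Q1_p - 1.5\,IQR_p) \lor (M > Q3_p + 1.5\,IQR_p)]}
#'
#' Per-level metrics are summarised across game levels as the mean of the
#' per-level Booleans — a proportion in \[0, 1\]; pooled metrics contribute a
#' single Boolean. The player x metric table of these values is the summary
#' matrix.
#'
#' @name atypicality
NULL

#' Reference-group quartiles and fences for one metric (x level)
#'
#' @param values Numeric metric values of one group's players (NAs dropped).
#' @param metric,level,group Labels carried into the output.
#' @return A one-row tibble (`group_fences`): `metric`, `level`, `group`,
#'   `q1`, `q3`, `iqr`, `lower`, `upper`, `n`. With fewer than two
#'   non-missing values the quartiles are undefined and all fence fields
#'   are `NA` (downstream cells become missing, with a warning).
#' @export
group_fences <- function(values, metric = NA_character_, level = NA_character_,
                         group = NA_character_) {
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    warning(
      "fewer than 2 values for ", group, " fences on ", metric,
      if (!is.na(level)) paste0(" x ", level), "; fences undefined",
      call. = FALSE
    )
    return(tibble::tibble(
      metric = metric, level = level, group = group,
      q1 = NA_real_, q3 = NA_real_, iqr = NA_real_,
      lower = NA_real_, upper = NA_real_, n = length(values)
    ))
  }
  f <- tukey_fences(values)
  tibble::tibble(
    metric = metric, level = level, group = group,
    q1 = f$q1, q3 = f$q3, iqr = f$iqr,
    lower = f$lower, upper = f$upper, n = f$n
  )
}

#' Atypicality Boolean for one value against two reference fences
#'
#' @param value Metric value (vectorised).
#' @param control_fences,patient_fences One-row tibbles (or lists) with
#'   `lower` and `upper`.
#' @return Logical: `TRUE` iff the value is strictly outside both groups'
#'   fences; `NA` where the value or either fence set is missing.
#' @export
atypical_flag <- function(value, control_fences, patient_fences) {
  out_c <- value < control_fences$lower | value > control_fences$upper
  out_p <- value < patient_fences$lower | value > patient_fences$upper
  out_c & out_p
}

#' Build the player x metric atypicality summary matrix
#'
#' Fences are estimated per metric x level (per metric for pooled scores)
#' within each reference group, including the evaluated player in their own
#' group's quartiles (set `leave_one_out = TRUE` to hold each player out of
#' their own group's fences). Per-level Booleans are averaged over the
#' player's non-missing levels; a missing level is dropped from the
#' denominator, never counted as typical. Cells whose value or fences are
#' missing stay missing. Groups smaller than 2 give undefined fences and
#' missing cells.
#'
#' @param metrics Long metric tibble from [compute_metrics()].
#' @param leave_one_out Hold the evaluated player out of their own group's
#'   fence estimation (default `FALSE`).
#' @return An `atypicality_matrix` object: a list with
#'   * `values` — players x 14 numeric matrix of proportions in \[0, 1\]
#'     (`NA` = missing),
#'   * `groups` — named character vector of group labels,
#'   * `flags` — tibble of the finest-grain Booleans (`player_id`, `group`,
#'     `metric`, `level`, `value`, `flag`),
#'   * `fences` — tibble of all [group_fences()] rows.
#' @export
build_summary_matrix <- function(metrics, leave_one_out = FALSE) {
  stopifnot(all(c("player_id", "group", "metric", "level", "value") %in% names(metrics)))
  players <- unique(metrics$player_id)
  groups <- metrics |>
    dplyr::distinct(.data$player_id, .data$group) |>
    (\(d) stats::setNames(d$group, d$player_id))()

  cells <- dplyr::distinct(metrics, .data$metric, .data$level)
  fence_rows <- list()
  flag_rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    m <- cells$metric[[i]]
    lv <- cells$level[[i]]
    sub <- metrics[metrics$metric == m & (metrics$level %in% lv | (is.na(lv) & is.na(metrics$level))), , drop = FALSE]
    fc <- group_fences(sub$value[sub$group == "control"], m, lv, "controls")
    fp <- group_fences(sub$value[sub$group == "patient"], m, lv, "patients")
    fence_rows[[length(fence_rows) + 1L]] <- dplyr::bind_rows(fc, fp)
    flag <- if (leave_one_out) {
      vapply(seq_len(nrow(sub)), function(j) {
        own <- sub$group[[j]]
        keep <- sub$player_id != sub$player_id[[j]]
        fc_j <- if (own == "control") {
          suppressWarnings(group_fences(sub$value[keep & sub$group == "control"]))
        } else {
          fc
        }
        fp_j <- if (own == "patient") {
          suppressWarnings(group_fences(sub$value[keep & sub$group == "patient"]))
        } else {
          fp
        }
        atypical_flag(sub$value[[j]], fc_j, fp_j)
      }, logical(1))
    } else {
      atypical_flag(sub$value, fc, fp)
    }
    flag_rows[[i]] <- dplyr::mutate(sub, flag = flag)
  }
  flags <- dplyr::bind_rows(flag_rows)
  fences <- dplyr::bind_rows(fence_rows)

  cellvals <- flags |>
    dplyr::group_by(.data$player_id, .data$metric) |>
    dplyr::summarise(
      value = if (all(is.na(.data$flag))) NA_real_ else mean(.data$flag, na.rm = TRUE),
      .groups = "drop"
    )
  mnames <- metric_names()$metric
  values <- matrix(NA_real_,
    nrow = length(players), ncol = length(mnames),
    dimnames = list(players, mnames)
  )
  present <- cellvals$metric %in% mnames
  idx <- cbind(
    match(cellvals$player_id[present], players),
    match(cellvals$metric[present], mnames)
  )
  values[idx] <- cellvals$value[present]

  structure(
    list(
      values = values,
      groups = groups[players],
      flags = flags,
      fences = fences
    ),
    class = "atypicality_matrix"
  )
}

#' Mean atypicality per player
#'
#' Mean of the non-missing summary-matrix cells in each player's row — an
#' overall atypicality proportion in \[0, 1\]. All-missing rows give `NA`.
#'
#' @param matrix An `atypicality_matrix` from [build_summary_matrix()].
#' @return A tibble: `player_id`, `group`, `mean_atypicality`,
#'   `n_metrics` (non-missing cells), `n_flagged` (cells with value > 0).
#' @export
mean_atypicality <- function(matrix) {
  stopifnot(inherits(matrix, "atypicality_matrix"))
  v <- matrix$values
  tibble::tibble(
    player_id = rownames(v),
    group = unname(matrix$groups[rownames(v)]),
    mean_atypicality = unname(apply(v, 1, function(r) {
      if (all(is.na(r))) NA_real_ else mean(r, na.rm = TRUE)
    })),
    n_metrics = unname(apply(v, 1, function(r) sum(!is.na(r)))),
    n_flagged = unname(apply(v, 1, function(r) sum(r > 0, na.rm = TRUE)))
  )
}

#' @export
print.atypicality_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "<atypicality_matrix> %d players x %d metrics (%d patients, %d controls)\n",
    nrow(v), ncol(v),
    sum(x$groups == "patient"), sum(x$groups == "control")
  ))
  cat(sprintf(
    "  cells: %d atypical > 0, %d missing\n",
    sum(v > 0, na.rm = TRUE), sum(is.na(v))
  ))
  invisible(x)
}

#' Export an atypicality analysis to CSV/JSON files
#'
#' Writes `summary_matrix.csv` (players x 14 metric columns, `NA` for
#' missing), `fences.csv`, and `atypicality_summary.json` (per-player mean
#' atypicality and flagged metric list).
#'
#' @param matrix An `atypicality_matrix`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_atypicality <- function(matrix, dir) {
  stopifnot(inherits(matrix, "atypicality_matrix"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sm <- tibble::as_tibble(matrix$values, rownames = "player_id") |>
    dplyr::mutate(group = unname(matrix$groups[.data$player_id]), .after = "player_id")
  p1 <- file.path(dir, "summary_matrix.csv")
  readr::write_csv(sm, p1, progress = FALSE)
  p2 <- file.path(dir, "fences.csv")
  readr::write_csv(matrix$fences, p2, progress = FALSE)
  ma <- mean_atypicality(matrix)
  flagged <- lapply(rownames(matrix$values), function(p) {
    r <- matrix$values[p, ]
    names(r)[!is.na(r) & r > 0]
  })
  names(flagged) <- rownames(matrix$values)
  summary <- lapply(seq_len(nrow(ma)), function(i) {
    list(
      player_id = ma$player_id[[i]],
      group = ma$group[[i]],
      mean_atypicality = ma$mean_atypicality[[i]],
      flagged_metrics = as.list(flagged[[ma$player_id[[i]]]])
    )
  })
  p3 <- file.path(dir, "atypicality_summary.json")
  jsonlite::write_json(summary, p3, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(list(summary_matrix = p1, fences = p2, summary = p3))
}
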