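#' Case reports, raycast histograms, and the end-to-end pipeline
#'
#' Figure outputs are data exports (histogram grids, summary tables) rather
#' than styled plots; `plot_raycast_histogram()` offers a thin optional
#' rendering layer when ggplot2 is available.
#'
#' @name reporting
NULL

#' 2-D raycast orientation histogram
#'
#' Bins search-phase (array / free-viewing) orientation frames into a
#' 100 x 100 grid with bounds -50 to +50 degrees and 1-degree half-open
#' bins `[edge, edge + 1)`. Out-of-bounds frames are excluded from the
#' counts but reported, so `sum(counts) + excluded` equals the number of
#' qualifying input frames.
#'
#' @param frames Frame tibble.
#' @param source `"headset"` or `"controller"`.
#' @param level Optional level name filter.
#' @param lim Half-width of the bounds in degrees (default 50).
#' @param bin Bin width in degrees (default 1).
#' @return A `raycast_histogram`: list with `counts` (lateral x vertical
#'   integer matrix), `edges` (bin lower edges), `excluded`, `source`,
#'   `level`, `n_frames`.
#' @export
raycast_histogram <- function(frames, source = c("headset", "controller"),
                              level = NULL, lim = 50, bin = 1) {
  source <- match.arg(source)
  pre <- if (source == "headset") "head_" else "ctrl_"
  keep <- frames$phase %in% c("array", "free")
  if (!is.null(level)) keep <- keep & frames$level == level
  lat <- frames[[paste0(pre, "lat")]][keep]
  vert <- frames[[paste0(pre, "vert")]][keep]
  edges <- seq(-lim, lim - bin, by = bin)
  nb <- length(edges)
  inb <- lat >= -lim & lat < lim & vert >= -lim & vert < lim
  ix <- floor((lat[inb] + lim) / bin) + 1
  iy <- floor((vert[inb] + lim) / bin) + 1
  counts <- matrix(0L, nb, nb, dimnames = list(lateral = edges, vertical = edges))
  if (any(inb)) {
    tab <- table(factor(ix, levels = seq_len(nb)), factor(iy, levels = seq_len(nb)))
    counts[] <- as.integer(tab)
  }
  structure(
    list(
      counts = counts, edges = edges, excluded = sum(!inb),
      source = source, level = level, n_frames = length(lat)
    ),
    class = "raycast_histogram"
  )
}

#' @export
print.raycast_histogram <- function(x, ...) {
  cat(sprintf(
    "<raycast_histogram> %s%s: %d frames binned, %d out of bounds\n",
    x$source, if (!is.null(x$level)) paste0(" / ", x$level) else "",
    sum(x$counts), x$excluded
  ))
  invisible(x)
}

#' Optional rendering of a raycast histogram
#'
#' @param hist A [raycast_histogram()].
#' @return A ggplot object (requires ggplot2).
#' @export
plot_raycast_histogram <- function(hist) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  df <- expand.grid(lateral = hist$edges, vertical = hist$edges)
  df$count <- as.vector(hist$counts)
  ggplot2::ggplot(df, ggplot2::aes(.data$lateral, .data$vertical, fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "lateral (deg)", y = "vertical (deg)",
      title = paste(hist$source, hist$level %||% "", "raycast map")
    )
}

#' Structured case report for one player
#'
#' Bundles the player's metric values with the reference fences and flags,
#' mean atypicality, per-level raycast histograms, and a strengths-first
#' narrative (descriptive wording; never phrases like "attention deficit").
#' Output is the package's case-report document and validates against
#' [validate_case_report()].
#'
#' @param session The player's [player_session()].
#' @param matrix The cohort `atypicality_matrix` (must contain the player).
#' @return A `case_report` list, serialisable with
#'   `jsonlite::write_json(..., auto_unbox = TRUE)`.
#' @export
case_report <- function(session, matrix) {
  stopifnot(inherits(session, "player_session"), inherits(matrix, "atypicality_matrix"))
  id <- session$player_id
  if (!id %in% rownames(matrix$values)) {
    stop("player ", id, " is not part of the summary matrix", call. = FALSE)
  }
  row <- matrix$values[id, ]
  flagged <- names(row)[!is.na(row) & row > 0]
  ma <- mean_atypicality(matrix)
  flags <- matrix$flags[matrix$flags$player_id == id, , drop = FALSE]
  levels <- setdiff(unique(c(session$trials$level, session$frames$level)), "tutorial")
  hists <- list()
  for (src in c("headset", "controller")) {
    for (lv in levels) {
      h <- raycast_histogram(session$frames, src, lv)
      hists[[paste(src, lv, sep = ".")]] <- list(
        source = src, level = lv, edges = h$edges,
        counts = h$counts, excluded = h$excluded
      )
    }
  }
  typical <- setdiff(names(row)[!is.na(row) & row == 0], flagged)
  narrative <- c(
    sprintf(
      "Player %s completed %d trials across %d level(s): %s.",
      id, nrow(session$trials), length(levels), paste(levels, collapse = ", ")
    ),
    sprintf(
      "Gameplay was within the typical range on %d of %d measured metrics.",
      length(typical), sum(!is.na(row))
    ),
    if (length(flagged)) {
      sprintf(
        "Measures outside the typical range, which may merit a closer look: %s.",
        paste(flagged, collapse = ", ")
      )
    } else {
      "No measures fell outside the typical range."
    }
  )
  structure(
    list(
      player_id = id,
      group = session$group,
      levels_completed = levels,
      n_trials = nrow(session$trials),
      metrics = flags[, c("metric", "level", "value", "flag")],
      summary_row = as.list(row),
      mean_atypicality = ma$mean_atypicality[ma$player_id == id],
      flagged_metrics = flagged,
      histograms = hists,
      narrative = narrative
    ),
    class = "case_report"
  )
}

#' Validate the structure of a case report
#'
#' Structural schema check: required fields present and well-typed,
#' summary-row values in \[0, 1\], histogram conservation.
#'
#' @param report A [case_report()].
#' @return `TRUE` (invisibly) or an error describing the violation.
#' @export
validate_case_report <- function(report) {
  need <- c(
    "player_id", "group", "levels_completed", "n_trials", "metrics",
    "summary_row", "mean_atypicality", "flagged_metrics", "histograms",
    "narrative"
  )
  miss <- setdiff(need, names(report))
  if (length(miss)) stop("case report missing fields: ", paste(miss, collapse = ", "), call. = FALSE)
  vals <- unlist(report$summary_row)
  vals <- vals[!is.na(vals)]
  if (any(vals < 0 | vals > 1)) stop("summary-row values must lie in [0, 1]", call. = FALSE)
  if (!report$group %in% c("patient", "control")) stop("bad group label", call. = FALSE)
  for (h in report$histograms) {
    if (any(h$counts < 0)) stop("negative histogram counts", call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' read (or accept) sessions -> attention metrics -> atypicality summary
#' matrix -> group statistics -> case reports, writing every artefact to
#' `out_dir`: `metrics.csv`, `summary_matrix.csv`, `fences.csv`,
#' `atypicality_summary.json`, `group_stats.json`, `reports/<player>.json`,
#' and `run_log.txt` (one line per stage with row counts). Any stage
#' failure aborts with a stage-named error and removes partial outputs.
#'
#' @param sessions List of [player_session()] objects, or `NULL` to read
#'   from `trials_path` / `frames_path` / `demographics_path`.
#' @param out_dir Output directory.
#' @param trials_path,frames_path,demographics_path Input CSVs when
#'   `sessions` is `NULL`.
#' @param leave_one_out Passed to [build_summary_matrix()].
#' @param grain Passed to [group_stats()].
#' @param write_reports Write per-player case-report JSONs.
#' @return Invisibly, a list with `metrics`, `matrix`, `stats`, and
#'   `paths`.
#' @export
run_pipeline <- function(sessions = NULL, out_dir,
                         trials_path = NULL, frames_path = NULL,
                         demographics_path = NULL,
                         leave_one_out = FALSE, grain = "boolean",
                         write_reports = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  logf <- function(stage, msg) {
    cat(sprintf("[%s] %s\n", stage, msg), file = log_path, append = TRUE)
  }
  cat("", file = log_path)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      unlink(out_dir, recursive = TRUE)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  sessions <- run_stage("read", {
    s <- sessions %||% read_sessions(trials_path, frames_path, demographics_path)
    logf("read", sprintf(
      "%d sessions, %d trials, %d frames", length(s),
      sum(vapply(s, function(x) nrow(x$trials), integer(1))),
      sum(vapply(s, function(x) nrow(x$frames), integer(1)))
    ))
    s
  })
  metrics <- run_stage("metrics", {
    m <- compute_metrics(sessions)
    readr::write_csv(
      dplyr::mutate(m,
        level_or_pooled = dplyr::coalesce(.data$level, "pooled"),
        missing = is.na(.data$value)
      ),
      file.path(out_dir, "metrics.csv"),
      progress = FALSE
    )
    logf("metrics", sprintf("%d metric rows for %d players", nrow(m), length(sessions)))
    m
  })
  matrix <- run_stage("atypicality", {
    mt <- build_summary_matrix(metrics, leave_one_out = leave_one_out)
    write_atypicality(mt, out_dir)
    logf("atypicality", sprintf(
      "%d x %d summary matrix, %d missing cells",
      nrow(mt$values), ncol(mt$values), sum(is.na(mt$values))
    ))
    mt
  })
  stats <- run_stage("group-stats", {
    st <- group_stats(matrix, grain = grain)
    jsonlite::write_json(
      list(
        counts = as.data.frame(st$counts),
        chisq = st$chisq, rank_sum = st$rank_sum, levene = st$levene,
        prevalence = st$prevalence, options = st$options
      ),
      file.path(out_dir, "group_stats.json"),
      auto_unbox = TRUE, digits = NA, na = "null"
    )
    logf("group-stats", sprintf(
      "chisq = %.3f, p = %.4g on %d counts",
      st$chisq$statistic, st$chisq$p, sum(st$counts)
    ))
    st
  })
  paths <- list(
    metrics = file.path(out_dir, "metrics.csv"),
    summary_matrix = file.path(out_dir, "summary_matrix.csv"),
    fences = file.path(out_dir, "fences.csv"),
    group_stats = file.path(out_dir, "group_stats.json"),
    log = log_path
  )
  if (write_reports) {
    run_stage("report", {
      rep_dir <- file.path(out_dir, "reports")
      dir.create(rep_dir, showWarnings = FALSE)
      for (s in sessions) {
        rp <- case_report(s, matrix)
        validate_case_report(rp)
        jsonlite::write_json(
          unclass(rp), file.path(rep_dir, paste0(s$player_id, ".json")),
          auto_unbox = TRUE, digits = NA, na = "null", matrix = "rowmajor"
        )
      }
      logf("report", sprintf("%d case reports", length(sessions)))
      paths$reports <- rep_dir
    })
  }
  invisible(list(metrics = metrics, matrix = matrix, stats = stats, paths = paths))
}
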