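#' Feasibility and demographic instrument scoring
#'
#' Scoring for the instruments used around gameplay: a single-category
#' simulator sickness rating (SSQ), the revised Game Experience
#' Questionnaire (GEQ-R, 25 five-point items, four factor means), the
#' System Usability Scale (SUS, 10 five-point items, 0-100 with
#' acceptability bands), and Functional Independence Measure (FIM)
#' normalisation to the 1-7 item scale.
#'
#' @name questionnaires
NULL

SSQ_LABELS <- c(
  "no symptoms", "stomach awareness", "mild nausea", "moderate nausea",
  "severe nausea", "retching", "vomiting"
)

#' Simulator-sickness eligibility
#'
#' Players are eligible when their SSQ category is below moderate nausea
#' (strictly less than category 4).
#'
#' @param category Integer 1-7 (1 = no symptoms ... 7 = vomiting).
#' @return Logical (vectorised).
#' @export
ssq_eligibility <- function(category) {
  if (any(is.na(category)) || any(category < 1 | category > 7 | category != round(category))) {
    stop("SSQ category must be an integer in 1..7", call. = FALSE)
  }
  category < 4
}

#' Default GEQ-R item-to-factor mapping
#'
#' The instrument's 25 items map each to exactly one of four factors:
#' positive affect, competence, negativity, and flow. The published
#' instrument does not ship its mapping with this package's sources, so
#' the default mapping here is an editable configuration — a CSV with
#' columns `item` (1-25) and `factor` — shipped at
#' `system.file("extdata", "geq_item_map.csv", package = "neglectvr")` and
#' replaceable via the `map` argument of [geq_factors()].
#'
#' @return Tibble with columns `item`, `factor`.
#' @export
geq_default_map <- function() {
  path <- system.file("extdata", "geq_item_map.csv", package = "neglectvr")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' GEQ-R factor means
#'
#' Each factor is the arithmetic mean of its items (scale 1-5). A factor
#' with any missing item is missing.
#'
#' @param items Numeric vector of 25 item scores in 1-5, in item order.
#' @param map Item-to-factor mapping tibble (`item`, `factor`);
#'   default [geq_default_map()].
#' @return Named numeric vector: `positive_affect`, `competence`,
#'   `negativity`, `flow`.
#' @export
geq_factors <- function(items, map = geq_default_map()) {
  if (length(items) != 25) stop("GEQ-R has 25 items", call. = FALSE)
  if (any(!is.na(items) & (items < 1 | items > 5))) {
    stop("GEQ-R items are scored 1..5", call. = FALSE)
  }
  factors <- c("positive_affect", "competence", "negativity", "flow")
  if (!setequal(unique(map$factor), factors) || !setequal(map$item, 1:25)) {
    stop("item map must assign each of items 1..25 to exactly one of the four factors",
      call. = FALSE
    )
  }
  vapply(factors, function(f) {
    vals <- items[map$item[map$factor == f]]
    if (any(is.na(vals))) NA_real_ else mean(vals)
  }, numeric(1))
}

#' System Usability Scale score and category
#'
#' Standard scoring: odd items contribute `score - 1`, even items
#' `5 - score`; the sum is scaled by 2.5 to 0-100. Categories use
#' lower-inclusive cut-offs: acceptable \[70, 100\], marginal \[50, 70),
#' unacceptable \[0, 50).
#'
#' @param items Numeric vector of 10 item scores in 1-5, in item order.
#' @return List: `score` (0-100), `category`.
#' @examples
#' sus_score(rep(3, 10))$score # 50
#' @export
sus_score <- function(items) {
  if (length(items) != 10 || any(is.na(items))) {
    stop("SUS needs a complete 10-item response", call. = FALSE)
  }
  if (any(items < 1 | items > 5)) stop("SUS items are scored 1..5", call. = FALSE)
  odd <- items[c(1, 3, 5, 7, 9)] - 1
  even <- 5 - items[c(2, 4, 6, 8, 10)]
  score <- 2.5 * sum(odd, even)
  category <- if (score >= 70) "acceptable" else if (score >= 50) "marginal" else "unacceptable"
  list(score = score, category = category)
}

#' Normalise FIM raw sums to the 1-7 item scale
#'
#' The FIM rates 18 activities of daily living on a 7-point scale,
#' composed of a 13-item Motor and a 5-item Cognition subscale. Raw
#' subscale sums are normalised by their item counts; the total is the
#' combined sum over 18 items.
#'
#' @param raw_motor Motor subscale sum, in \[13, 91\].
#' @param raw_cognition Cognition subscale sum, in \[5, 35\].
#' @return Named numeric vector: `motor`, `cognition`, `total`, each on
#'   1-7.
#' @export
fim_normalise <- function(raw_motor, raw_cognition) {
  if (raw_motor < 13 || raw_motor > 91) {
    stop("raw motor sum must lie in [13, 91]", call. = FALSE)
  }
  if (raw_cognition < 5 || raw_cognition > 35) {
    stop("raw cognition sum must lie in [5, 35]", call. = FALSE)
  }
  c(
    motor = raw_motor / 13,
    cognition = raw_cognition / 5,
    total = (raw_motor + raw_cognition) / 18
  )
}

#' Participant eligibility screen
#'
#' Eligible participants are not strongly susceptible to motion sickness
#' (SSQ below moderate nausea) and show high cognitive functioning on the
#' orientation-to-time-and-space questions (score >= 6 of 10).
#'
#' @param ssq_category SSQ rating 1-7.
#' @param mmse_orientation Orientation score 0-10.
#' @return Logical.
#' @export
eligibility_screen <- function(ssq_category, mmse_orientation) {
  if (any(mmse_orientation < 0 | mmse_orientation > 10)) {
    stop("orientation score must lie in 0..10", call. = FALSE)
  }
  ssq_eligibility(ssq_category) & mmse_orientation >= 6
}
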