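#' @title Decision values, staging, treatment recommendation, efficacy
#' @description Maps the four One-vs-Rest confidences to a scalar clinical
#'   decision value, looks the value up in the staging map, recommends a
#'   treatment, and assesses treatment efficacy across a patient's
#'   examination trajectory.
#' @name diagnosis
NULL

#' The decision-value staging map
#'
#' Ordered, contiguous intervals over the decision-value axis: healthy
#' `[0, 18)`, stage I `[18, 58)`, stage II `[58, 119)`, stage III
#' `[119, 180]` (the shared endpoint 119 and the endpoint 180 both belong to
#' III), stage IV `(180, Inf)`. `iv_cap` is the finite pseudo-upper bound of
#' the stage-IV interval used only when interpolating a decision value from
#' confidences.
#'
#' @param breaks Numeric interior break points `c(18, 58, 119, 180)`.
#' @param iv_cap Finite width cap for the open stage-IV interval.
#' @return A list of class `staging_map`.
#' @export
staging_map <- function(breaks = c(18, 58, 119, 180), iv_cap = 400) {
  stopifnot(length(breaks) == 4L, !is.unsorted(breaks, strictly = TRUE),
            breaks[1] > 0, iv_cap > breaks[4])
  structure(list(breaks = breaks, iv_cap = iv_cap,
                 categories = c("healthy", stage_levels)),
            class = "staging_map")
}

#' Stage category of a decision value
#'
#' Total, piecewise-constant and monotone in `v` under the order
#' healthy < I < II < III < IV.
#'
#' @param v Non-negative decision value (vectorised).
#' @param map A [staging_map()].
#' @return Character category in `c("healthy","I","II","III","IV")`.
#' @export
#' @examples
#' stage_from_decision_value(233.52)  # "IV"
#' stage_from_decision_value(10)      # "healthy"
stage_from_decision_value <- function(v, map = staging_map()) {
  stopifnot(inherits(map, "staging_map"))
  if (any(v < 0)) stop("decision value must be non-negative")
  b <- map$breaks
  vapply(v, function(vi) {
    if (vi < b[1]) "healthy"
    else if (vi < b[2]) "I"
    else if (vi < b[3]) "II"
    else if (vi <= b[4]) "III"    # both 119 and 180 belong to stage III
    else "IV"
  }, character(1))
}

#' Decision value from the four OvR confidences
#'
#' If the best confidence is below `nsclc_threshold` the record is read as
#' non-NSCLC and the value falls in the healthy interval (linear in the best
#' confidence). Otherwise the winning stage's confidence, rescaled from
#' `[threshold, 1]` to `[0, 1)`, interpolates linearly across that stage's
#' interval, which guarantees the round trip
#' `stage_from_decision_value(decision_value(c)) == argmax stage`.
#'
#' @param confidences Named numeric vector of per-stage `eta` values in
#'   `[0, 1]` (names among `c("I","II","III","IV")`).
#' @param map A [staging_map()].
#' @param nsclc_threshold Minimum winning confidence to call NSCLC.
#' @return A single non-negative decision value.
#' @export
decision_value <- function(confidences, map = staging_map(),
                           nsclc_threshold = 0.5) {
  if (!length(confidences)) stop("empty confidence map")
  stopifnot(all(names(confidences) %in% stage_levels),
            all(confidences >= 0 & confidences <= 1))
  full <- stats::setNames(numeric(4), stage_levels)
  full[names(confidences)] <- confidences
  best <- which.max(full)   # ties: earliest stage wins
  eta <- full[best]
  b <- map$breaks
  if (eta < nsclc_threshold) {
    return(unname(b[1] * eta / nsclc_threshold))
  }
  lo <- c(b[1], b[2], b[3], b[4])[best]
  hi <- c(b[2], b[3], b[4], map$iv_cap)[best]
  frac <- (eta - nsclc_threshold) / (1 - nsclc_threshold)
  # stage III owns its upper endpoint, the others are half-open: keep the
  # interpolant strictly inside every interval so the round trip holds
  v <- lo + frac * (hi - lo) * (1 - 1e-9)
  if (best == 4L) v <- max(v, b[4] + 1e-9)  # IV is open at 180
  unname(v)
}

treatment_rules <- list(
  coarse = list(
    healthy = list(primary = "further_tests", adjuvant = NA_character_),
    I   = list(primary = "surgery", adjuvant = NA_character_),
    II  = list(primary = "surgery", adjuvant = NA_character_),
    III = list(primary = "radiochemotherapy", adjuvant = "surgery"),
    IV  = list(primary = "radiochemotherapy", adjuvant = "surgery")
  ),
  stagewise = list(
    healthy = list(primary = "further_tests", adjuvant = NA_character_),
    I   = list(primary = "drug_therapy", adjuvant = NA_character_),
    II  = list(primary = "surgery", adjuvant = NA_character_),
    III = list(primary = "radiation_therapy", adjuvant = NA_character_),
    IV  = list(primary = "chemotherapy", adjuvant = NA_character_)
  )
)

#' Recommend a treatment strategy for a stage
#'
#' The default `"coarse"` profile recommends surgery as primary treatment
#' for operable early disease (I, II) and radiochemotherapy with surgery as
#' adjuvant for III/IV; `"stagewise"` is the finer per-stage rule used when
#' tracking a treatment trajectory (IV chemotherapy, III radiation therapy,
#' II surgery, I late-stage drug therapy). A healthy call always recommends
#' further confirmatory tests.
#'
#' @param stage Category in `c("healthy","I","II","III","IV")`.
#' @param profile `"coarse"` (default) or `"stagewise"`, or a custom rule
#'   table shaped like the built-ins.
#' @return A list `(stage, primary, adjuvant)`.
#' @export
#' @examples
#' recommend_treatment("II")$primary            # "surgery"
#' recommend_treatment("IV", "stagewise")$primary  # "chemotherapy"
recommend_treatment <- function(stage, profile = "coarse") {
  rules <- if (is.list(profile)) profile else {
    if (!profile %in% names(treatment_rules)) {
      stop("unknown treatment profile: ", profile)
    }
    treatment_rules[[profile]]
  }
  if (!stage %in% names(rules)) stop("unknown stage category: ", stage)
  c(list(stage = stage), rules[[stage]])
}

#' Assess treatment efficacy over an examination trajectory
#'
#' Compares each marker's first and last value along a patient's trajectory
#' (ordered by `exam_index`) and, when staging predictions are supplied, the
#' decision values before and after treatment. Treatment is flagged
#' effective when the decision value dropped by at least `threshold`
#' (default 40, one stage-I-band width). Markers missing from either the
#' first or last exam are flagged indeterminate and excluded.
#'
#' @param trajectory List of `patient_record`s, length `>= 2`.
#' @param predictions Optional list of `stage_prediction`s (same length) as
#'   produced by [predict_stage()].
#' @param threshold Minimum decision-value drop called significant.
#' @return A list of class `efficacy_report`: `markers` (data frame with
#'   `marker`, `first`, `last`, `decreased`), `decision_value_before`,
#'   `decision_value_after`, `delta`, `effective`.
#' @export
assess_treatment <- function(trajectory, predictions = NULL, threshold = 40) {
  if (length(trajectory) < 2L) stop("trajectory must contain at least 2 exams")
  ord <- order(vapply(trajectory, `[[`, integer(1), "exam_index"))
  trajectory <- trajectory[ord]
  first <- trajectory[[1L]]$markers
  last <- trajectory[[length(trajectory)]]$markers
  all_mk <- union(names(first), names(last))
  rows <- lapply(all_mk, function(mk) {
    f <- if (mk %in% names(first)) unname(first[[mk]]) else NA_real_
    l <- if (mk %in% names(last)) unname(last[[mk]]) else NA_real_
    data.frame(marker = mk, first = f, last = l,
               decreased = if (is.na(f) || is.na(l)) NA else l < f)
  })
  markers <- do.call(rbind, rows)
  dv_before <- dv_after <- delta <- NA_real_
  effective <- NA
  if (!is.null(predictions)) {
    stopifnot(length(predictions) == length(trajectory))
    predictions <- predictions[ord]
    dv_before <- predictions[[1L]]$decision_value
    dv_after <- predictions[[length(predictions)]]$decision_value
    delta <- dv_after - dv_before
    effective <- delta <= -threshold
  }
  structure(list(markers = markers,
                 decision_value_before = dv_before,
                 decision_value_after = dv_after,
                 delta = delta, effective = effective,
                 threshold = threshold),
            class = "efficacy_report")
}
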