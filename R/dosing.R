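#' Total daily dose of a drug class on a given day
#'
#' Sums `dose_mg_per_day` over every event of `drug_class` for `patient`
#' whose half-open coverage interval `[start_day, start_day + duration_days)`
#' contains the day. Concurrent prescriptions are additive.
#'
#' @param events Drug-event tibble (see [generate_cohort()] for the schema).
#' @param patient Patient identifier.
#' @param drug_class One of [drug_classes()].
#' @param day Integer day offset(s) from the index date; may be a vector.
#' @return Numeric vector of mg/day, one per `day`.
#' @export
#' @examples
#' ev <- tibble::tibble(patient_id = "P1", drug_class = "H1AH",
#'                      dose_mg_per_day = 20, start_day = 0L,
#'                      duration_days = 30L)
#' daily_dose(ev, "P1", "H1AH", c(29, 30))  # 20 then 0
daily_dose <- function(events, patient, drug_class, day) {
  check_events(events)
  if (!drug_class %in% drug_classes()) {
    stop("unknown drug_class: ", drug_class, call. = FALSE)
  }
  ev <- events[events$patient_id == patient &
                 events$drug_class == drug_class, , drop = FALSE]
  if (nrow(ev) == 0L) return(rep(0, length(day)))
  vapply(day, function(d) {
    sum(ev$dose_mg_per_day[ev$start_day <= d &
                             d < ev$start_day + ev$duration_days])
  }, numeric(1))
}

# Time-weighted mean daily dose of one class over the half-open day window
# [window[1], window[2]); exact interval arithmetic, no daily expansion.
window_mean_dose <- function(events, patient, drug_class, window) {
  len <- window[2] - window[1]
  ev <- events[events$patient_id == patient &
                 events$drug_class == drug_class, , drop = FALSE]
  if (nrow(ev) == 0L) return(0)
  overlap <- pmax(0, pmin(window[2], ev$start_day + ev$duration_days) -
                    pmax(window[1], ev$start_day))
  sum(ev$dose_mg_per_day * overlap) / len
}

#' Medication-score points for one drug class
#'
#' Implements the published medication-burden scoring scheme on
#' reference-drug equivalent daily doses:
#'
#' * H1-antihistamine: 1 point per 10 mg loratadine-equivalent/day
#'   (proportional, so fractional window means score fractionally);
#' * oral corticosteroid (prednisolone equivalents): 5 points below
#'   11 mg/day, 10 points from 11 to 25 mg/day, 15 points above 25 mg/day,
#'   0 at zero dose;
#' * cyclosporine use: 8 points; leukotriene receptor antagonist: 2 points;
#'   H2-antihistamine: 2 points (any positive dose);
#' * omalizumab is explicitly excluded from the score, intravenous steroids
#'   and methotrexate carry no points (they act in the response classifier
#'   instead).
#'
#' @param drug_class One of [drug_classes()].
#' @param dose Non-negative daily dose in reference-drug equivalents
#'   (mg/day); vectorised.
#' @return Numeric vector of points.
#' @export
#' @examples
#' score_component("H1AH", 10)      # 1
#' score_component("OCS_ORAL", 20)  # 10
#' score_component("CYCLOSPORINE", 100)  # 8
score_component <- function(drug_class, dose) {
  if (length(drug_class) != 1L || !drug_class %in% drug_classes()) {
    stop("unknown drug_class: ", paste(drug_class, collapse = ", "),
         call. = FALSE)
  }
  if (any(is.na(dose)) || any(dose < 0)) {
    stop("`dose` must be non-negative.", call. = FALSE)
  }
  switch(drug_class,
    H1AH = dose / 10,
    OCS_ORAL = ifelse(dose == 0, 0,
                      ifelse(dose < 11, 5, ifelse(dose <= 25, 10, 15))),
    CYCLOSPORINE = ifelse(dose > 0, 8, 0),
    LTRA = ifelse(dose > 0, 2, 0),
    H2RA = ifelse(dose > 0, 2, 0),
    # omalizumab is excluded from the score; IV steroids and methotrexate
    # carry no points and act only in the response classifier
    OMALIZUMAB = rep(0, length(dose)),
    OCS_IV = rep(0, length(dose)),
    METHOTREXATE = rep(0, length(dose))
  )
}

# drug classes that contribute points
scoring_classes <- function() {
  c("H1AH", "OCS_ORAL", "CYCLOSPORINE", "LTRA", "H2RA")
}

#' Medication score over a day window
#'
#' The sum over drug classes of [score_component()] applied to the
#' time-weighted mean daily equivalent dose in the half-open window
#' `[window[1], window[2])`. A patient with no chronic-urticaria medication
#' covering the window scores 0; omalizumab events never contribute.
#'
#' @inheritParams daily_dose
#' @param window Length-2 integer vector, half-open day interval.
#' @return A single non-negative score.
#' @export
medication_score <- function(events, patient, window) {
  check_events(events)
  if (length(window) != 2L || window[2] <= window[1]) {
    stop("`window` must be a half-open day interval c(start, end) with ",
         "end > start.", call. = FALSE)
  }
  sum(vapply(scoring_classes(), function(cl) {
    score_component(cl, window_mean_dose(events, patient, cl, window))
  }, numeric(1)))
}

#' Medication-score series at the assessment months
#'
#' Evaluates [medication_score()] for every patient on the window ending at
#' each assessment month (each window runs from the previous assessment
#' point; the month-1 window is days `[0, 30)`). The index date is each
#' patient's first omalizumab event, which must exist.
#'
#' @inheritParams daily_dose
#' @param months Assessment grid; defaults to [assessment_months()].
#' @return Long tibble with columns `patient_id`, `month`, `score`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_patients = 3, seed = 1))
#' score_series(cohort$events)
score_series <- function(events, months = assessment_months()) {
  check_events(events)
  patients <- sort(unique(events$patient_id))
  no_index <- setdiff(patients,
                      unique(events$patient_id[events$drug_class == "OMALIZUMAB"]))
  if (length(no_index) > 0L) {
    stop("patient(s) without an omalizumab index event: ",
         paste(head(no_index, 5), collapse = ", "), call. = FALSE)
  }
  tidyr::expand_grid(patient_id = patients, month = months) |>
    dplyr::mutate(score = purrr::map2_dbl(
      .data$patient_id, .data$month,
      function(p, m) medication_score(events, p, assessment_window(m))
    ))
}
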