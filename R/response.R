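#' Pre-index baseline H1-antihistamine dose
#'
#' Time-weighted mean daily loratadine-equivalent H1AH dose over the six
#' months before the index date (days `[-180, 0)`). This is the comparator
#' for the dose-reduction rule of the response classifier.
#'
#' @inheritParams daily_dose
#' @return Mean mg/day (a single number).
#' @export
baseline_h1ah_dose <- function(events, patient) {
  check_events(events)
  pre <- events[events$patient_id == patient &
                  events$drug_class == "H1AH" &
                  events$start_day < 0, , drop = FALSE]
  if (nrow(pre) == 0L) {
    stop("patient ", patient, " has no pre-index H1AH records; the cohort ",
         "entry criterion requires >= 6 months of antihistamine history.",
         call. = FALSE)
  }
  window_mean_dose(events, patient, "H1AH", c(-180L, 0L))
}

# Per-patient context reused across the nine assessment windows.
patient_response_context <- function(events, patient) {
  ev <- events[events$patient_id == patient, , drop = FALSE]
  om <- ev[ev$drug_class == "OMALIZUMAB", , drop = FALSE]
  if (nrow(om) == 0L) {
    stop("patient ", patient, " has no omalizumab event; the index date is ",
         "undefined.", call. = FALSE)
  }
  # daily oral-OCS coverage at >= 5 mg prednisolone-eq, days [-180, 720),
  # used for the "> 4 consecutive weeks" nonresponse rule (courses may
  # straddle assessment-window boundaries)
  days <- seq(-180L, 719L)
  ocs <- ev[ev$drug_class == "OCS_ORAL", , drop = FALSE]
  dose_day <- rep(0, length(days))
  for (j in seq_len(nrow(ocs))) {
    idx <- which(days >= ocs$start_day[j] &
                   days < ocs$start_day[j] + ocs$duration_days[j])
    dose_day[idx] <- dose_day[idx] + ocs$dose_mg_per_day[j]
  }
  runs <- rle(dose_day >= 5)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  long_runs <- which(runs$values & runs$lengths > 28L)
  list(
    events = ev,
    baseline = baseline_h1ah_dose(events, patient),
    om = om,
    csa_mtx = ev[ev$drug_class %in% c("CYCLOSPORINE", "METHOTREXATE"), ,
                 drop = FALSE],
    iv = ev[ev$drug_class == "OCS_IV", , drop = FALSE],
    ocs = ocs,
    # day intervals of >28-day continuous OCS coverage at >= 5 mg/day
    long_ocs_runs = cbind(start = days[starts[long_runs]],
                          end = days[ends[long_runs]] + 1L)
  )
}

overlaps_window <- function(ev, window) {
  any(ev$start_day < window[2] & ev$start_day + ev$duration_days > window[1])
}

classify_window <- function(ctx, window) {
  # (1) nonresponse, checked first in priority order
  om_before <- ctx$om$start_day[ctx$om$start_day < window[2]]
  last_om <- if (length(om_before) > 0L) max(om_before) else -Inf
  transition <- any(ctx$csa_mtx$start_day >= last_om &
                      ctx$csa_mtx$start_day < window[2])
  long_ocs <- nrow(ctx$long_ocs_runs) > 0L &&
    any(ctx$long_ocs_runs[, "start"] < window[2] &
          ctx$long_ocs_runs[, "end"] > window[1])
  iv_steroid <- overlaps_window(ctx$iv, window)
  if (transition || long_ocs || iv_steroid) return("NONRESPONSE")

  om_maintained <- overlaps_window(ctx$om, window)
  h1ah_mean <- window_mean_dose(ctx$events, ctx$events$patient_id[1],
                                "H1AH", window)
  # (2) remission: omalizumab discontinued, H1AH absent or < 10 mg/day
  if (!om_maintained && h1ah_mean < 10) return("REMISSION")

  ocs_in_window <- overlaps_window(ctx$ocs, window)
  # (3) complete: omalizumab maintained, no oral OCS, dose cut >= 10 mg
  if (om_maintained && !ocs_in_window &&
        h1ah_mean <= ctx$baseline - 10) return("COMPLETE")

  # (4) partial: stable/increased dose, or OCS despite a reduction
  "PARTIAL"
}

#' Classify one patient's response at one assessment month
#'
#' Applies the rule-based decision flow to the window ending at `month`
#' (the window runs from the previous assessment point). Rules in priority
#' order:
#'
#' 1. **Nonresponse** — transitioning from omalizumab to cyclosporine or
#'    methotrexate (a first such event at or after the last omalizumab
#'    injection), oral corticosteroids at >= 5 mg/day prednisolone-eq for
#'    more than 4 consecutive weeks (the course may straddle window
#'    boundaries), or any intravenous steroid prescription.
#' 2. **Remission** — omalizumab discontinued and H1AH absent or below
#'    10 mg loratadine-eq/day.
#' 3. **Complete response** — omalizumab maintained, no oral OCS in the
#'    window, and window-mean H1AH dose at least 10 mg below the pre-index
#'    baseline ([baseline_h1ah_dose()]).
#' 4. **Partial response** — otherwise (dose stable or increased without
#'    OCS, or OCS introduced despite a reduction).
#'
#' @inheritParams daily_dose
#' @param month One of [assessment_months()].
#' @return A single category name, see [response_levels()].
#' @export
classify_interval <- function(events, patient, month) {
  check_events(events)
  ctx <- patient_response_context(events, patient)
  classify_window(ctx, assessment_window(month))
}

#' Response trajectories for every patient
#'
#' Runs [classify_interval()] at each of the nine assessment months for
#' every patient in `events`.
#'
#' @inheritParams daily_dose
#' @return Long tibble `patient_id`, `month`, `category`, `code`
#'   (ordinal 0-3, see [response_levels()]).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_patients = 4, seed = 2))
#' response_trajectories(cohort$events)
response_trajectories <- function(events) {
  check_events(events)
  patients <- sort(unique(events$patient_id))
  months <- assessment_months()
  res <- purrr::map(patients, function(p) {
    ctx <- patient_response_context(events, p)
    cats <- vapply(months,
                   function(m) classify_window(ctx, assessment_window(m)),
                   character(1))
    tibble::tibble(patient_id = p, month = months, category = cats)
  })
  dplyr::bind_rows(res) |>
    dplyr::mutate(code = unname(response_levels()[.data$category]))
}

#' Wide view of response trajectories
#'
#' @param trajectories Long tibble from [response_trajectories()].
#' @param what `"category"` for labels, `"code"` for ordinal codes.
#' @return Tibble with one row per patient and one `m<month>` column per
#'   assessment month.
#' @export
trajectories_wide <- function(trajectories, what = c("category", "code")) {
  what <- match.arg(what)
  trajectories |>
    dplyr::select("patient_id", "month", dplyr::all_of(what)) |>
    tidyr::pivot_wider(names_from = "month", values_from = dplyr::all_of(what),
                       names_prefix = "m")
}

#' Month of first complete response or remission
#'
#' The smallest assessment month at which a patient is classified complete
#' response or remission; patients who never reach either are censored at
#' month 24 (`event = 0`).
#'
#' @param trajectories Long tibble from [response_trajectories()].
#' @return Tibble `patient_id`, `time` (months), `event` (1 = response
#'   observed, 0 = censored).
#' @export
first_complete_response <- function(trajectories) {
  trajectories |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      time = if (any(.data$category %in% c("COMPLETE", "REMISSION"))) {
        min(.data$month[.data$category %in% c("COMPLETE", "REMISSION")])
      } else max(assessment_months()),
      event = as.integer(any(.data$category %in% c("COMPLETE", "REMISSION"))),
      .groups = "drop"
    )
}

#' Responder-timing groups
#'
#' Early responders achieve a complete response or remission within 3
#' months of the index date, late responders after 3 months, and
#' nonresponders never during the 24-month observation window.
#'
#' @param trajectories Long tibble from [response_trajectories()].
#' @return Tibble `patient_id`, `group` (`EARLY`/`LATE`/`NONRESPONDER`),
#'   `first_cr_month` (NA when censored).
#' @export
responder_groups <- function(trajectories) {
  first_complete_response(trajectories) |>
    dplyr::mutate(
      group = dplyr::case_when(
        .data$event == 0L ~ "NONRESPONDER",
        .data$time <= 3 ~ "EARLY",
        TRUE ~ "LATE"
      ),
      first_cr_month = dplyr::if_else(.data$event == 1L, .data$time,
                                      NA_integer_)
    ) |>
    dplyr::select("patient_id", "group", "first_cr_month")
}

#' Cumulative complete-response rate
#'
#' Fraction of patients whose first complete response or remission occurs
#' at or before each month; monotone non-decreasing in month.
#'
#' @param trajectories Long tibble from [response_trajectories()].
#' @param months Months at which to evaluate the rate.
#' @return Tibble `month`, `rate`.
#' @export
cumulative_response_rate <- function(trajectories,
                                     months = assessment_months()) {
  fcr <- first_complete_response(trajectories)
  n <- nrow(fcr)
  tibble::tibble(
    month = months,
    rate = vapply(months, function(m) {
      if (n == 0L) return(NA_real_)
      sum(fcr$event == 1L & fcr$time <= m) / n
    }, numeric(1))
  )
}
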