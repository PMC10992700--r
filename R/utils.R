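#' Drug classes recognised in prescription-event tables
#'
#' The fixed vocabulary of the `drug_class` column of a drug-event table.
#' H1-antihistamine (`H1AH`) doses are expressed in loratadine 10 mg
#' equivalents and oral corticosteroid (`OCS_ORAL`) doses in prednisolone
#' equivalents; `OMALIZUMAB` doses are per injection.
#'
#' @return Character vector of valid drug classes.
#' @export
drug_classes <- function() {
  c("H1AH", "OCS_ORAL", "OCS_IV", "CYCLOSPORINE", "METHOTREXATE",
    "LTRA", "H2RA", "OMALIZUMAB")
}

#' Assessment grid for response evaluation
#'
#' Months after the index date (first omalizumab injection) at which the
#' treatment response and the medication score are assessed.
#'
#' @return Integer vector `c(1, 3, 6, 9, 12, 15, 18, 21, 24)`.
#' @export
assessment_months <- function() {
  c(1L, 3L, 6L, 9L, 12L, 15L, 18L, 21L, 24L)
}

#' Ordered response categories
#'
#' Response categories with their fixed ordinal codes: nonresponse 0,
#' partial 1, complete 2, remission 3. The ordinal coding is what the
#' trajectory clustering operates on.
#'
#' @return Named integer vector (names are category labels, values codes).
#' @export
response_levels <- function() {
  c(NONRESPONSE = 0L, PARTIAL = 1L, COMPLETE = 2L, REMISSION = 3L)
}

# Half-open day window (start, end) for the assessment month `month`:
# runs from the previous assessment point (or day 0) to month*30.
assessment_window <- function(month) {
  grid <- assessment_months()
  i <- match(month, grid)
  if (is.na(i)) {
    stop("`month` must be one of the assessment months: ",
         paste(grid, collapse = ", "), call. = FALSE)
  }
  start <- if (i == 1L) 0L else grid[i - 1L] * 30L
  c(start, grid[i] * 30L)
}

# Rescale the assessment grid to [0, 1] for the shape distance.
grid_times <- function(months = assessment_months()) {
  (months - min(months)) / (max(months) - min(months))
}

check_events <- function(events) {
  needed <- c("patient_id", "drug_class", "dose_mg_per_day",
              "start_day", "duration_days")
  missing <- setdiff(needed, names(events))
  if (length(missing) > 0L) {
    stop("drug-event table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(events$drug_class), drug_classes())
  if (length(bad) > 0L) {
    stop("unknown drug_class value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(events)
}
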