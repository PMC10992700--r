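#' Write a cohort to delimited text files
#'
#' Writes `events.csv`, `labs.csv` and `latent.csv` under `path`. The files
#' are plain comma-delimited text and round-trip through [read_cohort()]
#' field-for-field.
#'
#' @param cohort A `cu_cohort` (or any list with `events`, `labs`, `latent`
#'   tibbles in the cohort schema).
#' @param path Directory to write into (created if absent).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.list(cohort),
            all(c("events", "labs", "latent") %in% names(cohort)))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$events, file.path(path, "events.csv"))
  readr::write_csv(cohort$labs, file.path(path, "labs.csv"))
  readr::write_csv(cohort$latent, file.path(path, "latent.csv"))
  invisible(path)
}

#' Read a cohort written by [write_cohort()]
#'
#' Validates the schema on read: unknown drug classes, negative doses or
#' non-positive durations raise a parse error naming the file, line and
#' column of the first offending value.
#'
#' @param path Directory containing `events.csv`, `labs.csv`, `latent.csv`.
#' @return A `cu_cohort` list of tibbles.
#' @export
read_cohort <- function(path) {
  events <- readr::read_csv(
    file.path(path, "events.csv"),
    col_types = readr::cols(
      patient_id = readr::col_character(),
      drug_class = readr::col_character(),
      dose_mg_per_day = readr::col_double(),
      start_day = readr::col_integer(),
      duration_days = readr::col_integer()
    )
  )
  validate_events_file(events, file.path(path, "events.csv"))
  labs <- readr::read_csv(
    file.path(path, "labs.csv"),
    col_types = readr::cols(
      patient_id = readr::col_character(),
      sex = readr::col_character(),
      .default = readr::col_double()
    )
  )
  latent <- readr::read_csv(
    file.path(path, "latent.csv"),
    col_types = readr::cols(.default = readr::col_character())
  )
  structure(list(events = events, labs = labs, latent = latent),
            class = "cu_cohort")
}

# Raise a parse error naming the 1-based data line (header = line 1) and
# column of the first invalid field.
validate_events_file <- function(events, file) {
  fail <- function(rows, column, why) {
    if (any(rows)) {
      stop(sprintf("%s: line %d, column '%s': %s",
                   file, which(rows)[1] + 1L, column, why),
           call. = FALSE)
    }
  }
  fail(!events$drug_class %in% drug_classes(), "drug_class",
       "unknown drug class")
  fail(is.na(events$dose_mg_per_day) | events$dose_mg_per_day < 0,
       "dose_mg_per_day", "dose must be a non-negative number")
  fail(is.na(events$duration_days) | events$duration_days < 1,
       "duration_days", "duration must be a positive integer")
  fail(is.na(events$start_day), "start_day", "missing start day")
  invisible(events)
}
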