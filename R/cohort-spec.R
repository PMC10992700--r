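#' Default per-class prescription dynamics
#'
#' Monthly discrete-time dynamics on the 10 mg loratadine-equivalent dose
#' grid for the three latent responder classes. Each class is a list with:
#'
#' * `baseline_doses`, `baseline_probs`: distribution of the pre-index daily
#'   H1-antihistamine dose (mg loratadine-eq; at least 20 mg, the
#'   refractoriness entry criterion).
#' * `p_step_down`: monthly probability of a 10 mg dose reduction.
#' * `p_step_up`: monthly probability of a 10 mg relapse increase
#'   (evaluated only when no step-down occurred that month).
#' * `p_ocs`: monthly probability of starting an oral corticosteroid course;
#'   `ocs_doses`/`ocs_dose_probs` give the prednisolone-equivalent daily
#'   dose, `ocs_duration` the inclusive range of course lengths in days.
#' * `p_iv_steroid`: monthly probability of an intravenous steroid
#'   prescription.
#' * `p_switch`: monthly probability (from month 6, so the at-least-6-months
#'   omalizumab inclusion rule always holds) of switching from omalizumab to
#'   cyclosporine.
#' * `p_om_stop`: monthly probability (from month 9) of discontinuing
#'   omalizumab with the urticaria controlled, the path that can lead to
#'   remission.
#' * `p_ltra`, `p_h2ra`: per-patient probabilities of chronic leukotriene
#'   receptor antagonist / H2-antihistamine co-medication.
#'
#' The defaults make the favorable class step down early and often, the
#' intermediate class fluctuate, and the poor class hold its dose while
#' accumulating corticosteroid exposure.
#'
#' @return Named list with elements `favorable`, `intermediate`, `poor`.
#' @export
default_dose_params <- function() {
  base <- list(
    baseline_doses = c(20, 30, 40),
    baseline_probs = c(0.5, 0.3, 0.2),
    ocs_doses = c(5, 10, 20, 30),
    ocs_dose_probs = c(0.3, 0.4, 0.2, 0.1),
    p_ltra = 0.15,
    p_h2ra = 0.20
  )
  list(
    favorable = c(base, list(
      p_step_down = 0.60, p_step_up = 0.02,
      p_ocs = 0.01, ocs_duration = c(5L, 14L),
      p_iv_steroid = 0.000, p_switch = 0.000, p_om_stop = 0.04
    )),
    intermediate = c(base, list(
      p_step_down = 0.35, p_step_up = 0.25,
      p_ocs = 0.08, ocs_duration = c(7L, 21L),
      p_iv_steroid = 0.005, p_switch = 0.005, p_om_stop = 0.01
    )),
    poor = c(base, list(
      p_step_down = 0.04, p_step_up = 0.10,
      p_ocs = 0.25, ocs_duration = c(21L, 45L),
      p_iv_steroid = 0.08, p_switch = 0.04, p_om_stop = 0.00
    ))
  )
}

#' Default omalizumab dosing parameters
#'
#' @return List with `p_dose_300` (probability that the starting dose is at
#'   least 300 mg per injection; otherwise 150 mg) and
#'   `interval_days`/`interval_probs`, the per-patient injection interval
#'   distribution.
#' @export
default_omalizumab_params <- function() {
  list(
    p_dose_300 = 0.37,
    interval_days = c(28L, 42L, 56L),
    interval_probs = c(0.60, 0.25, 0.15)
  )
}

#' Default baseline laboratory distributions
#'
#' Per-class distributions for the one-row-per-patient baseline lab panel.
#' Cell counts are in cells/uL; platelets are stored in 10/uL units so that
#' the platelet-to-lymphocyte ratio `platelets / lymphocytes` lands on the
#' scale used in clinical reporting (typical value near 10); total IgE is
#' lognormal in kU/L with the poor class shifted low so that low-IgE
#' (< 40 kU/L) patients are enriched among poor responders; C3/C4 in mg/dL.
#'
#' @return Named list with elements `favorable`, `intermediate`, `poor`,
#'   each a list of distribution parameters.
#' @export
default_lab_params <- function() {
  base <- list(
    ige_meanlog = log(180), ige_sdlog = 1.20,
    baso_meanlog = log(32), baso_sdlog = 0.65,
    eos_meanlog = log(110), eos_sdlog = 0.80,
    lymph_mean = 2200, lymph_sd = 750,
    mono_mean = 520, mono_sd = 200,
    neut_meanlog = log(4300), neut_sdlog = 0.50,
    plt_mean = 21100, plt_sd = 8000,
    c3_mean = 114, c3_sd = 20,
    c4_mean = 26.6, c4_sd = 8.4,
    p_female = 0.394,
    age_mean = 42, age_sd = 13
  )
  poor <- base
  poor$ige_meanlog <- log(120)   # enriches IgE < 40 kU/L among poor responders
  poor$baso_meanlog <- log(28)
  poor$c4_mean <- 24.8
  list(favorable = base, intermediate = base, poor = poor)
}

#' Specify a synthetic cohort
#'
#' Bundles and validates every parameter of the synthetic EMR generator:
#' cohort size, latent class mixture, follow-up geometry, per-class
#' prescription dynamics, omalizumab dosing, and baseline lab distributions.
#' One spec plus one seed fully determines the generated cohort.
#'
#' @param n_patients Number of patients (non-negative integer).
#' @param class_probs Probabilities of the latent classes
#'   (favorable, intermediate, poor); must sum to 1.
#' @param seed Integer seed for the single random stream.
#' @param followup_months Post-index follow-up in 30-day months (default 24).
#' @param pre_index_months Pre-index history in months (default 6).
#' @param dropout_hazard Per-month probability of dropping out of follow-up,
#'   applied only after month 12 so every patient meets the at-least-12-months
#'   follow-up inclusion rule.
#' @param dose_params Per-class dynamics, see [default_dose_params()].
#' @param omalizumab_params See [default_omalizumab_params()].
#' @param lab_params See [default_lab_params()].
#'
#' @return An object of class `cohort_spec` (a validated list).
#' @export
#' @examples
#' spec <- cohort_spec(n_patients = 20, seed = 1)
#' cohort <- generate_cohort(spec)
#' cohort$events
cohort_spec <- function(n_patients,
                        class_probs = c(0.41, 0.37, 0.22),
                        seed = 1L,
                        followup_months = 24L,
                        pre_index_months = 6L,
                        dropout_hazard = 0.02,
                        dose_params = default_dose_params(),
                        omalizumab_params = default_omalizumab_params(),
                        lab_params = default_lab_params()) {
  if (length(n_patients) != 1L || is.na(n_patients) || n_patients < 0 ||
      n_patients != as.integer(n_patients)) {
    stop("`n_patients` must be a single non-negative integer.", call. = FALSE)
  }
  if (length(class_probs) != 3L || any(class_probs < 0) || any(class_probs > 1)) {
    stop("`class_probs` must be 3 probabilities in [0, 1].", call. = FALSE)
  }
  if (abs(sum(class_probs) - 1) > 1e-12) {
    stop("`class_probs` must sum to 1.", call. = FALSE)
  }
  classes <- c("favorable", "intermediate", "poor")
  stopifnot(all(classes %in% names(dose_params)),
            all(classes %in% names(lab_params)))
  for (cl in classes) {
    dp <- dose_params[[cl]]
    if (any(dp$baseline_doses %% 10 != 0) || any(dp$baseline_doses < 20)) {
      stop("baseline H1AH doses must be multiples of 10 mg and at least 20 mg ",
           "(class '", cl, "').", call. = FALSE)
    }
    probs <- c(dp$p_step_down, dp$p_step_up, dp$p_ocs, dp$p_iv_steroid,
               dp$p_switch, dp$p_om_stop, dp$p_ltra, dp$p_h2ra)
    if (any(probs < 0 | probs > 1)) {
      stop("all class dynamics probabilities must be in [0, 1] (class '",
           cl, "').", call. = FALSE)
    }
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      class_probs = setNames(as.numeric(class_probs), classes),
      seed = as.integer(seed),
      followup_months = as.integer(followup_months),
      pre_index_months = as.integer(pre_index_months),
      dropout_hazard = dropout_hazard,
      dose_params = dose_params,
      omalizumab_params = omalizumab_params,
      lab_params = lab_params
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>", x$n_patients, "patients; class mix",
      paste(sprintf("%s=%.2f", names(x$class_probs), x$class_probs),
            collapse = ", "),
      "; seed", x$seed, "\n")
  invisible(x)
}
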