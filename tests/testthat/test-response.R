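test_that("baseline_h1ah_dose is the time-weighted pre-index mean", {
  ev <- base_patient(baseline = 20)
  expect_equal(baseline_h1ah_dose(ev, "P1"), 20)

  # 30 mg for the first 90 days, 10 mg for the last 90 -> mean 20
  ev2 <- dplyr::bind_rows(
    event_row("P1", "H1AH", 30, -180, 90),
    event_row("P1", "H1AH", 10, -90, 90),
    event_row("P1", "OMALIZUMAB", 300, 0, 28)
  )
  expect_equal(baseline_h1ah_dose(ev2, "P1"), 20)

  no_pre <- event_row("P1", "OMALIZUMAB", 300, 0, 28)
  expect_error(baseline_h1ah_dose(no_pre, "P1"), "pre-index")
})

test_that("classify_interval applies the decision rules in priority order", {
  # complete: omalizumab maintained, 30 -> 10 mg, no OCS
  ev <- base_patient(monthly_h1ah(rep(10, 24)), baseline = 30)
  expect_equal(classify_interval(ev, "P1", 1), "COMPLETE")

  # any IV steroid in the window forces nonresponse despite the reduction
  ev_iv <- dplyr::bind_rows(ev, event_row("P1", "OCS_IV", 40, 10, 1))
  expect_equal(classify_interval(ev_iv, "P1", 1), "NONRESPONSE")
  expect_equal(classify_interval(ev_iv, "P1", 3), "COMPLETE")

  # omalizumab stopped and H1AH absent -> remission
  ev_rem <- dplyr::bind_rows(
    event_row("P1", "H1AH", 30, -180, 180),
    event_row("P1", "OMALIZUMAB", 300, 0, 28)
  )
  expect_equal(classify_interval(ev_rem, "P1", 3), "REMISSION")
  # ... and H1AH < 10 mg also counts as remission
  ev_rem5 <- dplyr::bind_rows(ev_rem, monthly_h1ah(rep(0, 1)))
  expect_equal(classify_interval(ev_rem5, "P1", 6), "REMISSION")

  # dose kept stable without OCS -> partial
  ev_stable <- base_patient(monthly_h1ah(rep(20, 24)), baseline = 20)
  expect_equal(classify_interval(ev_stable, "P1", 1), "PARTIAL")

  # short OCS course despite a reduction -> partial (not nonresponse)
  ev_ocs <- dplyr::bind_rows(base_patient(monthly_h1ah(rep(10, 24)),
                                          baseline = 30),
                             event_row("P1", "OCS_ORAL", 10, 5, 10))
  expect_equal(classify_interval(ev_ocs, "P1", 1), "PARTIAL")
})

test_that("long oral corticosteroid courses trigger nonresponse, across windows", {
  # 35 days at 10 mg starting day 20: straddles the month-1/month-3 windows
  long_ocs <- event_row("P1", "OCS_ORAL", 10, 20, 35)
  ev <- dplyr::bind_rows(base_patient(monthly_h1ah(rep(10, 24)),
                                      baseline = 30), long_ocs)
  expect_equal(classify_interval(ev, "P1", 1), "NONRESPONSE")
  expect_equal(classify_interval(ev, "P1", 3), "NONRESPONSE")
  expect_equal(classify_interval(ev, "P1", 6), "COMPLETE")

  # exactly 28 days is not "more than 4 weeks"
  ev28 <- dplyr::bind_rows(base_patient(monthly_h1ah(rep(10, 24)),
                                        baseline = 30),
                           event_row("P1", "OCS_ORAL", 10, 20, 28))
  expect_false(classify_interval(ev28, "P1", 1) == "NONRESPONSE")

  # below the 5 mg threshold, duration does not matter
  ev_low <- dplyr::bind_rows(base_patient(monthly_h1ah(rep(10, 24)),
                                          baseline = 30),
                             event_row("P1", "OCS_ORAL", 4, 0, 120))
  expect_false(classify_interval(ev_low, "P1", 3) == "NONRESPONSE")
})

test_that("switching to cyclosporine after the last injection is nonresponse", {
  ev <- dplyr::bind_rows(
    event_row("P1", "H1AH", 30, -180, 180),
    event_row("P1", "OMALIZUMAB", 300, 0, 28),
    event_row("P1", "OMALIZUMAB", 300, 28, 28),
    event_row("P1", "CYCLOSPORINE", 200, 90, 30)
  )
  expect_equal(classify_interval(ev, "P1", 6), "NONRESPONSE")
  # a cyclosporine course that ends before later omalizumab injections is
  # a brief overlap, not a transition
  ev2 <- dplyr::bind_rows(
    base_patient(monthly_h1ah(rep(20, 24)), baseline = 20),
    event_row("P1", "CYCLOSPORINE", 200, 30, 14)
  )
  expect_equal(classify_interval(ev2, "P1", 24), "PARTIAL")
})

test_that("trajectories are exhaustive, exclusive and composable", {
  co <- generate_cohort(cohort_spec(25, seed = 21))
  traj <- response_trajectories(co$events)
  expect_equal(nrow(traj), 25 * 9)
  expect_true(all(traj$category %in% names(response_levels())))
  expect_equal(traj$code, unname(response_levels()[traj$category]))
  # one category per patient-month
  expect_equal(nrow(dplyr::distinct(traj, patient_id, month)), nrow(traj))
  # matches per-call classification
  some <- traj[c(1, 40, 120, 200), ]
  for (i in seq_len(nrow(some))) {
    expect_equal(classify_interval(co$events, some$patient_id[i],
                                   some$month[i]),
                 some$category[i])
  }
  # wide export preserves content
  wide <- trajectories_wide(traj)
  expect_equal(dim(wide), c(25, 10))
  expect_equal(wide$m24[wide$patient_id == traj$patient_id[1]],
               traj$category[traj$patient_id == traj$patient_id[1] &
                               traj$month == 24])
})

test_that("first complete response takes the earliest qualifying month", {
  months <- assessment_months()
  make_traj <- function(cats) {
    tibble::tibble(patient_id = "X", month = months, category = cats,
                   code = unname(response_levels()[cats]))
  }
  all_partial <- make_traj(rep("PARTIAL", 9))
  expect_equal(first_complete_response(all_partial)$event, 0L)
  expect_equal(first_complete_response(all_partial)$time, 24L)

  at6 <- make_traj(c("PARTIAL", "PARTIAL", "COMPLETE", rep("PARTIAL", 6)))
  expect_equal(first_complete_response(at6)$time, 6L)

  # fluctuation: first occurrence counts even if the response is lost later
  fluct <- make_traj(c("PARTIAL", "COMPLETE", "PARTIAL", "COMPLETE",
                       rep("PARTIAL", 5)))
  expect_equal(first_complete_response(fluct)$time, 3L)
  # remission also qualifies
  rem <- make_traj(c(rep("PARTIAL", 8), "REMISSION"))
  expect_equal(first_complete_response(rem)$time, 24L)
  expect_equal(first_complete_response(rem)$event, 1L)
})

test_that("responder groups follow the 3-month boundary", {
  months <- assessment_months()
  lab <- function(cats) {
    responder_groups(tibble::tibble(patient_id = "X", month = months,
                                    category = cats,
                                    code = unname(response_levels()[cats])))
  }
  expect_equal(lab(c("COMPLETE", rep("PARTIAL", 8)))$group, "EARLY")
  expect_equal(lab(c("PARTIAL", "COMPLETE", rep("PARTIAL", 7)))$group,
               "EARLY")
  expect_equal(lab(c("PARTIAL", "PARTIAL", "COMPLETE",
                     rep("PARTIAL", 6)))$group, "LATE")
  expect_equal(lab(rep("PARTIAL", 9))$group, "NONRESPONDER")
  expect_true(is.na(lab(rep("PARTIAL", 9))$first_cr_month))
})

test_that("cumulative response rate is monotone and matches the geometric oracle", {
  # deterministic favorable dynamics with step-down probability p per month
  # give first-response hazard ~ geometric; check against the closed form
  p <- 0.5
  dp <- default_dose_params()
  dp$favorable[c("p_step_down", "p_step_up", "p_ocs", "p_iv_steroid",
                 "p_switch", "p_om_stop")] <- list(p, 0, 0, 0, 0, 0)
  co <- generate_cohort(cohort_spec(400, class_probs = c(1, 0, 0), seed = 31,
                                    dose_params = dp, dropout_hazard = 0))
  traj <- response_trajectories(co$events)
  cum <- cumulative_response_rate(traj)
  expect_true(all(diff(cum$rate) >= 0))
  expect_true(all(cum$rate >= 0 & cum$rate <= 1))
  # month-1 window shows a response iff the dose stepped down at month 0
  expected_m1 <- p
  se <- sqrt(p * (1 - p) / 400)
  expect_lt(abs(cum$rate[cum$month == 1] - expected_m1), 4 * se)

  expect_equal(cumulative_response_rate(traj, months = 0)$rate, 0)
})

test_that("adding an IV steroid event can only push a window to nonresponse", {
  co <- generate_cohort(cohort_spec(10, seed = 41))
  traj <- response_trajectories(co$events)
  p <- co$latent$patient_id[5]
  for (m in c(1, 6, 24)) {
    w <- c(if (m == 1) 0 else setdiff(assessment_months(),
                                      m)[sum(assessment_months() < m)] * 30,
           m * 30)
    ev_iv <- dplyr::bind_rows(co$events,
                              event_row(p, "OCS_IV", 40, w[1] + 1, 1))
    before <- traj$category[traj$patient_id == p & traj$month == m]
    after <- classify_interval(ev_iv, p, m)
    expect_equal(after, "NONRESPONSE")
    # other patients' windows unchanged
    other <- co$latent$patient_id[1]
    expect_equal(classify_interval(ev_iv, other, m),
                 traj$category[traj$patient_id == other & traj$month == m])
  }
})
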