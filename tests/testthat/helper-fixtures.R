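# Small in-code fixtures and independent oracles shared across tests.

event_row <- function(patient, drug, dose, start, dur) {
  tibble::tibble(patient_id = patient, drug_class = drug,
                 dose_mg_per_day = dose, start_day = as.integer(start),
                 duration_days = as.integer(dur))
}

# A patient with 6 months of pre-index H1AH at `baseline` mg/day and an
# omalizumab index injection covering the follow-up; extra events appended.
base_patient <- function(extra = NULL, patient = "P1", baseline = 30,
                         om_months = 24) {
  ev <- dplyr::bind_rows(
    event_row(patient, "H1AH", baseline, -180, 180),
    purrr::map_dfr(seq(0, om_months * 30 - 1, by = 30), function(d) {
      event_row(patient, "OMALIZUMAB", 300, d, 30)
    })
  )
  if (!is.null(extra)) ev <- dplyr::bind_rows(ev, extra)
  ev
}

# Monthly H1AH at the doses in `doses` (month i covers days [30(i-1), 30i)).
monthly_h1ah <- function(doses, patient = "P1") {
  purrr::map_dfr(seq_along(doses), function(i) {
    if (doses[i] <= 0) return(NULL)
    event_row(patient, "H1AH", doses[i], 30 * (i - 1), 30)
  })
}

# Independent brute-force oracle for the discrete Frechet distance:
# exhaustive recursion over all monotone couplings, memo-free (tiny n only).
brute_frechet <- function(ax, ay, bx, by) {
  n <- length(ax); m <- length(bx)
  dist_pt <- function(i, j) sqrt((ax[i] - bx[j])^2 + (ay[i] - by[j])^2)
  rec <- function(i, j) {
    d <- dist_pt(i, j)
    if (i == 1 && j == 1) return(d)
    prev <- Inf
    if (i > 1) prev <- min(prev, rec(i - 1, j))
    if (j > 1) prev <- min(prev, rec(i, j - 1))
    if (i > 1 && j > 1) prev <- min(prev, rec(i - 1, j - 1))
    max(d, prev)
  }
  rec(n, m)
}

# Direct-formula log-rank oracle for k groups (chi-square form with the
# hypergeometric variance), independent of the survival package.
oracle_logrank <- function(time, event, group) {
  group <- as.factor(group)
  k <- nlevels(group)
  times <- sort(unique(time[event == 1]))
  O <- E <- rep(0, k)
  V <- matrix(0, k, k)
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    d <- sum(event == 1 & time == t)
    for (g in seq_len(k)) {
      ng <- sum(at_risk & group == levels(group)[g])
      dg <- sum(event == 1 & time == t & group == levels(group)[g])
      O[g] <- O[g] + dg
      E[g] <- E[g] + d * ng / n
    }
    if (n > 1) {
      for (g in seq_len(k)) {
        for (h in seq_len(k)) {
          ng <- sum(at_risk & group == levels(group)[g])
          nh <- sum(at_risk & group == levels(group)[h])
          V[g, h] <- V[g, h] +
            d * (n - d) / (n - 1) *
            (ifelse(g == h, ng / n, 0) - ng * nh / n^2)
        }
      }
    }
  }
  u <- (O - E)[-1]
  vv <- V[-1, -1, drop = FALSE]
  drop(t(u) %*% solve(vv) %*% u)
}
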