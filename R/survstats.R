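#' Kaplan-Meier curve for time to first complete response
#'
#' Product-limit estimate of the probability of not yet having achieved a
#' complete response/remission, from records as produced by
#' [first_complete_response()] (patients with no observed response are
#' censored at month 24).
#'
#' @param records Tibble with columns `time` (months, positive) and
#'   `event` (0/1).
#' @return Tibble `time`, `n_risk`, `n_event`, `n_censor`, `survival`,
#'   `std_err`, `lower`, `upper` (Greenwood 95% interval), of class
#'   `km_curve`.
#' @export
km_curve <- function(records) {
  check_surv_records(records)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records)
  out <- tibble::tibble(
    time = fit$time,
    n_risk = fit$n.risk,
    n_event = fit$n.event,
    n_censor = fit$n.censor,
    survival = fit$surv,
    std_err = fit$surv * fit$std.err,
    lower = fit$lower,
    upper = fit$upper
  )
  class(out) <- c("km_curve", class(out))
  out
}

#' Log-rank test across groups
#'
#' K-group log-rank comparison of time-to-first-complete-response, with a
#' chi-square reference on `k - 1` degrees of freedom.
#'
#' @param records Tibble with `time` and `event` columns.
#' @param groups Group label per record (vector, or name of a column in
#'   `records`).
#' @return One-row tibble `statistic`, `df`, `p_value`.
#' @export
log_rank <- function(records, groups) {
  check_surv_records(records)
  if (is.character(groups) && length(groups) == 1L &&
        groups %in% names(records)) {
    groups <- records[[groups]]
  }
  stopifnot(length(groups) == nrow(records))
  df <- data.frame(time = records$time, event = records$event,
                   group = as.factor(groups))
  if (nlevels(df$group) < 2L) {
    stop("log_rank needs at least two groups.", call. = FALSE)
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  k <- nlevels(df$group)
  tibble::tibble(
    statistic = unname(sd$chisq),
    df = k - 1L,
    p_value = pchisq(unname(sd$chisq), df = k - 1L, lower.tail = FALSE)
  )
}

check_surv_records <- function(records) {
  stopifnot(all(c("time", "event") %in% names(records)))
  if (any(records$time <= 0)) {
    stop("survival times must be positive.", call. = FALSE)
  }
  if (!all(records$event %in% c(0L, 1L))) {
    stop("`event` must be 0 or 1.", call. = FALSE)
  }
  invisible(records)
}

#' Fleiss kappa for multi-rater categorical agreement
#'
#' Chance-corrected agreement `kappa = (P_bar - P_e) / (1 - P_e)` where
#' `P_bar` is the mean observed pairwise agreement per subject and `P_e`
#' the chance agreement from the marginal category proportions. Used here
#' with two "raters" per subject — the trajectory cluster and the
#' responder-timing group, both mapped to three categories.
#'
#' @param ratings Subjects x categories matrix of non-negative integer
#'   counts; every row must sum to the same number of raters (>= 2).
#' @return List with `kappa`, `p_bar`, `p_e`, `z`, `p_value` (large-sample
#'   normal test of kappa = 0), `degenerate` (TRUE when chance agreement is
#'   1, in which case `kappa` is `NA` rather than an error).
#' @export
#' @examples
#' r <- rbind(c(2, 0), c(0, 2), c(1, 1), c(1, 1))
#' fleiss_kappa(r)$kappa  # 0: agreement no better than chance here
fleiss_kappa <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (any(ratings < 0) || any(ratings != round(ratings))) {
    stop("`ratings` must contain non-negative integer counts.", call. = FALSE)
  }
  n_raters <- unique(rowSums(ratings))
  if (length(n_raters) != 1L) {
    stop("all rows of `ratings` must sum to the same number of raters.",
         call. = FALSE)
  }
  n <- n_raters
  if (n < 2) stop("at least two raters per subject are required.",
                  call. = FALSE)
  N <- nrow(ratings)
  p_j <- colSums(ratings) / (N * n)
  p_i <- (rowSums(ratings^2) - n) / (n * (n - 1))
  p_bar <- mean(p_i)
  p_e <- sum(p_j^2)
  if (1 - p_e < .Machine$double.eps) {
    return(list(kappa = NA_real_, p_bar = p_bar, p_e = p_e,
                z = NA_real_, p_value = NA_real_, degenerate = TRUE))
  }
  kappa <- (p_bar - p_e) / (1 - p_e)
  var_kappa <- 2 / (N * n * (n - 1)) *
    (p_e - (2 * n - 3) * p_e^2 + 2 * (n - 2) * sum(p_j^3)) / (1 - p_e)^2
  z <- kappa / sqrt(var_kappa)
  list(kappa = kappa, p_bar = p_bar, p_e = p_e, z = z,
       p_value = 2 * pnorm(-abs(z)), degenerate = FALSE)
}

#' Ratings matrix from two categorical labelings
#'
#' Builds the subjects x categories count matrix for [fleiss_kappa()] from
#' two per-subject labelings treated as two raters over a shared category
#' set.
#'
#' @param labels_a,labels_b Per-subject labels (equal length). For the
#'   cluster-vs-timing agreement, map both to a shared 3-level set first
#'   (cluster 1 ~ EARLY, 2 ~ LATE, 3 ~ NONRESPONDER).
#' @param categories Optional category universe; defaults to the union.
#' @return Integer matrix with one row per subject, row sums 2.
#' @export
rating_matrix <- function(labels_a, labels_b, categories = NULL) {
  stopifnot(length(labels_a) == length(labels_b))
  categories <- categories %||% sort(unique(c(labels_a, labels_b)))
  a <- factor(labels_a, levels = categories)
  b <- factor(labels_b, levels = categories)
  m <- matrix(0L, nrow = length(a), ncol = length(categories),
              dimnames = list(NULL, categories))
  for (i in seq_along(a)) {
    m[i, as.integer(a[i])] <- m[i, as.integer(a[i])] + 1L
    m[i, as.integer(b[i])] <- m[i, as.integer(b[i])] + 1L
  }
  m
}

#' Cross-tabulation of cluster labels against responder-timing groups
#'
#' @param cluster_labels Tibble `patient_id`, `cluster` (from a
#'   [shape_kmeans()] fit's `assignments`).
#' @param responder_labels Tibble `patient_id`, `group` (from
#'   [responder_groups()]).
#' @return Tibble in long form `cluster`, `group`, `n`, covering all
#'   cluster x group combinations (zero-filled).
#' @export
crosstab <- function(cluster_labels, responder_labels) {
  joined <- dplyr::inner_join(cluster_labels, responder_labels,
                              by = "patient_id")
  joined |>
    dplyr::count(.data$cluster, .data$group) |>
    tidyr::complete(cluster = sort(unique(joined$cluster)),
                    group = c("EARLY", "LATE", "NONRESPONDER"),
                    fill = list(n = 0L))
}
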