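#' Marker dichotomization cutoffs
#'
#' Holds the cutoffs used by [derive_markers()]. By default every cutoff is
#' recomputed from the analysis cohort (total IgE at its 10th and 90th
#' percentiles; medians for basophils, SIRI, PLR and C4); any field can be
#' pinned to a fixed value, e.g. to reproduce cutoffs realized in another
#' cohort (such as IgE 40 and 798.5 kU/L with PLR 11.5).
#'
#' @param ige_low,ige_high,basophils_median,siri_median,plr_median,c4_median
#'   Numeric cutoffs, or `NULL` to recompute from the cohort.
#' @return A named list of class `marker_cutoffs`.
#' @export
marker_cutoffs <- function(ige_low = NULL, ige_high = NULL,
                           basophils_median = NULL, siri_median = NULL,
                           plr_median = NULL, c4_median = NULL) {
  structure(
    list(ige_low = ige_low, ige_high = ige_high,
         basophils_median = basophils_median, siri_median = siri_median,
         plr_median = plr_median, c4_median = c4_median),
    class = "marker_cutoffs"
  )
}

#' Derived laboratory markers and dichotomizations
#'
#' Computes, per patient:
#'
#' * `siri` — systemic inflammation response index,
#'   (neutrophils x monocytes) / lymphocytes with counts on the
#'   10^3 cells/uL scale;
#' * `plr` — platelet-to-lymphocyte ratio, `platelets / lymphocytes`
#'   on the stored scales (clinical reporting scale, typical value ~10);
#' * `basopenia` (basophils < 10/uL, strict) and `eosinopenia`
#'   (eosinophils < 50/uL, strict);
#' * `ige_low` / `ige_high` — total IgE below the low cutoff / above the
#'   high cutoff (cohort 10th/90th percentiles unless pinned);
#' * above-median flags `baso_high`, `siri_high`, `plr_high`, `c4_high`.
#'
#' SIRI and PLR are undefined when lymphocytes are zero; such rows get `NA`
#' values and `ratio_undefined = TRUE`.
#'
#' @param labs Lab-panel tibble (see [generate_cohort()]).
#' @param cutoffs A [marker_cutoffs()]; `NULL` fields are recomputed from
#'   `labs`.
#' @return `labs` with the marker columns appended; the realized cutoffs
#'   are attached as attribute `"cutoffs"`.
#' @export
#' @examples
#' labs <- generate_cohort(cohort_spec(50, seed = 3))$labs
#' m <- derive_markers(labs)
#' attr(m, "cutoffs")
derive_markers <- function(labs, cutoffs = marker_cutoffs()) {
  stopifnot(all(c("neutrophils", "monocytes", "lymphocytes", "platelets",
                  "basophils", "eosinophils", "total_ige_ku_l", "c4_mg_dl")
                %in% names(labs)))
  ok <- labs$lymphocytes > 0
  siri <- ifelse(ok,
                 (labs$neutrophils / 1e3) * (labs$monocytes / 1e3) /
                   (labs$lymphocytes / 1e3),
                 NA_real_)
  plr <- ifelse(ok, labs$platelets / labs$lymphocytes, NA_real_)

  used <- list(
    ige_low = cutoffs$ige_low %||%
      unname(quantile(labs$total_ige_ku_l, 0.10, na.rm = TRUE)),
    ige_high = cutoffs$ige_high %||%
      unname(quantile(labs$total_ige_ku_l, 0.90, na.rm = TRUE)),
    basophils_median = cutoffs$basophils_median %||%
      median(labs$basophils, na.rm = TRUE),
    siri_median = cutoffs$siri_median %||% median(siri, na.rm = TRUE),
    plr_median = cutoffs$plr_median %||% median(plr, na.rm = TRUE),
    c4_median = cutoffs$c4_median %||% median(labs$c4_mg_dl, na.rm = TRUE)
  )

  out <- labs |>
    dplyr::mutate(
      siri = siri,
      plr = plr,
      ratio_undefined = !ok,
      basopenia = .data$basophils < 10,
      eosinopenia = .data$eosinophils < 50,
      ige_low = .data$total_ige_ku_l < used$ige_low,
      ige_high = .data$total_ige_ku_l > used$ige_high,
      baso_high = .data$basophils > used$basophils_median,
      siri_high = siri > used$siri_median,
      plr_high = plr >= used$plr_median,
      c4_high = .data$c4_mg_dl > used$c4_median
    )
  attr(out, "cutoffs") <- used
  out
}

#' Starting omalizumab dose flag
#'
#' Whether each patient's first omalizumab injection was at least 300 mg.
#'
#' @inheritParams daily_dose
#' @return Tibble `patient_id`, `om_start_300` (logical).
#' @export
om_start_flags <- function(events) {
  check_events(events)
  events |>
    dplyr::filter(.data$drug_class == "OMALIZUMAB") |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      om_start_300 = .data$dose_mg_per_day[which.min(.data$start_day)] >= 300,
      .groups = "drop"
    )
}

#' Group comparisons of clinical features
#'
#' One-way ANOVA for continuous features and the Pearson chi-square test
#' (uncorrected) for categorical features, across the levels of `group` —
#' the style of baseline-characteristics comparison tables. Constant
#' features are reported with a `degenerate` flag instead of a statistic.
#'
#' @param data Tibble of per-patient features.
#' @param group Name of the grouping column in `data`.
#' @param vars Character vector of feature columns to compare; defaults to
#'   every column except the group and any id column.
#' @return Tibble `feature`, `type` (`"continuous"`/`"categorical"`),
#'   `statistic` (F or X-squared), `df`, `p_value`, `degenerate`.
#' @export
compare_groups <- function(data, group, vars = NULL) {
  stopifnot(group %in% names(data))
  vars <- vars %||% setdiff(names(data), c(group, "patient_id"))
  g <- as.factor(data[[group]])
  purrr::map_dfr(vars, function(v) {
    x <- data[[v]]
    keep <- !is.na(x) & !is.na(g)
    x <- x[keep]; gg <- droplevels(g[keep])
    continuous <- is.numeric(x) && length(unique(x)) > 2L
    if (length(unique(x)) <= 1L || nlevels(gg) < 2L) {
      return(tibble::tibble(feature = v,
                            type = if (continuous) "continuous" else "categorical",
                            statistic = NA_real_, df = NA_real_,
                            p_value = NA_real_, degenerate = TRUE))
    }
    if (continuous) {
      fit <- aov(x ~ gg)
      s <- summary(fit)[[1]]
      tibble::tibble(feature = v, type = "continuous",
                     statistic = s[["F value"]][1], df = s[["Df"]][1],
                     p_value = s[["Pr(>F)"]][1], degenerate = FALSE)
    } else {
      ct <- suppressWarnings(chisq.test(table(x, gg), correct = FALSE))
      tibble::tibble(feature = v, type = "categorical",
                     statistic = unname(ct$statistic),
                     df = unname(ct$parameter),
                     p_value = unname(ct$p.value), degenerate = FALSE)
    }
  })
}

#' Logit-link GLM screening of response predictors
#'
#' Fits a binomial GLM with logit link by maximum likelihood (iteratively
#' reweighted least squares) and reports odds ratios with Wald 95%
#' confidence intervals, `exp(beta +/- 1.96 SE)`. The design matrix is
#' checked for full rank before fitting and collinear columns are named in
#' the error; non-convergence and separation are reported via flags, never
#' silently.
#'
#' @param data Tibble with the outcome and covariate columns.
#' @param outcome Name of a binary (logical/0-1/two-level) outcome column.
#' @param covariates Character vector of covariate column names.
#' @param model_name Label carried into [forest_table()] output.
#' @return Object of class `logit_screen` wrapping the `glm` fit, with
#'   [tidy()] and [glance()] methods.
#' @export
#' @examples
#' d <- tibble::tibble(y = rep(c(1, 1, 0, 0), c(20, 30, 10, 40)),
#'                     x = rep(c(1, 0, 1, 0), c(20, 30, 10, 40)))
#' tidy(fit_logit(d, "y", "x"))  # OR = (20*40)/(30*10)
fit_logit <- function(data, outcome, covariates,
                      model_name = paste(outcome, "~ covariates")) {
  stopifnot(outcome %in% names(data), all(covariates %in% names(data)))
  d <- data[, c(outcome, covariates)]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  y <- d[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (is.character(y) || is.factor(y)) {
    y <- as.integer(as.factor(y)) - 1L
  }
  if (!all(y %in% c(0L, 1L))) {
    stop("`outcome` must be binary.", call. = FALSE)
  }
  d[[outcome]] <- y
  quote_term <- function(v) {
    ifelse(grepl("^[a-zA-Z.][a-zA-Z0-9._]*$", v), v, paste0("`", v, "`"))
  }
  fml <- as.formula(paste0(quote_term(outcome), " ~ ",
                           paste(quote_term(covariates), collapse = " + ")))
  X <- model.matrix(fml, data = d)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("design matrix is rank-deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    glm(fml, data = d, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  # glm does not always warn on complete separation; extreme fitted
  # probabilities are the reliable symptom
  mu <- fit$fitted.values
  if (any(mu < 1e-8 | mu > 1 - 1e-8)) separation <- TRUE
  structure(
    list(fit = fit, model_name = model_name, n = nrow(d),
         converged = fit$converged, separation = separation),
    class = "logit_screen"
  )
}

#' @export
print.logit_screen <- function(x, ...) {
  cat("<logit_screen>", x$model_name, "- n =", x$n,
      if (!x$converged) "[NOT CONVERGED]" else "",
      if (x$separation) "[SEPARATION]" else "", "\n")
  print(tidy(x))
  invisible(x)
}

#' @describeIn fit_logit Coefficients as odds ratios with Wald 95% CIs:
#'   columns `term`, `estimate` (log-odds), `std_error`, `odds_ratio`,
#'   `conf_low`, `conf_high`, `p_value`.
#' @param x A `logit_screen` object.
#' @param ... Unused.
#' @export
tidy.logit_screen <- function(x, ...) {
  b <- coef(x$fit)
  se <- sqrt(diag(vcov(x$fit)))
  z <- b / se
  tibble::tibble(
    term = names(b),
    estimate = unname(b),
    std_error = unname(se),
    odds_ratio = exp(unname(b)),
    conf_low = exp(unname(b - 1.96 * se)),
    conf_high = exp(unname(b + 1.96 * se)),
    p_value = 2 * pnorm(-abs(unname(z)))
  )
}

#' @describeIn fit_logit One-row model summary: `model`, `n`,
#'   `null_deviance`, `deviance`, `aic`, `converged`, `separation`.
#' @export
glance.logit_screen <- function(x, ...) {
  tibble::tibble(
    model = x$model_name, n = x$n,
    null_deviance = x$fit$null.deviance, deviance = x$fit$deviance,
    aic = x$fit$aic, converged = x$converged, separation = x$separation
  )
}

#' Forest-style table of odds ratios across models
#'
#' Stacks the [tidy()] output of several `logit_screen` fits into one tidy
#' table (intercept rows dropped), preserving covariate order — the tabular
#' counterpart of a forest plot with its no-effect line at OR = 1.
#'
#' @param models A named list of `logit_screen` objects (or a single one).
#' @return Tibble `model`, `term`, `odds_ratio`, `conf_low`, `conf_high`,
#'   `p_value`.
#' @export
forest_table <- function(models) {
  if (inherits(models, "logit_screen")) models <- list(models)
  if (length(models) == 0L) {
    return(tibble::tibble(model = character(), term = character(),
                          odds_ratio = double(), conf_low = double(),
                          conf_high = double(), p_value = double()))
  }
  names(models) <- names(models) %||%
    vapply(models, function(m) m$model_name, character(1))
  purrr::imap_dfr(models, function(m, nm) {
    tidy(m) |>
      dplyr::filter(.data$term != "(Intercept)") |>
      dplyr::transmute(model = nm, term = .data$term,
                       odds_ratio = .data$odds_ratio,
                       conf_low = .data$conf_low,
                       conf_high = .data$conf_high,
                       p_value = .data$p_value)
  })
}
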