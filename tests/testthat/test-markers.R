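fake_labs <- function(n = 8, seed = 1) {
  set.seed(seed)
  tibble::tibble(
    patient_id = sprintf("P%02d", seq_len(n)),
    wbc = 7700,
    neutrophils = runif(n, 2000, 8000),
    lymphocytes = runif(n, 1200, 3500),
    monocytes = runif(n, 300, 800),
    eosinophils = runif(n, 20, 400),
    basophils = runif(n, 5, 80),
    platelets = runif(n, 12000, 35000),
    total_ige_ku_l = exp(runif(n, 2, 7)),
    c3_mg_dl = runif(n, 90, 140),
    c4_mg_dl = runif(n, 12, 40),
    sex = rep(c("F", "M"), length.out = n),
    age_years = runif(n, 20, 70)
  )
}

test_that("derived markers follow the published formulas", {
  labs <- fake_labs(3)
  labs$neutrophils[1] <- 4000; labs$monocytes[1] <- 500
  labs$lymphocytes[1] <- 2000; labs$platelets[1] <- 22000
  m <- derive_markers(labs)
  expect_equal(m$siri[1], 1.0)   # (4 x 0.5) / 2 on the 10^3/uL scale
  expect_equal(m$plr[1], 11.0)

  # basopenia strict at 10/uL, eosinopenia strict at 50/uL
  labs2 <- fake_labs(4)
  labs2$basophils <- c(9, 10, 10.5, 0)
  labs2$eosinophils <- c(49, 50, 51, 0)
  m2 <- derive_markers(labs2)
  expect_equal(m2$basopenia, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(m2$eosinopenia, c(TRUE, FALSE, FALSE, TRUE))

  # zero lymphocytes: ratios undefined and flagged, not an error
  labs3 <- fake_labs(2)
  labs3$lymphocytes[2] <- 0
  m3 <- derive_markers(labs3)
  expect_true(is.na(m3$siri[2]) && is.na(m3$plr[2]))
  expect_true(m3$ratio_undefined[2])
  expect_false(m3$ratio_undefined[1])
})

test_that("cutoffs default to cohort percentiles and can be pinned", {
  labs <- fake_labs(200, seed = 7)
  m <- derive_markers(labs)
  used <- attr(m, "cutoffs")
  expect_equal(used$ige_low,
               unname(quantile(labs$total_ige_ku_l, 0.10)))
  expect_equal(used$ige_high,
               unname(quantile(labs$total_ige_ku_l, 0.90)))
  expect_equal(mean(m$ige_low), 0.10, tolerance = 0.02)
  expect_equal(mean(m$ige_high), 0.10, tolerance = 0.02)

  pinned <- derive_markers(labs, marker_cutoffs(ige_low = 40,
                                                ige_high = 798.5,
                                                plr_median = 11.5))
  expect_equal(attr(pinned, "cutoffs")$ige_low, 40)
  expect_equal(pinned$ige_low, labs$total_ige_ku_l < 40)
  expect_equal(pinned$plr_high, pinned$plr >= 11.5)
})

test_that("scaling all cell counts leaves PLR flags fixed and scales SIRI", {
  labs <- fake_labs(50, seed = 3)
  m1 <- derive_markers(labs)
  scaled <- labs
  cols <- c("neutrophils", "lymphocytes", "monocytes", "eosinophils",
            "basophils", "platelets")
  scaled[cols] <- scaled[cols] * 3
  m2 <- derive_markers(scaled)
  expect_equal(m2$plr, m1$plr)
  expect_equal(m2$plr_high, m1$plr_high)
  expect_equal(m2$siri, 3 * m1$siri)
  expect_equal(m2$siri_high, m1$siri_high)  # median flags scale-invariant
})

test_that("group comparisons dispatch ANOVA and chi-square correctly", {
  set.seed(11)
  d <- tibble::tibble(
    grp = rep(c("a", "b", "c"), each = 20),
    cont = c(rnorm(20, 0), rnorm(20, 1), rnorm(20, 2)),
    flat = rnorm(60),
    bin = rbinom(60, 1, 0.5) == 1,
    const = 1
  )
  out <- compare_groups(d, "grp")
  expect_equal(out$type[out$feature == "cont"], "continuous")
  expect_equal(out$type[out$feature == "bin"], "categorical")
  expect_true(out$degenerate[out$feature == "const"])
  expect_lt(out$p_value[out$feature == "cont"], 0.001)
  expect_gt(out$p_value[out$feature == "flat"], 0.01)

  # identical groups: F is (numerically) 0
  d2 <- tibble::tibble(grp = rep(c("a", "b"), each = 3),
                       v = rep(c(1, 2, 3), 2))
  out2 <- compare_groups(d2, "grp", "v")
  expect_equal(out2$statistic, 0, tolerance = 1e-12)

  # 2x2 chi-square equals the (ad - bc)^2 N / (row x col products) formula
  a <- 12; b <- 8; cc <- 5; dd <- 15
  d3 <- tibble::tibble(
    grp = rep(c("g1", "g2"), c(a + b, cc + dd)),
    flag = c(rep(c(TRUE, FALSE), c(a, b)), rep(c(TRUE, FALSE), c(cc, dd)))
  )
  out3 <- compare_groups(d3, "grp", "flag")
  n_tot <- a + b + cc + dd
  hand <- (a * dd - b * cc)^2 * n_tot /
    ((a + b) * (cc + dd) * (a + cc) * (b + dd))
  expect_equal(out3$statistic, hand, tolerance = 1e-10)
})

test_that("logistic fit reproduces the closed-form 2x2 odds ratio", {
  d <- tibble::tibble(
    y = rep(c(1, 1, 0, 0), c(20, 30, 10, 40)),
    x = rep(c(1, 0, 1, 0), c(20, 30, 10, 40))
  )
  fit <- fit_logit(d, "y", "x")
  td <- tidy(fit)
  expect_equal(td$odds_ratio[td$term == "x"], (20 * 40) / (30 * 10),
               tolerance = 1e-6)
  expect_equal(td$odds_ratio, exp(td$estimate))
  expect_true(all(td$conf_low <= td$conf_high))
  expect_true(glance(fit)$converged)

  # a covariate independent of the outcome has OR ~ 1
  d2 <- tibble::tibble(y = rep(c(0, 1), 50), x = rep(c(0, 1), each = 50))
  td2 <- tidy(fit_logit(d2, "y", "x"))
  expect_equal(td2$odds_ratio[2], 1, tolerance = 1e-6)
})

test_that("collinear designs error naming the columns; separation is flagged", {
  d <- tibble::tibble(y = rbinom(30, 1, 0.5), x1 = rnorm(30))
  d$x2 <- 2 * d$x1
  expect_error(fit_logit(d, "y", c("x1", "x2")), "collinear.*x2")

  sep <- tibble::tibble(y = rep(c(0, 1), each = 20),
                        x = rep(c(0, 1), each = 20))
  fit <- fit_logit(sep, "y", "x")
  expect_true(fit$separation)
  expect_true(glance(fit)$separation)
})

test_that("coefficients are recovered from simulated logistic data", {
  set.seed(2024)
  n <- 5000
  beta <- c(intercept = -0.5, x1 = 0.8, x2 = -0.4)
  x1 <- rnorm(n)
  x2 <- rbinom(n, 1, 0.4)
  eta <- beta[1] + beta[2] * x1 + beta[3] * x2
  y <- rbinom(n, 1, 1 / (1 + exp(-eta)))
  d <- tibble::tibble(y = y, x1 = x1, x2 = x2)
  td <- tidy(fit_logit(d, "y", c("x1", "x2")))
  expect_true(all(abs(td$estimate - beta) <= 3 * td$std_error))

  # consistency: bias shrinks with n
  errs <- vapply(c(500, 5000), function(m) {
    td_m <- tidy(fit_logit(d[seq_len(m), ], "y", c("x1", "x2")))
    sqrt(mean((td_m$estimate - beta)^2))
  }, numeric(1))
  expect_lt(errs[2], errs[1] + 0.05)
})

test_that("forest tables stack models tidily and round-trip through CSV", {
  expect_equal(nrow(forest_table(list())), 0)
  d <- tibble::tibble(y = rbinom(80, 1, 0.5), a = rnorm(80), b = rnorm(80))
  m1 <- fit_logit(d, "y", c("a", "b"), model_name = "one")
  m2 <- fit_logit(d, "y", "a", model_name = "two")
  ft <- forest_table(list(one = m1, two = m2))
  expect_equal(ft$model, c("one", "one", "two"))
  expect_equal(ft$term[1:2], c("a", "b"))  # input covariate order kept
  expect_false("(Intercept)" %in% ft$term)

  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(ft, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(as.data.frame(back), as.data.frame(ft), tolerance = 1e-12)
})
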