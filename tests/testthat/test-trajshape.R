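test_that("k = 1 puts everyone in one cluster; perfectly separated groups split", {
  sim <- simulate_trajectory_classes(12, noise_sd = 0.2, seed = 3)
  one <- shape_kmeans(sim$trajectories, k = 1, seed = 1)
  expect_true(all(one$assignments$cluster == 1))

  # three copies each of three distinct constant trajectories
  mat <- rbind(matrix(0, 3, 9), matrix(1.5, 3, 9), matrix(3, 3, 9))
  rownames(mat) <- sprintf("T%02d", 1:9)
  fit <- shape_kmeans(mat, k = 3, seed = 1)
  expect_equal(fit$objective, 0)
  groups <- split(fit$assignments$patient_id, fit$assignments$cluster)
  expect_equal(lengths(groups), c(`1` = 3L, `2` = 3L, `3` = 3L))
  # label 1 is the most favorable (highest terminal level)
  expect_setequal(groups[["1"]], sprintf("T%02d", 7:9))
  expect_setequal(groups[["3"]], sprintf("T%02d", 1:3))

  expect_error(shape_kmeans(mat, k = 10, seed = 1), "cannot exceed")
  mat[1, 1] <- NA
  expect_error(shape_kmeans(mat, k = 2, seed = 1), "finite")
})

test_that("latent shape classes are recovered with high adjusted Rand index", {
  sim <- simulate_trajectory_classes(300, noise_sd = 0.3, seed = 11)
  fit <- shape_kmeans(sim$trajectories, k = 3, seed = 11)
  merged <- dplyr::inner_join(fit$assignments, sim$classes, by = "patient_id")
  ari <- mclust::adjustedRandIndex(merged$cluster, merged$class)
  expect_gte(ari, 0.9)
})

test_that("the fit is deterministic and invariant to input row order", {
  sim <- simulate_trajectory_classes(40, seed = 5)
  f1 <- shape_kmeans(sim$trajectories, k = 3, seed = 2)
  f2 <- shape_kmeans(sim$trajectories, k = 3, seed = 2)
  expect_identical(f1$assignments, f2$assignments)
  shuffled <- sim$trajectories[sample(nrow(sim$trajectories)), ]
  f3 <- shape_kmeans(shuffled, k = 3, seed = 2)
  expect_identical(f1$assignments, f3$assignments)
})

test_that("cluster mean curves are pointwise member means", {
  mat <- rbind(a = rep(0, 9), b = rep(2, 9), c = rep(3, 9))
  fit <- shape_kmeans(mat, k = 2, seed = 1)
  curves <- cluster_mean_curves(fit, mat)
  # singleton cluster reproduces its member; the pair averages
  sizes <- dplyr::count(fit$assignments, cluster)
  pair <- sizes$cluster[sizes$n == 2]
  members <- fit$assignments$patient_id[fit$assignments$cluster == pair]
  expected <- colMeans(mat[members, , drop = FALSE])
  expect_equal(curves$mean_value[curves$cluster == pair], unname(expected))
  single <- sizes$cluster[sizes$n == 1]
  m1 <- fit$assignments$patient_id[fit$assignments$cluster == single]
  expect_equal(curves$mean_value[curves$cluster == single],
               unname(mat[m1, ]))
})

test_that("tidy/glance/augment summarise the fit", {
  sim <- simulate_trajectory_classes(30, seed = 9)
  fit <- shape_kmeans(sim$trajectories, k = 3, seed = 1)
  td <- tidy(fit)
  expect_equal(sum(td$size), 30)
  expect_equal(td$cluster, 1:3)
  gl <- glance(fit)
  expect_equal(gl$n, 30)
  expect_gte(gl$objective, 0)
  aug <- augment(fit, sim$trajectories)
  expect_true(all(!is.na(aug$.cluster)))
  expect_equal(nrow(aug), nrow(sim$trajectories))
})

test_that("stratified refits partition the patients", {
  sim <- simulate_trajectory_classes(60, seed = 13)
  strata <- tibble::tibble(
    patient_id = sim$classes$patient_id,
    stratum = rep(c("<1y", ">=1y"), length.out = 60)
  )
  fits <- stratify_and_refit(sim$trajectories, strata, k = 3, seed = 1)
  expect_named(fits, c("<1y", ">=1y"))
  ids <- unlist(lapply(fits, function(f) f$assignments$patient_id))
  expect_setequal(ids, sim$classes$patient_id)
  expect_equal(length(ids), 60)

  # degenerate single stratum is identical to a plain fit
  one <- stratify_and_refit(sim$trajectories,
                            dplyr::mutate(strata, stratum = "all"),
                            k = 3, seed = 1)
  plain <- shape_kmeans(sim$trajectories, k = 3, seed = 1)
  expect_equal(one$all$assignments, plain$assignments)

  # per-stratum recovery stays high when strata have different mixtures
  sim2 <- simulate_trajectory_classes(200, noise_sd = 0.3, seed = 17)
  st2 <- tibble::tibble(patient_id = sim2$classes$patient_id,
                        stratum = rep(c("A", "B"), each = 100))
  fits2 <- stratify_and_refit(sim2$trajectories, st2, k = 3, seed = 17)
  for (s in names(fits2)) {
    m <- dplyr::inner_join(fits2[[s]]$assignments, sim2$classes,
                           by = "patient_id")
    expect_gte(mclust::adjustedRandIndex(m$cluster, m$class), 0.8)
  }
})

test_that("maintenance strata split on one year of omalizumab coverage", {
  short <- purrr::map_dfr(seq(0, 150, by = 30), function(d) {
    event_row("S", "OMALIZUMAB", 300, d, 30)
  })
  long <- purrr::map_dfr(seq(0, 390, by = 30), function(d) {
    event_row("L", "OMALIZUMAB", 300, d, 30)
  })
  strata <- maintenance_strata(dplyr::bind_rows(short, long))
  expect_equal(strata$stratum[strata$patient_id == "S"], "<1y")
  expect_equal(strata$stratum[strata$patient_id == "L"], ">=1y")
})
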