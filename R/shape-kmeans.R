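#' Shape-respecting K-means for response trajectories
#'
#' Clusters ordinal response trajectories with Lloyd-style alternation
#' under the discrete Frechet distance ([discrete_frechet()]): patients are
#' assigned to the nearest center, and each center is updated to the
#' cluster medoid (the member minimising the summed distance to all other
#' members). Medoid centers keep the update well-defined and deterministic
#' on a non-Euclidean distance. Initial centers are picked by a greedy
#' farthest-point sweep from a seed-selected start; ties always break
#' toward the lowest patient index, so the fit is a pure function of
#' (data, k, seed).
#'
#' After fitting, clusters are relabelled `1..k` by descending mean
#' terminal value, so cluster 1 is the most favorable (highest response
#' at the end of follow-up) and cluster `k` the poorest.
#'
#' @param trajectories Either a long tibble with columns `patient_id`,
#'   `month` and `code` (as from [response_trajectories()]) or a numeric
#'   matrix with one trajectory per row (rownames used as patient ids).
#' @param k Number of clusters (default 3).
#' @param seed Integer seed selecting the initial center sweep start.
#' @param max_iter Maximum Lloyd iterations.
#' @return An object of class `shape_kmeans` with elements `assignments`
#'   (tibble `patient_id`, `cluster`), `centers` (tibble of medoid
#'   trajectories in long form), `objective` (total within-cluster distance
#'   to medoids), `iterations`, `k`, `medoid_ids`.
#' @export
#' @examples
#' sim <- simulate_trajectory_classes(n = 30, seed = 1)
#' fit <- shape_kmeans(sim$trajectories, k = 3, seed = 1)
#' tidy(fit)
shape_kmeans <- function(trajectories, k = 3L, seed = 1L, max_iter = 50L) {
  mat <- trajectories_matrix(trajectories)
  n <- nrow(mat)
  if (k < 1L) stop("`k` must be at least 1.", call. = FALSE)
  if (k > n) {
    stop("`k` (", k, ") cannot exceed the number of trajectories (", n, ").",
         call. = FALSE)
  }
  if (!all(is.finite(mat))) {
    stop("trajectories must be finite.", call. = FALSE)
  }
  d <- frechet_distance_matrix(mat)

  # greedy farthest-point initialisation from a seed-selected start
  set.seed(seed)
  centers <- sample.int(n, 1L)
  while (length(centers) < k) {
    mind <- apply(d[, centers, drop = FALSE], 1, min)
    mind[centers] <- -Inf
    centers <- c(centers, which.max(mind))  # which.max: lowest index on ties
  }

  assign_step <- function(centers) {
    # nearest center, ties toward the lowest center label
    apply(d[, centers, drop = FALSE], 1, which.min)
  }
  assign <- assign_step(centers)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # medoid update: member minimising summed within-cluster distance
    new_centers <- vapply(seq_len(k), function(g) {
      members <- which(assign == g)
      if (length(members) == 0L) {
        # re-seed an empty cluster with the point farthest from its center
        worst <- which.max(vapply(seq_len(n),
                                  function(i) d[i, centers[assign[i]]],
                                  numeric(1)))
        return(worst)
      }
      sums <- colSums(d[members, members, drop = FALSE])
      members[which.min(sums)]
    }, integer(1))
    new_assign <- assign_step(new_centers)
    centers <- new_centers
    if (identical(new_assign, assign) || iter >= max_iter) {
      assign <- new_assign
      break
    }
    assign <- new_assign
  }

  # order labels by descending mean terminal value: 1 = most favorable
  terminal <- vapply(seq_len(k), function(g) {
    members <- which(assign == g)
    if (length(members) == 0L) -Inf else mean(mat[members, ncol(mat)])
  }, numeric(1))
  ord <- order(terminal, decreasing = TRUE)
  relabel <- match(seq_len(k), ord)
  assign <- relabel[assign]
  centers <- centers[ord]

  objective <- sum(vapply(seq_len(n), function(i) d[i, centers[assign[i]]],
                          numeric(1)))
  ids <- rownames(mat)
  months <- as.integer(sub("^m", "", colnames(mat)))
  centers_long <- purrr::map_dfr(seq_len(k), function(g) {
    tibble::tibble(cluster = g, month = months,
                   value = unname(mat[centers[g], ]))
  })
  structure(
    list(
      assignments = tibble::tibble(patient_id = ids,
                                   cluster = as.integer(assign)),
      centers = centers_long,
      medoid_ids = ids[centers],
      objective = objective,
      iterations = iter,
      k = as.integer(k),
      seed = as.integer(seed)
    ),
    class = "shape_kmeans"
  )
}

# Accept a long (patient_id, month, code/value) tibble or a plain matrix;
# return a patient x month matrix with m<month> colnames, rows sorted by id.
trajectories_matrix <- function(trajectories) {
  if (is.matrix(trajectories)) {
    mat <- trajectories
    if (is.null(rownames(mat))) rownames(mat) <- as.character(seq_len(nrow(mat)))
    if (is.null(colnames(mat))) {
      colnames(mat) <- paste0("m", assessment_months()[seq_len(ncol(mat))])
    }
    return(mat)
  }
  value_col <- intersect(c("code", "value"), names(trajectories))[1]
  if (is.na(value_col)) {
    stop("`trajectories` must have a `code` or `value` column.", call. = FALSE)
  }
  wide <- trajectories |>
    dplyr::select("patient_id", "month", dplyr::all_of(value_col)) |>
    dplyr::arrange(.data$patient_id, .data$month) |>
    tidyr::pivot_wider(names_from = "month",
                       values_from = dplyr::all_of(value_col),
                       names_prefix = "m")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$patient_id
  mat
}

#' @export
print.shape_kmeans <- function(x, ...) {
  sizes <- table(x$assignments$cluster)
  cat("<shape_kmeans> k =", x$k, "; sizes:",
      paste(sizes, collapse = "/"),
      sprintf("; objective %.3f after %d iteration(s)\n",
              x$objective, x$iterations))
  invisible(x)
}

#' Pointwise mean curve of each cluster
#'
#' @param model A [shape_kmeans()] fit.
#' @param trajectories The trajectories the model was fitted to (long
#'   tibble or matrix).
#' @return Tibble `cluster`, `month`, `mean_value`, `n`.
#' @export
cluster_mean_curves <- function(model, trajectories) {
  mat <- trajectories_matrix(trajectories)
  months <- as.integer(sub("^m", "", colnames(mat)))
  assign <- model$assignments
  purrr::map_dfr(sort(unique(assign$cluster)), function(g) {
    members <- assign$patient_id[assign$cluster == g]
    sub <- mat[rownames(mat) %in% members, , drop = FALSE]
    tibble::tibble(cluster = g, month = months,
                   mean_value = unname(colMeans(sub)), n = nrow(sub))
  })
}

#' Refit the clustering within strata
#'
#' Runs an independent [shape_kmeans()] per stratum (e.g. omalizumab
#' maintenance duration below versus at least one year).
#'
#' @param trajectories Long tibble or matrix of trajectories.
#' @param strata Tibble `patient_id`, `stratum`.
#' @param k,seed,max_iter Passed to [shape_kmeans()].
#' @return Named list of `shape_kmeans` fits, one per stratum level.
#' @export
stratify_and_refit <- function(trajectories, strata, k = 3L, seed = 1L,
                               max_iter = 50L) {
  mat <- trajectories_matrix(trajectories)
  levels <- sort(unique(strata$stratum))
  fits <- lapply(levels, function(s) {
    ids <- strata$patient_id[strata$stratum == s]
    sub <- mat[rownames(mat) %in% ids, , drop = FALSE]
    shape_kmeans(sub, k = min(k, nrow(sub)), seed = seed, max_iter = max_iter)
  })
  names(fits) <- as.character(levels)
  fits
}

#' Omalizumab maintenance-duration strata
#'
#' Splits patients by whether omalizumab coverage (first injection to end
#' of last injection interval) lasted less than one year or at least one
#' year, the stratification used for the sensitivity re-clustering.
#'
#' @inheritParams daily_dose
#' @param threshold_days Stratum boundary (default 365).
#' @return Tibble `patient_id`, `stratum` (`"<1y"` / `">=1y"`).
#' @export
maintenance_strata <- function(events, threshold_days = 365L) {
  check_events(events)
  events |>
    dplyr::filter(.data$drug_class == "OMALIZUMAB") |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      duration = max(.data$start_day + .data$duration_days) -
        min(.data$start_day),
      .groups = "drop"
    ) |>
    dplyr::mutate(stratum = dplyr::if_else(.data$duration < threshold_days,
                                           "<1y", ">=1y")) |>
    dplyr::select("patient_id", "stratum")
}

#' Simulate trajectories from three canonical shape classes
#'
#' Generates equal-thirds mixtures of three latent shapes on the ordinal
#' 0-3 response scale over the nine assessment months — monotone
#' improvement (rising 0 to 3), a hump (transient improvement that
#' relapses), and flat-low (persistent nonresponse) — with additive
#' Gaussian noise. Used for clustering recovery experiments where the
#' ground truth is known.
#'
#' @param n Number of trajectories.
#' @param noise_sd Standard deviation of the additive noise (default 0.3).
#' @param seed Integer seed.
#' @return List with `trajectories` (long tibble `patient_id`, `month`,
#'   `value`) and `classes` (tibble `patient_id`, `class`).
#' @export
simulate_trajectory_classes <- function(n, noise_sd = 0.3, seed = 1L) {
  months <- assessment_months()
  t01 <- grid_times(months)
  shapes <- list(
    up = 3 * t01,
    hump = 3 * sin(pi * t01),
    flat = rep(0.3, length(months))
  )
  set.seed(seed)
  class <- rep(names(shapes), length.out = n)
  ids <- sprintf("S%04d", seq_len(n))
  traj <- purrr::map_dfr(seq_len(n), function(i) {
    tibble::tibble(
      patient_id = ids[i], month = months,
      value = shapes[[class[i]]] + rnorm(length(months), 0, noise_sd)
    )
  })
  list(trajectories = traj,
       classes = tibble::tibble(patient_id = ids, class = class))
}
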