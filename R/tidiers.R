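#' Tidy a shape-respecting K-means fit
#'
#' @param x A [shape_kmeans()] object.
#' @param ... Unused.
#' @return One row per cluster: `cluster`, `size`, `medoid_id`,
#'   `within_objective`, `terminal_mean` (mean value at the last
#'   assessment month among members of the center trajectory).
#' @export
tidy.shape_kmeans <- function(x, ...) {
  per_cluster <- x$assignments |>
    dplyr::count(.data$cluster, name = "size")
  terminal <- x$centers |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(terminal_mean = .data$value[which.max(.data$month)],
                     .groups = "drop")
  per_cluster |>
    dplyr::mutate(medoid_id = x$medoid_ids[.data$cluster]) |>
    dplyr::left_join(terminal, by = "cluster")
}

#' @describeIn tidy.shape_kmeans One-row fit summary: `k`, `n`,
#'   `objective`, `iterations`, `seed`.
#' @export
glance.shape_kmeans <- function(x, ...) {
  tibble::tibble(
    k = x$k, n = nrow(x$assignments), objective = x$objective,
    iterations = x$iterations, seed = x$seed
  )
}

#' @describeIn tidy.shape_kmeans Attach the cluster assignment to a long
#'   trajectory tibble as column `.cluster`.
#' @param data Long trajectory tibble with a `patient_id` column.
#' @export
augment.shape_kmeans <- function(x, data, ...) {
  dplyr::left_join(
    data,
    dplyr::rename(x$assignments, .cluster = "cluster"),
    by = "patient_id"
  )
}
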