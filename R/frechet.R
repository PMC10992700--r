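#' Discrete Frechet distance between two trajectories
#'
#' The shape-respecting distance used by the trajectory clustering: the
#' minimum, over all monotone couplings of the two point sequences, of the
#' maximum Euclidean distance between coupled points, computed by dynamic
#' programming. It is symmetric, non-negative, zero exactly for identical
#' sequences, and satisfies the triangle inequality.
#'
#' By default trajectories are placed on the assessment grid with the time
#' axis rescaled to `[0, 1]` and values left on the 0-3 ordinal response
#' scale, so that shape differences in time and level are commensurate.
#' Sequences of unequal length are accepted.
#'
#' @param a,b Numeric value sequences (e.g. ordinal response codes).
#' @param time_a,time_b Optional time coordinates for each sequence. If
#'   `NULL`, a length-9 sequence gets the rescaled assessment grid and any
#'   other length an equally spaced grid on `[0, 1]`.
#' @return A single non-negative distance.
#' @export
#' @examples
#' discrete_frechet(c(0, 0, 0), c(1, 1, 1))  # 1: all couplings gap 1
discrete_frechet <- function(a, b, time_a = NULL, time_b = NULL) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("trajectories must be non-empty.", call. = FALSE)
  }
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("trajectories must be finite.", call. = FALSE)
  }
  time_a <- time_a %||% default_times(length(a))
  time_b <- time_b %||% default_times(length(b))
  stopifnot(length(time_a) == length(a), length(time_b) == length(b))
  cpp_discrete_frechet(as.numeric(time_a), as.numeric(a),
                       as.numeric(time_b), as.numeric(b))
}

default_times <- function(n) {
  if (n == length(assessment_months())) return(grid_times())
  if (n == 1L) return(0)
  seq(0, 1, length.out = n)
}

#' Pairwise Frechet distance matrix
#'
#' @param values Numeric matrix, one trajectory per row, all on the same
#'   time grid.
#' @param times Time coordinates of the columns; defaults as in
#'   [discrete_frechet()].
#' @return Symmetric `nrow(values)` square matrix of distances.
#' @export
frechet_distance_matrix <- function(values, times = NULL) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) {
    stop("trajectories must be finite.", call. = FALSE)
  }
  times <- times %||% default_times(ncol(values))
  cpp_frechet_matrix(values, as.numeric(times))
}
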