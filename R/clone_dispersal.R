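# Clone dispersal statistics: mean pairwise distance and mean distance to
# the clone's center of mass, per timepoint.

clone_points_matrix <- function(points, dims = c("3d", "2d")) {
  dims <- match.arg(dims)
  m <- if (is.data.frame(points)) {
    cols <- c("x_um", "y_um", "z_um")
    require_columns(points, cols[1:2], "point set")
    if (dims == "3d") {
      require_columns(points, cols, "point set")
      as.matrix(points[, cols])
    } else {
      as.matrix(points[, cols[1:2]])
    }
  } else {
    mm <- as.matrix(points)
    if (dims == "2d") mm[, 1:2, drop = FALSE] else mm
  }
  storage.mode(m) <- "double"
  if (!all(is.finite(m))) stop("point set has non-finite coordinates", call. = FALSE)
  m
}

#' Mean pairwise distance of a point set
#'
#' Mean Euclidean distance over all unordered pairs of labelled nuclei.
#'
#' @param points data frame with `x_um`, `y_um`, `z_um` (or a coordinate
#'   matrix); at least two points.
#' @param dims `"3d"` (default) or `"2d"` (drop the z coordinate, for
#'   sensitivity checks).
#' @return Mean pairwise distance in µm.
#' @export
mean_pairwise_distance <- function(points, dims = c("3d", "2d")) {
  m <- clone_points_matrix(points, dims)
  if (nrow(m) < 2L) stop("at least two points required", call. = FALSE)
  mean(stats::dist(m))
}

#' Mean distance to the center of mass
#'
#' Mean Euclidean distance of each labelled nucleus to the arithmetic
#' centroid of the set.
#'
#' @inheritParams mean_pairwise_distance
#' @return Mean centroid distance in µm.
#' @export
mean_centroid_distance <- function(points, dims = c("3d", "2d")) {
  m <- clone_points_matrix(points, dims)
  if (nrow(m) < 1L) stop("at least one point required", call. = FALSE)
  ctr <- colMeans(m)
  mean(sqrt(rowSums(sweep(m, 2L, ctr)^2)))
}

#' Dispersal metrics over a clone track
#'
#' Computes both dispersal proxies at every timepoint of a clone track.
#'
#' @param track data frame with `timepoint_min`, `cell_id`, `x_um`, `y_um`,
#'   `z_um`; timepoints strictly increasing, at least two cells each.
#' @param dims `"3d"` (default) or `"2d"`.
#' @return Data frame with `timepoint_min`, `n_cells`, `mean_pairwise_um`,
#'   `mean_centroid_um`.
#' @export
dispersal_timecourse <- function(track, dims = c("3d", "2d")) {
  dims <- match.arg(dims)
  require_columns(track, c("timepoint_min", "cell_id", "x_um", "y_um", "z_um"),
                  "clone track")
  tps <- sort(unique(track$timepoint_min))
  rows <- lapply(tps, function(tp) {
    pts <- track[track$timepoint_min == tp, , drop = FALSE]
    res <- tryCatch(
      data.frame(timepoint_min = tp, n_cells = nrow(pts),
                 mean_pairwise_um = mean_pairwise_distance(pts, dims),
                 mean_centroid_um = mean_centroid_distance(pts, dims)),
      error = function(e) {
        stop(sprintf("timepoint %g min: %s", tp, conditionMessage(e)), call. = FALSE)
      })
    res
  })
  do.call(rbind, rows)
}
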