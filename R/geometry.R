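# 3D-to-2D projection, wound re-centering and nearest-reference distances.

#' Construct a projection frame
#'
#' A projection frame defines the 2D plane that detected nuclei are projected
#' into: a unit projection axis, an origin, and an orthonormal in-plane basis.
#' The in-plane basis is obtained by Gram-Schmidt orthogonalisation of the
#' world X axis against the projection axis (falling back to the world Y axis
#' when the projection axis is parallel to X), so that in-plane coordinates
#' are reproducible across runs. Only pairwise distances and angles are
#' analysis-relevant; the fixed convention additionally makes raw (u, v)
#' coordinates testable.
#'
#' @param axis numeric length-3 projection direction; need not be normalised.
#' @param origin numeric length-3 origin of the plane, in micrometres.
#' @return An object of class `projection_frame`: a list with `axis` (unit
#'   vector), `origin`, and orthonormal in-plane basis vectors `e1`, `e2`.
#' @examples
#' frame <- projection_frame(c(0, 0, 1))
#' frame$e1  # world X
#' @export
projection_frame <- function(axis, origin = c(0, 0, 0)) {
  axis <- as.numeric(axis)
  origin <- as.numeric(origin)
  if (length(axis) != 3L || length(origin) != 3L) {
    stop("`axis` and `origin` must be numeric vectors of length 3", call. = FALSE)
  }
  if (!all(is.finite(axis)) || !all(is.finite(origin))) {
    stop("`axis` and `origin` must be finite", call. = FALSE)
  }
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-12) stop("projection axis has zero length", call. = FALSE)
  a <- axis / nrm
  e1 <- c(1, 0, 0) - sum(c(1, 0, 0) * a) * a
  if (sqrt(sum(e1^2)) < 1e-6) {
    e1 <- c(0, 1, 0) - sum(c(0, 1, 0) * a) * a
  }
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(a, e1)
  structure(list(axis = a, origin = origin, e1 = e1, e2 = e2),
            class = "projection_frame")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

as_xyz_matrix <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  if (is.data.frame(x)) {
    cols <- intersect(c("x_um", "y_um", "z_um"), names(x))
    if (length(cols) >= 2L) {
      return(as.matrix(x[, cols, drop = FALSE]))
    }
    cols <- intersect(c("u_um", "v_um"), names(x))
    if (length(cols) == 2L) {
      return(as.matrix(x[, cols, drop = FALSE]))
    }
    stop("data frame has no coordinate columns (x_um/y_um/z_um or u_um/v_um)",
         call. = FALSE)
  }
  matrix(as.numeric(x), nrow = 1L)
}

#' Project points into the plane of a projection frame
#'
#' Removes the component of each point along the frame's projection axis and
#' expresses the remainder in the frame's in-plane orthonormal basis. The
#' point count is preserved and the map is idempotent on (u, v).
#'
#' @param nuclei a nucleus table (data frame with `x_um`, `y_um`, `z_um` and
#'   optionally `nucleus_id`), or a numeric matrix with 3 columns.
#' @param frame a [projection_frame()].
#' @return Data frame with columns `nucleus_id`, `u_um`, `v_um`.
#' @export
project_to_plane <- function(nuclei, frame) {
  stopifnot(inherits(frame, "projection_frame"))
  m <- as_xyz_matrix(nuclei)
  if (nrow(m) == 0L) stop("no points to project", call. = FALSE)
  if (ncol(m) != 3L) stop("points must be 3D for projection", call. = FALSE)
  centred <- sweep(m, 2L, frame$origin)
  u <- as.numeric(centred %*% frame$e1)
  v <- as.numeric(centred %*% frame$e2)
  ids <- if (is.data.frame(nuclei) && "nucleus_id" %in% names(nuclei)) {
    nuclei$nucleus_id
  } else {
    seq_len(nrow(m))
  }
  data.frame(nucleus_id = ids, u_um = u, v_um = v)
}

as_uv_matrix <- function(x) {
  if (is.data.frame(x)) {
    if (all(c("u_um", "v_um") %in% names(x))) {
      return(as.matrix(x[, c("u_um", "v_um")]))
    }
    if (all(c("x_um", "y_um") %in% names(x))) {
      return(as.matrix(x[, c("x_um", "y_um")]))
    }
    stop("expected 2D coordinate columns u_um/v_um (or x_um/y_um)", call. = FALSE)
  }
  m <- if (is.matrix(x)) x else matrix(as.numeric(x), ncol = 2L, byrow = TRUE)
  storage.mode(m) <- "double"
  m
}

#' Re-center a projected table on the wounding site
#'
#' Applies the rigid transform (translation plus rotation) that places the
#' centroid of the wound-site points at the origin of the plane and maps the
#' direction from the wound centroid towards the re-centering point onto the
#' +u axis. All pairwise distances are preserved, so nearest-reference
#' distances are invariant to this step.
#'
#' @param proj a projected table (`u_um`, `v_um`) as from [project_to_plane()].
#' @param wound_points_2d wound-site points in the same plane (matrix or data
#'   frame with 2D coordinates); at least one point.
#' @param recenter_point_2d a single 2D point defining the orientation; must
#'   not coincide with the wound centroid.
#' @return The projected table with transformed `u_um`, `v_um` and an attribute
#'   `"recenter_transform"` (list with `center` and `angle_rad`) that can be
#'   applied to other point sets with [transform_points2d()].
#' @export
recenter_on_wound <- function(proj, wound_points_2d, recenter_point_2d) {
  w <- as_uv_matrix(wound_points_2d)
  if (nrow(w) < 1L) stop("at least one wound point required", call. = FALSE)
  ctr <- colMeans(w)
  r <- as.numeric(recenter_point_2d)[1:2] - ctr
  if (sqrt(sum(r^2)) < 1e-12) {
    stop("re-centering point coincides with the wound centroid; rotation undefined",
         call. = FALSE)
  }
  angle <- -atan2(r[2], r[1])
  tf <- list(center = ctr, angle_rad = angle)
  p <- as_uv_matrix(proj)
  p2 <- transform_points2d(p, tf)
  out <- proj
  out$u_um <- p2[, 1]
  out$v_um <- p2[, 2]
  attr(out, "recenter_transform") <- tf
  out
}

#' Apply a re-centering transform to 2D points
#'
#' @param points 2D points (matrix or data frame).
#' @param transform the `"recenter_transform"` attribute produced by
#'   [recenter_on_wound()].
#' @return A two-column numeric matrix.
#' @export
transform_points2d <- function(points, transform) {
  p <- as_uv_matrix(points)
  p <- sweep(p, 2L, transform$center)
  ca <- cos(transform$angle_rad)
  sa <- sin(transform$angle_rad)
  rot <- matrix(c(ca, sa, -sa, ca), 2L, 2L)
  p %*% t(rot)
}

#' Minimum Euclidean distance to a reference set
#'
#' For every query point, the distance to the closest reference point. Works
#' in any dimension (2D projected coordinates or raw 3D coordinates), as long
#' as query and reference dimensions agree.
#'
#' @param points query points (matrix, or data frame with coordinate columns).
#' @param refs reference points, same dimensionality; at least one.
#' @return Numeric vector of distances (micrometres), one per query point.
#' @export
distance_to_reference <- function(points, refs) {
  p <- coerce_points(points)
  r <- coerce_points(refs)
  if (nrow(r) < 1L) stop("reference set is empty", call. = FALSE)
  if (ncol(p) != ncol(r)) {
    stop("query and reference points have different dimensions", call. = FALSE)
  }
  if (nrow(p) == 0L) return(numeric(0))
  d2 <- outer(rowSums(p^2), rep(1, nrow(r))) +
    outer(rep(1, nrow(p)), rowSums(r^2)) -
    2 * (p %*% t(r))
  sqrt(pmax(apply(d2, 1L, min), 0))
}

coerce_points <- function(x) {
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(x)
  }
  if (is.data.frame(x)) {
    if (all(c("x_um", "y_um", "z_um") %in% names(x))) {
      return(as.matrix(x[, c("x_um", "y_um", "z_um")]))
    }
    if (all(c("u_um", "v_um") %in% names(x))) {
      return(as.matrix(x[, c("u_um", "v_um")]))
    }
    if (all(c("x_um", "y_um") %in% names(x))) {
      return(as.matrix(x[, c("x_um", "y_um")]))
    }
    stop("no coordinate columns found", call. = FALSE)
  }
  matrix(as.numeric(x), nrow = 1L)
}

#' Express distances as cell tiers
#'
#' Divides distances by the mean cell diameter so that distance 1 corresponds
#' to one cell row from the reference. Tiers are continuous; integer tier
#' bins for counting are obtained by flooring at binning time.
#'
#' @param dist_um distances in micrometres (non-negative).
#' @param cell_diameter_um mean cell diameter in micrometres (> 0).
#' @return Numeric vector of tiers.
#' @export
to_cell_tiers <- function(dist_um, cell_diameter_um) {
  if (!is.numeric(cell_diameter_um) || length(cell_diameter_um) != 1L ||
      !is.finite(cell_diameter_um) || cell_diameter_um <= 0) {
    stop("`cell_diameter_um` must be a single positive number", call. = FALSE)
  }
  if (any(dist_um < 0, na.rm = TRUE)) {
    stop("distances must be non-negative", call. = FALSE)
  }
  dist_um / cell_diameter_um
}

#' Project nuclei and measure nearest-reference distances
#'
#' Convenience wrapper chaining [project_to_plane()] on nuclei and reference
#' points, optional wound re-centering, [distance_to_reference()] and
#' [to_cell_tiers()], yielding a full projected table.
#'
#' @param nuclei nucleus table with 3D coordinates.
#' @param refs reference set with 3D coordinates.
#' @param frame a [projection_frame()].
#' @param cell_diameter_um optional mean cell diameter; when given, a `tier`
#'   column is added.
#' @param recenter_point optional 3D point (micrometres); when given the plane
#'   is re-centered on the projected wound centroid with this point's
#'   projection defining the +u direction.
#' @return Data frame with `nucleus_id`, `u_um`, `v_um`, `dist_to_ref_um` and
#'   optionally `tier`; the projected (and possibly re-centered) reference
#'   points are attached as attribute `"ref_points_2d"`.
#' @export
project_and_measure <- function(nuclei, refs, frame,
                                cell_diameter_um = NULL,
                                recenter_point = NULL) {
  proj <- project_to_plane(nuclei, frame)
  ref2d <- project_to_plane(refs, frame)
  if (!is.null(recenter_point)) {
    rc2d <- project_to_plane(matrix(as.numeric(recenter_point), nrow = 1L), frame)
    proj <- recenter_on_wound(proj, ref2d, c(rc2d$u_um, rc2d$v_um))
    tf <- attr(proj, "recenter_transform")
    ref_m <- transform_points2d(ref2d, tf)
    ref2d$u_um <- ref_m[, 1]
    ref2d$v_um <- ref_m[, 2]
  }
  proj$dist_to_ref_um <- distance_to_reference(proj, ref2d)
  if (!is.null(cell_diameter_um)) {
    proj$tier <- to_cell_tiers(proj$dist_to_ref_um, cell_diameter_um)
  }
  attr(proj, "ref_points_2d") <- ref2d
  proj
}
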