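# Shape and expression-domain morphometrics: circularity, extension
# classification and normalized length, batch QC, cavity position, 10-bin
# expression profiles, domain areas, EVL ROI intensity, cell-size summaries.

#' Signed polygon area (shoelace)
#' @noRd
polygon_signed_area <- function(outline) {
  m <- as_uv_matrix(outline)
  x <- m[, 1]; y <- m[, 2]
  n <- length(x)
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Polygon area
#'
#' Absolute shoelace area of a closed polygon given as ordered vertices (the
#' closing edge is implicit).
#'
#' @param outline data frame (`x_um`, `y_um`) or two-column matrix.
#' @return Area in µm².
#' @export
polygon_area <- function(outline) {
  abs(polygon_signed_area(outline))
}

polygon_perimeter <- function(outline) {
  m <- as_uv_matrix(outline)
  n <- nrow(m)
  j <- c(2:n, 1L)
  sum(sqrt(rowSums((m[j, , drop = FALSE] - m)^2)))
}

validate_outline <- function(outline) {
  m <- as_uv_matrix(outline)
  if (nrow(m) < 3L) stop("outline needs at least 3 vertices", call. = FALSE)
  if (!all(is.finite(m))) stop("outline has non-finite vertices", call. = FALSE)
  if (polygon_area(m) <= 0) stop("degenerate outline: zero area", call. = FALSE)
  invisible(m)
}

#' Outline circularity
#'
#' `4 * pi * area / perimeter^2`: 1 for a circle, smaller for elongated or
#' indented shapes. Invariant to scaling and rigid motion; clamped to at most
#' 1 against floating-point overshoot.
#'
#' @param outline closed 2D outline (data frame `x_um`, `y_um` or matrix).
#' @return Circularity in (0, 1].
#' @export
circularity <- function(outline) {
  m <- validate_outline(outline)
  val <- 4 * pi * polygon_area(m) / polygon_perimeter(m)^2
  min(val, 1)
}

# relative convexity defect: (hull area - polygon area) / polygon area
convexity_defect <- function(m) {
  hull <- grDevices::chull(m)
  a <- polygon_area(m)
  (polygon_area(m[hull, , drop = FALSE]) - a) / a
}

#' Classify an outline as extended or not
#'
#' The reference path mirrors the manual call: a sample is extended when
#' extension-base landmarks (the operator's "clear change in curvature")
#' are provided. An automatic mode is available as a clearly heuristic
#' alternative based on the relative convexity defect — the area between
#' the outline and its convex hull, as a fraction of the outline area.
#' Convex shapes (circles, ellipses) have a defect near zero even with
#' outlining wobble, while an indentation between the round back and the
#' extension lobe closes off hull area above the threshold.
#'
#' @param outline closed 2D outline.
#' @param landmarks landmark list; `extension_base` marks a manual extended
#'   call.
#' @param mode `"manual"` (default) or `"auto"`.
#' @param min_defect relative convexity-defect threshold for automatic mode
#'   (default 0.01).
#' @return `"extended"` or `"not_extended"`.
#' @export
classify_extension <- function(outline, landmarks = NULL,
                               mode = c("manual", "auto"),
                               min_defect = 0.01) {
  mode <- match.arg(mode)
  m <- validate_outline(outline)
  if (mode == "manual") {
    if (!is.null(landmarks) && !is.null(landmarks$extension_base)) "extended"
    else "not_extended"
  } else {
    if (convexity_defect(m) > min_defect) "extended" else "not_extended"
  }
}

polyline_length <- function(points) {
  m <- as_uv_matrix(points)
  if (nrow(m) < 2L) return(0)
  sum(sqrt(rowSums((m[-1L, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2)))
}

#' Normalized extension length
#'
#' Length of the tip-to-extension-base polyline divided by the total
#' back-to-tip axis length (back -> extension base -> tip, the segmented-line
#' measurement). Not-extended samples (no `extension_base` landmark) return 0
#' when `include_not_extended` is set, and raise an error otherwise.
#'
#' @param landmarks landmark list with `tip`, `back`, and for extended
#'   samples `extension_base` (a 2x2 matrix of the two base points, or a
#'   single 2D point).
#' @param include_not_extended treat samples without an extension as having
#'   normalized extension length 0.
#' @return Normalized extension length in `[0, 1]`.
#' @export
normalized_extension_length <- function(landmarks, include_not_extended = FALSE) {
  if (is.null(landmarks$extension_base)) {
    if (include_not_extended) return(0)
    stop("no extension_base landmark for an extended sample", call. = FALSE)
  }
  if (is.null(landmarks$tip) || is.null(landmarks$back)) {
    stop("landmarks must include `tip` and `back`", call. = FALSE)
  }
  base <- landmarks$extension_base
  base_mid <- if (is.matrix(base)) colMeans(base) else as.numeric(base)[1:2]
  tip <- as.numeric(landmarks$tip)[1:2]
  back <- as.numeric(landmarks$back)[1:2]
  ext_len <- polyline_length(rbind(tip, base_mid))
  total <- polyline_length(rbind(back, base_mid, tip))
  if (total <= 0) stop("degenerate landmarks: zero axis length", call. = FALSE)
  ext_len / total
}

#' Batch quality control on control extensions
#'
#' An experiment passes when at least 70% of its control samples show a
#' clearly recognisable extension.
#'
#' @param extended logical vector (or `"extended"`/`"not_extended"` strings),
#'   one per control sample.
#' @param min_fraction required extended fraction (default 0.70).
#' @return `"pass"` or `"fail"`.
#' @export
batch_qc <- function(extended, min_fraction = 0.70) {
  if (length(extended) == 0L) stop("empty control group", call. = FALSE)
  if (is.character(extended)) extended <- extended == "extended"
  if (!is.logical(extended) || anyNA(extended)) {
    stop("`extended` must be logical (or 'extended'/'not_extended')", call. = FALSE)
  }
  if (mean(extended) >= min_fraction) "pass" else "fail"
}

#' Normalized cavity position along the back-tip axis
#'
#' Projects the cavity edge points of the largest-area cavity onto the
#' tip-to-back axis and reports the normalized distance from the tip to the
#' nearest cavity edge and from the far cavity edge to the back. Both values
#' are invariant to rigid motion of the whole configuration.
#'
#' @param landmarks landmark list with `tip`, `back`, and `cavities`: a list
#'   of cavities, each a list with `edges` (2x2 matrix of the two edge
#'   points) and `area_um2`.
#' @return Named numeric: `tip_to_near_edge`, `far_edge_to_back` (fractions
#'   of total axis length).
#' @export
cavity_position <- function(landmarks) {
  cavities <- landmarks$cavities
  if (is.null(cavities) || length(cavities) == 0L) {
    stop("no cavity recorded for this sample", call. = FALSE)
  }
  areas <- vapply(cavities, function(cv) as.numeric(cv$area_um2), numeric(1))
  if (anyNA(areas)) stop("every cavity needs an `area_um2`", call. = FALSE)
  cv <- cavities[[which.max(areas)]]
  tip <- as.numeric(landmarks$tip)[1:2]
  back <- as.numeric(landmarks$back)[1:2]
  axis <- back - tip
  total <- sqrt(sum(axis^2))
  if (total <= 0) stop("degenerate landmarks: tip equals back", call. = FALSE)
  axis <- axis / total
  edges <- as_uv_matrix(cv$edges)
  proj <- as.numeric(sweep(edges, 2L, tip) %*% axis)   # distance from tip along axis
  near <- min(proj)
  far <- max(proj)
  c(tip_to_near_edge = near / total,
    far_edge_to_back = (total - far) / total)
}

#' Binary 10-bin profile of an expression domain
#'
#' The back-tip axis is split into 10 equal windows ordered tip to back;
#' bins are half-open `[i/10, (i+1)/10)` with the last bin closed. A bin is
#' 1 when the normalized domain interval intersects it with positive length.
#' Multiple domains in one sample (vectors `start`/`end`) are OR-combined.
#'
#' @param start,end distances from the tip to the domain start/end (same
#'   units as `total_length`); vectors for multiple domains.
#' @param total_length total explant length used for normalization (default 1
#'   for already-normalized inputs).
#' @return Numeric vector of length 10 with values 0/1.
#' @export
bin_domain <- function(start, end, total_length = 1) {
  check_positive(total_length, "total_length")
  if (length(start) != length(end) || length(start) < 1L) {
    stop("`start` and `end` must be equal-length, non-empty vectors", call. = FALSE)
  }
  s <- start / total_length
  e <- end / total_length
  tol <- 1e-9
  if (any(!is.finite(s)) || any(!is.finite(e)) || any(s < -tol) ||
      any(e > 1 + tol) || any(s >= e)) {
    stop("domain intervals must satisfy 0 <= start < end <= total_length", call. = FALSE)
  }
  profile <- numeric(10L)
  lo <- (0:9) / 10
  hi <- (1:10) / 10
  for (k in seq_along(s)) {
    overlap <- pmin(e[k], hi) - pmax(s[k], lo)
    profile[overlap > tol] <- 1
  }
  profile
}

#' Average binary profiles across samples
#'
#' Element-wise mean of equal-length bin profiles, giving the fraction of
#' samples expressing in each window.
#'
#' @param profiles list of numeric profiles (each length 10, values in
#'   `[0, 1]`), or a matrix with one profile per row.
#' @return Numeric vector of length 10 with values in `[0, 1]`.
#' @export
average_profiles <- function(profiles) {
  if (is.matrix(profiles)) profiles <- asplit(profiles, 1L)
  if (length(profiles) < 1L) stop("at least one profile required", call. = FALSE)
  lens <- lengths(profiles)
  if (any(lens != lens[1])) stop("profiles have mismatching lengths", call. = FALSE)
  m <- do.call(rbind, lapply(profiles, as.numeric))
  if (any(m < 0 | m > 1)) stop("profile values must lie in [0, 1]", call. = FALSE)
  colMeans(m)
}

#' Area of an expression-domain outline
#'
#' @param outline closed 2D outline of the domain.
#' @return Shoelace area in µm².
#' @export
domain_area <- function(outline) {
  validate_outline(outline)
  polygon_area(outline)
}

#' Classify mesendoderm induction from domain area
#'
#' Samples without any detectable reporter accumulation are `negative` and
#' their area is recorded as 0; samples with an area strictly below half the
#' control mean are `reduced`; all others are `normal`.
#'
#' @param area_um2 measured domain area (µm²).
#' @param control_mean_area_um2 mean domain area in control samples (> 0).
#' @param egfp_detected was any reporter accumulation detectable?
#' @return A list with `category` (`"normal"`, `"reduced"`, `"negative"`)
#'   and `area_um2` (0 for negative samples).
#' @export
classify_mesendoderm_area <- function(area_um2, control_mean_area_um2,
                                      egfp_detected = TRUE) {
  check_positive(control_mean_area_um2, "control_mean_area_um2")
  if (!egfp_detected) {
    return(list(category = "negative", area_um2 = 0))
  }
  if (!is.numeric(area_um2) || !is.finite(area_um2) || area_um2 < 0) {
    stop("`area_um2` must be a non-negative number", call. = FALSE)
  }
  category <- if (area_um2 < 0.5 * control_mean_area_um2) "reduced" else "normal"
  list(category = category, area_um2 = area_um2)
}

#' Background-subtracted ROI intensity on a SUM projection
#'
#' SUM-projects the first `n_planes` planes of an intensity stack, measures
#' the mean over a square ROI of the configured area centred on the image,
#' and subtracts the mean over a square background ROI placed at the image
#' corner (outside the sample).
#'
#' @param z_stack 3D numeric array `[rows, cols, planes]`.
#' @param n_planes number of planes to SUM-project (same across samples).
#' @param center_roi_area_um2 area of the central ROI in µm² (default 400.90).
#' @param bg_roi_side_um side of the square background ROI in µm (default
#'   24.91).
#' @param pixel_size_um pixel size in µm.
#' @return Background-subtracted mean intensity (arbitrary units).
#' @export
evl_intensity <- function(z_stack, n_planes,
                          center_roi_area_um2 = 400.90,
                          bg_roi_side_um = 24.91,
                          pixel_size_um = 1) {
  if (length(dim(z_stack)) != 3L) stop("`z_stack` must be a 3D array", call. = FALSE)
  if (n_planes < 1L || n_planes > dim(z_stack)[3]) {
    stop("`n_planes` exceeds the number of planes in the stack", call. = FALSE)
  }
  check_positive(pixel_size_um, "pixel_size_um")
  proj <- rowSums(z_stack[, , seq_len(n_planes), drop = FALSE], dims = 2L)
  nr <- nrow(proj); nc <- ncol(proj)
  side <- max(1L, round(sqrt(center_roi_area_um2) / pixel_size_um))
  bside <- max(1L, round(bg_roi_side_um / pixel_size_um))
  if (side > nr || side > nc || bside > nr || bside > nc) {
    stop("ROI exceeds image bounds", call. = FALSE)
  }
  r0 <- (nr - side) %/% 2L
  c0 <- (nc - side) %/% 2L
  centre <- proj[(r0 + 1L):(r0 + side), (c0 + 1L):(c0 + side)]
  bg <- proj[1:bside, 1:bside]
  mean(centre) - mean(bg)
}

#' Per-stage cell diameter summary
#'
#' Arithmetic mean and standard deviation of sampled deep-cell diameters per
#' developmental stage, for converting distances to cell tiers.
#'
#' @param samples named list: stage -> numeric vector of diameters (µm).
#' @return Data frame with `stage`, `n`, `mean_um`, `sd_um` (0 for single
#'   measurements).
#' @export
cell_diameter_summary <- function(samples) {
  if (!is.list(samples) || length(samples) == 0L || is.null(names(samples))) {
    stop("`samples` must be a non-empty named list of diameter vectors", call. = FALSE)
  }
  rows <- lapply(names(samples), function(st) {
    d <- as.numeric(samples[[st]])
    if (length(d) < 1L || !all(is.finite(d)) || any(d <= 0)) {
      stop(sprintf("stage '%s' has no valid diameters", st), call. = FALSE)
    }
    data.frame(stage = st, n = length(d), mean_um = mean(d),
               sd_um = if (length(d) > 1L) stats::sd(d) else 0)
  })
  do.call(rbind, rows)
}
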