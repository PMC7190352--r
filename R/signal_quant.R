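# Nuclear pSMAD2/3 scoring (filters, background subtraction, DAPI ratio,
# positivity, bright-nucleus selection, tier profiles, domain class) and
# nuclear beta-catenin summaries (tier counts, angular dispersion).

#' Scoring configuration for nuclear signal quantification
#'
#' Holds every constant of the nuclear scoring chain: the imaging-depth
#' window, the maximal distance from the reference, the background band, the
#' positivity threshold on the DAPI-normalized ratio, the bright fraction,
#' the control bright-nucleus counts per sample kind, and the reduction
#' fraction defining a strongly reduced domain.
#'
#' @param z_window depth window in µm; only nuclei within this window above
#'   the imaging-side surface are scored (default 100).
#' @param max_dist maximal distance from the reference in µm (default 150).
#' @param bg_band closed distance interval (µm) whose mean signal is used as
#'   background (default `c(120, 150)`).
#' @param ratio_threshold positivity threshold on the background-subtracted
#'   signal / DAPI ratio; strictly above counts as positive (default 0.1).
#' @param bright_fraction fraction of positive nuclei taken as "brightest"
#'   (default 0.30).
#' @param control_bright_mean named numeric: mean bright-nucleus count in
#'   wildtype controls per sample kind (default explant 22, embryo 81).
#' @param reduction_fraction fraction of the control mean at or below which a
#'   sample is called strongly reduced (default 0.5).
#' @return An object of class `quant_config`.
#' @export
quant_config <- function(z_window = 100,
                         max_dist = 150,
                         bg_band = c(120, 150),
                         ratio_threshold = 0.1,
                         bright_fraction = 0.30,
                         control_bright_mean = c(explant = 22, embryo = 81),
                         reduction_fraction = 0.5) {
  check_positive(z_window, "z_window")
  check_positive(max_dist, "max_dist")
  if (length(bg_band) != 2L || !all(is.finite(bg_band)) ||
      bg_band[1] >= bg_band[2] || bg_band[1] < 0 || bg_band[2] > max_dist) {
    stop("`bg_band` must be an increasing pair within [0, max_dist]", call. = FALSE)
  }
  if (!is.finite(ratio_threshold)) stop("`ratio_threshold` must be finite", call. = FALSE)
  if (!is.numeric(bright_fraction) || bright_fraction <= 0 || bright_fraction > 1) {
    stop("`bright_fraction` must be in (0, 1]", call. = FALSE)
  }
  if (is.null(names(control_bright_mean)) ||
      !all(nzchar(names(control_bright_mean))) ||
      !all(is.finite(control_bright_mean)) || any(control_bright_mean <= 0)) {
    stop("`control_bright_mean` must be a named positive numeric vector", call. = FALSE)
  }
  check_fraction(reduction_fraction, "reduction_fraction")
  structure(list(z_window = z_window, max_dist = max_dist,
                 bg_band = as.numeric(bg_band),
                 ratio_threshold = ratio_threshold,
                 bright_fraction = bright_fraction,
                 control_bright_mean = control_bright_mean,
                 reduction_fraction = reduction_fraction),
            class = "quant_config")
}

require_columns <- function(tbl, cols, what = "table") {
  missing <- setdiff(cols, names(tbl))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

join_distances <- function(tbl, proj) {
  if ("dist_to_ref_um" %in% names(tbl)) return(tbl)
  if (is.null(proj)) {
    stop("`tbl` has no dist_to_ref_um column and no projected table was supplied",
         call. = FALSE)
  }
  require_columns(proj, c("nucleus_id", "dist_to_ref_um"), "projected table")
  idx <- match(tbl$nucleus_id, proj$nucleus_id)
  if (anyNA(idx)) stop("some nuclei are missing from the projected table", call. = FALSE)
  tbl$dist_to_ref_um <- proj$dist_to_ref_um[idx]
  tbl
}

#' Filter nuclei for quantification
#'
#' Removes nuclei flagged as EVL, dividing, or low/inhomogeneous DAPI; keeps
#' only nuclei within the depth window (`z_window` µm, anchored at the
#' imaging-side z-minimum of the flag-passing nuclei) and within `max_dist`
#' µm of the reference. Every drop is accounted for by reason in the
#' `"drop_log"` attribute.
#'
#' @param tbl nucleus table (`nucleus_id`, `z_um`, flags, intensities).
#' @param proj projected table supplying `dist_to_ref_um` per `nucleus_id`
#'   (may be `NULL` if `tbl` already carries that column).
#' @param cfg a [quant_config()].
#' @return The filtered table (distances joined in), with attribute
#'   `"drop_log"`: a data frame of reasons and counts summing, together with
#'   the retained rows, to the input row count.
#' @export
filter_nuclei <- function(tbl, proj = NULL, cfg = quant_config()) {
  require_columns(tbl, c("nucleus_id", "z_um", "ch_signal_mean", "ch_dapi_mean",
                         "is_evl", "is_dividing"), "nucleus table")
  tbl <- join_distances(tbl, proj)
  n_in <- nrow(tbl)
  log <- list()
  if (n_in == 0L) {
    attr(tbl, "drop_log") <- data.frame(reason = character(0), n_dropped = integer(0))
    return(tbl)
  }
  drop_evl <- tbl$is_evl
  drop_div <- !drop_evl & tbl$is_dividing
  has_lowdapi <- "is_low_dapi" %in% names(tbl)
  drop_dapi <- if (has_lowdapi) !drop_evl & !drop_div & tbl$is_low_dapi else rep(FALSE, n_in)
  keep <- !(drop_evl | drop_div | drop_dapi)
  kept <- tbl[keep, , drop = FALSE]
  if (nrow(kept) > 0L) {
    z0 <- min(kept$z_um)
    in_z <- kept$z_um <= z0 + cfg$z_window
  } else {
    in_z <- logical(0)
  }
  n_z <- sum(!in_z)
  kept <- kept[in_z, , drop = FALSE]
  in_d <- kept$dist_to_ref_um <= cfg$max_dist
  n_d <- sum(!in_d)
  kept <- kept[in_d, , drop = FALSE]
  drop_log <- data.frame(
    reason = c("evl", "dividing", "low_dapi", "z_window", "distance"),
    n_dropped = c(sum(drop_evl), sum(drop_div), sum(drop_dapi), n_z, n_d)
  )
  stopifnot(nrow(kept) + sum(drop_log$n_dropped) == n_in)
  attr(kept, "drop_log") <- drop_log
  kept
}

#' Subtract the far-band background from the signal channel
#'
#' The background is the mean signal over nuclei whose distance to the
#' reference lies in the closed background band (default 120-150 µm). The
#' band mean of the background-subtracted signal is zero by construction.
#'
#' @param tbl filtered nucleus table carrying `dist_to_ref_um`.
#' @param proj optional projected table supplying distances.
#' @param cfg a [quant_config()].
#' @param background optional explicit background value overriding the band
#'   estimate (required when no nucleus falls in the band).
#' @return `tbl` with a `signal_bgsub` column; the background used is stored
#'   in attribute `"background"`.
#' @export
subtract_background <- function(tbl, proj = NULL, cfg = quant_config(),
                                background = NULL) {
  require_columns(tbl, "ch_signal_mean", "nucleus table")
  tbl <- join_distances(tbl, proj)
  if (is.null(background)) {
    in_band <- tbl$dist_to_ref_um >= cfg$bg_band[1] &
      tbl$dist_to_ref_um <= cfg$bg_band[2]
    if (!any(in_band)) {
      stop(sprintf(paste0("no nuclei in the background band [%g, %g] um; ",
                          "widen the band or supply an explicit `background` value"),
                   cfg$bg_band[1], cfg$bg_band[2]), call. = FALSE)
    }
    background <- mean(tbl$ch_signal_mean[in_band])
  }
  tbl$signal_bgsub <- tbl$ch_signal_mean - background
  attr(tbl, "background") <- background
  tbl
}

#' Compute the DAPI-normalized signal ratio
#'
#' Ratio of the background-subtracted signal to the DAPI mean intensity.
#' Because depth attenuation acts multiplicatively on both channels, the
#' ratio is depth-corrected by construction. Nuclei with non-positive
#' background-subtracted signal are dropped before positivity calling (only
#' nuclei with positive nuclear mean signal are analysed further), as are
#' nuclei with non-positive DAPI; both drops are logged.
#'
#' @param tbl table with `signal_bgsub` and `ch_dapi_mean`.
#' @param keep_nonpositive keep nuclei with `signal_bgsub <= 0` (useful for
#'   unbiased gradient fitting; such nuclei are never called positive by
#'   [call_positive()] since their ratio is <= 0). Default `FALSE`.
#' @return `tbl` with a `ratio` column; drops recorded in attribute
#'   `"drop_log"`.
#' @export
compute_ratio <- function(tbl, keep_nonpositive = FALSE) {
  require_columns(tbl, c("signal_bgsub", "ch_dapi_mean"), "nucleus table")
  bad_dapi <- !(tbl$ch_dapi_mean > 0)
  nonpos <- !bad_dapi & tbl$signal_bgsub <= 0
  keep <- !bad_dapi & (keep_nonpositive | !nonpos)
  out <- tbl[keep, , drop = FALSE]
  out$ratio <- out$signal_bgsub / out$ch_dapi_mean
  attr(out, "drop_log") <- data.frame(
    reason = c("nonpositive_dapi", "nonpositive_signal"),
    n_dropped = c(sum(bad_dapi), if (keep_nonpositive) 0L else sum(nonpos))
  )
  out
}

#' Call positive nuclei
#'
#' A nucleus is positive when its DAPI-normalized ratio is strictly above the
#' threshold (default 0.1): a ratio of exactly 0.1 is negative.
#'
#' @param tbl table with a `ratio` column.
#' @param cfg a [quant_config()].
#' @return `tbl` with a logical `is_positive` column.
#' @export
call_positive <- function(tbl, cfg = quant_config()) {
  require_columns(tbl, "ratio", "nucleus table")
  tbl$is_positive <- tbl$ratio > cfg$ratio_threshold
  tbl
}

#' Percentage of positive nuclei
#'
#' @param tbl table with `is_positive` over the considered nuclei.
#' @return `100 * n_positive / n_considered`.
#' @export
percent_positive <- function(tbl) {
  require_columns(tbl, "is_positive", "nucleus table")
  if (nrow(tbl) == 0L) stop("no nuclei considered; percentage undefined", call. = FALSE)
  100 * mean(tbl$is_positive)
}

#' Select the brightest positive nuclei
#'
#' The brightest nuclei are the top `bright_fraction` (default 30%) of
#' positive nuclei by DAPI-normalized ratio. The count is
#' `k = max(1, round_half_up(bright_fraction * n_positive))`; the selection
#' is empty when there are no positives. Ties are broken by `nucleus_id` so
#' the selection is deterministic.
#'
#' @param tbl table with `ratio` and `is_positive`.
#' @param cfg a [quant_config()].
#' @return The bright subset of `tbl` (rows in decreasing ratio order).
#' @export
select_brightest <- function(tbl, cfg = quant_config()) {
  require_columns(tbl, c("ratio", "is_positive", "nucleus_id"), "nucleus table")
  pos <- tbl[tbl$is_positive, , drop = FALSE]
  n_pos <- nrow(pos)
  if (n_pos == 0L) return(pos)
  k <- max(1L, as.integer(floor(cfg$bright_fraction * n_pos + 0.5)))
  ord <- order(-pos$ratio, pos$nucleus_id)
  pos[ord[seq_len(min(k, n_pos))], , drop = FALSE]
}

#' Tier profile of nuclear intensity
#'
#' Expresses each nucleus's distance to the reference in cell tiers and its
#' ratio normalized to the sample maximum (so profiles map to (0, 1] for
#' positive values), and averages the normalized intensity per integer
#' (floored) tier.
#'
#' @param tbl subset of scored nuclei (typically the bright subset from
#'   [select_brightest()], but any table with `ratio` and distances works).
#' @param cell_diameter_um mean cell diameter in µm.
#' @param proj optional projected table supplying distances.
#' @return A list with `per_nucleus` (data frame: `nucleus_id`, `tier`,
#'   `ratio`, `norm_intensity`) and `per_tier` (data frame: `tier_bin`,
#'   `mean_norm_intensity`, `n`).
#' @export
tier_profile <- function(tbl, cell_diameter_um, proj = NULL) {
  require_columns(tbl, c("nucleus_id", "ratio"), "nucleus table")
  tbl <- join_distances(tbl, proj)
  if (nrow(tbl) == 0L) stop("empty table; no tier profile", call. = FALSE)
  tier <- to_cell_tiers(tbl$dist_to_ref_um, cell_diameter_um)
  norm <- tbl$ratio / max(tbl$ratio)
  per_nucleus <- data.frame(nucleus_id = tbl$nucleus_id, tier = tier,
                            ratio = tbl$ratio, norm_intensity = norm)
  bin <- floor(tier)
  agg <- tapply(norm, bin, mean)
  per_tier <- data.frame(tier_bin = as.integer(names(agg)),
                         mean_norm_intensity = as.numeric(agg),
                         n = as.integer(table(bin)))
  list(per_nucleus = per_nucleus, per_tier = per_tier)
}

#' Classify the signalling domain of a sample
#'
#' `absent` when no bright positive nuclei are detected; `strongly_reduced`
#' when the bright count is at or below `reduction_fraction` (default 50%)
#' of the wildtype control mean for the sample kind (explant 22, embryo 81);
#' `present` otherwise.
#'
#' @param n_bright number of bright positive nuclei (>= 0).
#' @param sample_kind `"explant"` or `"embryo"` (must be a name of
#'   `cfg$control_bright_mean`).
#' @param cfg a [quant_config()].
#' @return One of `"present"`, `"strongly_reduced"`, `"absent"`.
#' @export
classify_domain <- function(n_bright, sample_kind, cfg = quant_config()) {
  if (!is.numeric(n_bright) || length(n_bright) != 1L || n_bright < 0) {
    stop("`n_bright` must be a single non-negative count", call. = FALSE)
  }
  if (!sample_kind %in% names(cfg$control_bright_mean)) {
    stop(sprintf("unknown sample kind '%s'; no control bright mean configured",
                 sample_kind), call. = FALSE)
  }
  ctrl <- cfg$control_bright_mean[[sample_kind]]
  if (n_bright == 0) "absent"
  else if (n_bright <= cfg$reduction_fraction * ctrl) "strongly_reduced"
  else "present"
}

#' Count positive nuclei per cell tier
#'
#' The cell diameter is the mean of the sampled diameters (the field
#' convention is ten randomly selected cells per sample); tiers are floored
#' and counts returned for every integer tier from 0 to the maximum occupied
#' tier.
#'
#' @param dist_um distances of positive nuclei to the reference (µm), or a
#'   projected table carrying `dist_to_ref_um`.
#' @param sampled_diameters_um measured cell diameters (µm), at least one.
#' @return Data frame with `tier` and `count`; counts sum to the number of
#'   nuclei. The diameter used is attached as attribute `"cell_diameter_um"`.
#' @export
bcat_counts_by_tier <- function(dist_um, sampled_diameters_um) {
  if (is.data.frame(dist_um)) {
    require_columns(dist_um, "dist_to_ref_um", "projected table")
    dist_um <- dist_um$dist_to_ref_um
  }
  if (length(dist_um) < 1L) stop("at least one positive nucleus required", call. = FALSE)
  if (length(sampled_diameters_um) < 1L || !all(is.finite(sampled_diameters_um)) ||
      any(sampled_diameters_um <= 0)) {
    stop("`sampled_diameters_um` must contain at least one positive diameter",
         call. = FALSE)
  }
  diam <- mean(sampled_diameters_um)
  tiers <- floor(to_cell_tiers(dist_um, diam))
  counts <- tabulate(tiers + 1L, nbins = max(tiers) + 1L)
  out <- data.frame(tier = seq_along(counts) - 1L, count = counts)
  attr(out, "cell_diameter_um") <- diam
  out
}

#' Angular dispersion of positive nuclei about a wound-anchored axis
#'
#' The reference axis runs from the wound centroid to the centroid of the
#' flagged brightest nuclei; those brightest nuclei are excluded from the
#' angle set. Angles are measured in degrees in (-180, 180] relative to the
#' axis. The summary is the circular mean and the mean resultant length
#' (the magnitude of the average unit vector: 1 = no dispersion, 0 =
#' uniform).
#'
#' @param points positive nuclei in the plane: data frame with `nucleus_id`,
#'   `u_um`, `v_um`.
#' @param wound_centroid 2D point (µm).
#' @param brightest_ids nucleus ids defining the axis endpoint (>= 1).
#' @return A list with `angles_deg` (named by nucleus id),
#'   `circular_mean_deg` and `mean_resultant_length`.
#' @export
angular_dispersion <- function(points, wound_centroid, brightest_ids) {
  require_columns(points, c("nucleus_id", "u_um", "v_um"), "point table")
  if (length(brightest_ids) < 1L) stop("at least one brightest nucleus required", call. = FALSE)
  wc <- as.numeric(wound_centroid)[1:2]
  is_bright <- points$nucleus_id %in% brightest_ids
  if (!any(is_bright)) stop("none of `brightest_ids` found in `points`", call. = FALSE)
  axis_vec <- c(mean(points$u_um[is_bright]), mean(points$v_um[is_bright])) - wc
  if (sqrt(sum(axis_vec^2)) < 1e-12) {
    stop("brightest-nuclei centroid coincides with the wound centroid; axis undefined",
         call. = FALSE)
  }
  rest <- points[!is_bright, , drop = FALSE]
  if (nrow(rest) == 0L) stop("no remaining positive nuclei after excluding the brightest",
                             call. = FALSE)
  du <- rest$u_um - wc[1]
  dv <- rest$v_um - wc[2]
  len <- sqrt(du^2 + dv^2)
  ok <- len > 1e-12
  if (!any(ok)) stop("all positive nuclei coincide with the wound centroid; angles undefined",
                     call. = FALSE)
  axis_angle <- atan2(axis_vec[2], axis_vec[1])
  ang <- atan2(dv[ok], du[ok]) - axis_angle
  ang <- ((ang + pi) %% (2 * pi)) - pi          # (-pi, pi]
  ang[ang <= -pi + 1e-15] <- pi
  angles_deg <- ang * 180 / pi
  names(angles_deg) <- rest$nucleus_id[ok]
  mc <- mean(cos(ang))
  ms <- mean(sin(ang))
  list(angles_deg = angles_deg,
       circular_mean_deg = atan2(ms, mc) * 180 / pi,
       mean_resultant_length = sqrt(mc^2 + ms^2))
}

#' Score one sample end to end
#'
#' Chains [filter_nuclei()], [subtract_background()], [compute_ratio()],
#' [call_positive()], [select_brightest()] and [classify_domain()] on a
#' nucleus table with distances, returning the per-sample quantification
#' result.
#'
#' @param tbl nucleus table.
#' @param proj projected table with `dist_to_ref_um` (or `NULL` if `tbl`
#'   already carries distances).
#' @param sample_kind `"explant"` or `"embryo"`.
#' @param cfg a [quant_config()].
#' @param background optional explicit background value.
#' @return A list of class `quant_result`: counts, percentage positive,
#'   bright ids/ratios, classification, background used, drop logs, and the
#'   per-nucleus scored table.
#' @export
quantify_sample <- function(tbl, proj = NULL, sample_kind = "explant",
                            cfg = quant_config(), background = NULL) {
  filtered <- filter_nuclei(tbl, proj, cfg)
  filter_log <- attr(filtered, "drop_log")
  bg <- subtract_background(filtered, NULL, cfg, background = background)
  rat <- compute_ratio(bg)
  ratio_log <- attr(rat, "drop_log")
  rat <- call_positive(rat, cfg)
  bright <- select_brightest(rat, cfg)
  n_considered <- nrow(rat)
  n_positive <- sum(rat$is_positive)
  rat$is_bright <- rat$nucleus_id %in% bright$nucleus_id
  res <- list(
    n_input = nrow(tbl),
    n_considered = n_considered,
    n_positive = n_positive,
    percent_positive = if (n_considered > 0) 100 * n_positive / n_considered else NA_real_,
    n_bright = nrow(bright),
    bright_ids = bright$nucleus_id,
    bright_ratio_values = bright$ratio,
    classification = classify_domain(nrow(bright), sample_kind, cfg),
    background = attr(bg, "background"),
    drop_log = rbind(filter_log, ratio_log),
    per_nucleus = rat
  )
  class(res) <- "quant_result"
  res
}

#' @export
print.quant_result <- function(x, ...) {
  cat("Nuclear signal quantification\n")
  cat(sprintf("  nuclei: %d in, %d considered, %d positive (%.1f%%)\n",
              x$n_input, x$n_considered, x$n_positive, x$percent_positive))
  cat(sprintf("  bright nuclei: %d; classification: %s\n",
              x$n_bright, x$classification))
  cat(sprintf("  background subtracted: %.3f\n", x$background))
  invisible(x)
}
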