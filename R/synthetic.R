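# Seeded synthetic generators: nucleus point clouds with a signal gradient,
# explant/embryo reference sets, outlines with known extension fractions,
# and random-walk clone tracks.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single number in [0, 1]", name), call. = FALSE)
  }
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive finite number", name), call. = FALSE)
  }
}

#' Configuration for the synthetic nucleus generator
#'
#' Defaults describe the conditions the downstream scoring assumes: an
#' explant-sized ball of radius 100 µm holding about 500 deep cells of 25 µm
#' diameter (an embryo-sized cap of radius 350 µm for `sample_kind =
#' "embryo"`), an exponentially decaying nuclear signal of amplitude 100
#' arbitrary units with decay length 40 µm from the reference, additive
#' Gaussian intensity noise of sd 5 (amplitude/noise = 20), a counterstain
#' (DAPI) base level of 100, multiplicative depth attenuation of 0.001 per µm
#' applied to both channels equally, a 10% outer EVL shell and a 5% dividing
#' fraction.
#'
#' @param sample_kind `"explant"` (ball with a wound disc) or `"embryo"`
#'   (hemispherical blastoderm cap with a margin ring).
#' @param n_nuclei number of nuclei (>= 1).
#' @param geometry_radius radius of the geometry in µm; defaults to 100 for
#'   explants and 350 for embryos.
#' @param cell_diameter mean cell diameter in µm.
#' @param gradient_amplitude signal amplitude at the reference (arbitrary
#'   units); 0 emulates samples without an instructive signal source.
#' @param gradient_decay_length exponential decay length of the signal in µm.
#' @param intensity_noise_sd sd of additive Gaussian noise on both channels.
#' @param dapi_base counterstain mean intensity at the surface.
#' @param depth_attenuation_per_um fractional intensity loss per µm of imaging
#'   depth, applied multiplicatively to both channels.
#' @param evl_fraction fraction of nuclei flagged as the outermost (EVL) shell.
#' @param dividing_fraction fraction of nuclei flagged as dividing.
#' @param seed integer RNG seed; identical config + seed gives identical output.
#' @return An object of class `synthetic_nuclei_config`.
#' @export
synthetic_nuclei_config <- function(sample_kind = c("explant", "embryo"),
                                    n_nuclei = 500,
                                    geometry_radius = NULL,
                                    cell_diameter = 25,
                                    gradient_amplitude = 100,
                                    gradient_decay_length = 40,
                                    intensity_noise_sd = 5,
                                    dapi_base = 100,
                                    depth_attenuation_per_um = 0.001,
                                    evl_fraction = 0.1,
                                    dividing_fraction = 0.05,
                                    seed = 1L) {
  sample_kind <- match.arg(sample_kind)
  if (is.null(geometry_radius)) {
    geometry_radius <- if (sample_kind == "explant") 100 else 350
  }
  if (!is.numeric(n_nuclei) || length(n_nuclei) != 1L || !is.finite(n_nuclei) ||
      n_nuclei < 1) {
    stop("`n_nuclei` must be >= 1", call. = FALSE)
  }
  check_positive(geometry_radius, "geometry_radius")
  check_positive(cell_diameter, "cell_diameter")
  check_positive(gradient_decay_length, "gradient_decay_length")
  for (nm in c("gradient_amplitude", "intensity_noise_sd", "dapi_base")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      stop(sprintf("`%s` must be a single non-negative finite number", nm),
           call. = FALSE)
    }
  }
  check_fraction(depth_attenuation_per_um, "depth_attenuation_per_um")
  check_fraction(evl_fraction, "evl_fraction")
  check_fraction(dividing_fraction, "dividing_fraction")
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  structure(list(sample_kind = sample_kind,
                 n_nuclei = as.integer(n_nuclei),
                 geometry_radius = geometry_radius,
                 cell_diameter = cell_diameter,
                 gradient_amplitude = gradient_amplitude,
                 gradient_decay_length = gradient_decay_length,
                 intensity_noise_sd = intensity_noise_sd,
                 dapi_base = dapi_base,
                 depth_attenuation_per_um = depth_attenuation_per_um,
                 evl_fraction = evl_fraction,
                 dividing_fraction = dividing_fraction,
                 seed = as.integer(seed)),
            class = "synthetic_nuclei_config")
}

# sunflower layout of n points in a disc of radius r in the plane x = x0
wound_disc_points <- function(n, r, x0) {
  k <- seq_len(n)
  golden <- pi * (3 - sqrt(5))
  rr <- r * sqrt(k / n)
  th <- k * golden
  cbind(x_um = rep(x0, n), y_um = rr * cos(th), z_um = rr * sin(th))
}

#' Generate a synthetic nucleus table and reference set
#'
#' Places nuclei uniformly in the sample geometry (embryo: blastoderm cap —
#' a spherical shell of thickness three cell diameters spanning the animal
#' hemisphere, with the margin ring at the rim as reference; explant: solid
#' ball with a wound disc of radius two cell diameters whose rim lies on the
#' sphere as reference). The signal channel decays exponentially with the
#' true 3D distance to the nearest reference point; the counterstain channel
#' is flat. Both channels are attenuated by the same multiplicative
#' per-micrometre factor with imaging depth (measured from the top of the
#' sample along +z) and carry additive Gaussian noise. The outermost
#' `evl_fraction` of nuclei by radial position is flagged `is_evl`; a random
#' `dividing_fraction` is flagged `is_dividing`. The true nearest-reference
#' distance is stored per nucleus as `true_dist_um` for use as a test oracle.
#'
#' @param cfg a [synthetic_nuclei_config()].
#' @param sample_id sample identifier written into the table.
#' @return A list with elements `nuclei` (data frame: `sample_id`,
#'   `nucleus_id`, `x_um`, `y_um`, `z_um`, `ch_signal_mean`, `ch_dapi_mean`,
#'   `is_evl`, `is_dividing`, `is_low_dapi`, `true_dist_um`) and `refs`
#'   (data frame: `ref_id`, `x_um`, `y_um`, `z_um`, `kind`), plus the
#'   generating config and seed recorded in attributes. For explants, the
#'   ball centre is attached as attribute `"recenter_point"` (used to orient
#'   the wound-to-centre axis after projection).
#' @export
generate_nuclei <- function(cfg, sample_id = "synthetic_1") {
  stopifnot(inherits(cfg, "synthetic_nuclei_config"))
  n <- cfg$n_nuclei
  R <- cfg$geometry_radius
  with_seed(cfg$seed, {
    if (cfg$sample_kind == "embryo") {
      # blastoderm cap: shell of thickness 3 cell diameters, animal hemisphere
      t_shell <- min(3 * cfg$cell_diameter, R * 0.9)
      r3 <- runif(n, (R - t_shell)^3, R^3)
      r <- r3^(1 / 3)
      cosb <- runif(n, 0, 1)          # polar angle 0..90 deg (area-uniform)
      sinb <- sqrt(1 - cosb^2)
      phi <- runif(n, 0, 2 * pi)
      pos <- cbind(x_um = r * sinb * cos(phi),
                   y_um = r * sinb * sin(phi),
                   z_um = r * cosb)
      nref <- 36L
      th <- seq(0, 2 * pi, length.out = nref + 1L)[-(nref + 1L)]
      refs <- cbind(x_um = R * cos(th), y_um = R * sin(th), z_um = rep(0, nref))
      ref_kind <- "ysl"
      recenter <- NULL
    } else {
      # explant ball; wound disc of radius 2 cell diameters, rim on the sphere
      u <- runif(n)
      r <- R * u^(1 / 3)
      z <- runif(n, -1, 1)
      phi <- runif(n, 0, 2 * pi)
      s <- sqrt(1 - z^2)
      pos <- cbind(x_um = r * s * cos(phi),
                   y_um = r * s * sin(phi),
                   z_um = r * z)
      r_w <- min(2 * cfg$cell_diameter, R * 0.99)
      x0 <- -sqrt(max(R^2 - r_w^2, 0))
      refs <- wound_disc_points(25L, r_w, x0)
      ref_kind <- "wound"
      recenter <- c(0, 0, 0)
    }
    true_d <- distance_to_reference(pos, refs)
    depth <- max(pos[, "z_um"]) - pos[, "z_um"]
    atten <- (1 - cfg$depth_attenuation_per_um)^depth
    signal <- cfg$gradient_amplitude *
      exp(-true_d / cfg$gradient_decay_length) * atten +
      rnorm(n, 0, cfg$intensity_noise_sd)
    dapi <- cfg$dapi_base * atten + rnorm(n, 0, cfg$intensity_noise_sd)
    radial <- sqrt(rowSums(pos^2))
    n_evl <- round(cfg$evl_fraction * n)
    is_evl <- logical(n)
    if (n_evl > 0) is_evl[order(radial, decreasing = TRUE)[seq_len(n_evl)]] <- TRUE
    n_div <- round(cfg$dividing_fraction * n)
    is_div <- logical(n)
    if (n_div > 0) is_div[sample.int(n, n_div)] <- TRUE
    nuclei <- data.frame(sample_id = sample_id,
                         nucleus_id = seq_len(n),
                         x_um = pos[, "x_um"],
                         y_um = pos[, "y_um"],
                         z_um = pos[, "z_um"],
                         ch_signal_mean = signal,
                         ch_dapi_mean = dapi,
                         is_evl = is_evl,
                         is_dividing = is_div,
                         is_low_dapi = FALSE,
                         true_dist_um = true_d)
    refs_df <- data.frame(ref_id = seq_len(nrow(refs)),
                          x_um = refs[, "x_um"],
                          y_um = refs[, "y_um"],
                          z_um = refs[, "z_um"],
                          kind = ref_kind)
    out <- list(nuclei = nuclei, refs = refs_df)
    attr(out, "config") <- cfg
    attr(out, "seed") <- cfg$seed
    attr(out, "sample_kind") <- cfg$sample_kind
    attr(out, "recenter_point") <- recenter
    out
  })
}

#' Configuration for the synthetic outline generator
#'
#' @param shape `"pear"` (round back plus narrower extension lobe), `"circle"`
#'   or `"ellipse"`.
#' @param total_length total back-to-tip length in µm (diameter for circles).
#' @param extension_fraction for pears, the normalized extension length in
#'   `[0, 1)`; the extension base sits at `(1 - f) * total_length` from the
#'   back.
#' @param body_width maximal body width in µm.
#' @param n_vertices number of polygon vertices (>= 32).
#' @param jitter_sd sd of radial vertex jitter as a fraction of body width
#'   (emulates manual-outlining wobble).
#' @param seed integer RNG seed for the jitter.
#' @return An object of class `synthetic_outline_config`.
#' @export
synthetic_outline_config <- function(shape = c("pear", "circle", "ellipse"),
                                     total_length = 600,
                                     extension_fraction = 0.33,
                                     body_width = 400,
                                     n_vertices = 256,
                                     jitter_sd = 0.002,
                                     seed = 1L) {
  shape <- match.arg(shape)
  check_positive(total_length, "total_length")
  check_positive(body_width, "body_width")
  if (!is.numeric(extension_fraction) || extension_fraction < 0 ||
      extension_fraction >= 1) {
    stop("`extension_fraction` must be in [0, 1)", call. = FALSE)
  }
  if (!is.numeric(n_vertices) || n_vertices < 32) {
    stop("`n_vertices` must be >= 32", call. = FALSE)
  }
  check_fraction(jitter_sd, "jitter_sd")
  structure(list(shape = shape, total_length = total_length,
                 extension_fraction = extension_fraction,
                 body_width = body_width,
                 n_vertices = as.integer(n_vertices),
                 jitter_sd = jitter_sd,
                 seed = as.integer(seed)),
            class = "synthetic_outline_config")
}

half_ellipse_width <- function(x, x_lo, x_hi, half_width) {
  c0 <- (x_lo + x_hi) / 2
  a <- (x_hi - x_lo) / 2
  t <- (x - c0) / a
  w <- numeric(length(x))
  inside <- abs(t) <= 1
  w[inside] <- half_width * sqrt(pmax(1 - t[inside]^2, 0))
  w
}

#' Generate a closed 2D outline with known extension fraction
#'
#' Pear shapes are built from two overlapping elliptical lobes sharing the
#' back-to-tip axis: a body lobe of the configured width up to the extension
#' base at `(1 - f) * L`, and a narrower extension lobe reaching the tip at
#' `L`. The outline width is the pointwise maximum of the two lobes, which
#' produces the concave neck ("clear change in curvature") at the extension
#' base. Landmarks (tip, back, the two extension-base points) are placed so
#' that the landmark-based extension measurement recovers `f` exactly up to
#' vertex discretisation.
#'
#' @param cfg a [synthetic_outline_config()].
#' @return A list: `outline` (data frame `x_um`, `y_um`, counter-clockwise,
#'   closed implicitly), `landmarks` (list with `tip`, `back`, and for pears
#'   with positive extension fraction `extension_base`, a 2x2 matrix), and
#'   `true_extension_fraction`.
#' @export
generate_outline <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_outline_config"))
  L <- cfg$total_length
  W <- cfg$body_width
  f <- if (cfg$shape == "pear") cfg$extension_fraction else 0
  n_half <- max(16L, cfg$n_vertices %/% 2L)
  tt <- seq(0, 1, length.out = n_half + 1L)
  x <- L * (1 - cos(pi * tt)) / 2   # cosine spacing: dense near back and tip
  if (cfg$shape == "circle") {
    w <- half_ellipse_width(x, 0, L, L / 2)
  } else if (cfg$shape == "ellipse" || f == 0) {
    w <- half_ellipse_width(x, 0, L, W / 2)
  } else {
    xb <- (1 - f) * L
    delta <- 0.15 * (L - xb)
    wb <- half_ellipse_width(x, 0, xb + delta, W / 2)
    we <- half_ellipse_width(x, xb - delta, L, 0.45 * W / 2)
    w <- pmax(wb, we)
  }
  top <- cbind(x, w)
  bottom <- cbind(rev(x[-c(1, length(x))]), -rev(w[-c(1, length(w))]))
  verts <- rbind(top, bottom)
  verts <- with_seed(cfg$seed, {
    jit <- rnorm(nrow(verts), 0, cfg$jitter_sd * W)
    interior <- verts[, 2] != 0
    verts[interior, 2] <- verts[interior, 2] + sign(verts[interior, 2]) * jit[interior]
    verts
  })
  outline <- data.frame(x_um = verts[, 1], y_um = verts[, 2])
  landmarks <- list(tip = c(L, 0), back = c(0, 0))
  if (cfg$shape == "pear" && f > 0) {
    xb <- (1 - f) * L
    wn <- max(half_ellipse_width(xb, 0, xb + 0.15 * (L - xb), W / 2),
              half_ellipse_width(xb, xb - 0.15 * (L - xb), L, 0.45 * W / 2))
    landmarks$extension_base <- rbind(c(xb, wn), c(xb, -wn))
  }
  if (polygon_area(outline) <= 0) {
    stop("degenerate outline (zero area); check configuration", call. = FALSE)
  }
  list(outline = outline, landmarks = landmarks, true_extension_fraction = f)
}

#' Configuration for the clone random-walk simulator
#'
#' @param n_cells number of labelled cells (>= 2).
#' @param step_sd per-axis sd of the Gaussian step between consecutive
#'   timepoints, in µm.
#' @param n_timepoints number of timepoints (>= 1), starting at 0 minutes.
#' @param timestep minutes between timepoints.
#' @param cluster_radius radius of the compact seed cluster at time 0, in µm.
#' @param seed integer RNG seed.
#' @return An object of class `clone_sim_config`.
#' @export
clone_sim_config <- function(n_cells = 20, step_sd = 5, n_timepoints = 3,
                             timestep = 60, cluster_radius = 20, seed = 1L) {
  if (!is.numeric(n_cells) || n_cells < 2) stop("`n_cells` must be >= 2", call. = FALSE)
  if (!is.numeric(step_sd) || step_sd < 0 || !is.finite(step_sd)) {
    stop("`step_sd` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(n_timepoints) || n_timepoints < 1) {
    stop("`n_timepoints` must be >= 1", call. = FALSE)
  }
  check_positive(timestep, "timestep")
  check_positive(cluster_radius, "cluster_radius")
  structure(list(n_cells = as.integer(n_cells), step_sd = step_sd,
                 n_timepoints = as.integer(n_timepoints), timestep = timestep,
                 cluster_radius = cluster_radius, seed = as.integer(seed)),
            class = "clone_sim_config")
}

#' Simulate a dispersing cell clone
#'
#' Cells start in a compact uniform ball of radius `cluster_radius` and each
#' performs an independent isotropic Gaussian random walk (per-axis sd
#' `step_sd` per timepoint).
#'
#' @param cfg a [clone_sim_config()].
#' @return A clone track data frame: `timepoint_min`, `cell_id`, `x_um`,
#'   `y_um`, `z_um`.
#' @export
generate_clone_track <- function(cfg) {
  stopifnot(inherits(cfg, "clone_sim_config"))
  with_seed(cfg$seed, {
    n <- cfg$n_cells
    u <- runif(n)
    r <- cfg$cluster_radius * u^(1 / 3)
    z <- runif(n, -1, 1)
    phi <- runif(n, 0, 2 * pi)
    s <- sqrt(1 - z^2)
    pos <- cbind(r * s * cos(phi), r * s * sin(phi), r * z)
    out <- vector("list", cfg$n_timepoints)
    for (ti in seq_len(cfg$n_timepoints)) {
      if (ti > 1L) {
        pos <- pos + matrix(rnorm(3 * n, 0, cfg$step_sd), ncol = 3L)
      }
      out[[ti]] <- data.frame(timepoint_min = (ti - 1L) * cfg$timestep,
                              cell_id = seq_len(n),
                              x_um = pos[, 1], y_um = pos[, 2], z_um = pos[, 3])
    }
    do.call(rbind, out)
  })
}

#' Fit an exponential decay length to a signal profile
#'
#' Fits `value = a * exp(-distance / lambda) + c` and returns `lambda`. The
#' offset `c` absorbs a constant background (including the residual left by
#' subtracting the mean signal of a far band from a slowly decaying
#' gradient). Method `"nls"` (default) uses Levenberg-Marquardt least squares
#' on the raw points; `"loglinear"` bins the profile, drops bins whose mean
#' falls below 2% of the peak, and fits a straight line to the log of the
#' binned means (appropriate when the offset is negligible).
#'
#' @param distance_um distances (or tiers scaled back to µm).
#' @param value signal values (same length).
#' @param method `"nls"` or `"loglinear"`.
#' @param bin_width bin width in µm for the log-linear method and for the
#'   starting-value estimate.
#' @return The fitted decay length in µm.
#' @export
fit_decay_length <- function(distance_um, value,
                             method = c("nls", "loglinear"),
                             bin_width = 10) {
  method <- match.arg(method)
  ok <- is.finite(distance_um) & is.finite(value)
  d <- distance_um[ok]
  y <- value[ok]
  if (length(d) < 4L) stop("too few points to fit a decay length", call. = FALSE)
  bins <- floor(d / bin_width)
  bm <- tapply(y, bins, mean)
  bd <- (as.numeric(names(bm)) + 0.5) * bin_width
  start_lambda <- {
    pos <- bm - min(bm) + 1e-9
    keep <- pos > max(pos) * 0.02
    if (sum(keep) >= 2L) {
      sl <- as.numeric(stats::coef(stats::lm(log(pos[keep]) ~ bd[keep]))[2])
      if (is.finite(sl) && sl < 0) -1 / sl else diff(range(d)) / 3
    } else diff(range(d)) / 3
  }
  if (method == "loglinear") {
    bn <- as.integer(table(bins))
    keep <- bm > max(bm) * 0.05 & bm > 0
    if (sum(keep) < 2L) stop("too few informative bins for log-linear fit", call. = FALSE)
    sl <- as.numeric(stats::coef(stats::lm(log(bm[keep]) ~ bd[keep],
                                           weights = bn[keep]))[2])
    if (!is.finite(sl) || sl >= 0) stop("profile is not decaying", call. = FALSE)
    return(as.numeric(-1 / sl))
  }
  fit <- minpack.lm::nlsLM(
    y ~ a * exp(-d / lambda) + cc,
    start = list(a = as.numeric(max(bm) - min(bm)),
                 lambda = as.numeric(start_lambda),
                 cc = as.numeric(min(bm))),
    lower = c(a = 0, lambda = bin_width / 10, cc = -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  as.numeric(stats::coef(fit)[["lambda"]])
}
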