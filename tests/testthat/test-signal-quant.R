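test_that("the eight-row worked example keeps three nuclei and logs all five drops", {
  tbl <- toy_eight_rows()
  out <- filter_nuclei(tbl, NULL, quant_config())
  expect_equal(nrow(out), 3L)
  expect_setequal(out$nucleus_id, c(1L, 2L, 3L))
  log <- attr(out, "drop_log")
  expect_equal(log$n_dropped[log$reason == "evl"], 2L)
  expect_equal(log$n_dropped[log$reason == "dividing"], 1L)
  expect_equal(log$n_dropped[log$reason == "z_window"], 1L)
  expect_equal(log$n_dropped[log$reason == "distance"], 1L)
  expect_equal(sum(log$n_dropped) + nrow(out), nrow(tbl))
})

test_that("filtering is the identity on clean in-range tables and tolerates empty input", {
  tbl <- make_nucleus_table(5, z = c(0, 10, 50, 99, 100), dist = 140)
  out <- filter_nuclei(tbl, NULL)
  expect_equal(out$nucleus_id, tbl$nucleus_id)
  expect_equal(sum(attr(out, "drop_log")$n_dropped), 0L)

  empty <- filter_nuclei(make_nucleus_table(0), NULL)
  expect_equal(nrow(empty), 0L)
})

test_that("missing required columns raise a schema error naming the column", {
  tbl <- make_nucleus_table(3)
  tbl$ch_dapi_mean <- NULL
  expect_error(filter_nuclei(tbl, NULL), "ch_dapi_mean")
})

test_that("background is the mean of the band and band mean of bgsub is zero", {
  tbl <- make_nucleus_table(4, dist = c(130, 135, 140, 50),
                            signal = c(10, 20, 30, 25))
  out <- subtract_background(tbl, NULL)
  expect_equal(attr(out, "background"), 20)
  expect_equal(out$signal_bgsub, c(-10, 0, 10, 5))
  in_band <- out$dist_to_ref_um >= 120 & out$dist_to_ref_um <= 150
  expect_equal(mean(out$signal_bgsub[in_band]), 0)

  flat <- subtract_background(make_nucleus_table(4, dist = c(125, 60, 20, 145),
                                                 signal = 42), NULL)
  expect_equal(flat$signal_bgsub, rep(0, 4))
})

test_that("an empty background band errors unless an explicit value is supplied", {
  tbl <- make_nucleus_table(3, dist = 50, signal = 30)
  expect_error(subtract_background(tbl, NULL), "widen the band")
  out <- subtract_background(tbl, NULL, background = 10)
  expect_equal(out$signal_bgsub, rep(20, 3))
})

test_that("the band mean of a synthetic gradient matches the closed-form expectation", {
  cfg <- synthetic_nuclei_config("explant", n_nuclei = 4000,
                                 gradient_decay_length = 40,
                                 geometry_radius = 150,
                                 intensity_noise_sd = 1,
                                 depth_attenuation_per_um = 0, seed = 12)
  sim <- generate_nuclei(cfg)
  tbl <- sim$nuclei
  tbl$dist_to_ref_um <- tbl$true_dist_um
  out <- subtract_background(tbl, NULL)
  in_band <- tbl$true_dist_um >= 120 & tbl$true_dist_um <= 150
  # closed form: mean of A*exp(-d/lambda) over the band nuclei actually drawn
  expected <- mean(100 * exp(-tbl$true_dist_um[in_band] / 40))
  expect_equal(attr(out, "background"), expected,
               tolerance = 3 / sqrt(sum(in_band)))
  # far of the reference the subtracted signal is near zero relative to the
  # amplitude (the gradient still decays slowly across the band itself)
  far <- tbl$true_dist_um > 120
  expect_lt(abs(mean(out$signal_bgsub[far])), 0.05 * 100)
})

test_that("the DAPI ratio is computed only for positive signal and positive DAPI", {
  tbl <- make_nucleus_table(3, dist = 50)
  tbl$signal_bgsub <- c(5, -2, 4)
  tbl$ch_dapi_mean <- c(50, 100, 0)
  out <- compute_ratio(tbl)
  expect_equal(out$nucleus_id, 1L)
  expect_equal(out$ratio, 0.1)
  log <- attr(out, "drop_log")
  expect_equal(log$n_dropped[log$reason == "nonpositive_signal"], 1L)
  expect_equal(log$n_dropped[log$reason == "nonpositive_dapi"], 1L)

  kept <- compute_ratio(tbl, keep_nonpositive = TRUE)
  expect_equal(nrow(kept), 2L)
  expect_true(-0.02 %in% kept$ratio)
})

test_that("the ratio decorrelates signal from imaging depth", {
  cfg <- synthetic_nuclei_config("explant", n_nuclei = 500,
                                 gradient_decay_length = 1e6,
                                 intensity_noise_sd = 0.01,
                                 depth_attenuation_per_um = 0.005, seed = 13)
  sim <- generate_nuclei(cfg)
  tbl <- sim$nuclei
  tbl$dist_to_ref_um <- tbl$true_dist_um
  depth <- max(tbl$z_um) - tbl$z_um
  # raw signal attenuates strongly with depth; the DAPI ratio does not
  expect_lt(cor(tbl$ch_signal_mean, depth), -0.9)
  tbl$signal_bgsub <- tbl$ch_signal_mean          # flat gradient: no band needed
  rat <- compute_ratio(tbl)
  expect_lt(abs(cor(rat$ratio, depth[match(rat$nucleus_id, tbl$nucleus_id)])), 0.1)
})

test_that("positivity is strict: ratio 0.1 is negative, 0.11 positive", {
  tbl <- make_nucleus_table(3)
  tbl$ratio <- c(0.1, 0.11, 0.0999999)
  out <- call_positive(tbl)
  expect_equal(out$is_positive, c(FALSE, TRUE, FALSE))
})

test_that("the positive count never increases with the threshold", {
  set.seed(99)
  for (i in 1:25) {
    tbl <- make_nucleus_table(40)
    tbl$ratio <- rnorm(40, 0.1, 0.05)
    counts <- vapply(seq(0, 0.3, by = 0.01), function(th) {
      sum(call_positive(tbl, quant_config(ratio_threshold = th))$is_positive)
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("percent positive is the count ratio on a percentage scale", {
  tbl <- make_nucleus_table(20)
  tbl$is_positive <- c(rep(TRUE, 5), rep(FALSE, 15))
  expect_equal(percent_positive(tbl), 25)
  tbl$is_positive <- FALSE
  expect_equal(percent_positive(tbl), 0)
  expect_error(percent_positive(tbl[0, ]), "undefined")
  set.seed(7)
  tbl$is_positive <- runif(20) > 0.5
  expect_equal(percent_positive(tbl), 100 * sum(tbl$is_positive) / 20)
})

test_that("the brightest selection takes the rounded top fraction with deterministic ties", {
  tbl <- make_nucleus_table(12)
  tbl$ratio <- c(seq(0.2, 1.1, by = 0.1), 0.05, 0.08)
  tbl$is_positive <- tbl$ratio > 0.1
  bright <- select_brightest(tbl)        # 10 positives -> k = 3
  expect_equal(nrow(bright), 3L)
  expect_equal(sort(bright$ratio), c(0.9, 1.0, 1.1))

  tbl7 <- make_nucleus_table(7)
  tbl7$ratio <- seq(0.2, 0.8, by = 0.1)
  tbl7$is_positive <- TRUE
  expect_equal(nrow(select_brightest(tbl7)), 2L)  # round_half_up(2.1) = 2

  none <- tbl
  none$is_positive <- FALSE
  expect_equal(nrow(select_brightest(none)), 0L)

  ties <- make_nucleus_table(10)
  ties$ratio <- 0.5
  ties$is_positive <- TRUE
  expect_equal(select_brightest(ties)$nucleus_id, 1:3)
})

test_that("tier profiles normalize to the sample maximum and match hand-binned means", {
  tbl <- make_nucleus_table(12, dist = c(5, 10, 20, 26, 30, 40, 51, 55, 60, 70, 76, 99))
  tbl$ratio <- c(1.0, 0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.35, 0.3, 0.25, 0.2, 0.1)
  tp <- tier_profile(tbl, 25)
  expect_equal(max(tp$per_nucleus$norm_intensity), 1)
  expect_equal(tp$per_nucleus$tier, tbl$dist_to_ref_um / 25)
  # hand binning: tiers 0 = d<25 (ratios 1,.9,.8), 1 = 25-50 (.7,.6,.5),
  # 2 = 50-75 (.4,.35,.3,.25), 3 = 75-100 (.2,.1)
  expect_equal(tp$per_tier$tier_bin, 0:3)
  expect_equal(tp$per_tier$mean_norm_intensity,
               c(mean(c(1, .9, .8)), mean(c(.7, .6, .5)),
                 mean(c(.4, .35, .3, .25)), mean(c(.2, .1))))
  expect_equal(tp$per_tier$n, c(3L, 3L, 4L, 2L))
})

test_that("domain classification honors the wildtype control means and boundary rule", {
  cfg <- quant_config()
  expect_equal(classify_domain(10, "explant", cfg), "strongly_reduced")
  expect_equal(classify_domain(0, "explant", cfg), "absent")
  expect_equal(classify_domain(22, "explant", cfg), "present")
  expect_equal(classify_domain(11, "explant", cfg), "strongly_reduced")  # <= 50%
  expect_equal(classify_domain(12, "explant", cfg), "present")
  expect_equal(classify_domain(40, "embryo", cfg), "strongly_reduced")
  expect_equal(classify_domain(41, "embryo", cfg), "present")
  expect_error(classify_domain(5, "organoid", cfg), "unknown sample kind")
  # monotone: increasing counts never move toward absent
  lvl <- c(absent = 0, strongly_reduced = 1, present = 2)
  cls <- lvl[vapply(0:60, classify_domain, character(1),
                    sample_kind = "explant", cfg = cfg)]
  expect_true(all(diff(cls) >= 0))
})

test_that("beta-catenin tier counts floor tiers and conserve the nucleus count", {
  out <- bcat_counts_by_tier(c(10, 30, 35), 20)
  expect_equal(out$tier, 0:1)
  expect_equal(out$count, c(1L, 2L))
  expect_equal(attr(out, "cell_diameter_um"), 20)

  zero <- bcat_counts_by_tier(c(0, 0, 0), c(18, 22))
  expect_equal(zero$count, 3L)

  set.seed(15)
  d <- runif(200, 0, 200)
  counts <- bcat_counts_by_tier(d, runif(10, 15, 30))
  expect_equal(sum(counts$count), 200L)
  expect_error(bcat_counts_by_tier(numeric(0), 20), "at least one")
  expect_error(bcat_counts_by_tier(c(1, 2), numeric(0)), "diameter")
})

test_that("angular dispersion matches closed forms about the bright-nucleus axis", {
  for (theta in c(15, 45, 80)) {
    th <- theta * pi / 180
    pts <- data.frame(nucleus_id = 1:3,
                      u_um = c(10, 5 * cos(th), 5 * cos(-th)),
                      v_um = c(0, 5 * sin(th), 5 * sin(-th)))
    res <- angular_dispersion(pts, c(0, 0), brightest_ids = 1)
    expect_equal(res$circular_mean_deg, 0, tolerance = 1e-9)
    expect_equal(res$mean_resultant_length, cos(th), tolerance = 1e-9)
    expect_equal(length(res$angles_deg), 2L)  # brightest excluded
  }
  on_axis <- data.frame(nucleus_id = 1:4, u_um = c(10, 1, 2, 3), v_um = 0)
  res <- angular_dispersion(on_axis, c(0, 0), 1)
  expect_equal(res$mean_resultant_length, 1, tolerance = 1e-12)
})

test_that("uniform angles give near-zero resultant and degenerate input errors", {
  set.seed(17)
  th <- runif(5000, -pi, pi)
  pts <- data.frame(nucleus_id = 0:5000,
                    u_um = c(10, cos(th)), v_um = c(0, sin(th)))
  res <- angular_dispersion(pts, c(0, 0), 0)
  expect_lt(res$mean_resultant_length, 0.05)

  coincident <- data.frame(nucleus_id = 1:2, u_um = c(10, 0), v_um = 0)
  expect_error(angular_dispersion(coincident, c(0, 0), 1), "coincide")
  expect_error(angular_dispersion(pts, c(0, 0), integer(0)), "at least one")
})

test_that("the scoring chain is invariant to a rigid motion of nuclei and references", {
  cfg <- synthetic_nuclei_config("explant", n_nuclei = 300, seed = 19)
  sim <- generate_nuclei(cfg)
  frame <- projection_frame(c(0, 0, 1))
  proj0 <- project_and_measure(sim$nuclei, sim$refs, frame)
  q0 <- quantify_sample(sim$nuclei, proj0, "explant")

  # rotate everything about z and translate in the plane; same frame axis
  ang <- 0.9
  rot <- function(df) {
    x <- df$x_um * cos(ang) - df$y_um * sin(ang) + 40
    y <- df$x_um * sin(ang) + df$y_um * cos(ang) - 15
    df$x_um <- x; df$y_um <- y
    df
  }
  proj1 <- project_and_measure(rot(sim$nuclei), rot(sim$refs), frame)
  q1 <- quantify_sample(rot(sim$nuclei), proj1, "explant")
  expect_equal(q1$n_positive, q0$n_positive)
  expect_equal(q1$percent_positive, q0$percent_positive, tolerance = 1e-9)
  expect_equal(sort(q1$bright_ids), sort(q0$bright_ids))
  expect_equal(q1$classification, q0$classification)
})

test_that("percent positive grows with gradient amplitude in expectation", {
  pp <- vapply(c(0, 50, 150), function(amp) {
    mean(vapply(1:5, function(s) {
      cfg <- synthetic_nuclei_config("explant", n_nuclei = 300,
                                     gradient_amplitude = amp, seed = s)
      sim <- generate_nuclei(cfg)
      tbl <- sim$nuclei
      tbl$dist_to_ref_um <- tbl$true_dist_um
      q <- quantify_sample(tbl, NULL, "explant")
      q$percent_positive
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(pp) > 0))
})
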