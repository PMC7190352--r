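# shared in-code fixtures

# nucleus table with explicit per-row flags/coordinates; defaults are clean
make_nucleus_table <- function(n, z = 0, dist = 50, signal = 50, dapi = 100,
                               evl = FALSE, dividing = FALSE, low_dapi = FALSE) {
  data.frame(sample_id = rep_len("s1", n),
             nucleus_id = seq_len(n),
             x_um = rep_len(dist, n), y_um = rep_len(0, n), z_um = rep_len(z, n),
             ch_signal_mean = rep_len(signal, n),
             ch_dapi_mean = rep_len(dapi, n),
             is_evl = rep_len(evl, n),
             is_dividing = rep_len(dividing, n),
             is_low_dapi = rep_len(low_dapi, n),
             dist_to_ref_um = rep_len(dist, n))
}

# the eight-nucleus worked example: 2 EVL, 1 dividing, 1 outside the
# 100 um depth window, 1 beyond 150 um from the reference, 3 clean
toy_eight_rows <- function() {
  tbl <- make_nucleus_table(8)
  tbl$z_um <- c(0, 10, 20, 5, 5, 130, 50, 15)
  tbl$dist_to_ref_um <- c(10, 50, 100, 30, 40, 60, 160, 140)
  tbl$is_evl <- c(FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, FALSE)
  tbl$is_dividing <- c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  tbl
}

# regular n-gon approximating a circle of radius r
regular_polygon <- function(n, r = 1, center = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  data.frame(x_um = center[1] + r * cos(th), y_um = center[2] + r * sin(th))
}

rotate2d <- function(m, angle, shift = c(0, 0)) {
  rot <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L, 2L)
  sweep(as.matrix(m) %*% t(rot), 2L, -shift)
}
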