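# Shared fixtures: small fields and fast camera settings so unit tests run
# in seconds; full-scale runs live in the acceptance tests.

small_spec <- function(...) {
  field_spec(width_px = 192, height_px = 192, n_cells_target = 12, ...)
}

quiet_camera <- function(binning = 2, ...) {
  camera_model(offset = 100, read_noise_sd = 0, gain = 2,
               shot_noise = FALSE, binning = binning, ...)
}

# distribution from raw values with minimal ceremony
dist_of <- function(values, condition = "cond") {
  intensity_distribution(values, condition)
}

# Brute-force spherocylinder boundary distance oracle: dense sampling of both
# axis segments, used to check the placement gap contract independently of
# the package's analytic segment-distance code.
brute_gap <- function(g1, g2, k = 200) {
  ax1 <- axis_points(g1, k); ax2 <- axis_points(g2, k)
  d2 <- outer(ax1$x, ax2$x, `-`)^2 + outer(ax1$y, ax2$y, `-`)^2
  sqrt(min(d2)) - (g1$width_px + g2$width_px) / 2
}

axis_points <- function(g, k) {
  half <- (g$length_px - g$width_px) / 2
  t <- seq(-half, half, length.out = k)
  list(x = g$cx + t * cos(g$theta), y = g$cy + t * sin(g$theta))
}
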