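# Shared fixtures: everything is generated in code at test time.

default_geometry <- function() scan_geometry()

# a small noise-free synthetic superior arcuate
superior_spec <- function(beta = -1.9, pair = c(100, 130), seed = 7, ...) {
  simulation_spec(beta_true = beta, phi0_pair = pair, seed = seed, ...)
}

# shortest distance from points to a densely sampled trajectory polyline
dist_to_trajectory <- function(points_xy, trajectory) {
  poly <- trajectory$polyline
  vapply(seq_len(nrow(points_xy)), function(i) {
    min(sqrt((poly[, 1] - points_xy[i, 1])^2 +
               (poly[, 2] - points_xy[i, 2])^2))
  }, numeric(1))
}

border_points_xy <- function(border) {
  cart_from_onh_polar(border$points$r, border$points$phi,
                      border$geometry$bmo_center)
}
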