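test_that("auxiliary equations evaluate exactly at their centers", {
  expect_identical(c_sup(121), 1.9)
  expect_identical(c_inf(-90), 1.0)
  # frozen high-precision scalar evaluations
  expect_equal(c_sup(135), 2.9662318183380707, tolerance = 1e-15)
  expect_equal(b_sup(121, -1.9), 0.14956861922263506, tolerance = 1e-15)
  expect_equal(b_inf(-90, 0.7), -2.0137527074704766, tolerance = 1e-15)
})

test_that("auxiliary equations enforce their sectors and signs", {
  expect_error(c_sup(50), "superior")
  expect_error(c_inf(30), "inferior")
  phi_s <- seq(60, 180, by = 1)
  phi_i <- seq(-179, -60, by = 1)
  for (beta in c(-1.3, -1.9, -2.5)) {
    expect_true(all(b_sup(phi_s, beta) > 0))
  }
  for (beta in c(1.3, 0.7, 0.1)) {
    expect_true(all(b_inf(phi_i, beta) < 0))
  }
  # curvature-location functions are strictly increasing in phi0 / -phi0
  expect_true(all(diff(c_sup(phi_s)) > 0))
  expect_true(all(diff(c_inf(rev(phi_i))) > 0))
})

test_that("phi(phi0, r0) = phi0 exactly over random parameter draws", {
  set.seed(42)
  for (i in 1:1000) {
    if (i %% 2 == 0) {
      phi0 <- runif(1, 60, 180); beta <- runif(1, -2.5, -1.3)
    } else {
      phi0 <- runif(1, -179.9, -60); beta <- runif(1, 0.1, 1.3)
    }
    r0 <- runif(1, 2, 8)
    expect_lt(abs(phi_of_r(phi0, r0, r0, beta) - phi0), 1e-12)
  }
})

test_that("phi_of_r matches a frozen scalar oracle and is monotone", {
  expect_equal(phi_of_r(121, 9, 4, -1.9), 124.18334341751347,
               tolerance = 1e-12)
  r <- seq(6, 20, by = 0.1)
  expect_true(all(diff(phi_of_r(130, r, 6, -1.9)) > 0))   # superior: up
  expect_true(all(diff(phi_of_r(-130, r, 6, 0.7)) < 0))   # inferior: down
  expect_error(phi_of_r(130, 3, 4, -1.9), "r must be >= r0")
})

test_that("sector classification honors the boundary conventions", {
  expect_equal(region_of_phi0(60), "superior")
  expect_equal(region_of_phi0(180), "superior")
  expect_equal(region_of_phi0(-60), "inferior")
  expect_equal(region_of_phi0(0), "nasal")
  expect_equal(region_of_phi0(c(59.9, -59.9)), c("nasal", "nasal"))
  expect_equal(phi0_internal(230), -130)
  expect_equal(phi0_external(-130), 230)
})

test_that("beta grids have 11 evenly spaced values with the printed anchors", {
  gs <- beta_grid("superior")
  gi <- beta_grid("inferior")
  expect_length(gs, 11)
  expect_length(gi, 11)
  expect_equal(gs[6], -1.90)
  expect_equal(gs[5], -1.78)
  expect_equal(gi[6], 0.70)
  expect_equal(gi[5], 0.82)
  expect_equal(gs[1], -1.3)
  expect_equal(gs[11], -2.5)
  expect_equal(unique(round(diff(gi), 12)), -(1.3 - 0.1) / 10)
})

test_that("trajectories start on the circle scan and stay in their hemifield", {
  geo <- default_geometry()
  for (phi0 in c(80, 120, 170, -80, -150, 0, 30)) {
    beta <- switch(region_of_phi0(phi0), superior = -1.9, inferior = 0.7,
                   NA_real_)
    tr <- sample_trajectory(geo, phi0, beta)
    pol <- onh_polar_from_cart(tr$polyline[1, , drop = FALSE], geo$bmo_center)
    expect_equal(pol$r, geo$r_c, tolerance = 1e-9)
    expect_true(all(diff(tr$r) > 0))
  }
  # superior trajectory clipped at the fovea-latitude (raphe) line
  tr <- sample_trajectory(geo, 170, -1.3)
  expect_true(all(tr$polyline[, 2] > -1e-9))
  expect_true(tr$clip_reason %in% c("raphe", "fd_line"))
})

test_that("nasal trajectories are straight radial rays", {
  geo <- default_geometry()
  tr <- sample_trajectory(geo, 0, NA)
  expect_equal(tr$region, "nasal")
  # collinearity with the ray from the BMO center
  d <- tr$polyline[, 2] - geo$bmo_center[2]
  expect_lt(max(abs(d)), 1e-9)
  tr2 <- sample_trajectory(geo, 30, NA)
  pol <- onh_polar_from_cart(tr2$polyline, geo$bmo_center)
  expect_lt(max(abs(wrap_phi(pol$phi - 30))), 1e-9)
})

test_that("zero relative FD angle and zero offset reproduce the model frame", {
  geo <- default_geometry()  # fd -7.59, bmo (15, 2): identity transform
  tr <- sample_trajectory(geo, 120, -1.9)
  expected <- cart_from_onh_polar(tr$r, tr$phi_model, c(15, 2))
  n <- length(tr$r)
  expect_equal(tr$polyline[seq_len(n), ], expected, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(tr$phi_scan, tr$phi_model)
})

test_that("trajectory sampling commutes with eye mirroring", {
  od <- default_geometry()
  os <- scan_geometry(bmo_center = c(-15, 2), fd_angle = 7.59,
                      laterality = "OS")
  os_n <- normalize_to_right_eye(os)$geometry
  tr_od <- sample_trajectory(od, 120, -1.9)
  tr_os <- sample_trajectory(os_n, 120, -1.9)
  expect_equal(tr_os$polyline, tr_od$polyline)
  expect_error(sample_trajectory(os, 120, -1.9), "normalized")
})

test_that("same-sector trajectories with one beta never cross", {
  geo <- default_geometry()
  for (pair in list(c(90, 110), c(120, 150), c(-90, -120))) {
    beta <- if (pair[1] > 0) -1.9 else 0.7
    t1 <- sample_trajectory(geo, pair[1], beta)
    t2 <- sample_trajectory(geo, pair[2], beta)
    n <- min(length(t1$r), length(t2$r))
    d <- t2$phi_model[seq_len(n)] - t1$phi_model[seq_len(n)]
    expect_true(all(d > 0) || all(d < 0))
  }
})

test_that("degenerate sampling requests are rejected", {
  geo <- default_geometry()
  expect_error(sample_trajectory(geo, 120, -1.9, bundle_params(r_max = 5)),
               "r_c")
  expect_error(sample_trajectory(geo, 120, -0.5), "empirical")
  # explicit override admits out-of-range beta
  tr <- sample_trajectory(geo, 120, -0.5,
                          bundle_params(allow_beta_outside = TRUE))
  expect_s3_class(tr, "trajectory")
  expect_error(sample_trajectory(geo, 120, NA), "beta is required")
})

test_that("trajectory export carries scan-frame polar coordinates", {
  tr <- sample_trajectory(default_geometry(), 100, -1.9)
  d <- as.data.frame(tr)
  expect_named(d, c("x_deg", "y_deg", "r_deg", "phi_deg"))
  expect_equal(d$r_deg[1], 6, tolerance = 1e-9)
})
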