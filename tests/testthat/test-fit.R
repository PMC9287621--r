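test_that("rms difference handles exact, offset and hand-computed cases", {
  geo <- default_geometry()
  tr <- sample_trajectory(geo, 120, -1.9)
  b <- border_from_trajectory(tr, "upper")
  expect_equal(rms_difference(b, tr)$rms, 0, tolerance = 1e-12)

  # constant +2 degree angular offset
  b2 <- b
  b2$points$phi <- wrap_phi(b2$points$phi + 2)
  r <- rms_difference(b2, tr)
  expect_equal(r$rms, 2, tolerance = 1e-12)
  expect_equal(r$coverage, 1)

  # two bins with differences +3 and -4 -> sqrt(12.5)
  b3 <- b
  b3$points <- b3$points[1:2, ]
  b3$points$phi <- wrap_phi(b3$points$phi + c(-3, 4))
  expect_equal(rms_difference(b3, tr)$rms, sqrt(12.5), tolerance = 1e-12)

  # disjoint radial support
  b4 <- b
  b4$points$r <- b4$points$r + 100
  expect_error(rms_difference(b4, tr), class = "no_overlap")
})

test_that("rms difference is invariant under a joint rigid rotation", {
  rms_in_frame <- function(geo) {
    tr <- sample_trajectory(geo, 115, -1.9)
    b <- border_from_trajectory(tr, "upper")
    b$points$phi <- wrap_phi(b$points$phi + 1.5)
    rms_difference(b, tr)$rms
  }
  expect_equal(rms_in_frame(default_geometry()),
               rms_in_frame(scan_geometry(fd_angle = -2.3)),
               tolerance = 1e-9)
})

test_that("phi0 search recovers on-grid and off-grid truths", {
  geo <- default_geometry()
  tr <- sample_trajectory(geo, 123.25, -1.9)
  b <- border_from_trajectory(tr, "upper")
  fit <- best_fit_phi0(b, -1.9)
  expect_equal(fit$phi0_best, 123.25)
  expect_lt(fit$rms, 1e-6)

  tr2 <- sample_trajectory(geo, 123.10, -1.9)
  b2 <- border_from_trajectory(tr2, "upper")
  fit2 <- best_fit_phi0(b2, -1.9)
  expect_lte(abs(fit2$phi0_best - 123.10), 0.25)
  # brute-force scan at 0.01-degree steps around the coarse optimum
  fine <- seq(122.5, 123.7, by = 0.01)
  rms_fine <- vapply(fine, function(p0) {
    rms_difference(b2, sample_trajectory(geo, p0, -1.9))$rms
  }, numeric(1))
  expect_lte(abs(fine[which.min(rms_fine)] - 123.10), 0.02)
})

test_that("the analytic scan equals a brute-force tabulation over candidates", {
  geo <- default_geometry()
  spec <- superior_spec(beta = -1.78, pair = c(95, 125), seed = 21)
  pm <- generate_arcuate_pmap(spec)
  border <- extract_arcuate_borders(pm, hemifield = "superior")$upper
  fit <- best_fit_phi0(border, -1.78)
  cand <- seq(60, 180, by = 0.25)
  brute <- vapply(cand, function(p0) {
    tryCatch(rms_difference(border, sample_trajectory(geo, p0, -1.78))$rms,
             arcuatefit_error = function(e) Inf)
  }, numeric(1))
  j <- which.min(brute)
  expect_equal(fit$phi0_best, cand[j])
  expect_equal(fit$rms, brute[j], tolerance = 1e-9)
})

test_that("nasal initial angles are never searched", {
  expect_equal(range(arcuatefit:::phi0_candidates("superior")), c(60, 180))
  inf <- arcuatefit:::phi0_candidates("inferior")
  expect_equal(range(inf), c(-179.75, -60))
  expect_true(all(region_of_phi0(inf) == "inferior"))
  tr <- sample_trajectory(default_geometry(), 70, -1.9)
  fit <- best_fit_phi0(border_from_trajectory(tr, "lower"), -1.9)
  expect_true(fit$phi0_best >= 60 && fit$phi0_best <= 180)
})

test_that("rms normalization matches the normal-CDF oracle", {
  expect_equal(normalize_rms(c(1, 2, 3)), 100 * pnorm(c(-1, 0, 1)))
  expect_equal(normalize_rms(rep(4, 11)), rep(50, 11))
  x <- c(0.3, 1.1, 0.9, 2.4, 0.2, 0.8, 1.5, 1.9, 0.4, 0.6, 1.0)
  p <- normalize_rms(x)
  expect_equal(order(p), order(x))            # rank preserving
  expect_equal(normalize_rms(10 + 3 * x), p)  # shift/scale invariant
  expect_true(all(p >= 0 & p <= 100))
})

test_that("beta sweeps cover the grid in order and recover the truth", {
  geo <- default_geometry()
  tr <- sample_trajectory(geo, 110, -1.78)
  b <- border_from_trajectory(tr, "upper")
  sw <- sweep_betas(b)
  expect_length(sw$rms, 11)
  expect_equal(sw$betas, beta_grid("superior"))
  expect_equal(sw$betas[which.min(sw$normalized)], -1.78)
  expect_lt(min(sw$rms), 1e-6)
  d <- as.data.frame(sw)
  expect_equal(nrow(d), 11)
  expect_true(all(c("beta", "phi0_best", "rms", "normalized") %in% names(d)))
})

test_that("cohort percentile summaries reduce correctly", {
  geo <- default_geometry()
  tr <- sample_trajectory(geo, 110, -1.9)
  sw <- sweep_betas(border_from_trajectory(tr, "upper"))
  one <- cohort_percentile_summary(list(sw))
  expect_equal(one$p2.5, sw$normalized)
  expect_equal(one$p50, sw$normalized)
  expect_equal(one$p97.5, sw$normalized)

  # minima-aligned curves keep their minimum under the pointwise median
  mk <- function(shift) {
    s <- sw
    s$normalized <- c(90, 70, 50, 30, 10, 5, 10, 30, 50, 70, 90) + shift
    s
  }
  sm <- cohort_percentile_summary(list(mk(0), mk(2), mk(-1)))
  expect_equal(sm$beta[which.min(sm$p50)], sw$betas[6])
  expect_error(cohort_percentile_summary(list()), "no sweeps")
})

test_that("sweep export writes CSV and JSON", {
  spec <- superior_spec(seed = 9)
  pm <- generate_arcuate_pmap(spec)
  bd <- extract_arcuate_borders(pm, hemifield = "superior")
  sw <- arcuate_sweep(bd$upper, bd$lower)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_sweep(sw, csv)
  write_sweep(sw, js)
  d <- utils::read.csv(csv)
  expect_equal(nrow(d), 11)
  expect_equal(d$beta, sw$betas)
  j <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(nrow(j), 11)
})
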