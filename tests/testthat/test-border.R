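make_pmap_from_grid <- function(grid, pixel_size = 0.25,
                                origin = c(-15, 12.5),
                                geometry = default_geometry()) {
  pmap(grid, pixel_size, origin, geometry)
}

test_that("binarization keeps only the 1% category", {
  g <- matrix(0L, 10, 10)
  pm <- make_pmap_from_grid(g)
  expect_true(all(binarize_pmap(pm)$grid == 0L))

  g[4, 5] <- 2L   # p <= 1
  g[6, 6] <- 1L   # p <= 5 only
  g[2, 2] <- 255L # outside field
  m <- binarize_pmap(make_pmap_from_grid(g))
  expect_equal(sum(m$grid), 1L)
  expect_equal(m$grid[4, 5], 1L)
  expect_equal(m$grid[6, 6], 0L)
})

test_that("component selection honors seeds and angular extent", {
  # two annular sectors about the BMO center: 40 and 5 degrees wide
  spec <- superior_spec()
  pm <- generate_arcuate_pmap(spec)
  nr <- nrow(pm$grid); nc <- ncol(pm$grid)
  cen <- list(x = pm$origin[1] + (rep(seq_len(nc), each = nr) - 1) * 0.25,
              y = pm$origin[2] - (rep(seq_len(nr), times = nc) - 1) * 0.25)
  pol <- onh_polar_from_cart(
    cbind(cen$x, cen$y + 1e-9), pm$geometry$bmo_center)
  big <- pol$r >= 7 & pol$r <= 10 & pol$phi >= 100 & pol$phi <= 140
  small <- pol$r >= 7 & pol$r <= 10 & pol$phi >= 160 & pol$phi <= 165
  grid <- matrix(0L, nr, nc)
  grid[big] <- 1L
  grid[small] <- 1L
  mask <- binary_mask(grid, pm$pixel_size, pm$origin, pm$geometry)

  # brute-force extents from pixel angles confirm the qualifying component
  ext_big <- diff(range(pol$phi[big]))
  ext_small <- diff(range(pol$phi[small]))
  expect_gt(ext_big, 20)
  expect_lt(ext_small, 20)

  sel <- select_arcuate_component(mask, bridge = FALSE)
  expect_equal(sum(sel$grid), sum(big))
  expect_true(all(which(sel$grid == 1L) %in% which(big)))

  # a seed inside the smaller component overrides extent-based selection
  seed_pt <- cart_from_onh_polar(8.5, 162.5, pm$geometry$bmo_center)
  sel2 <- select_arcuate_component(mask, seed = seed_pt, bridge = FALSE)
  expect_equal(sum(sel2$grid), sum(small))

  # single component, no seed: returned unchanged
  mask1 <- binary_mask(matrix(as.integer(big), nr, nc), pm$pixel_size,
                       pm$origin, pm$geometry)
  expect_equal(sum(select_arcuate_component(mask1)$grid), sum(big))

  empty <- binary_mask(matrix(0L, nr, nc), pm$pixel_size, pm$origin,
                       pm$geometry)
  expect_error(select_arcuate_component(empty), class = "no_arcuate")
  expect_error(select_arcuate_component(mask, seed = c(-14, -12)),
               class = "no_arcuate")
})

test_that("perimeter extraction matches a brute-force neighbor scan", {
  geo <- default_geometry()
  mk <- function(g) binary_mask(g, 0.25, c(-15, 12.5), geo)

  g <- matrix(0L, 7, 7); g[4, 4] <- 1L
  expect_equal(extract_perimeter(mk(g))$grid, g)

  g <- matrix(0L, 7, 7); g[3:5, 3:5] <- 1L
  per <- extract_perimeter(mk(g))
  expect_equal(sum(per$grid), 8L)
  expect_equal(per$grid[4, 4], 0L)

  # filled disc of radius 10 px vs. brute-force 4-neighbor scan
  n <- 25
  g <- matrix(0L, n, n)
  for (i in 1:n) for (j in 1:n) {
    if ((i - 13)^2 + (j - 13)^2 <= 100) g[i, j] <- 1L
  }
  per <- extract_perimeter(mk(g))$grid
  brute <- matrix(0L, n, n)
  at <- function(i, j) if (i < 1 || i > n || j < 1 || j > n) 0L else g[i, j]
  for (i in 1:n) for (j in 1:n) {
    if (g[i, j] == 1L &&
        (at(i - 1, j) == 0L || at(i + 1, j) == 0L ||
         at(i, j - 1) == 0L || at(i, j + 1) == 0L)) brute[i, j] <- 1L
  }
  expect_equal(per, brute)
})

test_that("borders of a model-generated band track the generating trajectories", {
  spec <- superior_spec(beta = -1.9, pair = c(100, 130))
  pm <- generate_arcuate_pmap(spec)
  borders <- extract_arcuate_borders(pm, hemifield = "superior")
  geo <- pm$geometry
  up <- sample_trajectory(geo, 130, -1.9)
  lo <- sample_trajectory(geo, 100, -1.9)
  # within the trajectory's radial support (beyond its raphe clip the
  # defect is bounded by the raphe line instead), every border point lies
  # within one pixel of its generating trajectory
  in_support <- function(b, tr) b$points$r <= max(tr$r)
  expect_lt(max(dist_to_trajectory(
    border_points_xy(borders$upper)[in_support(borders$upper, up), ], up)),
    pm$pixel_size)
  expect_lt(max(dist_to_trajectory(
    border_points_xy(borders$lower)[in_support(borders$lower, lo), ], lo)),
    pm$pixel_size)
  expect_equal(borders$upper$hemifield, "superior")
  expect_gte(nrow(borders$upper$points), 5)
})

test_that("an annulus sector yields borders at its two constant angles", {
  geo <- default_geometry()
  nr <- 101; nc <- 121
  origin <- c(-15, 12.5)
  x <- origin[1] + (rep(seq_len(nc), each = nr) - 1) * 0.25
  y <- origin[2] - (rep(seq_len(nr), times = nc) - 1) * 0.25
  pol <- onh_polar_from_cart(cbind(x, y + 1e-9), geo$bmo_center)
  sector <- pol$r >= 6.5 & pol$r <= 11 & pol$phi >= 100 & pol$phi <= 125
  mask <- binary_mask(matrix(as.integer(sector), nr, nc), 0.25, origin, geo)
  per <- extract_perimeter(mask)
  borders <- split_borders(per, geo, component = mask)
  expect_lt(max(abs(borders$upper$points$phi - 125)), 2.5)
  expect_lt(max(abs(borders$lower$points$phi - 100)), 2.5)
})

test_that("degenerate perimeters raise a classed condition", {
  geo <- default_geometry()
  nr <- 101; nc <- 121
  origin <- c(-15, 12.5)
  x <- origin[1] + (rep(seq_len(nc), each = nr) - 1) * 0.25
  y <- origin[2] - (rep(seq_len(nr), times = nc) - 1) * 0.25
  pol <- onh_polar_from_cart(cbind(x, y + 1e-9), geo$bmo_center)
  # one-pixel-wide arc: upper and lower sides coincide
  arc <- abs(pol$r - 8) < 0.125 & pol$phi >= 100 & pol$phi <= 130
  mask <- binary_mask(matrix(as.integer(arc), nr, nc), 0.25, origin, geo)
  expect_error(split_borders(extract_perimeter(mask), geo, component = mask),
               class = "degenerate_border")
})

test_that("border extraction is idempotent at the mask level", {
  spec <- superior_spec()
  pm <- generate_arcuate_pmap(spec)
  first <- extract_arcuate_borders(pm, hemifield = "superior")
  # rasterize the selected component back into a p-map and re-extract
  grid2 <- first$component$grid * 2L  # category code for p <= 1%
  pm2 <- pmap(grid2, pm$pixel_size, pm$origin, pm$geometry)
  second <- extract_arcuate_borders(pm2)
  expect_equal(second$upper$points, first$upper$points)
  expect_equal(second$lower$points, first$lower$points)
})

test_that("border extraction commutes with eye mirroring", {
  od_spec <- superior_spec(seed = 3)
  pm_od <- generate_arcuate_pmap(od_spec)
  os_geo <- scan_geometry(bmo_center = c(-15, 2), fd_angle = 7.59,
                          laterality = "OS")
  os_spec <- superior_spec(seed = 3, geometry = os_geo)
  pm_os <- generate_arcuate_pmap(os_spec)
  b_od <- extract_arcuate_borders(pm_od, hemifield = "superior")
  b_os <- extract_arcuate_borders(pm_os, hemifield = "superior")
  # the OS map is normalized into the right-eye frame first, so its
  # borders coincide with the OD borders
  expect_equal(b_os$upper$points, b_od$upper$points)
  expect_equal(b_os$lower$points, b_od$lower$points)
  expect_true(b_os$upper$geometry$normalized)
})

test_that("borders survive CSV round-trips", {
  spec <- superior_spec()
  pm <- generate_arcuate_pmap(spec)
  borders <- extract_arcuate_borders(pm, hemifield = "superior")
  path <- withr::local_tempfile(fileext = ".csv")
  write_arcuate_borders(borders, path)
  back <- read_arcuate_borders(path, pm$geometry, "superior")
  expect_equal(back$upper$points$r, borders$upper$points$r)
  expect_equal(back$lower$points$phi, borders$lower$points$phi)
})

test_that("p-maps survive CSV round-trips with their sidecar", {
  pm <- generate_arcuate_pmap(superior_spec())
  path <- withr::local_tempfile(fileext = ".csv")
  write_pmap(pm, path)
  back <- read_pmap(path)
  expect_equal(back$grid, pm$grid)
  expect_equal(back$pixel_size, pm$pixel_size)
  expect_equal(back$origin, pm$origin)
  expect_equal(back$geometry$bmo_center, pm$geometry$bmo_center)
})
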