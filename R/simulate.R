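# Seeded synthetic data: georeferenced p-maps whose arcuate defect is the
# region between two model trajectories, matching cpRNFL profiles with
# localized thinning, and cohorts of such eyes with controlled noise. All
# randomness flows from the recorded seed.

# evaluate a function with a deterministic RNG state, restoring the caller's
with_seed_ <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Specification of one synthetic eye
#'
#' Defines the arcuate defect of a synthetic eye: the generating curvature
#' parameter, the pair of initial angles bounding the defect, the scan
#' geometry, the noise levels and the seed. Defaults emulate a
#' macula-centered 30 x 25 degree field at 0.25 degrees/pixel with a
#' 6-degree circle scan.
#'
#' @param beta_true Generating curvature parameter.
#' @param phi0_pair Two distinct initial angles (internal convention, or
#'   external inferior values in (180, 300]) in one hemifield.
#' @param geometry A [scan_geometry()]. Default: fovea (0,0), BMO (15,2),
#'   FD -7.59 degrees, r_c 6 degrees, OD.
#' @param noise List with `flip_prob` (independent pixel-flip probability)
#'   and `jitter_sd` (Gaussian angular jitter SD, degrees, applied to the
#'   border curves per radial bin). Default both 0.
#' @param seed Integer seed recorded in all outputs.
#' @param pixel_size Raster resolution, degrees/pixel. Default 0.25.
#' @param field_deg Field width and height in degrees. Default `c(30, 25)`.
#' @param halo_deg Angular width of an optional p <= 5% halo around the
#'   defect. Default 1.5.
#' @param params A [bundle_params()].
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(beta_true, phi0_pair, geometry = scan_geometry(),
                            noise = list(flip_prob = 0, jitter_sd = 0),
                            seed = 1L, pixel_size = 0.25,
                            field_deg = c(30, 25), halo_deg = 1.5,
                            params = bundle_params()) {
  phi0_pair <- phi0_internal(phi0_pair)
  stopifnot(length(phi0_pair) == 2, inherits(geometry, "scan_geometry"),
            pixel_size > 0, length(field_deg) == 2)
  if (phi0_pair[1] == phi0_pair[2]) {
    abort_arcuate("the two initial angles must differ", "degenerate_region")
  }
  reg <- region_of_phi0(phi0_pair)
  if (length(unique(reg)) != 1 || any(reg == "nasal")) {
    stop("phi0_pair must lie in a single superior or inferior hemifield")
  }
  noise <- utils::modifyList(list(flip_prob = 0, jitter_sd = 0), noise)
  stopifnot(noise$flip_prob >= 0, noise$flip_prob <= 1, noise$jitter_sd >= 0)
  structure(list(beta_true = beta_true, phi0_pair = sort(phi0_pair),
                 hemifield = reg[1], geometry = geometry, noise = noise,
                 seed = as.integer(seed), pixel_size = pixel_size,
                 field_deg = as.numeric(field_deg), halo_deg = halo_deg,
                 params = params),
            class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf(
    "<simulation_spec> %s arcuate: beta = %.2f, phi0 = (%.2f, %.2f) deg, seed %d\n",
    x$hemifield, x$beta_true, phi0_external(x$phi0_pair[1]),
    phi0_external(x$phi0_pair[2]), x$seed))
  cat(sprintf("  noise: flip %.3g, jitter %.3g deg; %.3g deg/px\n",
              x$noise$flip_prob, x$noise$jitter_sd, x$pixel_size))
  invisible(x)
}

#' Generate a synthetic p-map with a model-derived arcuate defect
#'
#' Rasterizes the region between the spec's two trajectories -- from the
#' circle scan outward, bounded by the fovea-latitude (raphe / FD) line --
#' as the p <= 1% category, with an optional surrounding p <= 5% halo,
#' then applies seeded border jitter and pixel-flip noise. Deterministic
#' given the seed. Left-eye (OS) geometries are simulated in the right-eye
#' frame and mirrored on output.
#'
#' @param spec A [simulation_spec()].
#' @return A [pmap()]; the generating truth (`beta_true`, `phi0_pair`,
#'   `hemifield`, `seed`) is attached as attribute `"truth"`.
#' @export
generate_arcuate_pmap <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  geo <- spec$geometry
  mirrored <- identical(geo$laterality, "OS")
  if (mirrored) geo <- normalize_to_right_eye(geo)$geometry
  params <- spec$params
  ps <- spec$pixel_size
  nc <- round(spec$field_deg[1] / ps) + 1
  nr <- round(spec$field_deg[2] / ps) + 1
  origin <- geo$fovea + c(-spec$field_deg[1] / 2, spec$field_deg[2] / 2)

  x <- origin[1] + (rep(seq_len(nc), each = nr) - 1) * ps
  y <- origin[2] - (rep(seq_len(nr), times = nc) - 1) * ps
  q <- scan_to_model(cbind(x, y), geo, params)
  dx <- q[, 1] - params$onh_assumed[1]
  dy <- q[, 2] - params$onh_assumed[2]
  r <- sqrt(dx^2 + dy^2)
  phi <- unwrap_hemifield(wrap_phi(rad2deg(atan2(dy, dx))), spec$hemifield)

  hs <- hemifield_sign(spec$hemifield)
  p0 <- unwrap_hemifield(spec$phi0_pair, spec$hemifield)
  lo <- min(p0); hi <- max(p0)
  r_ok <- r >= geo$r_c & r <= params$r_max
  phi_lo <- phi_hi <- rep(NA_real_, length(r))
  phi_lo[r_ok] <- phi_of_r(lo, r[r_ok], geo$r_c, spec$beta_true,
                           spec$hemifield)
  phi_hi[r_ok] <- phi_of_r(hi, r[r_ok], geo$r_c, spec$beta_true,
                           spec$hemifield)

  grid_codes <- with_seed_(spec$seed, {
    jl <- jh <- 0
    if (spec$noise$jitter_sd > 0) {
      nbin <- floor(params$r_max / 0.25) + 1L
      jl <- stats::rnorm(nbin, 0, spec$noise$jitter_sd)[floor(r / 0.25) + 1L]
      jh <- stats::rnorm(nbin, 0, spec$noise$jitter_sd)[floor(r / 0.25) + 1L]
    }
    defect <- r_ok & hs * q[, 2] > 0 &
      phi >= phi_lo + jl & phi <= phi_hi + jh
    defect[is.na(defect)] <- FALSE
    halo <- rep(FALSE, length(r))
    if (spec$halo_deg > 0) {
      halo <- r_ok & hs * q[, 2] > 0 & !defect &
        phi >= phi_lo + jl - spec$halo_deg &
        phi <= phi_hi + jh + spec$halo_deg
      halo[is.na(halo)] <- FALSE
    }
    codes <- rep(PMAP_CODES[["normal"]], length(r))
    codes[halo] <- PMAP_CODES[["p5"]]
    codes[defect] <- PMAP_CODES[["p1"]]
    if (spec$noise$flip_prob > 0) {
      flip <- stats::runif(length(r)) < spec$noise$flip_prob
      codes[flip] <- ifelse(codes[flip] == PMAP_CODES[["p1"]],
                            PMAP_CODES[["normal"]], PMAP_CODES[["p1"]])
    }
    codes
  })

  grid <- matrix(grid_codes, nrow = nr)
  out_geo <- geo
  if (mirrored) {
    grid <- grid[, rev(seq_len(nc)), drop = FALSE]
    out_geo <- spec$geometry  # original OS geometry
    origin <- c(-(origin[1] + (nc - 1) * ps), origin[2])
  }
  out <- pmap(grid, ps, origin, out_geo)
  attr(out, "truth") <- list(beta_true = spec$beta_true,
                             phi0_pair = spec$phi0_pair,
                             hemifield = spec$hemifield,
                             seed = spec$seed)
  out
}

# double-hump normative cpRNFL mean: peaks at the superior (90) and
# inferior (270) poles, troughs temporally and nasally
cprnfl_norm_mean <- function(tsnit) 72 + 38 * sin(deg2rad(tsnit))^2

#' Generate a synthetic cpRNFL profile with designed thinning
#'
#' The normative mean is a smooth double-hump curve
#' `72 + 38 sin(t)^2` micrometers with constant SD 10; the measured
#' thickness equals the normative mean except over a designed sub-arc of
#' the trajectory-determined region (anchored at its start), where it is
#' depressed clearly below the 1% normative quantile. [fraction_below()]
#' then recovers `abnormal_fraction` up to spacing discretization.
#'
#' @param spec A [simulation_spec()].
#' @param abnormal_fraction Designed abnormal fraction of the
#'   trajectory-determined region, in \[0, 1\]. Default 1.
#' @param spacing TSNIT spacing in degrees. Default 0.5.
#' @return A [cprnfl_profile()]; the designed region is attached as
#'   attribute `"region"`.
#' @export
generate_cprnfl_profile <- function(spec, abnormal_fraction = 1,
                                    spacing = 0.5) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (abnormal_fraction < 0 || abnormal_fraction > 1) {
    stop("abnormal_fraction must be in [0, 1]")
  }
  positions <- seq(0, 360 - spacing, by = spacing)
  norm_mean <- cprnfl_norm_mean(positions)
  norm_sd <- rep(10, length(positions))
  thickness <- norm_mean

  t0 <- sort(tsnit_from_phi(wrap_phi(spec$phi0_pair)))
  region <- angular_region(t0[1], t0[2], spec$hemifield)
  if (abnormal_fraction > 0) {
    sub_len <- abnormal_fraction * region$length
    bad <- positions >= region$start & positions <= region$start + sub_len
    thickness[bad] <- norm_mean[bad] + stats::qnorm(0.01) * norm_sd[bad] - 5
  }
  out <- cprnfl_profile(positions, thickness, norm_mean, norm_sd)
  attr(out, "region") <- region
  out
}

#' Generate a seeded cohort of synthetic arcuate eyes
#'
#' Draws `n` independent eyes with randomized defect positions and widths,
#' each with its own derived seed, and returns p-maps, cpRNFL profiles and
#' truth records for recovery scoring.
#'
#' @param n Number of eyes (>= 1).
#' @param region `"superior"` or `"inferior"`.
#' @param beta_true Generating curvature parameter (scalar, or a function
#'   of no arguments returning one draw).
#' @param noise Noise list as in [simulation_spec()].
#' @param seed Cohort seed; per-eye seeds are derived from it.
#' @param phi0_start_range Range (degrees, internal superior convention;
#'   mirrored for inferior) for the defect's lower initial angle.
#' @param width_range Range (degrees) for the defect's angular width at the
#'   circle scan.
#' @param geometry,pixel_size,halo_deg,params Passed to [simulation_spec()].
#' @return List of `n` cases, each a list with `spec`, `pmap`, `profile`
#'   and `truth` (a list with `beta_true`, `phi0_pair`, `hemifield`,
#'   `seed`).
#' @export
generate_cohort <- function(n, region = "superior", beta_true = -1.9,
                            noise = list(flip_prob = 0, jitter_sd = 0),
                            seed = 1L, phi0_start_range = c(85, 105),
                            width_range = c(25, 40),
                            geometry = scan_geometry(), pixel_size = 0.25,
                            halo_deg = 1.5, params = bundle_params()) {
  stopifnot(n >= 1)
  region <- match.arg(region, c("superior", "inferior"))
  draws <- with_seed_(seed, {
    lapply(seq_len(n), function(i) {
      start <- stats::runif(1, phi0_start_range[1], phi0_start_range[2])
      width <- stats::runif(1, width_range[1], width_range[2])
      b <- if (is.function(beta_true)) beta_true() else beta_true
      list(start = start, width = width, beta = b)
    })
  })
  lapply(seq_len(n), function(i) {
    d <- draws[[i]]
    pair <- if (region == "superior") c(d$start, d$start + d$width)
            else -c(d$start, d$start + d$width)
    spec <- simulation_spec(beta_true = d$beta, phi0_pair = pair,
                            geometry = geometry, noise = noise,
                            seed = seed + 7919L * i, pixel_size = pixel_size,
                            halo_deg = halo_deg, params = params)
    pm <- generate_arcuate_pmap(spec)
    list(spec = spec, pmap = pm,
         profile = generate_cprnfl_profile(spec),
         truth = attr(pm, "truth"))
  })
}

#' Write / read a simulation truth record as JSON
#'
#' @param truth Truth list (`beta_true`, `phi0_pair`, `hemifield`, `seed`).
#' @param path JSON file path.
#' @return `read_truth()` returns the truth list; `write_truth()` returns
#'   `path` invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(beta_true = as.numeric(j$beta_true),
       phi0_pair = as.numeric(j$phi0_pair),
       hemifield = as.character(j$hemifield),
       seed = as.integer(j$seed))
}
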