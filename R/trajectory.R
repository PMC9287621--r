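# The trajectory model: phi(phi0, r) = phi0 + b(phi0) * (r - r0)^c(phi0),
# in polar coordinates about the ONH. c() locates the curvature along the
# path, b() sets its amount; each has a superior and an inferior form, and
# the free parameter beta (beta_sup / beta_inf) scales the curvature. The
# nasal sector is approximated by straight radial rays from the circle scan.

BETA_SUP_RANGE <- c(-1.3, -2.5)
BETA_INF_RANGE <- c(1.3, 0.1)

#' Bundle trajectory model parameters
#'
#' Fixed parameters of the trajectory model and its anchoring to the scan:
#' the assumed ONH eccentricity in the model frame, the assumed fovea-disc
#' angle, the default initial radius of the original model, and the radial
#' sampling used when tracing trajectories.
#'
#' @param r0_default Initial radius of the original model formulation, in
#'   degrees (default 4). Retained for reference; trajectories traced from a
#'   circle scan use the scan's own radius `r_c` as the starting radius.
#' @param onh_assumed Assumed ONH center in the model frame, degrees
#'   (default `c(15, 2)`: 15 degrees nasal, 2 degrees superior of the fovea).
#' @param fd_assumed Assumed fovea-disc angle for a right eye, degrees
#'   (default -7.59). Trajectories are rotated by the difference between the
#'   recorded and assumed FD angles ("relative FD angle").
#' @param r_step Radial sampling step in degrees (default 0.05, sub-pixel
#'   relative to typical raster resolution).
#' @param r_max Field cutoff radius in degrees (default 34: the far corner
#'   of a macula-centered 30 x 25 degree field lies about 33 degrees from
#'   the ONH).
#' @param allow_beta_outside Allow beta values outside the empirical ranges
#'   (superior -1.3..-2.5, inferior 1.3..0.1)? Default `FALSE`.
#' @return An object of class `bundle_params`.
#' @export
bundle_params <- function(r0_default = 4, onh_assumed = c(15, 2),
                          fd_assumed = -7.59, r_step = 0.05, r_max = 34,
                          allow_beta_outside = FALSE) {
  stopifnot(r_step > 0, r_max > r0_default, length(onh_assumed) == 2)
  structure(list(r0_default = r0_default,
                 onh_assumed = as.numeric(onh_assumed),
                 fd_assumed = fd_assumed, r_step = r_step, r_max = r_max,
                 allow_beta_outside = isTRUE(allow_beta_outside)),
            class = "bundle_params")
}

# ---- sectors ---------------------------------------------------------------

#' Sector of an initial angular position
#'
#' Classifies the initial angle phi0 (degrees, ONH convention) into the
#' superior-temporal sector (60 <= phi0 <= 180), the inferior-temporal sector
#' (-180 < phi0 <= -60), or the nasal sector (-60 < phi0 < 60). Both
#' boundaries at +/-60 belong to the superior / inferior sectors.
#'
#' @param phi0 Initial angle(s) in degrees, in (-180, 180].
#' @return Character vector: `"superior"`, `"inferior"` or `"nasal"`.
#' @export
#' @examples
#' region_of_phi0(c(60, -60, 0, 180))
region_of_phi0 <- function(phi0) {
  stopifnot(all(is.finite(phi0)), all(phi0 > -180), all(phi0 <= 180))
  ifelse(phi0 >= 60 & phi0 <= 180, "superior",
         ifelse(phi0 > -180 & phi0 <= -60, "inferior", "nasal"))
}

#' Convert between internal and external inferior phi0 conventions
#'
#' The inferior sector is computed internally in (-180, -60] as the model
#' equations require, but reported externally in (180, 300] so that the full
#' search range reads 60..300 degrees. `phi0_internal()` maps external
#' values in (180, 300] down by 360; `phi0_external()` maps internal inferior
#' values up by 360.
#'
#' @param phi0 Initial angle(s) in degrees.
#' @return Converted angle(s).
#' @export
phi0_internal <- function(phi0) ifelse(phi0 > 180 & phi0 <= 300, phi0 - 360, phi0)

#' @rdname phi0_internal
#' @export
phi0_external <- function(phi0) ifelse(phi0 > -180 & phi0 <= -60, phi0 + 360, phi0)

check_sector <- function(phi0, region) {
  ok <- region_of_phi0(phi0) == region
  if (!all(ok)) {
    stop("phi0 = ", paste(phi0[!ok], collapse = ", "),
         " outside the ", region, " sector")
  }
  invisible(TRUE)
}

# ---- auxiliary equations ---------------------------------------------------

#' Curvature-location and curvature-amount functions
#'
#' The auxiliary functions of the trajectory model. `c_sup()` / `c_inf()`
#' give the curvature-location exponent, `b_sup()` / `b_inf()` the signed
#' curvature amount, for the superior (60 <= phi0 <= 180) and inferior
#' (-180 < phi0 <= -60) sectors:
#' \deqn{c_{Sup} = 1.9 + 1.4\,\tanh\{(\phi_0-121)/14\}}
#' \deqn{c_{Inf} = 1.0 + 0.5\,\tanh\{(-\phi_0-90)/25\}}
#' \deqn{b_{Sup} = \exp(\beta_{Sup} + 3.9\tanh\{-(\phi_0-121)/14\})}
#' \deqn{b_{Inf} = -\exp(\beta_{Inf} + 1.5\tanh\{-(-\phi_0-90)/25\})}
#' `b_sup` is always positive (superior trajectories curve counterclockwise
#' toward the temporal raphe) and `b_inf` always negative.
#'
#' @param phi0 Initial angle(s) in degrees, within the respective sector.
#' @param beta_sup,beta_inf Curvature parameter; empirical ranges are
#'   -1.3..-2.5 (superior, mean -1.90) and 1.3..0.1 (inferior, mean 0.70).
#' @return Numeric vector.
#' @export
#' @examples
#' c_sup(121)        # 1.9 (tanh term vanishes)
#' c_inf(-90)        # 1.0
#' b_sup(121, -1.9)  # exp(-1.9)
c_sup <- function(phi0) {
  check_sector(phi0, "superior")
  1.9 + 1.4 * tanh((phi0 - 121) / 14)
}

#' @rdname c_sup
#' @export
c_inf <- function(phi0) {
  check_sector(phi0, "inferior")
  1.0 + 0.5 * tanh((-phi0 - 90) / 25)
}

#' @rdname c_sup
#' @export
b_sup <- function(phi0, beta_sup) {
  check_sector(phi0, "superior")
  exp(beta_sup + 3.9 * tanh(-(phi0 - 121) / 14))
}

#' @rdname c_sup
#' @export
b_inf <- function(phi0, beta_inf) {
  check_sector(phi0, "inferior")
  -exp(beta_inf + 1.5 * tanh(-(-phi0 - 90) / 25))
}

#' Trajectory angle as a function of radius
#'
#' Evaluates phi(phi0, r) = phi0 + b(phi0) * (r - r0)^c(phi0) for superior or
#' inferior trajectories. At r = r0 this returns phi0 exactly. The returned
#' angle is unwrapped (it may leave (-180, 180] as the trajectory bends
#' toward the raphe).
#'
#' @param phi0 Initial angle in degrees (scalar).
#' @param r Radius or radii in degrees; must satisfy `r >= r0`.
#' @param r0 Initial radius in degrees.
#' @param beta Curvature parameter for the sector of `phi0`.
#' @param region Optional sector override (`"superior"` / `"inferior"`);
#'   inferred from `phi0` by default.
#' @return Unwrapped angle(s) phi in degrees.
#' @export
#' @examples
#' phi_of_r(121, c(4, 9), r0 = 4, beta = -1.9)
phi_of_r <- function(phi0, r, r0, beta, region = NULL) {
  stopifnot(length(phi0) == 1)
  if (is.null(region)) region <- region_of_phi0(phi0)
  if (!region %in% c("superior", "inferior")) {
    stop("phi_of_r applies to superior or inferior trajectories only")
  }
  if (any(r < r0)) stop("r must be >= r0")
  if (region == "superior") {
    phi0 + b_sup(phi0, beta) * (r - r0)^c_sup(phi0)
  } else {
    phi0 + b_inf(phi0, beta) * (r - r0)^c_inf(phi0)
  }
}

# ---- beta grids ------------------------------------------------------------

#' The 11-point beta grid of a sector
#'
#' Eleven evenly spaced curvature-parameter values spanning the empirical
#' range, ordered from the first printed endpoint: superior -1.3 .. -2.5
#' (middle element -1.90), inferior 1.3 .. 0.1 (middle element 0.70).
#'
#' @param region `"superior"` or `"inferior"`.
#' @return Numeric vector of 11 beta values.
#' @export
#' @examples
#' beta_grid("superior")
beta_grid <- function(region) {
  region <- match.arg(region, c("superior", "inferior"))
  if (region == "superior") {
    seq(BETA_SUP_RANGE[1], BETA_SUP_RANGE[2], length.out = 11)
  } else {
    seq(BETA_INF_RANGE[1], BETA_INF_RANGE[2], length.out = 11)
  }
}

check_beta <- function(beta, region, params) {
  rng <- sort(if (region == "superior") BETA_SUP_RANGE else BETA_INF_RANGE)
  if (!params$allow_beta_outside && (beta < rng[1] || beta > rng[2])) {
    stop("beta = ", beta, " outside the empirical ", region, " range [",
         rng[1], ", ", rng[2], "]; set allow_beta_outside = TRUE to override")
  }
  invisible(TRUE)
}

# ---- frame transforms ------------------------------------------------------

# Model frame: fovea at (0, 0), ONH at the assumed eccentricity (15, 2),
# right-eye orientation, FD angle at its assumed value. Mapping to the scan
# frame: rotate about the fovea by the relative FD angle
# (recorded - assumed), then translate so the rotated assumed ONH lands on
# the recorded BMO center. Radii about the ONH and angular differences are
# preserved; angles about the ONH shift by the relative FD angle.
relative_fd <- function(geometry, params) geometry$fd_angle - params$fd_assumed

model_to_scan <- function(p, geometry, params) {
  m <- as_xy(p)
  delta <- relative_fd(geometry, params)
  q <- rotate_about(m, c(0, 0), delta)
  t0 <- geometry$bmo_center -
    as.numeric(rotate_about(params$onh_assumed, c(0, 0), delta))
  cbind(x = q[, 1] + t0[1], y = q[, 2] + t0[2])
}

scan_to_model <- function(p, geometry, params) {
  m <- as_xy(p)
  delta <- relative_fd(geometry, params)
  t0 <- geometry$bmo_center -
    as.numeric(rotate_about(params$onh_assumed, c(0, 0), delta))
  rotate_about(cbind(m[, 1] - t0[1], m[, 2] - t0[2]), c(0, 0), -delta)
}

# ---- trajectory sampling ---------------------------------------------------

#' Trace one fiber-bundle trajectory in the scan frame
#'
#' Samples a trajectory of the model for a given initial angle and curvature
#' parameter, anchored to an eye's scan geometry: the trajectory starts on
#' the circle b-scan (r = r_c about the BMO center) and is traced outward in
#' steps of `r_step`. Nasal initial angles produce straight radial rays
#' (lines perpendicular to the circle scan). The path is computed in the
#' model frame, clipped at its first crossing of the horizontal line through
#' the fovea -- the temporal raphe on the temporal side of the fovea, the FD
#' line on the nasal side (the boundary itself rotates with the relative FD
#' angle) -- then rotated by the relative FD angle and re-centered on the
#' recorded BMO center.
#'
#' @param geometry A [scan_geometry()] in the right-eye frame (see
#'   [normalize_to_right_eye()]).
#' @param phi0 Initial angle in degrees at r = r_c, internal convention
#'   (external inferior values in (180, 300] are accepted and converted).
#' @param beta Curvature parameter (ignored for nasal rays).
#' @param params A [bundle_params()].
#' @return An object of class `trajectory` with fields `phi0`, `beta`,
#'   `region`, `r` (sample radii about the BMO center), `phi_model`
#'   (unwrapped model-frame angles), `phi_scan` (unwrapped scan-frame
#'   angles), `polyline` (n x 2 scan-frame points in degrees, including the
#'   interpolated clipping terminus), and `clip_reason` (`"raphe"`,
#'   `"fd_line"` or `"field_edge"`).
#' @export
#' @examples
#' traj <- sample_trajectory(scan_geometry(), 120, -1.9)
#' traj
sample_trajectory <- function(geometry, phi0, beta = NA_real_,
                              params = bundle_params()) {
  stopifnot(inherits(geometry, "scan_geometry"))
  if (identical(geometry$laterality, "OS") && !isTRUE(geometry$normalized)) {
    stop("geometry must be normalized to the right-eye frame first")
  }
  phi0 <- phi0_internal(phi0)
  region <- region_of_phi0(phi0)
  r_c <- geometry$r_c
  if (r_c >= params$r_max) stop("r_c must be smaller than r_max")

  r <- seq(r_c, params$r_max, by = params$r_step)
  if (region == "nasal") {
    phi <- rep(phi0, length(r))
    beta <- NA_real_
  } else {
    if (is.na(beta)) stop("beta is required for ", region, " trajectories")
    check_beta(beta, region, params)
    phi <- phi_of_r(phi0, r, r0 = r_c, beta = beta, region = region)
  }

  # model-frame cartesian; clip at the first crossing of the fovea-latitude
  # line (y = 0 in the model frame)
  onh <- params$onh_assumed
  a <- deg2rad(phi)
  x <- onh[1] + r * cos(a)
  y <- onh[2] + r * sin(a)
  s0 <- sign(y[1])
  if (s0 == 0) {
    abort_arcuate("trajectory starts on the raphe/FD boundary",
                  "degenerate_trajectory")
  }
  crossing <- which(sign(y) != s0)
  clip_reason <- "field_edge"
  terminus <- NULL
  if (length(crossing)) {
    k <- crossing[1]
    if (k < 2) {
      abort_arcuate("trajectory clipped to an empty polyline",
                    "degenerate_trajectory")
    }
    # linear interpolation between samples k-1 and k to the y = 0 crossing
    w <- y[k - 1] / (y[k - 1] - y[k])
    terminus <- c(x[k - 1] + w * (x[k] - x[k - 1]), 0)
    clip_reason <- if (terminus[1] < 0) "raphe" else "fd_line"
    keep <- seq_len(k - 1)
    r <- r[keep]; phi <- phi[keep]; x <- x[keep]; y <- y[keep]
  }
  if (length(r) < 2) {
    abort_arcuate("trajectory clipped to an empty polyline",
                  "degenerate_trajectory")
  }

  pts_model <- cbind(x, y)
  if (!is.null(terminus)) pts_model <- rbind(pts_model, terminus)
  polyline <- model_to_scan(pts_model, geometry, params)
  delta <- relative_fd(geometry, params)

  structure(list(phi0 = phi0, beta = beta, region = region,
                 r = r, phi_model = phi, phi_scan = phi + delta,
                 polyline = polyline, clip_reason = clip_reason,
                 geometry = geometry, params = params),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %s phi0 = %.2f deg%s, %d samples (r %.2f..%.2f deg), clipped at %s\n",
    x$region, phi0_external(x$phi0),
    if (is.na(x$beta)) "" else sprintf(", beta = %.2f", x$beta),
    length(x$r), x$r[1], x$r[length(x$r)], x$clip_reason))
  invisible(x)
}

#' Export a trajectory polyline as a data frame
#'
#' @param x A `trajectory`.
#' @param ... Unused.
#' @return Data frame with columns `x_deg`, `y_deg`, `r_deg`, `phi_deg`
#'   (scan frame; the interpolated clipping terminus, if any, is included
#'   with its own radius/angle about the BMO center).
#' @export
as.data.frame.trajectory <- function(x, ...) {
  pol <- onh_polar_from_cart(x$polyline, x$geometry$bmo_center)
  data.frame(x_deg = x$polyline[, 1], y_deg = x$polyline[, 2],
             r_deg = pol$r, phi_deg = pol$phi)
}
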