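# ---- angle helpers ---------------------------------------------------------

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap an angle into (-180, 180]
#'
#' All stored angular positions about the optic nerve head (ONH) use the
#' convention phi = 0 along the nasal horizontal ray from the ONH (pointing
#' away from the fovea), positive counterclockwise in the right-eye frame,
#' stored in (-180, 180].
#'
#' @param phi Numeric vector of angles in degrees.
#' @return Angles wrapped into (-180, 180].
#' @export
#' @examples
#' wrap_phi(c(190, -190, 180, 360))
wrap_phi <- function(phi) {
  p <- phi %% 360
  ifelse(p > 180, p - 360, p)
}

# Unwrap wrapped angles onto the continuous branch of one hemifield:
# superior -> [0, 360), inferior -> (-360, 0]. The branch cut sits on the
# nasal horizontal, which no valid arcuate border reaches.
unwrap_hemifield <- function(phi, hemifield) {
  p <- phi %% 360
  if (identical(hemifield, "superior")) p else p - 360
}

hemifield_sign <- function(hemifield) {
  switch(hemifield, superior = 1, inferior = -1,
         stop("unknown hemifield: ", hemifield))
}

# ---- points ----------------------------------------------------------------

# Points are plain numeric (x, y) pairs or n x 2 matrices in degrees of
# visual angle: fovea-centered retinal map frame, +x nasal (toward the disc),
# +y superior, right-eye convention.
as_xy <- function(p) {
  if (is.data.frame(p)) p <- as.matrix(p)
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 2)
    m <- unname(p)
  } else {
    stopifnot(is.numeric(p), length(p) == 2)
    m <- matrix(as.numeric(p), nrow = 1)
  }
  colnames(m) <- c("x", "y")
  m
}

#' Rotate points about a center
#'
#' Rigid counterclockwise rotation of one or more points about an arbitrary
#' center, in degrees.
#'
#' @param p Point as `c(x, y)` or an n x 2 matrix (degrees).
#' @param center Pivot point `c(x, y)`.
#' @param angle Rotation angle in degrees, counterclockwise positive.
#' @return Rotated points, same shape as `p` (always an n x 2 matrix).
#' @export
#' @examples
#' rotate_about(c(1, 0), c(0, 0), 90)
rotate_about <- function(p, center, angle) {
  m <- as_xy(p)
  c0 <- as_xy(center)
  a <- deg2rad(angle)
  dx <- m[, 1] - c0[1, 1]
  dy <- m[, 2] - c0[1, 2]
  out <- cbind(x = c0[1, 1] + cos(a) * dx - sin(a) * dy,
               y = c0[1, 2] + sin(a) * dx + cos(a) * dy)
  out
}

# ---- scan geometry ---------------------------------------------------------

#' Per-eye scan geometry
#'
#' Anatomical frame of one OCT acquisition: fovea center, Bruch's membrane
#' opening (BMO / disc) center, the fovea-disc (FD) axis angle recorded by the
#' instrument, the circle b-scan radius, and eye laterality. All coordinates
#' are degrees of visual angle in a fovea-referenced frame with +x nasal and
#' +y superior (right-eye convention after normalization).
#'
#' @param fovea Fovea center `c(x, y)` in degrees. Default `c(0, 0)`.
#' @param bmo_center BMO (disc) center `c(x, y)` in degrees. Default `c(15, 2)`.
#' @param fd_angle Recorded fovea-disc angle in degrees. Default `-7.59`.
#' @param r_c Circle b-scan radius in degrees; must be positive. Default `6`
#'   (a 3.5 mm-diameter circle at roughly 0.291 mm/degree).
#' @param laterality `"OD"` (right) or `"OS"` (left).
#' @return An object of class `scan_geometry`.
#' @export
#' @examples
#' geo <- scan_geometry()
#' geo
scan_geometry <- function(fovea = c(0, 0), bmo_center = c(15, 2),
                          fd_angle = -7.59, r_c = 6, laterality = "OD") {
  fovea <- as.numeric(as_xy(fovea))
  bmo_center <- as.numeric(as_xy(bmo_center))
  stopifnot(all(is.finite(fovea)), all(is.finite(bmo_center)),
            is.finite(fd_angle), is.finite(r_c))
  if (r_c <= 0) stop("r_c must be positive")
  if (!laterality %in% c("OD", "OS")) {
    stop("unknown laterality code: ", laterality, " (expected 'OD' or 'OS')")
  }
  structure(list(fovea = fovea, bmo_center = bmo_center,
                 fd_angle = fd_angle, r_c = r_c, laterality = laterality,
                 normalized = identical(laterality, "OD")),
            class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("<scan_geometry> %s%s\n", x$laterality,
              if (isTRUE(x$normalized)) " (right-eye frame)" else ""))
  cat(sprintf("  fovea: (%.2f, %.2f) deg   BMO center: (%.2f, %.2f) deg\n",
              x$fovea[1], x$fovea[2], x$bmo_center[1], x$bmo_center[2]))
  cat(sprintf("  FD angle: %.2f deg   circle radius r_c: %.2f deg\n",
              x$fd_angle, x$r_c))
  invisible(x)
}

#' Mirror points across the vertical axis
#'
#' Left-eye (OS) coordinates are brought into the common right-eye frame by
#' mirroring x -> -x. The operation is an involution.
#'
#' @param p Point(s) as `c(x, y)` or an n x 2 matrix.
#' @return Mirrored points (n x 2 matrix).
#' @export
mirror_points <- function(p) {
  m <- as_xy(p)
  m[, 1] <- -m[, 1]
  m
}

#' Normalize a scan to the right-eye frame
#'
#' Left eyes (OS) are mirrored across the vertical axis (x -> -x, applied to
#' fovea, BMO center and any supplied points) and the recorded FD angle is
#' negated, since mirroring reverses angular orientation. Right eyes pass
#' through unchanged. Re-normalizing an already-normalized geometry is a
#' no-op.
#'
#' @param geometry A [scan_geometry()].
#' @param points Optional points (`c(x, y)` or n x 2 matrix) to transform
#'   alongside the geometry.
#' @return A list with elements `geometry` and `points` (`NULL` if no points
#'   were supplied).
#' @export
#' @examples
#' os <- scan_geometry(bmo_center = c(-15, 2), fd_angle = -7.59,
#'                     laterality = "OS")
#' normalize_to_right_eye(os)$geometry
normalize_to_right_eye <- function(geometry, points = NULL) {
  stopifnot(inherits(geometry, "scan_geometry"))
  if (isTRUE(geometry$normalized)) {
    return(list(geometry = geometry,
                points = if (is.null(points)) NULL else as_xy(points)))
  }
  g <- geometry
  g$fovea <- as.numeric(mirror_points(g$fovea))
  g$bmo_center <- as.numeric(mirror_points(g$bmo_center))
  g$fd_angle <- -g$fd_angle
  g$normalized <- TRUE
  pts <- if (is.null(points)) NULL else mirror_points(points)
  if (g$bmo_center[1] <= g$fovea[1]) {
    warning("normalized BMO center is not nasal of the fovea; ",
            "check input laterality")
  }
  list(geometry = g, points = pts)
}

# ---- polar transforms about the ONH ----------------------------------------

#' Polar coordinates about the optic nerve head
#'
#' Converts retinal-map points to polar coordinates about an ONH center:
#' radius `r` in degrees and angle `phi` with 0 along the nasal horizontal
#' ray from the ONH (pointing away from the fovea, i.e. +x), positive
#' counterclockwise, wrapped to (-180, 180].
#'
#' @param p Point(s) as `c(x, y)` or an n x 2 matrix (degrees).
#' @param onh_center ONH (BMO) center `c(x, y)`.
#' @return A data frame with columns `r` and `phi`.
#' @export
#' @examples
#' onh_polar_from_cart(c(21, 2), c(15, 2)) # r = 6, phi = 0
onh_polar_from_cart <- function(p, onh_center) {
  m <- as_xy(p)
  c0 <- as_xy(onh_center)
  dx <- m[, 1] - c0[1, 1]
  dy <- m[, 2] - c0[1, 2]
  r <- sqrt(dx^2 + dy^2)
  if (any(r == 0)) stop("point coincides with the ONH center (zero radius)")
  data.frame(r = unname(r), phi = unname(wrap_phi(rad2deg(atan2(dy, dx)))))
}

#' @rdname onh_polar_from_cart
#' @param r Radius (degrees) from the ONH center.
#' @param phi Angle (degrees), same convention as above.
#' @export
cart_from_onh_polar <- function(r, phi, onh_center) {
  c0 <- as_xy(onh_center)
  a <- deg2rad(phi)
  cbind(x = c0[1, 1] + r * cos(a), y = c0[1, 2] + r * sin(a))
}

# ---- clock hours and TSNIT positions ---------------------------------------

#' Clock-hour position from an ONH angle
#'
#' Maps the ONH-polar angle to the clock-hour position theta_c on the circle
#' scan, real-valued in (0, 12], right-eye frame: superior (90 deg) -> 12,
#' nasal (0 deg) -> 3, inferior (-90 deg) -> 6, temporal (180 deg) -> 9.
#'
#' @param phi Angle(s) in degrees (ONH convention).
#' @return Clock hours in (0, 12].
#' @export
#' @examples
#' clock_hour_from_phi(c(90, 0, -90, 180))
clock_hour_from_phi <- function(phi) {
  stopifnot(all(is.finite(phi)))
  12 - ((-(90 - phi) / 30) %% 12)
}

#' @rdname clock_hour_from_phi
#' @param hour Clock hour(s) in (0, 12].
#' @export
phi_from_clock_hour <- function(hour) {
  stopifnot(all(is.finite(hour)))
  wrap_phi(90 - 30 * hour)
}

#' TSNIT profile position from an ONH angle
#'
#' Maps the ONH-polar angle to the unwrapped circle-scan position in
#' temporal-superior-nasal-inferior-temporal (TSNIT) order: temporal
#' (phi = 180) -> 0, superior -> 90, nasal -> 180, inferior -> 270.
#'
#' @param phi Angle(s) in degrees (ONH convention).
#' @return TSNIT positions in [0, 360).
#' @export
#' @examples
#' tsnit_from_phi(c(180, 90, 0, -90))
tsnit_from_phi <- function(phi) {
  stopifnot(all(is.finite(phi)))
  (180 - phi) %% 360
}

#' @rdname tsnit_from_phi
#' @param tsnit TSNIT position(s) in degrees.
#' @export
phi_from_tsnit <- function(tsnit) {
  wrap_phi(180 - tsnit)
}

# ---- geometry JSON sidecar -------------------------------------------------

#' Read / write a scan-geometry JSON sidecar
#'
#' The sidecar stores keys `fovea_xy_deg`, `bmo_center_xy_deg`,
#' `fd_angle_deg`, `r_c_deg` and `laterality`.
#'
#' @param path File path of the JSON sidecar.
#' @return `read_scan_geometry()` returns a [scan_geometry()];
#'   `write_scan_geometry()` returns `path` invisibly.
#' @export
read_scan_geometry <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("fovea_xy_deg", "bmo_center_xy_deg", "fd_angle_deg",
            "r_c_deg", "laterality")
  missing <- setdiff(need, names(j))
  if (length(missing)) {
    stop("geometry sidecar is missing key(s): ", paste(missing, collapse = ", "))
  }
  scan_geometry(fovea = as.numeric(j$fovea_xy_deg),
                bmo_center = as.numeric(j$bmo_center_xy_deg),
                fd_angle = as.numeric(j$fd_angle_deg),
                r_c = as.numeric(j$r_c_deg),
                laterality = as.character(j$laterality))
}

#' @rdname read_scan_geometry
#' @param geometry A [scan_geometry()].
#' @export
write_scan_geometry <- function(geometry, path) {
  stopifnot(inherits(geometry, "scan_geometry"))
  jsonlite::write_json(
    list(fovea_xy_deg = geometry$fovea,
         bmo_center_xy_deg = geometry$bmo_center,
         fd_angle_deg = geometry$fd_angle,
         r_c_deg = geometry$r_c,
         laterality = geometry$laterality),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
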