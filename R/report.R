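# Static arcuate report rendering: trajectory overlays on the p-map and the
# trajectory-determined bounds on the cpRNFL plot, written as a PNG.

pmap_palette <- c(normal = "grey92", p5 = "#f5c542", p1 = "#d64541",
                  outside = "grey60")

# draw a pmap with image(); x increases nasally, y upward
draw_pmap <- function(x, main = "RNFL p-map") {
  nr <- nrow(x$grid); nc <- ncol(x$grid)
  xs <- x$origin[1] + (seq_len(nc) - 1) * x$pixel_size
  ys <- x$origin[2] - (seq_len(nr) - 1) * x$pixel_size
  z <- matrix(match(x$grid, unname(PMAP_CODES)), nr, nc)
  graphics::image(xs, rev(ys), t(z[nr:1, , drop = FALSE]),
                  col = unname(pmap_palette), zlim = c(1, 4),
                  xlab = "x (deg, nasal +)", ylab = "y (deg, superior +)",
                  main = main, asp = 1, useRaster = TRUE)
}

draw_circle <- function(center, radius, ...) {
  a <- seq(0, 2 * pi, length.out = 361)
  graphics::lines(center[1] + radius * cos(a), center[2] + radius * sin(a), ...)
}

#' Render a static arcuate report
#'
#' Two panels: the p-map with the best-fit bounding trajectories (plus
#' intermediate fill trajectories between them) and the circle-scan outline;
#' and the cpRNFL plot with its normative bands and the
#' trajectory-determined bounds. Layout is deterministic for fixed inputs.
#'
#' @param x A [pmap()].
#' @param fit_upper,fit_lower [best_fit_phi0()] results bounding the
#'   arcuate.
#' @param profile Optional [cprnfl_profile()].
#' @param out PNG output path.
#' @param n_fill Number of intermediate fill trajectories. Default 4.
#' @param params A [bundle_params()].
#' @param width,height Device size in pixels.
#' @return `out`, invisibly.
#' @export
render_report <- function(x, fit_upper = NULL, fit_lower = NULL,
                          profile = NULL, out = "arcuate-report.png",
                          n_fill = 4, params = bundle_params(),
                          width = 1400, height = 600) {
  stopifnot(inherits(x, "pmap"))
  geo <- normalize_to_right_eye(x$geometry)$geometry
  have_fits <- !is.null(fit_upper) && !is.null(fit_lower)
  if (!have_fits) warning("missing fits: rendering partial report")

  grDevices::png(out, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))

  draw_pmap(x)
  draw_circle(x$geometry$bmo_center, x$geometry$r_c, col = "black", lty = 2)
  if (have_fits) {
    beta <- fit_upper$beta
    phis <- seq(fit_lower$phi0_best, fit_upper$phi0_best,
                length.out = n_fill + 2)
    mirror <- !isTRUE(x$geometry$normalized) &&
      identical(x$geometry$laterality, "OS")
    for (k in seq_along(phis)) {
      tr <- sample_trajectory(geo, phis[k], beta, params)
      poly <- tr$polyline
      if (mirror) poly <- mirror_points(poly)
      bound <- k == 1 || k == length(phis)
      graphics::lines(poly[, 1], poly[, 2],
                      col = if (bound) "blue" else "#7799ff",
                      lwd = if (bound) 2 else 1)
    }
  }

  if (!is.null(profile)) {
    q5 <- profile$norm_mean + stats::qnorm(0.05) * profile$norm_sd
    q1 <- profile$norm_mean + stats::qnorm(0.01) * profile$norm_sd
    graphics::plot(profile$positions, profile$norm_mean, type = "l",
                   col = "darkgreen", lty = 2, ylim = c(0, 130),
                   xlab = "TSNIT position (deg)", ylab = "thickness (um)",
                   main = "cpRNFL profile")
    graphics::polygon(c(profile$positions, rev(profile$positions)),
                      c(q5, rev(q1)), col = "#f5c54255", border = NA)
    graphics::polygon(c(profile$positions, rev(profile$positions)),
                      c(q1, rep(0, length(q1))), col = "#d6454155",
                      border = NA)
    graphics::lines(profile$positions, profile$thickness, lwd = 2)
    if (have_fits) {
      reg <- region_from_fits(fit_upper, fit_lower)
      graphics::abline(v = c(reg$start, reg$end), col = "blue", lwd = 2)
    }
  } else {
    graphics::plot.new()
    graphics::title("cpRNFL profile unavailable")
  }
  invisible(out)
}

#' Export a beta sweep as CSV or JSON
#'
#' One row/entry per grid beta with the best-fit angles (external
#' convention), clock hours, RMS, coverage and normalized percentile.
#'
#' @param sweep A `beta_sweep`.
#' @param path Output path; `.json` selects JSON, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  d <- as.data.frame(sweep)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(d, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows", na = "null")
  } else {
    utils::write.csv(d, path, row.names = FALSE)
  }
  invisible(path)
}
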