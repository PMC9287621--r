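# RNFL probability maps (p-maps) are rasters of percentile categories over a
# macula-centered field (~30 x 25 degrees). Category codes: 0 = normal,
# 1 = below the 5% normative percentile, 2 = below 1%, 255 = outside field.

PMAP_CODES <- c(normal = 0L, p5 = 1L, p1 = 2L, outside = 255L)

#' RNFL probability map
#'
#' A georeferenced raster of percentile categories. Row 1 is the superior
#' edge; pixel (i, j) has center `origin + ((j-1) * pixel_size,
#' -(i-1) * pixel_size)` in scan-frame degrees.
#'
#' @param grid Integer matrix with codes 0 (normal), 1 (p <= 5%), 2
#'   (p <= 1%), 255 (outside field).
#' @param pixel_size Pixel size in degrees per pixel (> 0).
#' @param origin Scan-frame coordinates `c(x, y)` of the center of pixel
#'   (1, 1) (top-left / superior-temporal corner for a right eye).
#' @param geometry A [scan_geometry()].
#' @return An object of class `pmap`.
#' @export
pmap <- function(grid, pixel_size, origin, geometry) {
  stopifnot(is.matrix(grid), pixel_size > 0, length(origin) == 2,
            inherits(geometry, "scan_geometry"))
  grid <- matrix(as.integer(grid), nrow = nrow(grid))
  bad <- setdiff(unique(as.vector(grid)), unname(PMAP_CODES))
  if (length(bad)) stop("unknown p-map category code(s): ",
                        paste(bad, collapse = ", "))
  structure(list(grid = grid, pixel_size = pixel_size,
                 origin = as.numeric(origin), geometry = geometry),
            class = "pmap")
}

#' @export
print.pmap <- function(x, ...) {
  tab <- table(factor(x$grid, levels = unname(PMAP_CODES),
                      labels = names(PMAP_CODES)))
  cat(sprintf("<pmap> %d x %d px at %.3g deg/px, origin (%.2f, %.2f)\n",
              nrow(x$grid), ncol(x$grid), x$pixel_size,
              x$origin[1], x$origin[2]))
  cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = "  "), "\n")
  invisible(x)
}

# scan-frame coordinates of every pixel center, as vectors aligned with
# column-major matrix order
pixel_centers <- function(x) {
  nr <- nrow(x$grid); nc <- ncol(x$grid)
  list(x = x$origin[1] + (rep(seq_len(nc), each = nr) - 1) * x$pixel_size,
       y = x$origin[2] - (rep(seq_len(nr), times = nc) - 1) * x$pixel_size)
}

# pixel (i, j) containing a scan-frame point, or NA if outside the raster
pixel_at <- function(x, p) {
  p <- as.numeric(as_xy(p))
  j <- round((p[1] - x$origin[1]) / x$pixel_size) + 1
  i <- round((x$origin[2] - p[2]) / x$pixel_size) + 1
  if (i < 1 || i > nrow(x$grid) || j < 1 || j > ncol(x$grid)) return(NULL)
  c(i = i, j = j)
}

# ---- binary masks ----------------------------------------------------------

#' Binary defect mask aligned with a p-map
#'
#' @param grid Integer 0/1 matrix.
#' @param pixel_size,origin,geometry Georeference, as in [pmap()].
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(grid, pixel_size, origin, geometry) {
  stopifnot(is.matrix(grid), all(grid %in% c(0L, 1L)))
  structure(list(grid = matrix(as.integer(grid), nrow = nrow(grid)),
                 pixel_size = pixel_size, origin = as.numeric(origin),
                 geometry = geometry),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %d foreground\n",
              nrow(x$grid), ncol(x$grid), sum(x$grid)))
  invisible(x)
}

# ---- p-map I/O -------------------------------------------------------------

#' Read / write a p-map raster with its JSON sidecar
#'
#' The raster is stored as a headerless CSV of integer category codes (or an
#' 8-bit single-channel PNG if `path` ends in `.png` and the png package is
#' available); the sidecar holds the geometry plus `pixel_size_deg` and
#' `origin_xy_deg`.
#'
#' @param path Raster file path (`.csv` or `.png`).
#' @param sidecar Sidecar JSON path; defaults to `paste0(path, ".json")`.
#' @return `read_pmap()` returns a [pmap()]; `write_pmap()` returns `path`
#'   invisibly.
#' @export
read_pmap <- function(path, sidecar = paste0(path, ".json")) {
  j <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  geometry <- scan_geometry(fovea = as.numeric(j$geometry$fovea_xy_deg),
                            bmo_center = as.numeric(j$geometry$bmo_center_xy_deg),
                            fd_angle = as.numeric(j$geometry$fd_angle_deg),
                            r_c = as.numeric(j$geometry$r_c_deg),
                            laterality = as.character(j$geometry$laterality))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("reading PNG p-maps requires the png package")
    }
    grid <- round(png::readPNG(path) * 255)
  } else {
    grid <- as.matrix(utils::read.csv(path, header = FALSE))
  }
  dimnames(grid) <- NULL
  pmap(grid, pixel_size = as.numeric(j$pixel_size_deg),
       origin = as.numeric(j$origin_xy_deg), geometry = geometry)
}

#' @rdname read_pmap
#' @param x A [pmap()].
#' @export
write_pmap <- function(x, path, sidecar = paste0(path, ".json")) {
  stopifnot(inherits(x, "pmap"))
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("writing PNG p-maps requires the png package")
    }
    png::writePNG(x$grid / 255, path)
  } else {
    utils::write.table(x$grid, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  g <- x$geometry
  jsonlite::write_json(
    list(geometry = list(fovea_xy_deg = g$fovea,
                         bmo_center_xy_deg = g$bmo_center,
                         fd_angle_deg = g$fd_angle,
                         r_c_deg = g$r_c,
                         laterality = g$laterality),
         pixel_size_deg = x$pixel_size,
         origin_xy_deg = x$origin),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
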