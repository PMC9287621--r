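# Arcuate border extraction: binarize the p-map at the 1% category, isolate
# the arcuate-shaped component, reduce it to its perimeter, and split the
# perimeter into an upper and a lower border curve in ONH-polar coordinates.

#' Binarize a p-map at the 1% category
#'
#' Pixels at or below the 1% normative percentile become 1, everything else
#' (normal, 5%-only, outside-field) becomes 0.
#'
#' @param x A [pmap()].
#' @return A [binary_mask()].
#' @export
binarize_pmap <- function(x) {
  stopifnot(inherits(x, "pmap"))
  binary_mask((x$grid == PMAP_CODES[["p1"]]) * 1L,
              x$pixel_size, x$origin, x$geometry)
}

# 8-connected component labels of a binary matrix, via a pixel adjacency
# graph (EBImage's labeling is 4-connected, which would split components
# joined only diagonally)
label_components_8 <- function(grid) {
  nr <- nrow(grid); nc <- ncol(grid)
  fg <- which(grid == 1L)
  labels <- matrix(0L, nr, nc)
  if (!length(fg)) return(labels)
  id <- matrix(0L, nr, nc)
  id[fg] <- seq_along(fg)
  i <- (fg - 1L) %% nr + 1L
  j <- (fg - 1L) %/% nr + 1L
  edges <- NULL
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    i2 <- i + off[1]; j2 <- j + off[2]
    ok <- i2 >= 1L & i2 <= nr & j2 >= 1L & j2 <= nc
    ok[ok] <- grid[cbind(i2[ok], j2[ok])] == 1L
    if (any(ok)) {
      edges <- rbind(edges,
                     cbind(id[fg[ok]], id[cbind(i2[ok], j2[ok])]))
    }
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges)) g <- igraph::add_edges(g, t(edges))
  labels[fg] <- igraph::components(g)$membership
  labels
}

# angular extent (degrees) of a point set about a center: 360 minus the
# largest circular gap between consecutive sorted angles
angular_extent <- function(phi) {
  if (length(phi) < 2) return(0)
  p <- sort(phi %% 360)
  gaps <- c(diff(p), 360 - (p[length(p)] - p[1]))
  360 - max(gaps)
}

#' Select the arcuate-shaped component of a defect mask
#'
#' Replaces manual curation of non-arcuate abnormal regions: with a seed
#' point, the 8-connected component containing the seed is kept; without,
#' the largest component whose angular extent about the BMO center exceeds
#' `min_extent_deg` is kept. All other pixels are zeroed. An arcuate that
#' leaves and re-enters the field of view appears as several fragments, so
#' defect pixels separated only by the scan-field boundary zone (`bridge`)
#' are treated as one component.
#'
#' @param mask A [binary_mask()].
#' @param seed Optional scan-frame point `c(x, y)` inside the wanted
#'   component.
#' @param min_extent_deg Minimum angular extent (degrees) about the BMO
#'   center for seedless selection. Default 20.
#' @param bridge Optional logical matrix marking the field-boundary zone
#'   through which fragments connect; defaults to the raster's outermost
#'   ring. Pass `FALSE` to disable bridging.
#' @return A [binary_mask()] containing a single component, with attribute
#'   `component_id`.
#' @export
select_arcuate_component <- function(mask, seed = NULL, min_extent_deg = 20,
                                     bridge = NULL) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$grid == 1L)) {
    abort_arcuate("mask contains no abnormal pixels", "no_arcuate")
  }
  if (is.null(bridge)) bridge <- field_boundary(mask$grid)
  if (isFALSE(bridge)) bridge <- matrix(FALSE, nrow(mask$grid), ncol(mask$grid))
  labels <- label_components_8((mask$grid == 1L | bridge) * 1L)
  labels[mask$grid != 1L] <- 0L  # bridge pixels join, but are not defect
  if (!is.null(seed)) {
    ij <- pixel_at(mask, seed)
    if (is.null(ij) || labels[ij[1], ij[2]] == 0L) {
      abort_arcuate("seed point is not inside an abnormal component",
                    "no_arcuate")
    }
    keep <- labels[ij[1], ij[2]]
  } else {
    cen <- pixel_centers(mask)
    dx <- cen$x - mask$geometry$bmo_center[1]
    dy <- cen$y - mask$geometry$bmo_center[2]
    phi <- wrap_phi(rad2deg(atan2(dy, dx)))  # pixel at the BMO center, if
    phi[dx == 0 & dy == 0] <- NA             # any, carries no direction
    ids <- sort(unique(labels[labels > 0L]))
    extents <- vapply(ids, function(k) {
      angular_extent(phi[labels == k & !is.na(phi)])
    }, numeric(1))
    sizes <- vapply(ids, function(k) sum(labels == k), numeric(1))
    ok <- extents > min_extent_deg
    if (!any(ok)) {
      abort_arcuate(
        sprintf("no component exceeds the %g-degree angular extent", min_extent_deg),
        "no_arcuate")
    }
    keep <- ids[ok][which.max(sizes[ok])]
  }
  out <- binary_mask((labels == keep) * 1L, mask$pixel_size, mask$origin,
                     mask$geometry)
  attr(out, "component_id") <- as.integer(keep)
  out
}

#' Reduce a component to its perimeter pixels
#'
#' Keeps foreground pixels with at least one 4-neighbor equal to 0 (raster
#' edges count as background); interior pixels are removed.
#'
#' @param mask A [binary_mask()].
#' @return A [binary_mask()] of perimeter pixels (attributes preserved).
#' @export
extract_perimeter <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  g <- mask$grid
  nr <- nrow(g); nc <- ncol(g)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- g
  inner <- pad[1:nr, 2:(nc + 1)] & pad[3:(nr + 2), 2:(nc + 1)] &
    pad[2:(nr + 1), 1:nc] & pad[2:(nr + 1), 3:(nc + 2)]
  out <- binary_mask((g == 1L & !inner) * 1L, mask$pixel_size, mask$origin,
                     mask$geometry)
  attr(out, "component_id") <- attr(mask, "component_id")
  out
}

#' One border curve of an arcuate defect
#'
#' Polar points about the BMO center (scan frame), one per radial bin.
#'
#' @param points Data frame with columns `r` (degrees) and `phi` (degrees,
#'   wrapped to (-180, 180]).
#' @param side `"upper"` or `"lower"` (the maximum- / minimum-phi side on
#'   the hemifield's unwrapped branch).
#' @param hemifield `"superior"` or `"inferior"`.
#' @param geometry The [scan_geometry()] the points refer to.
#' @param source_component_id Integer id of the originating component.
#' @param bin_width Radial bin width (degrees) used to build the border.
#' @return An object of class `arcuate_border`.
#' @export
arcuate_border <- function(points, side, hemifield, geometry,
                           source_component_id = 1L, bin_width = 0.25) {
  stopifnot(is.data.frame(points), all(c("r", "phi") %in% names(points)),
            side %in% c("upper", "lower"),
            hemifield %in% c("superior", "inferior"),
            inherits(geometry, "scan_geometry"))
  if (nrow(points) < 5) {
    abort_arcuate("an arcuate border needs at least 5 points",
                  "degenerate_border")
  }
  if (any(points$r <= 0)) stop("border radii must be positive")
  points$phi <- wrap_phi(points$phi)
  structure(list(points = points[order(points$r), , drop = FALSE],
                 side = side, hemifield = hemifield, geometry = geometry,
                 source_component_id = as.integer(source_component_id),
                 bin_width = bin_width),
            class = "arcuate_border")
}

#' @export
print.arcuate_border <- function(x, ...) {
  cat(sprintf("<arcuate_border> %s %s: %d points, r %.2f..%.2f deg\n",
              x$hemifield, x$side, nrow(x$points),
              min(x$points$r), max(x$points$r)))
  invisible(x)
}

# mirror a left-eye p-map into the right-eye frame (flip columns, mirror
# the origin and geometry)
mirror_pmap <- function(x) {
  nc <- ncol(x$grid)
  geometry <- normalize_to_right_eye(x$geometry)$geometry
  pmap(x$grid[, rev(seq_len(nc)), drop = FALSE], x$pixel_size,
       c(-(x$origin[1] + (nc - 1) * x$pixel_size), x$origin[2]), geometry)
}

# 8-neighborhood dilation of a logical matrix
dilate8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  out <- matrix(FALSE, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    out <- out | pad[(2 + di):(nr + 1 + di), (2 + dj):(nc + 1 + dj)]
  }
  out
}

# pixels on the scan-field boundary: the raster's outermost ring plus
# anything 8-adjacent to an outside-field pixel
field_boundary <- function(grid) {
  nr <- nrow(grid); nc <- ncol(grid)
  e <- matrix(FALSE, nr, nc)
  e[c(1, nr), ] <- TRUE
  e[, c(1, nc)] <- TRUE
  out <- grid == PMAP_CODES[["outside"]]
  if (any(out)) e <- e | dilate8(out)
  e
}

#' Split a perimeter into upper and lower arcuate borders
#'
#' Perimeter pixels are converted to ONH-polar coordinates about the BMO
#' center and classified by where the defect interior lies relative to
#' them: for each perimeter pixel the offsets to its 8-neighbors inside the
#' component are summed as a radial part (delta r) and an angular arc part
#' (r delta phi, on the hemifield's unwrapped branch). A pixel whose
#' interior offset is predominantly angular bounds the defect in angle --
#' interior at larger phi means the pixel is on the lower border, interior
#' at smaller phi the upper border. Pixels with a predominantly radial
#' interior offset (the circle-scan arc, radial end caps) are not borders
#' and are dropped, as are pixels on or adjacent to the scan-field boundary
#' (`exclude`), where the defect is cut off by the field of view rather
#' than bounded by a fiber bundle. Finally each radial bin (`bin_width`)
#' contributes at most one point per side: the maximum-phi upper-labeled
#' pixel and the minimum-phi lower-labeled pixel.
#'
#' @param perimeter A single-component perimeter [binary_mask()].
#' @param geometry A [scan_geometry()] (defaults to the mask's).
#' @param bin_width Radial bin width in degrees; keep equal to the fitting
#'   bin width. Default 0.25.
#' @param params A [bundle_params()] (used to locate the fovea-latitude line
#'   that defines the hemifield).
#' @param exclude Optional logical matrix (same shape) marking field-boundary
#'   pixels; defaults to the raster's outermost ring.
#' @param component Optional [binary_mask()] of the filled component the
#'   perimeter came from; defaults to the perimeter itself (adequate for
#'   thin components, but the filled mask gives more reliable interior
#'   directions).
#' @return List with elements `upper` and `lower`, both [arcuate_border()]s.
#' @export
split_borders <- function(perimeter, geometry = perimeter$geometry,
                          bin_width = 0.25, params = bundle_params(),
                          exclude = NULL, component = NULL) {
  stopifnot(inherits(perimeter, "binary_mask"))
  if (is.null(exclude)) exclude <- field_boundary(perimeter$grid)
  stopifnot(identical(dim(exclude), dim(perimeter$grid)))
  comp_grid <- if (is.null(component)) perimeter$grid else component$grid
  stopifnot(identical(dim(comp_grid), dim(perimeter$grid)))

  nr <- nrow(perimeter$grid); nc <- ncol(perimeter$grid)
  cen <- pixel_centers(perimeter)
  X <- matrix(cen$x, nr, nc); Y <- matrix(cen$y, nr, nc)
  DX <- X - geometry$bmo_center[1]; DY <- Y - geometry$bmo_center[2]
  R <- sqrt(DX^2 + DY^2)
  fg_all <- which(perimeter$grid == 1L)
  if (!length(fg_all)) abort_arcuate("empty perimeter", "degenerate_border")
  y_model <- scan_to_model(cbind(X[fg_all], Y[fg_all]), geometry, params)[, 2]
  hemifield <- if (mean(y_model > 0) >= 0.5) "superior" else "inferior"
  U <- matrix(unwrap_hemifield(wrap_phi(rad2deg(atan2(DY, DX))), hemifield),
              nr, nc)
  U[R == 0] <- NA

  # interior-offset sums over 8-neighbors inside the component
  shift <- function(m, di, dj, fill = 0) {
    out <- matrix(fill, nr, nc)
    si <- max(1, 1 + di):min(nr, nr + di)
    sj <- max(1, 1 + dj):min(nc, nc + dj)
    out[si, sj] <- m[si - di, sj - dj]
    out
  }
  sum_dr <- sum_da <- matrix(0, nr, nc)
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    Cn <- shift(comp_grid, di, dj)
    sum_dr <- sum_dr + Cn * (shift(R, di, dj) - R)
    sum_da <- sum_da + Cn * R * deg2rad(shift(U, di, dj) - U)
  }

  near_edge <- dilate8(exclude)
  eligible <- perimeter$grid == 1L & !exclude & !near_edge
  angular <- abs(sum_da) > abs(sum_dr)
  lab <- matrix(NA_character_, nr, nc)
  lab[eligible & angular & sum_da > 0] <- "lower"
  lab[eligible & angular & sum_da < 0] <- "upper"

  hi <- which(lab == "upper")
  lo <- which(lab == "lower")
  if (length(unique(floor(R[hi] / bin_width))) < 5 ||
      length(unique(floor(R[lo] / bin_width))) < 5) {
    abort_arcuate("fewer than 5 usable radial bins in the perimeter",
                  "degenerate_border")
  }

  # sub-pixel refinement: a chosen pixel center sits on average half a pixel
  # inside the true boundary, so shift it half a pixel along the outward
  # boundary normal (the opposite of the interior-offset direction)
  refine <- function(idx) {
    n <- sqrt(sum_dr[idx]^2 + sum_da[idx]^2)
    n[n == 0] <- 1
    r_new <- R[idx] - 0.5 * perimeter$pixel_size * sum_dr[idx] / n
    u_new <- U[idx] -
      rad2deg(0.5 * perimeter$pixel_size * (sum_da[idx] / n) / R[idx])
    data.frame(r = r_new, phi = wrap_phi(u_new))
  }
  cid <- attr(perimeter, "component_id")
  if (is.null(cid)) cid <- 1L
  list(upper = arcuate_border(refine(hi), "upper", hemifield, geometry,
                              cid, bin_width),
       lower = arcuate_border(refine(lo), "lower", hemifield, geometry,
                              cid, bin_width))
}

#' Run the full border-extraction pipeline on a p-map
#'
#' Binarize at the 1% category, optionally restrict to one hemifield
#' (relative to the rotated fovea-latitude line), select the arcuate
#' component, reduce it to its perimeter, and split it into the two border
#' curves.
#'
#' @param x A [pmap()].
#' @param seed Optional seed point for component selection.
#' @param hemifield Optional `"superior"` / `"inferior"` restriction.
#' @param min_extent_deg Passed to [select_arcuate_component()].
#' @param bin_width Radial bin width for border splitting (degrees).
#' @param params A [bundle_params()].
#' @return List with `upper`, `lower` ([arcuate_border()]s), `component` and
#'   `perimeter` ([binary_mask()]s).
#' @export
extract_arcuate_borders <- function(x, seed = NULL, hemifield = NULL,
                                    min_extent_deg = 20, bin_width = 0.25,
                                    params = bundle_params()) {
  if (identical(x$geometry$laterality, "OS") &&
      !isTRUE(x$geometry$normalized)) {
    x <- mirror_pmap(x)
    if (!is.null(seed)) seed <- as.numeric(mirror_points(seed))
  }
  mask <- binarize_pmap(x)
  if (!is.null(hemifield)) {
    hemifield <- match.arg(hemifield, c("superior", "inferior"))
    cen <- pixel_centers(mask)
    y_model <- scan_to_model(cbind(cen$x, cen$y), x$geometry, params)[, 2]
    want <- if (hemifield == "superior") y_model > 0 else y_model < 0
    mask$grid <- mask$grid * matrix(want * 1L, nrow(mask$grid))
  }
  comp <- select_arcuate_component(mask, seed = seed,
                                   min_extent_deg = min_extent_deg)
  per <- extract_perimeter(comp)
  borders <- split_borders(per, x$geometry, bin_width = bin_width,
                           params = params, exclude = field_boundary(x$grid),
                           component = comp)
  c(borders, list(component = comp, perimeter = per))
}

# ---- border I/O ------------------------------------------------------------

#' Read / write arcuate borders as CSV
#'
#' Columns: `r_deg`, `phi_deg`, `side`. Both borders of one arcuate go in
#' one file.
#'
#' @param path CSV file path.
#' @param geometry A [scan_geometry()] for the read borders.
#' @param hemifield Hemifield of the stored borders.
#' @return `read_arcuate_borders()` returns a list with `upper` and `lower`;
#'   `write_arcuate_borders()` returns `path` invisibly.
#' @export
read_arcuate_borders <- function(path, geometry, hemifield) {
  d <- utils::read.csv(path)
  out <- lapply(c(upper = "upper", lower = "lower"), function(s) {
    sub <- d[d$side == s, , drop = FALSE]
    arcuate_border(data.frame(r = sub$r_deg, phi = sub$phi_deg),
                   s, hemifield, geometry)
  })
  out
}

#' @rdname read_arcuate_borders
#' @param borders List with elements `upper` and `lower`.
#' @export
write_arcuate_borders <- function(borders, path) {
  rows <- do.call(rbind, lapply(c("upper", "lower"), function(s) {
    b <- borders[[s]]
    data.frame(r_deg = b$points$r, phi_deg = b$points$phi, side = s)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
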