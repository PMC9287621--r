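# Circumpapillary RNFL (cpRNFL) thickness profiles in TSNIT order
# (temporal-superior-nasal-inferior-temporal), with per-position normative
# mean and SD. Percentile categories follow a per-position Gaussian
# normative model: below the 1% / 5% quantile of N(mean, sd).

#' Circumpapillary RNFL profile
#'
#' @param positions TSNIT positions in degrees, equally spaced, covering
#'   \[0, 360) with a spacing that divides 360.
#' @param thickness Measured thickness in micrometers, one per position.
#' @param norm_mean,norm_sd Normative mean and standard deviation in
#'   micrometers, one per position; `norm_sd` must be positive.
#' @return An object of class `cprnfl_profile`.
#' @export
cprnfl_profile <- function(positions, thickness, norm_mean, norm_sd) {
  n <- length(positions)
  stopifnot(n > 1, length(thickness) == n, length(norm_mean) == n,
            length(norm_sd) == n)
  if (any(norm_sd <= 0)) stop("norm_sd must be positive everywhere")
  sp <- unique(round(diff(positions), 9))
  if (length(sp) != 1 || sp <= 0 || round(360 / sp, 9) %% 1 != 0) {
    stop("positions must be equally spaced with a spacing dividing 360")
  }
  if (abs(positions[1]) > 1e-9 || n * sp != 360) {
    stop("positions must start at 0 and cover [0, 360)")
  }
  structure(list(positions = as.numeric(positions),
                 thickness = as.numeric(thickness),
                 norm_mean = as.numeric(norm_mean),
                 norm_sd = as.numeric(norm_sd),
                 spacing = sp),
            class = "cprnfl_profile")
}

#' @export
print.cprnfl_profile <- function(x, ...) {
  cls <- classify_percentile(x)
  cat(sprintf(
    "<cprnfl_profile> %d positions at %.2f deg; %d below 5%%, %d below 1%%\n",
    length(x$positions), x$spacing, sum(cls != "normal"), sum(cls == "p1")))
  invisible(x)
}

#' Classify cpRNFL positions against the normative distribution
#'
#' Per position: `"p1"` if thickness falls below the 1% quantile of the
#' normative Gaussian, else `"p5"` if below the 5% quantile, else
#' `"normal"`.
#'
#' @param profile A [cprnfl_profile()].
#' @return Character vector, one category per position.
#' @export
classify_percentile <- function(profile) {
  stopifnot(inherits(profile, "cprnfl_profile"))
  q1 <- profile$norm_mean + stats::qnorm(0.01) * profile$norm_sd
  q5 <- profile$norm_mean + stats::qnorm(0.05) * profile$norm_sd
  ifelse(profile$thickness < q1, "p1",
         ifelse(profile$thickness < q5, "p5", "normal"))
}

#' Angular region on the TSNIT circle
#'
#' A wrap-aware arc from `start` to `end` in increasing TSNIT degrees.
#'
#' @param start,end TSNIT positions in degrees (\[0, 360)).
#' @param hemifield Optional hemifield label carried along.
#' @return An object of class `angular_region`.
#' @export
angular_region <- function(start, end, hemifield = NULL) {
  start <- start %% 360; end <- end %% 360
  len <- (end - start) %% 360
  if (len == 0) {
    abort_arcuate("angular region is degenerate (zero arc length)",
                  "degenerate_region")
  }
  structure(list(start = start, end = end, length = len,
                 hemifield = hemifield),
            class = "angular_region")
}

#' @export
print.angular_region <- function(x, ...) {
  cat(sprintf("<angular_region> TSNIT %.2f..%.2f deg (%.2f deg arc)%s\n",
              x$start, x$end, x$length,
              if (is.null(x$hemifield)) "" else paste0(", ", x$hemifield)))
  invisible(x)
}

#' Trajectory-determined region from two border fits
#'
#' Maps the two best-fit initial angles of one arcuate's borders onto the
#' TSNIT circle and returns the arc between them that lies within the
#' arcuate's hemifield (the complementary arc through the opposite
#' hemifield is anatomically meaningless).
#'
#' @param fit_upper,fit_lower [best_fit_phi0()] results for the same
#'   arcuate's two borders.
#' @return An [angular_region()].
#' @export
region_from_fits <- function(fit_upper, fit_lower) {
  stopifnot(inherits(fit_upper, "fit_result"), inherits(fit_lower, "fit_result"))
  if (!identical(fit_upper$hemifield, fit_lower$hemifield)) {
    stop("the two fits belong to different hemifields")
  }
  t1 <- tsnit_from_phi(wrap_phi(fit_upper$phi0_best))
  t2 <- tsnit_from_phi(wrap_phi(fit_lower$phi0_best))
  if (t1 == t2) {
    abort_arcuate("coincident bounds give a degenerate region",
                  "degenerate_region")
  }
  # superior phi0 in [60, 180] maps to TSNIT [0, 120]; inferior internal
  # (-180, -60] maps to (240, 360]; within one hemifield min..max is the
  # hemifield-interior arc
  angular_region(min(t1, t2), max(t1, t2), fit_upper$hemifield)
}

# logical mask of profile positions lying on the arc (inclusive bounds)
positions_in_region <- function(profile, region) {
  p <- profile$positions
  if (region$start <= region$end) {
    p >= region$start & p <= region$end
  } else {
    p >= region$start | p <= region$end
  }
}

#' Fraction of a cpRNFL region below a normative threshold
#'
#' Angular fraction of the region's profile positions whose thickness falls
#' at or below the given percentile level; positions are weighted equally.
#'
#' @param profile A [cprnfl_profile()].
#' @param region An [angular_region()].
#' @param level Percentile level, `5` or `1`.
#' @return Fraction in \[0, 1\].
#' @export
fraction_below <- function(profile, region, level = 5) {
  stopifnot(inherits(profile, "cprnfl_profile"),
            inherits(region, "angular_region"))
  if (!level %in% c(5, 1)) stop("level must be 5 or 1")
  inside <- positions_in_region(profile, region)
  if (!any(inside)) stop("region contains no profile positions")
  cls <- classify_percentile(profile)[inside]
  bad <- if (level == 5) cls %in% c("p5", "p1") else cls == "p1"
  mean(bad)
}

# ---- profile I/O -----------------------------------------------------------

#' Read / write a cpRNFL profile as CSV
#'
#' Columns: `tsnit_deg`, `thickness_um`, `norm_mean_um`, `norm_sd_um`.
#'
#' @param path CSV file path.
#' @return `read_cprnfl_profile()` returns a [cprnfl_profile()];
#'   `write_cprnfl_profile()` returns `path` invisibly.
#' @export
read_cprnfl_profile <- function(path) {
  d <- utils::read.csv(path)
  cprnfl_profile(d$tsnit_deg, d$thickness_um, d$norm_mean_um, d$norm_sd_um)
}

#' @rdname read_cprnfl_profile
#' @param profile A [cprnfl_profile()].
#' @export
write_cprnfl_profile <- function(profile, path) {
  utils::write.csv(
    data.frame(tsnit_deg = profile$positions,
               thickness_um = profile$thickness,
               norm_mean_um = profile$norm_mean,
               norm_sd_um = profile$norm_sd),
    path, row.names = FALSE)
  invisible(path)
}
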