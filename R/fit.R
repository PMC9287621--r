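# Fitting trajectories to arcuate borders. Border points and trajectory
# samples are assigned to radial bins about the BMO center; per bin the
# angular positions (unwrapped onto the hemifield branch) are averaged and
# differenced, and the fit quality is the RMS of those per-bin differences.
# For each beta on the 11-point grid the initial angle phi0 is found by
# exhaustive search in 0.25-degree steps over 60..180 (superior) or
# 180..300 (inferior, internally (-180, -60]); nasal starts are excluded.

#' RMS angular difference between a border and a trajectory
#'
#' Both point sets are binned by radius about the BMO center (bin k covers
#' \[k w, (k+1) w)). Per bin present in both, the difference is between the
#' border's mean angle and the trajectory's mean angle on the hemifield's
#' unwrapped branch; the statistic is the root mean square over matched
#' bins. Bins beyond the trajectory's clipping point are unmatched and
#' excluded; `coverage` reports the matched fraction of border bins.
#'
#' @param border An [arcuate_border()].
#' @param trajectory A [sample_trajectory()] result in the same frame.
#' @param bin_width Radial bin width in degrees (defaults to the border's).
#' @return List with `rms` (degrees), `n_bins` (matched bins) and
#'   `coverage` (matched / border bins).
#' @export
rms_difference <- function(border, trajectory, bin_width = border$bin_width) {
  stopifnot(inherits(border, "arcuate_border"),
            inherits(trajectory, "trajectory"), bin_width > 0)
  u_b <- unwrap_hemifield(border$points$phi, border$hemifield)
  bin_b <- floor(border$points$r / bin_width)
  mean_b <- tapply(u_b, bin_b, mean)

  bin_t <- floor(trajectory$r / bin_width)
  mean_t <- tapply(trajectory$phi_scan, bin_t, mean)

  matched <- intersect(names(mean_b), names(mean_t))
  if (!length(matched)) {
    abort_arcuate("no radial bins shared by border and trajectory",
                  "no_overlap")
  }
  d <- mean_t[matched] - mean_b[matched]
  list(rms = sqrt(mean(d^2)), n_bins = length(matched),
       coverage = length(matched) / length(mean_b))
}

# Candidate initial angles for a hemifield (internal convention). The
# inferior external range (180, 300] maps to (-180, -60].
phi0_candidates <- function(hemifield, step = 0.25) {
  if (hemifield == "superior") seq(60, 180, by = step)
  else seq(-180 + step, -60, by = step)
}

#' Best-fitting initial angle for one beta
#'
#' Exhaustive scan of phi0 in `phi0_step` increments over the border's
#' hemifield range, minimizing [rms_difference()] against the model
#' trajectory; ties break toward the smaller phi0. The scan is evaluated
#' analytically on the common radial sampling grid, which is exactly
#' equivalent to tracing each candidate trajectory and calling
#' [rms_difference()].
#'
#' @param border An [arcuate_border()].
#' @param beta Curvature parameter for the border's hemifield.
#' @param geometry A [scan_geometry()] (defaults to the border's).
#' @param params A [bundle_params()].
#' @param phi0_step Search step in degrees. Default 0.25.
#' @param bin_width Radial bin width in degrees (defaults to the border's).
#' @return An object of class `fit_result`: `beta`, `phi0_best` (internal),
#'   `phi0_best_external`, `theta_c_best` (clock hours), `rms`,
#'   `n_bins_used`, `coverage`, `hemifield`, `low_coverage`.
#' @export
best_fit_phi0 <- function(border, beta, geometry = border$geometry,
                          params = bundle_params(), phi0_step = 0.25,
                          bin_width = border$bin_width) {
  stopifnot(inherits(border, "arcuate_border"))
  hemifield <- border$hemifield
  check_beta(beta, hemifield, params)
  cand <- phi0_candidates(hemifield, phi0_step)

  # border in the model frame (radii about the ONH are preserved by the
  # rigid model-to-scan map; angles shift by the relative FD angle)
  pts <- cart_from_onh_polar(border$points$r, border$points$phi,
                             geometry$bmo_center)
  pol <- onh_polar_from_cart(scan_to_model(pts, geometry, params),
                             params$onh_assumed)
  u_b <- unwrap_hemifield(pol$phi, hemifield)
  # bin by the stored radii: the rigid scan-to-model map preserves radii
  # about the ONH, and re-deriving them numerically could shift a border
  # point across a bin edge
  bin_b <- floor(border$points$r / bin_width)
  mean_b <- tapply(u_b, bin_b, mean)
  bins_b <- names(mean_b)
  mean_b <- as.vector(mean_b)

  r_c <- geometry$r_c
  if (r_c >= params$r_max) stop("r_c must be smaller than r_max")
  rr <- seq(r_c, params$r_max, by = params$r_step)
  A <- rr - r_c
  if (hemifield == "superior") {
    cc <- 1.9 + 1.4 * tanh((cand - 121) / 14)
    bb <- exp(beta + 3.9 * tanh(-(cand - 121) / 14))
  } else {
    cc <- 1.0 + 0.5 * tanh((-cand - 90) / 25)
    bb <- -exp(beta + 1.5 * tanh(-(-cand - 90) / 25))
  }
  PHI <- sweep(outer(A, cc, `^`), 2, bb, `*`)
  PHI <- sweep(PHI, 2, cand, `+`)
  Y <- params$onh_assumed[2] + rr * sin(deg2rad(PHI))
  # truncate each candidate at its first crossing of the fovea-latitude line
  OK <- sweep(Y, 2, sign(Y[1, ]), `*`) > 0
  V <- apply(OK, 2, cumprod)

  bin_r <- floor(rr / bin_width)
  SW <- rowsum(PHI * V, bin_r)
  NW <- rowsum(V, bin_r)
  idx <- match(bins_b, rownames(SW))
  D <- SW[idx, , drop = FALSE] / NW[idx, , drop = FALSE] - mean_b
  D[NW[idx, , drop = FALSE] == 0] <- NA
  n_j <- colSums(!is.na(D))
  rms_j <- sqrt(colSums(D^2, na.rm = TRUE) / n_j)
  rms_j[n_j == 0] <- Inf
  if (all(n_j == 0)) {
    abort_arcuate("no phi0 candidate overlaps the border radially",
                  "fit_failure")
  }
  j <- which.min(rms_j)
  coverage <- n_j[[j]] / length(mean_b)
  structure(list(beta = beta, phi0_best = cand[j],
                 phi0_best_external = phi0_external(cand[j]),
                 theta_c_best = clock_hour_from_phi(wrap_phi(cand[j])),
                 rms = rms_j[[j]], n_bins_used = n_j[[j]],
                 coverage = coverage, hemifield = hemifield,
                 low_coverage = coverage < 0.5),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf(
    "<fit_result> beta = %.2f: phi0 = %.2f deg (theta_c %.2f), rms = %.4g deg, coverage %.0f%%%s\n",
    x$beta, x$phi0_best_external, x$theta_c_best, x$rms, 100 * x$coverage,
    if (x$low_coverage) " [low]" else ""))
  invisible(x)
}

#' Normalize RMS values across a beta grid
#'
#' Converts the 11 per-beta RMS values of one arcuate to z-scores (sample
#' standard deviation, n - 1) and then to percentiles via the standard
#' normal CDF. If the standard deviation is zero, all percentiles are 50.
#'
#' @param rms_values Numeric vector (NA allowed for failed fits).
#' @return Percentiles in \[0, 100\] (NA where input is NA).
#' @export
#' @examples
#' normalize_rms(1:11)
normalize_rms <- function(rms_values) {
  m <- mean(rms_values, na.rm = TRUE)
  s <- stats::sd(rms_values, na.rm = TRUE)
  if (is.na(s) || s == 0) {
    return(ifelse(is.na(rms_values), NA_real_, 50))
  }
  100 * stats::pnorm((rms_values - m) / s)
}

sweep_skeleton <- function(hemifield) {
  list(region = hemifield, betas = beta_grid(hemifield))
}

#' Sweep the beta grid for one border
#'
#' Runs [best_fit_phi0()] for each of the 11 grid beta values of the
#' border's hemifield, then attaches normalized percentiles via
#' [normalize_rms()]. A fit failure at one beta yields NA there; the sweep
#' fails only if all 11 fail.
#'
#' @inheritParams best_fit_phi0
#' @return An object of class `beta_sweep`: `region`, `betas` (11 values in
#'   grid order), `results` (list of [best_fit_phi0()] results or NULL),
#'   `rms`, `normalized`.
#' @export
sweep_betas <- function(border, geometry = border$geometry,
                        params = bundle_params(), phi0_step = 0.25,
                        bin_width = border$bin_width) {
  sk <- sweep_skeleton(border$hemifield)
  results <- lapply(sk$betas, function(b) {
    tryCatch(best_fit_phi0(border, b, geometry, params, phi0_step, bin_width),
             fit_failure = function(e) NULL,
             no_overlap = function(e) NULL)
  })
  rms <- vapply(results, function(f) if (is.null(f)) NA_real_ else f$rms,
                numeric(1))
  if (all(is.na(rms))) {
    abort_arcuate("all beta values failed to fit the border", "fit_failure")
  }
  structure(list(region = sk$region, betas = sk$betas, results = results,
                 rms = rms, normalized = normalize_rms(rms)),
            class = "beta_sweep")
}

#' Sweep the beta grid for one arcuate (both borders pooled)
#'
#' One arcuate contributes one normalized-RMS curve: per beta, each border
#' gets its own best-fit phi0, and the two fits are pooled as the RMS over
#' all matched bins of both borders.
#'
#' @param upper,lower The arcuate's two [arcuate_border()]s.
#' @inheritParams best_fit_phi0
#' @return A `beta_sweep` whose `results` element holds per-beta lists with
#'   `upper` and `lower` [best_fit_phi0()] fits.
#' @export
arcuate_sweep <- function(upper, lower, geometry = upper$geometry,
                          params = bundle_params(), phi0_step = 0.25,
                          bin_width = upper$bin_width) {
  stopifnot(identical(upper$hemifield, lower$hemifield))
  sk <- sweep_skeleton(upper$hemifield)
  results <- lapply(sk$betas, function(b) {
    fits <- lapply(list(upper = upper, lower = lower), function(bd) {
      tryCatch(best_fit_phi0(bd, b, geometry, params, phi0_step, bin_width),
               fit_failure = function(e) NULL,
               no_overlap = function(e) NULL)
    })
    fits
  })
  rms <- vapply(results, function(fits) {
    ok <- !vapply(fits, is.null, logical(1))
    if (!any(ok)) return(NA_real_)
    n <- vapply(fits[ok], `[[`, numeric(1), "n_bins_used")
    r <- vapply(fits[ok], `[[`, numeric(1), "rms")
    sqrt(sum(n * r^2) / sum(n))
  }, numeric(1))
  if (all(is.na(rms))) {
    abort_arcuate("all beta values failed to fit the arcuate", "fit_failure")
  }
  structure(list(region = sk$region, betas = sk$betas, results = results,
                 rms = rms, normalized = normalize_rms(rms)),
            class = "beta_sweep")
}

#' @export
print.beta_sweep <- function(x, ...) {
  j <- which.min(x$normalized)
  cat(sprintf(
    "<beta_sweep> %s: 11 beta values, normalized-RMS minimum at beta = %.2f\n",
    x$region, x$betas[j]))
  invisible(x)
}

#' @export
as.data.frame.beta_sweep <- function(x, ...) {
  one <- function(f, suffix = "") {
    if (is.null(f)) {
      out <- data.frame(phi0_best = NA_real_, theta_c_best = NA_real_,
                        rms = NA_real_, coverage = NA_real_)
    } else {
      out <- data.frame(phi0_best = f$phi0_best_external,
                        theta_c_best = f$theta_c_best,
                        rms = f$rms, coverage = f$coverage)
    }
    names(out) <- paste0(names(out), suffix)
    out
  }
  rows <- lapply(seq_along(x$betas), function(i) {
    f <- x$results[[i]]
    d <- if (is.list(f) && !inherits(f, "fit_result")) {
      cbind(one(f$upper, "_upper"), one(f$lower, "_lower"))
    } else {
      one(f)
    }
    cbind(data.frame(beta = x$betas[i]), d,
          data.frame(rms_pooled = x$rms[i], normalized = x$normalized[i]))
  })
  do.call(rbind, rows)
}

#' Cohort percentile summary of normalized RMS curves
#'
#' For each grid beta, empirical percentiles of the normalized values across
#' arcuates (linear-interpolation quantiles, `stats::quantile` type 7).
#'
#' @param sweeps List of `beta_sweep`s of one region.
#' @param probs Percentile probabilities. Default `c(0.025, 0.5, 0.975)`.
#' @return Data frame with `beta` plus one column per percentile
#'   (`p2.5`, `p50`, `p97.5` for the defaults).
#' @export
cohort_percentile_summary <- function(sweeps, probs = c(0.025, 0.5, 0.975)) {
  if (!length(sweeps)) stop("no sweeps supplied")
  region <- unique(vapply(sweeps, `[[`, character(1), "region"))
  if (length(region) != 1) stop("sweeps mix superior and inferior arcuates")
  M <- do.call(rbind, lapply(sweeps, `[[`, "normalized"))
  Q <- apply(M, 2, stats::quantile, probs = probs, na.rm = TRUE, type = 7)
  out <- data.frame(beta = sweeps[[1]]$betas, t(Q))
  names(out) <- c("beta", paste0("p", format(100 * probs)))
  names(out) <- gsub(" ", "", names(out))
  rownames(out) <- NULL
  out
}

#' Ideal border from a trajectory's own samples
#'
#' Builds an [arcuate_border()] whose points are the per-bin means of a
#' traced trajectory -- the noise-free border an exact extraction would
#' recover. Used for self-recovery checks and simulation truth records.
#'
#' @param trajectory A [sample_trajectory()] result (superior or inferior).
#' @param side `"upper"` or `"lower"`.
#' @param bin_width Radial bin width in degrees. Default 0.25.
#' @return An [arcuate_border()].
#' @export
border_from_trajectory <- function(trajectory, side, bin_width = 0.25) {
  stopifnot(inherits(trajectory, "trajectory"))
  if (trajectory$region == "nasal") {
    stop("nasal rays do not bound arcuate defects")
  }
  bin <- floor(trajectory$r / bin_width)
  r <- as.numeric(tapply(trajectory$r, bin, mean))
  phi <- as.numeric(tapply(trajectory$phi_scan, bin, mean))
  arcuate_border(data.frame(r = r, phi = wrap_phi(phi)), side,
                 trajectory$region, trajectory$geometry,
                 bin_width = bin_width)
}
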