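#' Select the mid focal plane carrying the most probe signal
#'
#' The radial assay is performed on one optical section toward the middle of
#' the nucleus containing the largest amount of paint signal. The search is
#' restricted to a central window of the z-range; ties are broken toward the
#' window centre, then toward the lower index.
#'
#' @param probe_mask logical 3D array or `binary_mask3d`.
#' @param z_window central fraction of the stack searched (default 1/3).
#' @return 1-based z index of the selected plane.
#' @export
select_midplane <- function(probe_mask, z_window = 1 / 3) {
  m <- if (inherits(probe_mask, "binary_mask3d")) probe_mask$voxels else probe_mask
  nz <- dim(m)[1]
  counts <- rowSums(matrix(m, nrow = nz))
  centre <- (nz + 1) / 2
  half <- z_window * nz / 2
  win <- which(abs(seq_len(nz) - centre) <= half)
  if (length(win) == 0L) win <- as.integer(round(centre))
  cw <- counts[win]
  if (all(cw == 0)) stop("no-signal error: probe mask empty in the central window")
  best <- win[cw == max(cw)]
  best[order(abs(best - centre), best)][1]
}

#' Shape eligibility of a nuclear plane mask
#'
#' The radial assay is restricted to nuclei that are spherical or ellipsoid
#' shaped. This operationalizes that rule on the largest connected component
#' of the mid-plane nuclear mask: the minor/major axis ratio must reach
#' `axis_ratio` and the solidity (pixel area over convex-hull area) must
#' reach `solidity`.
#'
#' @param plane_mask logical 2D matrix (non-empty).
#' @param limits list with `axis_ratio` (default 0.5) and `solidity`
#'   (default 0.85) minima.
#' @return list(eligible, metrics = c(axis_ratio, solidity)).
#' @export
check_eligibility <- function(plane_mask, limits = list()) {
  lim <- utils::modifyList(list(axis_ratio = 0.5, solidity = 0.85), limits)
  if (!any(plane_mask)) stop("empty nuclear plane mask")
  comp <- largest_component_2d(plane_mask)
  pts <- which(comp, arr.ind = TRUE)          # columns: row (y), col (x)
  n <- nrow(pts)
  cv <- stats::cov(pts) * (n - 1) / n + diag(1 / 12, 2)  # + pixel variance
  ev <- eigen(cv, symmetric = TRUE)$values
  ar <- sqrt(max(ev[2], 0) / ev[1])
  sol <- n / convex_hull_pixel_area(pts)
  list(eligible = (ar >= lim$axis_ratio) && (sol >= lim$solidity),
       metrics = c(axis_ratio = ar, solidity = min(sol, 1)))
}

largest_component_2d <- function(plane_mask) {
  m3 <- array(plane_mask, dim = c(1L, dim(plane_mask)))
  lab <- label3d_cpp(m3, dim(m3))
  sizes <- tabulate(lab[lab > 0L])
  matrix(lab == which.max(sizes), nrow = dim(plane_mask)[1])
}

# Area of the convex hull of the pixel *squares* (hull of centres, grown by
# the Minkowski sum with a unit square: + perimeter/2 + 1). Exact for convex
# shapes, so a filled rectangle has solidity exactly 1.
convex_hull_pixel_area <- function(pts) {
  h <- grDevices::chull(pts[, 1], pts[, 2])
  hp <- pts[h, , drop = FALSE]
  k <- nrow(hp)
  if (k < 3L) {
    # degenerate hull (collinear points): area = length * 1-px width
    span <- sqrt(sum((apply(hp, 2, max) - apply(hp, 2, min))^2))
    return(span + 1)
  }
  i2 <- c(2:k, 1)
  area <- abs(sum(hp[, 1] * hp[i2, 2] - hp[i2, 1] * hp[, 2])) / 2
  perim <- sum(sqrt(rowSums((hp[i2, ] - hp)^2)))
  area + perim / 2 + 1
}

#' Fit the moments-equivalent ellipse of a 2D mask
#'
#' Returns the ellipse with the same centroid and second central moments as
#' the mask (an automated, reproducible substitute for hand-drawn ovals):
#' centre at the mask centroid, semi-axes `a >= b` from the eigenvalues of
#' the pixel covariance (semi-axis = 2 sqrt(eigenvalue), with the 1/12
#' within-pixel variance included), orientation of the major axis in
#' `[-pi/2, pi/2)`.
#'
#' @param plane_mask logical 2D matrix with >= 5 true pixels.
#' @return An object of class `ellipse_params`: `center` (y, x), `a`, `b`,
#'   `orientation` (radians).
#' @export
fit_equivalent_ellipse <- function(plane_mask) {
  pts <- which(plane_mask, arr.ind = TRUE)
  n <- nrow(pts)
  if (n < 5L) stop("underdetermined error: fewer than 5 pixels in mask")
  ctr <- colMeans(pts)
  cv <- stats::cov(pts) * (n - 1) / n + diag(1 / 12, 2)
  ed <- eigen(cv, symmetric = TRUE)
  a <- 2 * sqrt(ed$values[1])
  b <- 2 * sqrt(max(ed$values[2], 0))
  v <- ed$vectors[, 1]                       # (y, x) direction of major axis
  theta <- atan2(v[1], v[2])                 # angle from +x axis
  if (theta >= pi / 2) theta <- theta - pi
  if (theta < -pi / 2) theta <- theta + pi
  structure(list(center = c(y = unname(ctr[1]), x = unname(ctr[2])),
                 a = a, b = b, orientation = theta),
            class = "ellipse_params")
}

#' Build three concentric equal-area elliptical zones
#'
#' Divides the fitted nuclear ellipse into three concentric zones of equal
#' area: the central zone is the ellipse scaled by sqrt(1/3), the
#' intermediate zone the sqrt(2/3) ellipse minus the central one, and the
#' peripheral zone the full ellipse minus the inner two. Each pixel is
#' assigned by its centre to the innermost zone containing it.
#'
#' @param ellipse an `ellipse_params`.
#' @param plane_shape integer (ny, nx) of the plane.
#' @return list of logical matrices `peripheral`, `intermediate`, `central`,
#'   plus a logical `clipped` flag set when the full ellipse extends beyond
#'   the plane.
#' @export
build_equal_area_zones <- function(ellipse, plane_shape) {
  if (!inherits(ellipse, "ellipse_params") || ellipse$b <= 0)
    stop("degenerate ellipse")
  ny <- plane_shape[1]; nx <- plane_shape[2]
  yy <- matrix(seq_len(ny) - ellipse$center["y"], ny, nx)
  xx <- matrix(rep(seq_len(nx) - ellipse$center["x"], each = ny), ny, nx)
  ct <- cos(ellipse$orientation); st <- sin(ellipse$orientation)
  u <- xx * ct + yy * st
  v <- -xx * st + yy * ct
  r2 <- (u / ellipse$a)^2 + (v / ellipse$b)^2
  central <- r2 <= 1 / 3
  intermediate <- r2 > 1 / 3 & r2 <= 2 / 3
  peripheral <- r2 > 2 / 3 & r2 <= 1
  ext <- sqrt((ellipse$a * ct)^2 + (ellipse$b * st)^2)  # x half-extent
  eyt <- sqrt((ellipse$a * st)^2 + (ellipse$b * ct)^2)  # y half-extent
  clipped <- (ellipse$center["y"] - eyt < 0.5) || (ellipse$center["y"] + eyt > ny + 0.5) ||
             (ellipse$center["x"] - ext < 0.5) || (ellipse$center["x"] + ext > nx + 0.5)
  list(peripheral = peripheral, intermediate = intermediate,
       central = central, clipped = unname(clipped))
}

#' Run the three-zone radial assay on one stack
#'
#' Composes the full assay: segmentation of both channels, mid-plane
#' selection on the probe mask, shape eligibility of the nuclear plane,
#' equivalent-ellipse fit, equal-area zone construction, and per-zone probe
#' pixel counts normalized by their sum over the three zones.
#'
#' @param stack an `image_stack`. The xy voxel sizes must be equal
#'   (isotropic in-plane sampling); anisotropic xy raises an error.
#' @param config list: segmentation options (see
#'   [measure_volume_fraction()]) plus `z_window` (default 1/3),
#'   `eligibility` limits, and `exclude_clipped` (default TRUE).
#' @param nucleus_id label carried into the result.
#' @return An object of class `zone_profile`: `fractions` named
#'   (peripheral, intermediate, central) summing to 1 when eligible (NA
#'   otherwise), `plane_index`, `eligible`, `eligibility_metrics`,
#'   `clipped`.
#' @export
run_zonal_assay <- function(stack, config = list(), nucleus_id = "n001") {
  cfg <- utils::modifyList(list(z_window = 1 / 3, eligibility = list(),
                                exclude_clipped = TRUE), config)
  vs <- stack$voxel_size
  if (abs(vs[2] - vs[3]) > 1e-12)
    stop("zone geometry requires isotropic xy voxel sizes")
  seg <- segment_stack(stack, cfg)
  z <- select_midplane(seg$probe_mask, cfg$z_window)
  nuc_plane <- largest_component_2d(seg$dapi_mask[z, , ])
  nuc_plane <- EBImage::fillHull(nuc_plane * 1L) > 0L
  elig <- check_eligibility(nuc_plane, cfg$eligibility)
  out <- list(fractions = c(peripheral = NA_real_, intermediate = NA_real_,
                            central = NA_real_),
              plane_index = z, eligible = elig$eligible,
              eligibility_metrics = elig$metrics, clipped = NA)
  class(out) <- "zone_profile"
  if (!elig$eligible) return(out)
  ell <- fit_equivalent_ellipse(nuc_plane)
  zones <- build_equal_area_zones(ell, dim(nuc_plane))
  out$clipped <- zones$clipped
  if (zones$clipped && cfg$exclude_clipped) {
    out$eligible <- FALSE
    return(out)
  }
  probe_plane <- seg$probe_mask[z, , ]
  counts <- c(peripheral = sum(probe_plane & zones$peripheral),
              intermediate = sum(probe_plane & zones$intermediate),
              central = sum(probe_plane & zones$central))
  if (sum(counts) == 0L) stop("no-signal error: no probe signal inside the zones")
  out$fractions <- counts / sum(counts)
  out
}

#' Run the three-zone assay across a synthetic cohort
#'
#' @param cohort list as returned by [generate_cohort()].
#' @param config passed to [run_zonal_assay()].
#' @return A data.frame with one row per nucleus: plane index, eligibility,
#'   metrics, the three zone fractions, and the generator's ground-truth
#'   zone masses. The attribute `percent_eligible` reports the cohort-level
#'   eligibility percentage.
#' @export
run_zonal_cohort <- function(cohort, config = list()) {
  rows <- lapply(cohort, function(nuc) {
    zp <- run_zonal_assay(nuc$stack, config, nucleus_id = nuc$nucleus_id %||% "n000")
    data.frame(
      nucleus_id = nuc$nucleus_id %||% "n000",
      seed = nuc$truth$seed,
      plane_index = zp$plane_index,
      eligible = zp$eligible,
      axis_ratio = unname(zp$eligibility_metrics["axis_ratio"]),
      solidity = unname(zp$eligibility_metrics["solidity"]),
      peripheral = unname(zp$fractions["peripheral"]),
      intermediate = unname(zp$fractions["intermediate"]),
      central = unname(zp$fractions["central"]),
      true_peripheral = unname(nuc$truth$true_zone_masses["peripheral"]),
      true_intermediate = unname(nuc$truth$true_zone_masses["intermediate"]),
      true_central = unname(nuc$truth$true_zone_masses["central"]),
      stringsAsFactors = FALSE
    )
  })
  df <- do.call(rbind, rows)
  attr(df, "percent_eligible") <- 100 * mean(df$eligible)
  df
}

#' @export
print.zone_profile <- function(x, ...) {
  if (x$eligible) {
    cat(sprintf("<zone_profile> plane %d, P/I/C = %s\n", x$plane_index,
                paste(sprintf("%.3f", x$fractions), collapse = "/")))
  } else {
    cat(sprintf("<zone_profile> plane %d, ineligible (axis ratio %.2f, solidity %.2f)\n",
                x$plane_index, x$eligibility_metrics["axis_ratio"],
                x$eligibility_metrics["solidity"]))
  }
  invisible(x)
}
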