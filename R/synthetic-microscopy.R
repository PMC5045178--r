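#' Specification for a synthetic two-channel nucleus stack
#'
#' Describes the forward model for one intestinal-type nucleus: an
#' ellipsoidal DNA-stain (dapi) volume containing one or two painted
#' chromosome territories of known volume fraction and radial placement.
#' The defaults emulate a ~10 um intestinal nucleus imaged at typical
#' widefield sampling: a 48 x 192 x 192 voxel stack at 0.2 x 0.1 x 0.1 um
#' with nuclear semi-axes 3.5 x 6 x 6 um.
#'
#' @param stack_shape integer (z, y, x) voxel counts.
#' @param voxel_size numeric (z, y, x) voxel edge lengths in um.
#' @param nucleus_semiaxes numeric (z, y, x) nuclear semi-axes in um.
#' @param territory_fraction target fraction of nuclear volume occupied by
#'   the territory (all territories pooled), in (0, 1).
#' @param radial_bias radial placement of territory seed points: 0 places
#'   them at the nuclear centre, 1 at the nuclear envelope. Seed directions
#'   are drawn in the equatorial (xy) plane so territories always intersect
#'   the true mid-plane.
#' @param n_territories 1 (single X, male/XO) or 2 (hermaphrodite homologs).
#' @param blur_sigma Gaussian blur sigma in um (applied per axis in voxel
#'   units; emulates optical blur). Blur is applied before noise.
#' @param noise_sd additive Gaussian noise sd in intensity units (clipped
#'   at zero).
#' @param background_level,nuclear_intensity,probe_intensity intensity units.
#' @param foci_count number of optional bright puncta added to the probe
#'   channel inside the nucleus.
#' @param size_cv coefficient of variation of nuclear size used by
#'   [generate_cohort()] (lognormal scale jitter of all three semi-axes).
#' @param fraction_cv coefficient of variation of the per-nucleus territory
#'   fraction used by [generate_cohort()] (truncated-normal multiplicative
#'   jitter around `territory_fraction`), emulating nucleus-to-nucleus
#'   biological variability; the cohort mean stays at `territory_fraction`.
#'
#' @return An object of class `imaging_spec` (a validated list).
#' @export
imaging_spec <- function(stack_shape = c(48L, 192L, 192L),
                         voxel_size = c(0.2, 0.1, 0.1),
                         nucleus_semiaxes = c(3.5, 6, 6),
                         territory_fraction = 0.10,
                         radial_bias = 0.8,
                         n_territories = 2L,
                         blur_sigma = 0.15,
                         noise_sd = 8,
                         background_level = 10,
                         nuclear_intensity = 100,
                         probe_intensity = 150,
                         foci_count = 0L,
                         size_cv = 0.1,
                         fraction_cv = 0.15) {
  spec <- list(
    stack_shape = as.integer(stack_shape),
    voxel_size = as.numeric(voxel_size),
    nucleus_semiaxes = as.numeric(nucleus_semiaxes),
    territory_fraction = territory_fraction,
    radial_bias = radial_bias,
    n_territories = as.integer(n_territories),
    blur_sigma = blur_sigma,
    noise_sd = noise_sd,
    background_level = background_level,
    nuclear_intensity = nuclear_intensity,
    probe_intensity = probe_intensity,
    foci_count = as.integer(foci_count),
    size_cv = size_cv,
    fraction_cv = fraction_cv
  )
  class(spec) <- "imaging_spec"
  validate_imaging_spec(spec)
  spec
}

#' Validate an imaging spec
#'
#' Checks field domains and that the nucleus fits inside the stack with at
#' least a 2-voxel margin on every axis.
#'
#' @param spec an `imaging_spec`.
#' @return The spec, invisibly; stops with a geometry error otherwise.
#' @export
validate_imaging_spec <- function(spec) {
  stopifnot(inherits(spec, "imaging_spec"))
  if (length(spec$stack_shape) != 3L || any(spec$stack_shape < 1L))
    stop("stack_shape must be three positive voxel counts")
  if (length(spec$voxel_size) != 3L || any(spec$voxel_size <= 0))
    stop("voxel_size must be three positive lengths (um)")
  if (length(spec$nucleus_semiaxes) != 3L || any(spec$nucleus_semiaxes <= 0))
    stop("nucleus_semiaxes must be three positive lengths (um)")
  if (!is.numeric(spec$territory_fraction) ||
      spec$territory_fraction <= 0 || spec$territory_fraction >= 1)
    stop("territory_fraction must lie in (0, 1)")
  if (spec$radial_bias < 0 || spec$radial_bias > 1)
    stop("radial_bias must lie in [0, 1]")
  if (!spec$n_territories %in% c(1L, 2L))
    stop("n_territories must be 1 or 2")
  if (spec$blur_sigma < 0 || spec$noise_sd < 0 || spec$background_level < 0 ||
      spec$nuclear_intensity <= 0 || spec$probe_intensity <= 0)
    stop("intensity and blur parameters must be non-negative (intensities > 0)")
  if (spec$foci_count < 0L) stop("foci_count must be >= 0")
  if (spec$size_cv < 0) stop("size_cv must be >= 0")
  if (spec$fraction_cv < 0 || spec$fraction_cv > 0.3)
    stop("fraction_cv must lie in [0, 0.3]")
  semi_vox <- spec$nucleus_semiaxes / spec$voxel_size
  margin <- spec$stack_shape / 2 - semi_vox
  if (any(margin < 2))
    stop("geometry error: nucleus does not fit in the stack with a 2-voxel margin")
  invisible(spec)
}

# Geometry shared by mask construction and rendering: voxel-centre offsets
# from the stack centre in um, the nuclear ellipsoid mask, and the linear
# indices plus um coordinates of nucleus voxels.
nucleus_geometry <- function(spec) {
  dims <- spec$stack_shape
  vs <- spec$voxel_size
  ax <- spec$nucleus_semiaxes                       # (z, y, x) um
  centre <- (dims + 1) / 2                          # voxel index units
  off <- lapply(1:3, function(i) (seq_len(dims[i]) - centre[i]) * vs[i])
  n2 <- lapply(1:3, function(i) (off[[i]] / ax[i])^2)
  # norm2[z,y,x] = sum of per-axis normalized squared offsets
  norm2 <- outer(outer(n2[[1]], n2[[2]], `+`), n2[[3]], `+`)
  mask <- norm2 <= 1
  idx <- which(mask)
  # recover (z, y, x) subscripts arithmetically (faster than arr.ind)
  i0 <- idx - 1L
  z <- i0 %% dims[1]
  y <- (i0 %/% dims[1]) %% dims[2]
  x <- i0 %/% (dims[1] * dims[2])
  coords <- cbind(
    z = (z + 1 - centre[1]) * vs[1],
    y = (y + 1 - centre[2]) * vs[2],
    x = (x + 1 - centre[3]) * vs[3]
  )
  list(dims = dims, centre = centre, mask = mask, idx = idx, coords = coords,
       midplane = as.integer(round(centre[1])))
}

# Construct the territory mask by weighted-distance growth from seed points.
# Seeds sit at normalized radius `radial_bias` along random equatorial
# directions; each territory claims the budgeted number of nucleus voxels
# nearest to its seed under a random anisotropic metric (convex balls inside
# the convex nucleus, so each territory is connected and its voxel count is
# exact). Consumes RNG draws; caller controls the seed.
build_territory <- function(geom, spec) {
  n_nuc <- length(geom$idx)
  k <- as.integer(round(spec$territory_fraction * n_nuc))
  if (k < 1L || k > n_nuc)
    stop("infeasibility error: territory_fraction unachievable at this discretization")
  nt <- spec$n_territories
  ax <- spec$nucleus_semiaxes
  phi1 <- runif(1, 0, 2 * pi)
  # second homolog seeded on the far side (>= 120 degrees away)
  phis <- if (nt == 2L) c(phi1, phi1 + pi + runif(1, -pi / 3, pi / 3)) else phi1
  w <- matrix(exp(runif(3 * nt, -0.3, 0.3)), nrow = nt)  # metric weights
  rb <- spec$radial_bias
  seeds <- cbind(z = rep(0, nt),
                 y = rb * ax[2] * cos(phis),
                 x = rb * ax[3] * sin(phis))
  d2 <- sapply(seq_len(nt), function(t) {
    (w[t, 1] * (geom$coords[, "z"] - seeds[t, "z"])^2 +
     w[t, 2] * (geom$coords[, "y"] - seeds[t, "y"])^2 +
     w[t, 3] * (geom$coords[, "x"] - seeds[t, "x"])^2)
  })
  sel <- integer(0)
  if (nt == 1L) {
    sel <- order(d2[, 1])[seq_len(k)]
  } else {
    part <- max.col(-d2, ties.method = "first")  # nearer seed claims voxel
    n1 <- sum(part == 1L); n2 <- n_nuc - n1
    # equal split, rebalanced when one partition is too small (degenerate
    # near-coincident seeds at low radial bias)
    b1 <- min(max(k %/% 2L, k - n2), n1)
    budgets <- c(b1, k - b1)
    for (t in 1:2) {
      in_t <- which(part == t)
      if (budgets[t] > 0L)
        sel <- c(sel, in_t[order(d2[in_t, t])[seq_len(budgets[t])]])
    }
  }
  tmask <- array(FALSE, dim = geom$dims)
  tmask[geom$idx[sel]] <- TRUE
  list(mask = tmask, sel = sel, k = k, seeds = seeds)
}

# Analytic three-zone masses of the territory on the true mid-plane,
# measured against the continuous nuclear ellipse cross-section (avoids
# discretization bias in the oracle).
true_zone_masses <- function(geom, spec, territory_mask) {
  zmid <- geom$midplane
  vs <- spec$voxel_size
  ax <- spec$nucleus_semiaxes
  dz <- (zmid - geom$centre[1]) * vs[1]
  s <- sqrt(max(0, 1 - (dz / ax[1])^2))   # cross-section scale at mid-plane
  plane <- territory_mask[zmid, , ]
  pid <- which(plane)
  if (length(pid) == 0L)
    return(c(peripheral = NA_real_, intermediate = NA_real_, central = NA_real_))
  ny <- geom$dims[2]
  yy <- ((pid - 1L) %% ny + 1 - geom$centre[2]) * vs[2]
  xx <- ((pid - 1L) %/% ny + 1 - geom$centre[3]) * vs[3]
  r2 <- (yy / (ax[2] * s))^2 + (xx / (ax[3] * s))^2
  cen <- sum(r2 <= 1 / 3)
  mid <- sum(r2 > 1 / 3 & r2 <= 2 / 3)
  per <- length(r2) - cen - mid
  c(peripheral = per, intermediate = mid, central = cen) / length(r2)
}

# Separable 3D Gaussian blur with per-axis sigma in voxel units, via banded
# kernel-matrix multiplication along each axis. Kernels are truncated at
# 4 sigma and renormalised per output row (edge renormalisation).
gaussian_blur_3d <- function(a, sigma_vox) {
  dims <- dim(a)
  blur_axis <- function(arr, axis, sigma) {
    if (sigma <= 0) return(arr)
    n <- dims[axis]
    half <- max(1L, ceiling(4 * sigma))
    kern <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
    K <- matrix(0, n, n)
    for (j in seq_len(n)) {
      lo <- max(1L, j - half); hi <- min(n, j + half)
      K[j, lo:hi] <- kern[(lo:hi) - j + half + 1L]
      K[j, ] <- K[j, ] / sum(K[j, ])
    }
    perm <- switch(axis, `1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L), `3` = c(3L, 1L, 2L))
    b <- if (axis == 1L) arr else aperm(arr, perm)
    m <- matrix(b, nrow = n)
    m <- K %*% m
    b <- array(m, dim = dims[perm])
    if (axis == 1L) b else aperm(b, order(perm))
  }
  for (ax in 1:3) a <- blur_axis(a, ax, sigma_vox[ax])
  a
}

#' Generate one synthetic two-channel nucleus stack with ground truth
#'
#' Forward model: the nucleus is rendered as a filled ellipsoid in the dapi
#' channel and the painted territory as `n_territories` connected blobs in
#' the probe channel, occupying `territory_fraction` of the nuclear voxels
#' (exactly, up to budget rounding) at a radial placement controlled by
#' `radial_bias`. Both channels are blurred (sigma converted to voxels per
#' axis) and corrupted with additive Gaussian noise clipped at zero.
#' Identical `(spec, seed)` give bit-identical output.
#'
#' @param spec an [imaging_spec()].
#' @param seed integer seed controlling all randomness.
#' @return A list with elements `stack` (class `image_stack`: channels
#'   `dapi` and `probe`, `voxel_size`, `metadata`) and `truth` (class
#'   `ground_truth`: pre-blur `nucleus_mask` and `territory_mask`,
#'   `true_volume_fraction` in percent, `true_midplane`, `true_zone_masses`
#'   as (peripheral, intermediate, central) fractions summing to 1,
#'   `spec_echo`, `seed`).
#' @export
generate_nucleus_stack <- function(spec, seed) {
  validate_imaging_spec(spec)
  seed <- as.integer(seed)
  geom <- nucleus_geometry(spec)
  set.seed(seed)
  terr <- build_territory(geom, spec)
  zones <- true_zone_masses(geom, spec, terr$mask)

  dapi <- spec$background_level + spec$nuclear_intensity * geom$mask
  probe <- spec$background_level + spec$probe_intensity * terr$mask
  if (spec$foci_count > 0L) {
    fidx <- sample(geom$idx, spec$foci_count)
    probe[fidx] <- probe[fidx] + 2 * spec$probe_intensity
  }
  sigma_vox <- spec$blur_sigma / spec$voxel_size
  dapi <- gaussian_blur_3d(dapi, sigma_vox)
  probe <- gaussian_blur_3d(probe, sigma_vox)
  if (spec$noise_sd > 0) {
    dapi <- dapi + rnorm(length(dapi), 0, spec$noise_sd)
    probe <- probe + rnorm(length(probe), 0, spec$noise_sd)
  }
  dapi <- pmax(dapi, 0); dim(dapi) <- geom$dims
  probe <- pmax(probe, 0); dim(probe) <- geom$dims

  stack <- structure(list(
    channels = list(dapi = dapi, probe = probe),
    voxel_size = spec$voxel_size,
    metadata = list(generator = "xterritory", seed = seed)
  ), class = "image_stack")
  truth <- structure(list(
    nucleus_mask = geom$mask,
    territory_mask = terr$mask,
    true_volume_fraction = 100 * terr$k / length(geom$idx),
    true_midplane = geom$midplane,
    true_zone_masses = zones,
    spec_echo = spec,
    seed = seed
  ), class = "ground_truth")
  list(stack = stack, truth = truth)
}

#' Ground truth only (no rendering)
#'
#' Builds the nucleus and territory masks and the analytic zone masses for a
#' `(spec, seed)` pair without blurring, noise or channel rendering. The
#' masks are identical to the pre-blur masks of [generate_nucleus_stack()]
#' for the same arguments.
#'
#' @inheritParams generate_nucleus_stack
#' @return A `ground_truth` object.
#' @export
generate_ground_truth <- function(spec, seed) {
  validate_imaging_spec(spec)
  seed <- as.integer(seed)
  geom <- nucleus_geometry(spec)
  set.seed(seed)
  terr <- build_territory(geom, spec)
  structure(list(
    nucleus_mask = geom$mask,
    territory_mask = terr$mask,
    true_volume_fraction = 100 * terr$k / length(geom$idx),
    true_midplane = geom$midplane,
    true_zone_masses = true_zone_masses(geom, spec, terr$mask),
    spec_echo = spec,
    seed = seed
  ), class = "ground_truth")
}

# Deterministic per-nucleus seed derivation from a cohort base seed.
derive_seed <- function(base_seed, i) {
  as.integer((as.numeric(base_seed) %% 1e6 * 1009 + 104729 * i) %% 2147483647)
}

#' Generate a cohort of synthetic nuclei
#'
#' Produces `n` independent nuclei with per-nucleus seeds derived
#' deterministically from `base_seed`. Nuclear semi-axes are jittered by a
#' lognormal scale factor with coefficient of variation `spec$size_cv`,
#' mimicking the large nucleus-to-nucleus size variability of FISH
#' preparations; the territory fraction (a ratio) is unaffected.
#'
#' @param spec an [imaging_spec()].
#' @param n number of nuclei (>= 1).
#' @param base_seed integer cohort seed.
#' @param radial_bias optional numeric vector of length `n` overriding
#'   `spec$radial_bias` per nucleus (used by calibrated zonal cohorts).
#' @return A list of `n` elements, each as returned by
#'   [generate_nucleus_stack()].
#' @export
generate_cohort <- function(spec, n, base_seed, radial_bias = NULL) {
  validate_imaging_spec(spec)
  n <- as.integer(n)
  if (n < 1L) stop("cohort size n must be >= 1")
  if (!is.null(radial_bias) && length(radial_bias) != n)
    stop("radial_bias override must have one value per nucleus")
  lapply(seq_len(n), function(i) {
    si <- derive_seed(base_seed, i)
    set.seed(si)
    # truncated (+/- 2.5 sd) lognormal size jitter, further clamped to the
    # largest scale the stack margin admits, so extreme draws cannot push
    # the nucleus past the 2-voxel margin
    zdev <- max(min(rnorm(1), 2.5), -2.5)
    scale <- exp(zdev * sqrt(log(1 + spec$size_cv^2)))
    max_scale <- min((spec$stack_shape / 2 - 2) * spec$voxel_size /
                       spec$nucleus_semiaxes)
    scale <- min(scale, max_scale * 0.999)
    fdev <- max(min(rnorm(1), 2.5), -2.5)
    spec_i <- spec
    spec_i$nucleus_semiaxes <- spec$nucleus_semiaxes * scale
    spec_i$territory_fraction <-
      spec$territory_fraction * (1 + spec$fraction_cv * fdev)
    if (!is.null(radial_bias)) spec_i$radial_bias <- radial_bias[i]
    validate_imaging_spec(spec_i)
    out <- generate_nucleus_stack(spec_i, si)
    out$nucleus_id <- sprintf("n%03d", i)
    out
  })
}

#' Calibrate radial bias to a target central-zone ground truth
#'
#' The analytic central-zone mass of a territory decreases as its seed moves
#' from the nuclear centre (`radial_bias = 0`) to the envelope (`= 1`). This
#' solves, by bisection on `radial_bias` with the seed's random draws held
#' fixed, for the bias whose ground-truth central-zone mass matches
#' `target_central`. Used to build cohorts whose true radial statistics are
#' pinned to a chosen value.
#'
#' @param spec an [imaging_spec()] (its `radial_bias` is ignored).
#' @param target_central desired central-zone mass in `[0, 1]`.
#' @param seed integer seed (same meaning as in [generate_nucleus_stack()]).
#' @param tol bisection tolerance on the central mass.
#' @param max_iter maximum bisection iterations.
#' @return The calibrated `radial_bias` (numeric scalar) with the achieved
#'   ground-truth central mass as attribute `achieved`.
#' @export
calibrate_radial_bias <- function(spec, target_central, seed,
                                  tol = 0.005, max_iter = 30L) {
  stopifnot(target_central >= 0, target_central <= 1)
  geom <- nucleus_geometry(spec)
  central_at <- function(rb) {
    sp <- spec; sp$radial_bias <- rb
    set.seed(as.integer(seed))
    terr <- build_territory(geom, sp)
    unname(true_zone_masses(geom, sp, terr$mask)["central"])
  }
  lo <- 0; hi <- 1
  f_lo <- central_at(lo); f_hi <- central_at(hi)
  if (f_lo <= target_central) return(structure(lo, achieved = f_lo))
  if (f_hi >= target_central) return(structure(hi, achieved = f_hi))
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f_mid <- central_at(mid)
    if (abs(f_mid - target_central) <= tol) return(structure(mid, achieved = f_mid))
    if (f_mid > target_central) lo <- mid else hi <- mid
  }
  mid <- (lo + hi) / 2
  structure(mid, achieved = central_at(mid))
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<image_stack> %d x %d x %d voxels (z,y,x) @ %s um, channels: %s\n",
              d[1], d[2], d[3], paste(x$voxel_size, collapse = " x "),
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> territory %.2f%% of %d nucleus voxels; mid-plane z=%d; zones (P/I/C) %s\n",
    x$true_volume_fraction, sum(x$nucleus_mask), x$true_midplane,
    paste(sprintf("%.3f", x$true_zone_masses), collapse = "/")))
  invisible(x)
}
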