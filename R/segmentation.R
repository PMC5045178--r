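#' Automatic intensity threshold (Otsu's criterion)
#'
#' Chooses the threshold maximizing the between-class variance of a
#' `levels`-bin histogram of the intensities. The acquisition software used
#' for the original measurements relies on a user-defined threshold
#' separating signal from background; this deterministic default reproduces
#' the "same level of background for all nuclei" policy, and every
#' segmentation entry point accepts a manual override.
#'
#' @param channel numeric array (any shape) of finite intensities.
#' @param levels number of histogram bins.
#' @return A single threshold value, strictly between the minimum and
#'   maximum intensity for a non-constant channel. Masks are formed by
#'   `intensity >= threshold` (ties included).
#' @export
auto_threshold <- function(channel, levels = 256L) {
  x <- as.numeric(channel)
  if (length(x) == 0L || any(!is.finite(x)))
    stop("channel must be non-empty with finite intensities")
  rng <- range(x)
  if (rng[1] == rng[2])
    stop("degenerate-histogram error: channel is constant")
  breaks <- seq(rng[1], rng[2], length.out = levels + 1L)
  bins <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  h <- tabulate(bins, nbins = levels)
  w <- h / length(x)
  mids <- (breaks[-1] + breaks[-(levels + 1L)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[levels]
  denom <- omega * (1 - omega)
  sigma_b <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, -Inf)
  sigma_b <- sigma_b[-levels]   # split must leave both classes non-empty
  k <- as.integer(round(mean(which(sigma_b == max(sigma_b)))))
  breaks[k + 1L]
}

#' Threshold a channel into a 3D binary mask
#'
#' A voxel is true iff its intensity is `>= threshold`; connected components
#' smaller than `min_component_voxels` (26-connectivity) are then removed.
#'
#' @param channel 3D numeric array, dim (z, y, x).
#' @param threshold intensity threshold (>= 0).
#' @param min_component_voxels minimum component size kept (1 keeps all).
#' @return An object of class `binary_mask3d`: list with `voxels` (logical
#'   array), `source_channel`, `threshold_used`.
#' @export
threshold_mask <- function(channel, threshold, min_component_voxels = 1L,
                           source_channel = "channel") {
  if (threshold < 0) stop("threshold must be >= 0")
  m <- channel >= threshold
  if (min_component_voxels > 1L && any(m)) {
    lab <- label3d_cpp(m, dim(m))
    sizes <- tabulate(lab[lab > 0L])
    keep <- which(sizes >= min_component_voxels)
    m <- array(lab %in% keep & lab > 0L, dim = dim(m))
  }
  structure(list(voxels = m, source_channel = source_channel,
                 threshold_used = threshold),
            class = "binary_mask3d")
}

# Nucleus-mask post-processing: keep the largest 26-connected component and
# fill holes per z-slice.
clean_nucleus_mask <- function(m) {
  if (!any(m)) return(m)
  lab <- label3d_cpp(m, dim(m))
  sizes <- tabulate(lab[lab > 0L])
  m <- array(lab == which.max(sizes), dim = dim(m))
  for (z in seq_len(dim(m)[1])) {
    sl <- m[z, , ]
    if (any(sl)) m[z, , ] <- EBImage::fillHull(sl * 1L) > 0L
  }
  m
}

# Build the dapi (primary) and probe (secondary) masks for a stack.
segment_stack <- function(stack, config = list()) {
  cfg <- utils::modifyList(list(
    dapi_threshold = NULL, probe_threshold = NULL,
    min_component_voxels = 27L, levels = 256L
  ), config)
  dapi <- stack$channels$dapi
  probe <- stack$channels$probe
  t_dapi <- if (is.null(cfg$dapi_threshold)) auto_threshold(dapi, cfg$levels) else cfg$dapi_threshold
  dmask <- dapi >= t_dapi
  dmask <- clean_nucleus_mask(dmask)
  if (!any(dmask)) stop("no-nucleus error: empty dapi mask")
  t_probe <- if (is.null(cfg$probe_threshold)) {
    # threshold the probe on its within-nucleus histogram
    auto_threshold(probe[dmask], cfg$levels)
  } else cfg$probe_threshold
  pmask <- threshold_mask(probe, t_probe, cfg$min_component_voxels, "probe")$voxels
  list(dapi_mask = dmask, probe_mask = pmask,
       thresholds = c(dapi = t_dapi, probe = t_probe))
}

#' Measure the territory volume fraction of a nucleus
#'
#' Reproduces the cross-mask volume quantification: the dapi mask is the
#' primary mask (largest component, holes filled per slice), the probe mask
#' the secondary one (components >= `min_component_voxels` kept, so both
#' homolog territories are allowed), and the reported statistic is
#' `100 * |probe AND dapi| / |dapi|` — the percent of nuclear volume
#' occupied by the painted chromosome.
#'
#' @param stack an `image_stack` with `dapi` and `probe` channels.
#' @param config list of options: `dapi_threshold`, `probe_threshold`
#'   (NULL = automatic via [auto_threshold()]; the probe threshold is
#'   computed on the within-nucleus histogram), `min_component_voxels`
#'   (default 27).
#' @param nucleus_id label carried into the result.
#' @return An object of class `nucleus_measurement`: `nucleus_voxels`,
#'   `overlap_voxels`, `volume_fraction_percent`, `thresholds`, `nucleus_id`.
#' @export
measure_volume_fraction <- function(stack, config = list(), nucleus_id = "n001") {
  if (!all(c("dapi", "probe") %in% names(stack$channels)))
    stop("stack must contain dapi and probe channels")
  seg <- segment_stack(stack, config)
  n_nuc <- sum(seg$dapi_mask)
  n_ov <- sum(seg$probe_mask & seg$dapi_mask)
  structure(list(
    nucleus_id = nucleus_id,
    nucleus_voxels = n_nuc,
    overlap_voxels = n_ov,
    volume_fraction_percent = 100 * n_ov / n_nuc,
    thresholds = seg$thresholds
  ), class = "nucleus_measurement")
}

#' Measure volume fractions across a synthetic cohort
#'
#' @param cohort list as returned by [generate_cohort()].
#' @param config passed to [measure_volume_fraction()].
#' @return A data.frame with one row per nucleus: `nucleus_id`, `seed`,
#'   voxel counts, `volume_fraction_percent`, thresholds, and the
#'   generator's `true_volume_fraction`.
#' @export
measure_volume_cohort <- function(cohort, config = list()) {
  rows <- lapply(cohort, function(nuc) {
    m <- measure_volume_fraction(nuc$stack, config,
                                 nucleus_id = nuc$nucleus_id %||% "n000")
    data.frame(
      nucleus_id = m$nucleus_id,
      seed = nuc$truth$seed,
      nucleus_voxels = m$nucleus_voxels,
      overlap_voxels = m$overlap_voxels,
      volume_fraction_percent = m$volume_fraction_percent,
      threshold_dapi = unname(m$thresholds["dapi"]),
      threshold_probe = unname(m$thresholds["probe"]),
      true_volume_fraction = nuc$truth$true_volume_fraction,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.nucleus_measurement <- function(x, ...) {
  cat(sprintf("<nucleus_measurement> %s: %.2f%% of %d nuclear voxels (overlap %d)\n",
              x$nucleus_id, x$volume_fraction_percent,
              x$nucleus_voxels, x$overlap_voxels))
  invisible(x)
}
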