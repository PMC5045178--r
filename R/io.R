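#' Write an image stack as multi-page TIFF files
#'
#' One 16-bit multi-page TIFF per channel (`<prefix>_<channel>.tif`, one
#' page per z-plane) plus a YAML sidecar `<prefix>_meta.yaml` recording
#' voxel sizes and per-channel intensity scales.
#'
#' @param stack an `image_stack`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Invisibly, the paths written.
#' @export
write_image_stack <- function(stack, dir, prefix = "stack") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scales <- list()
  paths <- character(0)
  for (ch in names(stack$channels)) {
    a <- stack$channels[[ch]]
    sc <- max(a, 1e-12)
    scales[[ch]] <- sc
    pages <- lapply(seq_len(dim(a)[1]), function(z) a[z, , ] / sc)
    path <- file.path(dir, sprintf("%s_%s.tif", prefix, ch))
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    paths <- c(paths, path)
  }
  meta <- list(voxel_size = as.numeric(stack$voxel_size),
               channels = names(stack$channels),
               intensity_scale = scales,
               metadata = stack$metadata)
  mpath <- file.path(dir, sprintf("%s_meta.yaml", prefix))
  yaml::write_yaml(meta, mpath)
  invisible(c(paths, mpath))
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param dir directory containing the files.
#' @param prefix file-name prefix used at write time.
#' @return An `image_stack`.
#' @export
read_image_stack <- function(dir, prefix = "stack") {
  meta <- yaml::read_yaml(file.path(dir, sprintf("%s_meta.yaml", prefix)))
  channels <- list()
  for (ch in meta$channels) {
    pages <- tiff::readTIFF(file.path(dir, sprintf("%s_%s.tif", prefix, ch)),
                            all = TRUE)
    a <- array(0, dim = c(length(pages), dim(pages[[1]])))
    for (z in seq_along(pages)) a[z, , ] <- pages[[z]]
    channels[[ch]] <- a * meta$intensity_scale[[ch]]
  }
  structure(list(channels = channels,
                 voxel_size = as.numeric(meta$voxel_size),
                 metadata = meta$metadata),
            class = "image_stack")
}

#' Write a 3D binary mask as an 8-bit multi-page TIFF
#'
#' @param mask logical 3D array or `binary_mask3d`.
#' @param path output file path.
#' @export
write_mask_tiff <- function(mask, path) {
  m <- if (inherits(mask, "binary_mask3d")) mask$voxels else mask
  pages <- lapply(seq_len(dim(m)[1]), function(z) m[z, , ] * 1.0)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a 3D binary mask written by [write_mask_tiff()]
#'
#' @param path TIFF path.
#' @return logical 3D array, dim (z, y, x).
#' @export
read_mask_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  a <- array(FALSE, dim = c(length(pages), dim(pages[[1]])))
  for (z in seq_along(pages)) a[z, , ] <- pages[[z]] > 0.5
  a
}

#' Write a synthetic cohort to disk with a manifest
#'
#' Writes every nucleus (both channels, ground-truth masks) plus a TSV
#' manifest (`manifest.tsv`) with nucleus id, file paths, seed and ground
#' truth values — sufficient to regenerate or re-analyze the cohort.
#'
#' @param cohort list as returned by [generate_cohort()].
#' @param dir output directory.
#' @return The manifest data.frame, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(cohort, function(nuc) {
    id <- nuc$nucleus_id %||% "n000"
    write_image_stack(nuc$stack, dir, prefix = id)
    nm <- file.path(dir, sprintf("%s_nucleus_mask.tif", id))
    tm <- file.path(dir, sprintf("%s_territory_mask.tif", id))
    write_mask_tiff(nuc$truth$nucleus_mask, nm)
    write_mask_tiff(nuc$truth$territory_mask, tm)
    data.frame(nucleus_id = id,
               dapi_tif = sprintf("%s_dapi.tif", id),
               probe_tif = sprintf("%s_probe.tif", id),
               nucleus_mask_tif = basename(nm),
               territory_mask_tif = basename(tm),
               seed = nuc$truth$seed,
               true_volume_fraction = nuc$truth$true_volume_fraction,
               true_peripheral = unname(nuc$truth$true_zone_masses["peripheral"]),
               true_intermediate = unname(nuc$truth$true_zone_masses["intermediate"]),
               true_central = unname(nuc$truth$true_zone_masses["central"]),
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}

#' Write a data.frame as TSV
#' @param df data.frame.
#' @param path output path.
#' @export
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path input path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
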