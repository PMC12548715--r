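#' Write a stack as multi-page 16-bit TIFF with a JSON sidecar
#'
#' One TIFF page per z-slice; intensities are rounded to the 16-bit
#' integer grid (values above 65535 are clipped), so the round trip is
#' lossless for integer-valued stacks in range. Voxel size and channel
#' go to `<path>.json`.
#'
#' @param stack a [volume_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "VolumeStack"))
  v <- round(pmin(stack$voxels, 65535))
  pages <- lapply(seq_len(dim(v)[1]), function(z) v[z, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(voxel_size_um = c(stack$voxel_size_um, stack$voxel_size_um,
                           stack$voxel_size_um),
         axis_order = "zyx", channel = stack$channel),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a multi-page TIFF stack
#'
#' Reads a single-channel 8/16-bit multi-page TIFF into a
#' [volume_stack()]. The voxel size comes from the `<path>.json` sidecar
#' when present, else from `voxel_size_um`; it must be isotropic.
#'
#' @param path TIFF path.
#' @param voxel_size_um fallback voxel size when no sidecar exists.
#' @return a [volume_stack()].
#' @export
read_stack <- function(path, voxel_size_um = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(dim(pages[[1]])) == 3L)
    stop("multi-sample (RGB) TIFF: expected one channel per file")
  channel <- ""
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    vs <- meta$voxel_size_um
    if (length(unique(vs)) != 1L)
      stop("anisotropic voxel size in sidecar; the pipeline requires isotropic voxels")
    voxel_size_um <- vs[1]
    if (!is.null(meta$channel)) channel <- meta$channel
  }
  if (is.null(voxel_size_um))
    stop("no voxel size: supply `voxel_size_um` or a sidecar JSON")
  d <- dim(pages[[1]])
  vox <- array(0, c(length(pages), d[1], d[2]))
  for (z in seq_along(pages)) vox[z, , ] <- pages[[z]]
  volume_stack(vox, voxel_size_um, channel)
}

#' Write / read ground truth as JSON
#'
#' Centerline points are world coordinates in micrometres, z/y/x order.
#'
#' @param truth a `GroundTruth` from [generate_axon_stack()].
#' @param path JSON path.
#' @return `path` (write) or the `GroundTruth` (read).
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "GroundTruth"))
  jsonlite::write_json(
    list(axis_order = "zyx",
         voxel_size_um = truth$voxel_size_um,
         total_length_um = truth$total_length_um,
         centerlines = lapply(truth$centerlines, function(m)
           unname(as.matrix(m))),
         boutons = truth$boutons),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- j$centerlines
  if (is.matrix(cls)) cls <- list(cls)   # single centerline collapses
  bt <- as.data.frame(j$boutons)
  if (!nrow(bt)) bt <- data.frame(z = numeric(0), y = numeric(0),
                                  x = numeric(0), radius_um = numeric(0))
  structure(list(centerlines = lapply(cls, as.matrix),
                 total_length_um = j$total_length_um,
                 boutons = bt, voxel_size_um = j$voxel_size_um),
            class = "GroundTruth")
}

#' Read a retrograde cell-count table from CSV
#'
#' Expects columns region, animal, genotype, count and optionally
#' excluded.
#'
#' @param path CSV path.
#' @return a [cell_count_table()].
#' @export
read_count_table <- function(path) {
  cell_count_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_count_table
#' @param table a [cell_count_table()].
#' @export
write_count_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}
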