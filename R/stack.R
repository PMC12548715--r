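#' Volumetric intensity stack
#'
#' A `VolumeStack` is the package's container for a single-channel 3D
#' fluorescence image: a numeric array of non-negative intensities plus an
#' isotropic physical voxel size. Axis order is z, y, x (first array
#' dimension = z), with world coordinates in micrometres measured from the
#' centre of voxel (1, 1, 1).
#'
#' @param voxels 3D numeric array of finite, non-negative intensities.
#' @param voxel_size_um positive scalar; one edge length shared by all
#'   three axes (the pipeline assumes isotropic voxels).
#' @param channel free-text channel name.
#'
#' @return An object of class `VolumeStack` with elements `voxels`,
#'   `voxel_size_um` and `channel`.
#' @export
volume_stack <- function(voxels, voxel_size_um, channel = "") {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  if (!is.numeric(voxels) || anyNA(voxels) || any(!is.finite(voxels)))
    stop("voxel intensities must be finite numbers")
  if (any(voxels < 0))
    stop("voxel intensities must be >= 0")
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0)
    stop("`voxel_size_um` must be a single positive number (isotropic voxels)")
  structure(
    list(voxels = voxels, voxel_size_um = as.numeric(voxel_size_um),
         channel = as.character(channel)),
    class = "VolumeStack"
  )
}

#' @export
print.VolumeStack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("VolumeStack %d x %d x %d voxels (z,y,x), %.4g um/voxel%s\n",
              d[1], d[2], d[3], x$voxel_size_um,
              if (nzchar(x$channel)) paste0(", channel '", x$channel, "'") else ""))
  cat(sprintf("  intensity range [%.4g, %.4g], volume %.4g um^3\n",
              min(x$voxels), max(x$voxels), stack_volume_um3(x)))
  invisible(x)
}

#' Physical volume of a stack in cubic micrometres
#'
#' @param stack a [volume_stack()].
#' @return `prod(dim) * voxel_size^3`.
#' @export
stack_volume_um3 <- function(stack) {
  stopifnot(inherits(stack, "VolumeStack"))
  prod(dim(stack$voxels)) * stack$voxel_size_um^3
}

is_binary_array <- function(a) {
  is.array(a) && (is.logical(a) || all(a %in% c(0, 1)))
}
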