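#' Hessian tubeness score of a 3D stack
#'
#' Smooths the stack with an isotropic Gaussian of physical standard
#' deviation `sigma_um` and scores each voxel by the classical
#' bright-tube measure: with Hessian eigenvalues sorted by signed value
#' (e1 >= e2 >= e3), the score is `sqrt(e2 * e3)` where both e2 and e3
#' are negative, and 0 elsewhere. A bright tube on a dark background has
#' two strongly negative cross-sectional curvatures and one near-zero
#' axial curvature, so the score peaks on the tube midline. The default
#' scale, 0.32 um, targets neurites at the minimum axon diameter of
#' 0.32 um. Scores are multiplied by sigma^2 (in voxels) for standard
#' scale normalisation; only relative values matter downstream.
#'
#' @param stack a [volume_stack()].
#' @param sigma_um Gaussian scale, um; must be at least the voxel size
#'   (smaller scales are undersampled).
#' @return list of class `TubenessMap`: `score` (array, >= 0),
#'   `sigma_um`, `voxel_size_um`.
#' @export
tubeness <- function(stack, sigma_um = 0.32) {
  stopifnot(inherits(stack, "VolumeStack"))
  if (sigma_um < stack$voxel_size_um)
    stop("sigma_um (", sigma_um, ") is below the voxel size (",
         stack$voxel_size_um, "): scale undersampled")
  s_vox <- sigma_um / stack$voxel_size_um
  sm <- gaussian_smooth3(stack$voxels, s_vox)
  ev <- eigen_sym3(hessian3(sm))
  sc <- array(0, dim(sm))
  neg <- ev$e2 < 0 & ev$e3 < 0
  sc[neg] <- sqrt(ev$e2[neg] * ev$e3[neg]) * s_vox^2
  structure(list(score = sc, sigma_um = sigma_um,
                 voxel_size_um = stack$voxel_size_um),
            class = "TubenessMap")
}

#' Otsu threshold of the positive tubeness scores
#'
#' Computes Otsu's between-class-variance-maximising threshold over the
#' strictly positive scores (the zero class would otherwise dominate the
#' histogram). Used as the default seed (`high`) threshold.
#'
#' @param x numeric vector or array of scores.
#' @param nbins histogram bins.
#' @return threshold on the score scale (0 if no positive scores).
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  v <- x[x > 0]
  if (!length(v)) return(0)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- as.numeric(tabulate(findInterval(v, br, rightmost.closed = TRUE),
                           nbins))
  mids <- (br[-1] + br[-length(br)]) / 2
  w1 <- cumsum(h); w2 <- sum(h) - w1
  m1 <- cumsum(h * mids) / pmax(w1, 1)
  m2 <- (sum(h * mids) - cumsum(h * mids)) / pmax(w2, 1)
  bcv <- w1 * w2 * (m1 - m2)^2
  bcv[w1 == 0 | w2 == 0] <- -Inf
  mids[which.max(bcv)]
}

#' Two-level (hysteresis) thresholding of a tubeness map
#'
#' Voxels scoring at least `high` (and strictly above 0) seed the
#' foreground; voxels scoring at least `low` are kept when 26-connected
#' to a seed. `low == high` degenerates to a simple threshold. Defaults
#' are data-driven: `high` from [otsu_threshold()], `low = 0.5 * high`.
#'
#' @param map a [tubeness()] result.
#' @param low,high thresholds with `0 <= low <= high`; `NULL` for the
#'   data-driven defaults.
#' @return logical array (foreground mask), with attribute `thresholds`.
#' @export
threshold_tubeness <- function(map, low = NULL, high = NULL) {
  stopifnot(inherits(map, "TubenessMap"))
  if (is.null(high)) high <- otsu_threshold(map$score)
  if (is.null(low)) low <- 0.5 * high
  if (low < 0 || low > high) stop("need 0 <= low <= high")
  fg <- .hysteresis_cpp(as.numeric(map$score), dim(map$score),
                        as.numeric(low), as.numeric(high))
  attr(fg, "thresholds") <- c(low = low, high = high)
  fg
}

#' Topology-preserving 3D skeletonization
#'
#' Thins a binary volume to a one-voxel-wide curve skeleton by iterative
#' directional peeling of simple points (border voxels whose removal
#' changes neither the 26-connectivity of the foreground nor the
#' 6-connectivity of the background in their neighbourhood), with curve
#' endpoints preserved. The operation is idempotent and keeps the number
#' of connected components and holes of the foreground.
#'
#' @param mask logical (or 0/1) 3D array.
#' @param voxel_size_um physical voxel size carried into the result.
#' @return list of class `Skeleton`: `mask` (logical array), `voxel_size_um`.
#' @export
skeletonize <- function(mask, voxel_size_um) {
  if (!is_binary_array(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a binary 3D array")
  m <- .thin3d_cpp(array(as.logical(mask), dim(mask)), dim(mask))
  structure(list(mask = m, voxel_size_um = voxel_size_um),
            class = "Skeleton")
}

#' Total skeleton length in micrometres
#'
#' Sums, over every unique pair of 26-adjacent skeleton voxels, the step
#' length: voxel size times 1, sqrt(2) or sqrt(3) for face, edge and
#' corner adjacency. Each pair is counted once (a graph-edge sum), so an
#' isolated voxel contributes 0.
#'
#' @param sk a [skeletonize()] result, or a binary 3D array (then
#'   `voxel_size_um` must be given).
#' @param voxel_size_um voxel size when `sk` is a plain array.
#' @return total length, um.
#' @export
skeleton_length <- function(sk, voxel_size_um = NULL) {
  if (inherits(sk, "Skeleton")) {
    m <- sk$mask; voxel <- sk$voxel_size_um
  } else {
    if (is.null(voxel_size_um)) stop("`voxel_size_um` required for raw masks")
    m <- array(as.logical(sk), dim(sk)); voxel <- voxel_size_um
  }
  d <- dim(m)
  total <- 0
  # the 13 half-space offsets enumerate each unique 26-neighbour pair once
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    if (dz < 0 || (dz == 0 && (dy < 0 || (dy == 0 && dx <= 0)))) next
    iz <- seq_len(d[1] - dz); jz <- iz + dz
    iy <- if (dy >= 0) seq_len(d[2] - dy) else seq(1 - dy, d[2])
    jy <- iy + dy
    ix <- if (dx >= 0) seq_len(d[3] - dx) else seq(1 - dx, d[3])
    jx <- ix + dx
    if (!length(iz) || !length(iy) || !length(ix)) next
    npair <- sum(m[iz, iy, ix, drop = FALSE] & m[jz, jy, jx, drop = FALSE])
    total <- total + npair * sqrt(dz^2 + dy^2 + dx^2)
  }
  total * voxel
}

#' End-to-end axon density of a z-stack
#'
#' Runs the full quantification chain: optional bouton removal (when a
#' trained classifier is supplied), tubeness at `sigma_um`, hysteresis
#' thresholding, skeletonization, total length, and density = length
#' divided by the physical stack volume.
#'
#' @param stack a [volume_stack()].
#' @param classifier optional [train_bouton_classifier()] model; `NULL`
#'   skips bouton removal.
#' @param sigma_um tubeness scale, um.
#' @param low,high thresholds for [threshold_tubeness()] (`NULL` =
#'   data-driven).
#' @param keep_intermediates if `TRUE` the returned object carries the
#'   tubeness map, mask and skeleton.
#' @return list of class `DensityResult`: `total_length_um`,
#'   `stack_volume_um3`, `density_um_per_um3`, `config` and (optionally)
#'   `intermediates`.
#' @export
axon_density <- function(stack, classifier = NULL, sigma_um = 0.32,
                         low = NULL, high = NULL,
                         keep_intermediates = FALSE) {
  stopifnot(inherits(stack, "VolumeStack"))
  work <- stack
  if (!is.null(classifier)) {
    mask <- withCallingHandlers(
      segment_boutons(stack, classifier),
      error = function(e) stop("bouton-removal stage: ", conditionMessage(e),
                               call. = FALSE))
    work <- remove_boutons(stack, mask)
  }
  tm <- tubeness(work, sigma_um)
  fg <- threshold_tubeness(tm, low = low, high = high)
  sk <- skeletonize(fg, stack$voxel_size_um)
  len <- skeleton_length(sk)
  vol <- stack_volume_um3(stack)
  res <- list(total_length_um = len, stack_volume_um3 = vol,
              density_um_per_um3 = len / vol,
              config = list(sigma_um = sigma_um,
                            thresholds = attr(fg, "thresholds"),
                            bouton_removal = !is.null(classifier),
                            voxel_size_um = stack$voxel_size_um))
  if (keep_intermediates)
    res$intermediates <- list(tubeness = tm, foreground = fg, skeleton = sk)
  structure(res, class = "DensityResult")
}

#' @export
print.DensityResult <- function(x, ...) {
  cat(sprintf("Axon density: %.4g um / um^3 (length %.4g um in %.4g um^3)\n",
              x$density_um_per_um3, x$total_length_um, x$stack_volume_um3))
  invisible(x)
}
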