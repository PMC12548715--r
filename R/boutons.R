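#' Per-voxel feature stack for trainable segmentation
#'
#' Computes, for every voxel, the hand-crafted feature menu used by
#' trainable voxel classifiers on fluorescence stacks: raw intensity,
#' 3^3-neighbourhood mean and variance, gradient magnitude, Laplacian,
#' difference of Gaussians and a third-derivative magnitude (all at the
#' first scale), plus the three Hessian eigenvalues (sorted ascending) at
#' every requested scale. The feature count is therefore
#' `7 + 3 * length(scales_um)`. All filters use mirrored boundaries.
#'
#' @param stack a [volume_stack()].
#' @param scales_um smoothing scales in um, each at least the voxel size;
#'   `NULL` uses 1, 2 and 4 voxels.
#' @return list of class `FeatureStack`: `features` (voxels x features
#'   matrix), `feature_names`, `dim`, `scales_um`, `voxel_size_um`.
#' @export
compute_feature_stack <- function(stack, scales_um = NULL) {
  stopifnot(inherits(stack, "VolumeStack"))
  voxel <- stack$voxel_size_um
  if (is.null(scales_um)) scales_um <- voxel * c(1, 2, 4)
  if (!length(scales_um)) stop("`scales_um` must be non-empty")
  if (any(scales_um < voxel))
    stop("smoothing scales below the voxel size are undersampled")
  a <- stack$voxels
  d <- dim(a)
  for (s in scales_um) {
    r <- max(1L, ceiling(4 * s / voxel))
    if (min(d) < r + 1L)
      stop(sprintf("stack extent %d is too small for scale %.3g um (kernel half-width %d voxels)",
                   min(d), s, r))
  }
  s1 <- scales_um[1] / voxel
  sm1 <- gaussian_smooth3(a, s1)
  g1 <- conv_axis3(sm1, D1, 1); g2 <- conv_axis3(sm1, D1, 2)
  g3 <- conv_axis3(sm1, D1, 3)
  h <- hessian3(sm1)
  # third derivative along each axis (derivative of the second difference)
  t1 <- conv_axis3(h$h11, D1, 1); t2 <- conv_axis3(h$h22, D1, 2)
  t3 <- conv_axis3(h$h33, D1, 3)
  feats <- list(
    raw = a,
    nbhd_mean = box_mean3(a),
    nbhd_var = box_var3(a),
    gradmag = sqrt(g1^2 + g2^2 + g3^2),
    laplacian = h$h11 + h$h22 + h$h33,
    dog = sm1 - gaussian_smooth3(a, 1.6 * s1),
    d3mag = sqrt(t1^2 + t2^2 + t3^2)
  )
  for (i in seq_along(scales_um)) {
    sv <- scales_um[i] / voxel
    ev <- eigen_sym3(hessian3(gaussian_smooth3(a, sv)))
    feats[[sprintf("hess_ev1_s%d", i)]] <- ev$e3  # ascending order
    feats[[sprintf("hess_ev2_s%d", i)]] <- ev$e2
    feats[[sprintf("hess_ev3_s%d", i)]] <- ev$e1
  }
  fm <- vapply(feats, as.numeric, numeric(length(a)))
  structure(list(features = fm, feature_names = colnames(fm), dim = d,
                 scales_um = scales_um, voxel_size_um = voxel),
            class = "FeatureStack")
}

#' Train a random-forest voxel classifier for boutons
#'
#' Fits a random-forest ensemble on the labeled voxels of a feature
#' stack. Labels are sparse: unlabeled voxels (`NA`) are ignored. Three
#' classes are supported (`bouton`, `axon`, `background`); at least two
#' must be present.
#'
#' @param features a [compute_feature_stack()] result.
#' @param labels character (or factor) vector/array with one entry per
#'   voxel; `NA` = unlabeled.
#' @param num_trees forest size (default 100).
#' @param seed integer seed making training reproducible.
#' @return list of class `BoutonClassifier`: `model` (ranger forest),
#'   `feature_names`, `scales_um`, `classes`, `seed`.
#' @export
train_bouton_classifier <- function(features, labels, num_trees = 100L,
                                    seed = 1L) {
  stopifnot(inherits(features, "FeatureStack"))
  labels <- as.character(labels)
  if (length(labels) != nrow(features$features))
    stop("`labels` must have one entry per voxel")
  keep <- !is.na(labels)
  if (!any(keep)) stop("no labeled voxels")
  cls <- sort(unique(labels[keep]))
  if (length(cls) < 2L)
    stop("need at least two label classes, got: ", paste(cls, collapse = ", "))
  df <- as.data.frame(features$features[keep, , drop = FALSE])
  df$.class <- factor(labels[keep], levels = cls)
  fit <- ranger::ranger(
    dependent.variable.name = ".class", data = df,
    num.trees = num_trees, seed = seed,
    num.threads = 1L, verbose = FALSE
  )
  structure(list(model = fit, feature_names = features$feature_names,
                 scales_um = features$scales_um, classes = cls,
                 seed = as.integer(seed)),
            class = "BoutonClassifier")
}

#' Segment bouton voxels with a trained classifier
#'
#' Recomputes the feature stack at the classifier's training scales and
#' predicts a class per voxel. The returned mask follows the
#' multiply-to-remove convention: 0 where the predicted class is
#' `bouton`, 1 elsewhere.
#'
#' @param stack a [volume_stack()].
#' @param classifier a [train_bouton_classifier()] model.
#' @return integer 0/1 array of class `BoutonMask`, same shape as the
#'   stack.
#' @export
segment_boutons <- function(stack, classifier) {
  stopifnot(inherits(stack, "VolumeStack"),
            inherits(classifier, "BoutonClassifier"))
  fs <- compute_feature_stack(stack, classifier$scales_um)
  if (!identical(fs$feature_names, classifier$feature_names))
    stop("feature configuration mismatch between stack and classifier")
  pred <- stats::predict(classifier$model,
                         data = as.data.frame(fs$features),
                         num.threads = 1L,
                         seed = classifier$seed)$predictions
  mask <- array(as.integer(pred != "bouton"), dim(stack$voxels))
  class(mask) <- c("BoutonMask", class(mask))
  mask
}

#' Zero out bouton voxels
#'
#' Multiplies the stack by a 0/1 mask (0 = bouton), yielding a
#' bouton-free stack; voxel size and channel are preserved. Never
#' increases any intensity.
#'
#' @param stack a [volume_stack()].
#' @param mask binary array of the same shape (0 = remove, 1 = keep).
#' @return a [volume_stack()].
#' @export
remove_boutons <- function(stack, mask) {
  stopifnot(inherits(stack, "VolumeStack"))
  if (!identical(dim(stack$voxels), dim(mask)))
    stop("stack and mask shapes differ")
  m <- array(as.numeric(mask), dim(mask))
  if (!all(m %in% c(0, 1))) stop("mask must be binary")
  volume_stack(stack$voxels * m, stack$voxel_size_um, stack$channel)
}

# set TRUE inside a sphere of `radius_um` around `center_um` (world um)
mark_sphere <- function(arr, center_um, radius_um, voxel) {
  d <- dim(arr)
  cv <- center_um / voxel + 1
  r <- ceiling(radius_um / voxel)
  rng <- lapply(1:3, function(ax)
    seq(max(1L, floor(cv[ax] - r)), min(d[ax], ceiling(cv[ax] + r))))
  if (any(lengths(rng) == 0L)) return(arr)
  dz <- (rng[[1]] - cv[1]) * voxel
  dy <- (rng[[2]] - cv[2]) * voxel
  dx <- (rng[[3]] - cv[3]) * voxel
  d2 <- outer(outer(dz^2, dy^2, `+`), dx^2, `+`)
  arr[rng[[1]], rng[[2]], rng[[3]]] <-
    arr[rng[[1]], rng[[2]], rng[[3]]] | (d2 <= radius_um^2)
  arr
}

#' Voxel labels from synthetic ground truth
#'
#' Builds a sparse training label array (`bouton` / `axon` /
#' `background`, `NA` elsewhere) from the ground truth of a
#' [generate_axon_stack()] simulation: bouton spheres become `bouton`,
#' the tube interior (outside boutons) becomes `axon`, and voxels far
#' from any structure become `background` (randomly subsampled to
#' `max_per_class`).
#'
#' @param truth `GroundTruth` from [generate_axon_stack()].
#' @param stack_shape voxel counts of the rendered stack.
#' @param axon_radius_um tube radius used in the simulation.
#' @param bouton_label_factor bouton voxels are labeled out to this
#'   multiple of the nominal bouton radius, so the class covers the whole
#'   visible (blur-skirted) swelling rather than just its core — leaving
#'   the bright skirt unlabeled would let removal carve shell artifacts.
#' @param max_per_class cap on labeled voxels per class.
#' @param seed seed for the background subsample.
#' @return character array (`stack_shape`) with sparse labels.
#' @export
labels_from_truth <- function(truth, stack_shape, axon_radius_um = 0.16,
                              bouton_label_factor = 1.5,
                              max_per_class = 3000L, seed = 1L) {
  stopifnot(inherits(truth, "GroundTruth"))
  voxel <- truth$voxel_size_um
  boutonM <- array(FALSE, stack_shape)
  if (nrow(truth$boutons))
    for (i in seq_len(nrow(truth$boutons)))
      boutonM <- mark_sphere(boutonM,
                             unlist(truth$boutons[i, c("z", "y", "x")]),
                             bouton_label_factor *
                               truth$boutons$radius_um[i], voxel)
  tubeM <- array(FALSE, stack_shape)
  nearM <- array(FALSE, stack_shape)
  for (cl in truth$centerlines) {
    dense <- resample_polyline(cl, voxel / 2)
    for (i in seq_len(nrow(dense))) {
      tubeM <- mark_sphere(tubeM, dense[i, ], axon_radius_um, voxel)
      nearM <- mark_sphere(nearM, dense[i, ], 4 * axon_radius_um, voxel)
    }
  }
  if (nrow(truth$boutons))
    for (i in seq_len(nrow(truth$boutons)))
      nearM <- mark_sphere(nearM, unlist(truth$boutons[i, c("z", "y", "x")]),
                           2 * truth$boutons$radius_um[i], voxel)
  lab <- array(NA_character_, stack_shape)
  lab[!nearM] <- "background"
  lab[tubeM & !boutonM] <- "axon"
  lab[boutonM] <- "bouton"
  # subsample each class to keep training sparse and balanced
  set.seed(seed)
  for (cls in c("bouton", "axon", "background")) {
    idx <- which(lab == cls)
    if (length(idx) > max_per_class)
      lab[sample(idx, length(idx) - max_per_class)] <- NA_character_
  }
  lab
}
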