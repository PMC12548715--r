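# Shared fixtures, all generated in code.

# straight axis-aligned centerline of `n` voxel-spaced points along the
# third (x) axis, centred in a z/y cross-section
straight_centerline <- function(n = 100, voxel = 0.09, zy = c(0.9, 0.9),
                                x0 = 0.45) {
  cbind(rep(zy[1], n), rep(zy[2], n),
        seq(x0, by = voxel, length.out = n))
}

# noiseless, bouton-free rendering of given centerlines
render_clean <- function(centerlines, shape = c(20L, 20L, 110L),
                         voxel = 0.09) {
  p <- sim_params(stack_shape = shape, voxel_size_um = voxel, n_axons = 0L,
                  noise_sd = 0, bouton_rate_per_um = 0,
                  background_level = 0)
  generate_axon_stack(p, centerlines = centerlines)
}

# O(n^2) brute-force skeleton length: sum over all voxel pairs at
# Chebyshev distance 1 of the Euclidean step, counted once per pair
brute_skeleton_length <- function(mask, voxel) {
  pts <- which(mask, arr.ind = TRUE)
  n <- nrow(pts)
  if (n < 2L) return(0)
  tot <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d <- pts[j, ] - pts[i, ]
    if (max(abs(d)) == 1L) tot <- tot + sqrt(sum(d^2))
  }
  tot * voxel
}

# true bouton voxel mask at the nominal radius
true_bouton_mask <- function(truth, shape) {
  bm <- array(FALSE, shape)
  if (nrow(truth$boutons))
    for (i in seq_len(nrow(truth$boutons)))
      bm <- axonquant:::mark_sphere(
        bm, unlist(truth$boutons[i, c("z", "y", "x")]),
        truth$boutons$radius_um[i], truth$voxel_size_um)
  bm
}

# train the default bouton classifier on a small synthetic stack
train_fixture_classifier <- function(seed = 101L) {
  p <- sim_params(stack_shape = c(48L, 48L, 48L), n_axons = 2L,
                  noise_sd = 3, bouton_rate_per_um = 0.6, seed = seed)
  sim <- generate_axon_stack(p)
  lab <- labels_from_truth(sim$truth, dim(sim$stack$voxels), seed = 1L)
  fs <- compute_feature_stack(sim$stack)
  list(clf = train_bouton_classifier(fs, lab, seed = 1L), sim = sim,
       features = fs, labels = lab)
}
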