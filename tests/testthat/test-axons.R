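test_that("tubeness vanishes on constant stacks and rejects bad scales", {
  st <- volume_stack(array(3, c(16L, 16L, 16L)), 0.09)
  tm <- tubeness(st)
  expect_true(all(tm$score == 0))
  expect_error(tubeness(st, sigma_um = 0.05), "undersampled")
})

test_that("tubeness peaks on the centerline of a straight tube", {
  cl <- straight_centerline(80, zy = c(0.9, 0.9))
  sim <- render_clean(list(cl), shape = c(20L, 20L, 90L))
  tm <- tubeness(sim$stack)
  hits <- 0; total <- 0
  for (x in 15:75) {   # interior axial positions
    slice <- tm$score[, , x]
    am <- which(slice == max(slice), arr.ind = TRUE)[1, ]
    total <- total + 1
    if (max(abs(am - c(11, 11))) <= 1) hits <- hits + 1
  }
  expect_gte(hits / total, 0.95)
})

test_that("a tube outscores an isolated point of equal peak", {
  cl <- straight_centerline(80, zy = c(0.9, 0.9))
  tube <- render_clean(list(cl), shape = c(20L, 20L, 90L))
  pt <- array(0, c(20L, 20L, 90L))
  pt[11, 11, 45] <- max(tube$stack$voxels)
  point_stack <- volume_stack(pt, 0.09)
  tt <- tubeness(tube$stack); tp <- tubeness(point_stack)
  mean_tube <- mean(tt$score[11, 11, 15:75])
  expect_gt(mean_tube, max(tp$score))
})

test_that("tubeness matches a brute-force Hessian eigen computation", {
  cl <- straight_centerline(40, zy = c(0.9, 0.9))
  sim <- render_clean(list(cl), shape = c(20L, 20L, 50L))
  tm <- tubeness(sim$stack, sigma_um = 0.32)
  s_vox <- 0.32 / 0.09
  sm <- axonquant:::gaussian_smooth3(sim$stack$voxels, s_vox)
  for (vox in list(c(11L, 11L, 25L), c(13L, 11L, 25L), c(11L, 8L, 20L))) {
    i <- vox[1]; j <- vox[2]; k <- vox[3]
    H <- matrix(0, 3, 3)
    H[1, 1] <- sm[i - 1, j, k] - 2 * sm[i, j, k] + sm[i + 1, j, k]
    H[2, 2] <- sm[i, j - 1, k] - 2 * sm[i, j, k] + sm[i, j + 1, k]
    H[3, 3] <- sm[i, j, k - 1] - 2 * sm[i, j, k] + sm[i, j, k + 1]
    H[1, 2] <- H[2, 1] <- (sm[i + 1, j + 1, k] - sm[i + 1, j - 1, k] -
                             sm[i - 1, j + 1, k] + sm[i - 1, j - 1, k]) / 4
    H[1, 3] <- H[3, 1] <- (sm[i + 1, j, k + 1] - sm[i + 1, j, k - 1] -
                             sm[i - 1, j, k + 1] + sm[i - 1, j, k - 1]) / 4
    H[2, 3] <- H[3, 2] <- (sm[i, j + 1, k + 1] - sm[i, j + 1, k - 1] -
                             sm[i, j - 1, k + 1] + sm[i, j - 1, k - 1]) / 4
    ev <- sort(eigen(H, symmetric = TRUE)$values, decreasing = TRUE)
    want <- if (ev[2] < 0 && ev[3] < 0) sqrt(ev[2] * ev[3]) * s_vox^2 else 0
    expect_equal(tm$score[i, j, k], want, tolerance = 1e-8)
  }
})

test_that("tubeness is rotation-equivariant on straight tubes", {
  cl_x <- straight_centerline(60, zy = c(1.35, 1.35))
  sim_x <- render_clean(list(cl_x), shape = c(30L, 30L, 70L))
  cl_z <- cbind(seq(0.45, by = 0.09, length.out = 60),
                rep(1.35, 60), rep(1.35, 60))
  sim_z <- render_clean(list(cl_z), shape = c(70L, 30L, 30L))
  mx <- mean(tubeness(sim_x$stack)$score[16, 16, 15:55])
  mz <- mean(tubeness(sim_z$stack)$score[15:55, 16, 16])
  expect_lt(abs(mx - mz) / mx, 0.10)
})

test_that("hysteresis thresholding follows the flood-fill contract", {
  # 5^3 fixture: plateau >= high, attached skirt >= low, detached skirt
  sc <- array(0, c(5L, 5L, 5L))
  sc[2, 2, 2] <- 10; sc[2, 2, 3] <- 10      # plateau (seeds)
  sc[2, 2, 4] <- 3; sc[2, 3, 4] <- 3        # skirt, 26-connected to seeds
  sc[5, 5, 5] <- 3                          # detached skirt voxel
  tm <- structure(list(score = sc, sigma_um = 0.32, voxel_size_um = 0.09),
                  class = "TubenessMap")
  fg <- threshold_tubeness(tm, low = 2, high = 5)
  # brute-force flood fill oracle: iterate dilation from seeds
  seed <- sc >= 5; reach <- sc >= 2
  keep <- seed
  repeat {
    grown <- keep
    idx <- which(keep, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        p <- idx[r, ] + c(dz, dy, dx)
        if (all(p >= 1) && all(p <= 5) && reach[p[1], p[2], p[3]])
          grown[p[1], p[2], p[3]] <- TRUE
      }
    }
    if (identical(grown, keep)) break
    keep <- grown
  }
  expect_identical(array(as.logical(fg), dim(fg)), keep)
  expect_false(fg[5, 5, 5])
  # degenerate settings
  expect_error(threshold_tubeness(tm, low = 6, high = 5), "low <= high")
  empty <- threshold_tubeness(
    structure(list(score = array(0, c(4L, 4L, 4L)), sigma_um = 0.32,
                   voxel_size_um = 0.09), class = "TubenessMap"),
    low = 0, high = 0)
  expect_false(any(empty))
  above <- threshold_tubeness(tm, low = max(sc) + 1, high = max(sc) + 1)
  expect_false(any(above))
})

test_that("raising the low threshold never grows the foreground", {
  set.seed(5)
  sc <- array(runif(10^3), c(10L, 10L, 10L))
  tm <- structure(list(score = sc, sigma_um = 0.32, voxel_size_um = 0.09),
                  class = "TubenessMap")
  high <- 0.9
  counts <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9), function(lo)
    sum(threshold_tubeness(tm, low = lo, high = high)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("skeletonization thins a thick bar to its midline", {
  m <- array(FALSE, c(9L, 9L, 40L))
  m[4:6, 4:6, 3:38] <- TRUE
  sk <- skeletonize(m, 0.09)
  expect_true(all(sk$mask[sk$mask] %in% TRUE))
  pts <- which(sk$mask, arr.ind = TRUE)
  # single-voxel-wide straight line along the bar axis
  expect_true(all(pts[, 1] == 5) && all(pts[, 2] == 5))
  expect_equal(sort(unique(pts[, 3])), 3:38)
  # idempotent
  sk2 <- skeletonize(sk$mask, 0.09)
  expect_identical(sk2$mask, sk$mask)
})

test_that("skeletonization preserves topology (empty mask, torus cycle)", {
  expect_equal(sum(skeletonize(array(FALSE, c(5L, 5L, 5L)), 0.09)$mask), 0)
  # solid torus: skeleton must keep exactly one cycle
  d <- c(7L, 21L, 21L)
  m <- array(FALSE, d)
  for (i in 1:7) for (j in 1:21) for (k in 1:21) {
    rad <- sqrt((j - 11)^2 + (k - 11)^2)
    m[i, j, k] <- (rad - 6)^2 + (i - 4)^2 <= 2^2
  }
  sk <- skeletonize(m, 0.09)$mask
  pts <- which(sk, arr.ind = TRUE)
  V <- nrow(pts)
  E <- 0
  for (a in seq_len(V - 1L)) for (b in (a + 1L):V)
    if (max(abs(pts[b, ] - pts[a, ])) == 1L) E <- E + 1
  C <- max(axonquant:::.label26_cpp(sk, dim(sk)))
  expect_equal(C, 1L)
  expect_equal(E - V + C, 1L)   # one independent cycle survives thinning
})

test_that("non-binary masks are rejected", {
  expect_error(skeletonize(array(runif(27), c(3L, 3L, 3L)), 0.09),
               "binary")
})

test_that("skeleton length matches the analytic chain values", {
  d <- c(3L, 3L, 110L)
  axis_chain <- array(FALSE, d); axis_chain[2, 2, 1:100] <- TRUE
  expect_equal(skeleton_length(axis_chain, 0.09), 99 * 0.09,
               tolerance = 1e-9)
  diag_chain <- array(FALSE, c(12L, 12L, 12L))
  for (i in 1:10) diag_chain[i, i, i] <- TRUE
  expect_equal(skeleton_length(diag_chain, 0.09), 9 * 0.09 * sqrt(3),
               tolerance = 1e-9)
  # isolated voxels contribute nothing
  lone <- array(FALSE, c(5L, 5L, 5L)); lone[2, 2, 2] <- TRUE; lone[4, 4, 4] <- TRUE
  expect_equal(skeleton_length(lone, 0.09), 0)
})

test_that("skeleton length equals brute-force pair enumeration", {
  set.seed(13)
  for (rep in 1:5) {
    m <- array(runif(8^3) < 0.12, c(8L, 8L, 8L))
    expect_equal(skeleton_length(m, 0.09), brute_skeleton_length(m, 0.09),
                 tolerance = 1e-12)
  }
})

test_that("skeleton length is invariant under axis permutation", {
  set.seed(21)
  m <- array(runif(7 * 8 * 9) < 0.15, c(7L, 8L, 9L))
  l0 <- skeleton_length(m, 0.09)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1)))
    expect_equal(skeleton_length(aperm(m, perm), 0.09), l0,
                 tolerance = 1e-12)
})

test_that("blank stacks have zero axon density", {
  p <- sim_params(stack_shape = c(24L, 24L, 24L), n_axons = 0L,
                  noise_sd = 0, seed = 1L)
  sim <- generate_axon_stack(p)
  dr <- axon_density(sim$stack)
  expect_equal(dr$density_um_per_um3, 0)
  expect_equal(dr$stack_volume_um3, 24^3 * 0.09^3)
})

test_that("density recovers ground truth within the thinning tolerance", {
  p <- sim_params(stack_shape = c(64L, 64L, 64L), n_axons = 3L,
                  noise_sd = 0, bouton_rate_per_um = 0, seed = 3L)
  sim <- generate_axon_stack(p)
  dr <- axon_density(sim$stack)
  truth_density <- sim$truth$total_length_um / stack_volume_um3(sim$stack)
  expect_lt(abs(dr$density_um_per_um3 - truth_density) / truth_density,
            0.15)
})

test_that("density is invariant under content duplication (tiling)", {
  # tiling runs along x, so axons are kept away from the x faces: the
  # duplicated copies then cannot interact across the seam through the
  # smoothing kernel
  cls <- list(
    cbind(seq(0.3, 4.0, length.out = 80), seq(0.2, 4.1, length.out = 80),
          seq(1.9, 2.3, length.out = 80)),
    cbind(seq(3.9, 0.5, length.out = 80), seq(0.3, 4.0, length.out = 80),
          seq(2.4, 2.0, length.out = 80)))
  sim <- render_clean(cls, shape = c(48L, 48L, 48L))
  v <- sim$stack$voxels
  tiled <- volume_stack(array(c(v, v), c(48L, 48L, 96L)), 0.09)
  d1 <- axon_density(sim$stack)
  d2 <- axon_density(tiled)
  expect_lt(abs(d2$density_um_per_um3 / d1$density_um_per_um3 - 1), 0.02)
})

test_that("density scales linearly with simulated length", {
  p0 <- sim_params(stack_shape = c(64L, 64L, 64L), n_axons = 0L,
                   noise_sd = 0, bouton_rate_per_um = 0, seed = 2L)
  pL <- sim_params(stack_shape = c(64L, 64L, 64L), n_axons = 2L,
                   noise_sd = 0, bouton_rate_per_um = 0, seed = 2L)
  simL <- generate_axon_stack(pL)
  # 2L: the same axons plus an independent second pair in the same volume
  p2 <- sim_params(stack_shape = c(64L, 64L, 64L), n_axons = 2L,
                   noise_sd = 0, bouton_rate_per_um = 0, seed = 15L)
  sim2 <- generate_axon_stack(p2)
  both <- generate_axon_stack(p0, centerlines = c(simL$truth$centerlines,
                                                  sim2$truth$centerlines))
  dL <- axon_density(simL$stack)$density_um_per_um3
  dB <- axon_density(both$stack)$density_um_per_um3
  ratio_truth <- both$truth$total_length_um / simL$truth$total_length_um
  expect_lt(abs(dB / dL / ratio_truth - 1), 0.15)
})
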