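test_that("empty simulation yields pure background and zero length", {
  p <- sim_params(stack_shape = c(16L, 16L, 16L), n_axons = 0L,
                  noise_sd = 0, background_level = 7, seed = 3L)
  sim <- generate_axon_stack(p)
  expect_equal(sim$truth$total_length_um, 0)
  expect_true(all(sim$stack$voxels == 7))
  expect_equal(length(sim$truth$centerlines), 0L)
})

test_that("a straight axis-aligned centerline has the analytic length", {
  cl <- straight_centerline(100)
  sim <- render_clean(list(cl))
  expect_equal(sim$truth$total_length_um, 99 * 0.09, tolerance = 1e-12)
})

test_that("the simulation is a deterministic function of the seed", {
  p <- sim_params(stack_shape = c(24L, 24L, 24L), n_axons = 2L,
                  bouton_rate_per_um = 0.5, seed = 11L)
  a <- generate_axon_stack(p)
  b <- generate_axon_stack(p)
  expect_identical(a$stack$voxels, b$stack$voxels)
  expect_identical(a$truth, b$truth)
  c <- generate_axon_stack(sim_params(stack_shape = c(24L, 24L, 24L),
                                      n_axons = 2L,
                                      bouton_rate_per_um = 0.5,
                                      seed = 12L))
  expect_false(identical(a$stack$voxels, c$stack$voxels))
})

test_that("ground-truth invariants hold on random simulations", {
  for (sd in 1:5) {
    p <- sim_params(stack_shape = c(32L, 32L, 32L), n_axons = 3L,
                    bouton_rate_per_um = 1, seed = sd)
    sim <- generate_axon_stack(p)
    tr <- sim$truth
    # recorded total equals the sum of polyline segment lengths
    expect_equal(tr$total_length_um, polyline_length(tr$centerlines),
                 tolerance = 1e-9)
    # every bouton centre lies on (within its radius of) a centerline
    if (nrow(tr$boutons)) {
      for (i in seq_len(nrow(tr$boutons))) {
        ctr <- unlist(tr$boutons[i, c("z", "y", "x")])
        dmin <- min(vapply(tr$centerlines, function(cl) {
          dense <- axonquant:::resample_polyline(cl, 0.01)
          min(sqrt(colSums((t(dense) - ctr)^2)))
        }, numeric(1)))
        expect_lt(dmin, tr$boutons$radius_um[i])
      }
    }
  }
})

test_that("polyline length is invariant under rigid rotation", {
  set.seed(42)
  for (rep in 1:5) {
    pts <- matrix(rnorm(30), 10, 3)
    # random rotation via QR of a random matrix
    qr_ <- qr(matrix(rnorm(9), 3, 3))
    R <- qr.Q(qr_)
    expect_equal(polyline_length(pts %*% R), polyline_length(pts),
                 tolerance = 1e-6)
  }
})

test_that("rendered tubes are bright on dark (noiseless contract)", {
  cl <- straight_centerline(60)
  sim <- render_clean(list(cl), shape = c(24L, 24L, 70L))
  v <- sim$stack$voxels
  # on-centerline voxel vs voxel 3 radii away perpendicular
  on <- v[11, 11, 35]
  off <- v[11 + round(3 * 0.16 / 0.09) + 2, 11, 35]
  expect_gt(on, off)
  expect_gt(on, 0.9 * 200)
})

test_that("too-small stacks are rejected", {
  expect_error(generate_axon_stack(
    sim_params(stack_shape = c(3L, 3L, 3L), n_axons = 1L)),
    "too small")
})

test_that("region field reproduces the requested intensity levels", {
  # noiseless: exact
  f0 <- generate_region_field(shape = c(60L, 90L), noise_sd = 0)
  for (r in c("MDm", "transition", "core"))
    expect_equal(unique(f0$image[f0$labels == r]), unname(f0$levels[r]))
  # noisy: within 3 standard errors of the mean
  f1 <- generate_region_field(shape = c(200L, 300L),
                              intensity_levels = c(MDm = 10, transition = 20,
                                                   core = 40),
                              noise_sd = 1, seed = 5)
  for (r in c("MDm", "transition", "core")) {
    n <- sum(f1$labels == r)
    expect_lt(abs(mean(f1$image[f1$labels == r]) - f1$levels[r]),
              3 / sqrt(n))
  }
})

test_that("non-monotone region levels are flagged", {
  expect_warning(
    f <- generate_region_field(intensity_levels = c(MDm = 40,
                                                    transition = 20,
                                                    core = 10)),
    "not ordered")
  expect_true(f$nonmonotone)
})

test_that("degenerate multinomial puts all cells in one region", {
  tab <- generate_count_table(list(vGAT = c(A = 1.0)), totals = 100,
                              n_animals = 2L, seed = 1L)
  expect_true(all(tab$count[tab$region == "A"] == 100))
})

test_that("multinomial fractions converge at the binomial standard error", {
  tab <- generate_count_table(list(vGAT = c(A = 0.5, B = 0.5)),
                              totals = 10000, n_animals = 1L, seed = 2L)
  fa <- tab$count[tab$region == "A"] / 10000
  expect_lt(abs(fa - 0.5), 3 * sqrt(0.25 / 10000))
  # law of large numbers at growing totals
  for (tot in c(1e3, 1e5)) {
    t2 <- generate_count_table(list(g = c(A = 0.3, B = 0.6)), totals = tot,
                               n_animals = 1L, seed = 3L)
    pA <- t2$count[t2$region == "A"] / tot
    expect_lt(abs(pA - 0.3), 3 * sqrt(0.3 * 0.7 / tot))
  }
})

test_that("count tables are reproducible and validated", {
  fr <- list(vGAT = c(A = 0.4, B = 0.3), vGLUT2 = c(A = 0.2, C = 0.5))
  a <- generate_count_table(fr, totals = 400, n_animals = 3L, seed = 9L)
  b <- generate_count_table(fr, totals = 400, n_animals = 3L, seed = 9L)
  expect_identical(a, b)
  expect_error(generate_count_table(list(g = c(A = 0.7, B = 0.6)), 100),
               "sum to <= 1")
  expect_error(generate_count_table(list(g = c(A = -0.1)), 100),
               "non-negative")
  expect_error(generate_count_table(list(g = c(A = 0.5)), -5),
               "non-negative")
})
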