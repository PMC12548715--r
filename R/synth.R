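#' Simulation parameters for synthetic axon stacks
#'
#' Bundles the geometry, optics and noise settings used by
#' [generate_axon_stack()]. Defaults mirror the acquisition geometry the
#' pipeline is designed for: isotropic 0.09 um voxels and axons of
#' 0.32 um minimum diameter (radius 0.16 um), rendered as Gaussian-profile
#' tubes (cross-sectional sd = radius / 2, a diffraction-blur stand-in).
#'
#' @param stack_shape integer vector of 3 voxel counts (z, y, x).
#' @param voxel_size_um isotropic voxel edge, um.
#' @param n_axons number of random axons to draw (0 allowed).
#' @param axon_radius_um tube radius, um (default 0.16, diameter 0.32).
#' @param axon_peak_intensity peak tube intensity above background, AU.
#' @param bouton_rate_per_um Poisson rate of en passant boutons per um of
#'   arc length (0 disables boutons).
#' @param bouton_radius_um bouton radius, um.
#' @param bouton_peak_intensity peak bouton intensity above background, AU.
#' @param terminal_boutons if `TRUE`, one additional drumstick-like bouton
#'   is placed at each axon end.
#' @param background_level constant background offset, AU.
#' @param noise_sd Gaussian read-noise standard deviation, AU (0 = none).
#' @param poisson_scale photon scale for shot noise; 0 disables. When
#'   positive, voxel values v are replaced by `rpois(v * scale) / scale`.
#' @param tortuosity curvature scale of the random centerlines
#'   (standard deviation of the direction perturbation per um^(1/2);
#'   0 gives straight lines).
#' @param seed integer seed; the whole simulation is a deterministic
#'   function of it.
#'
#' @return a list of class `SimParams`.
#' @export
sim_params <- function(stack_shape = c(64L, 64L, 64L),
                       voxel_size_um = 0.09,
                       n_axons = 3L,
                       axon_radius_um = 0.16,
                       axon_peak_intensity = 200,
                       bouton_rate_per_um = 0.2,
                       bouton_radius_um = 0.4,
                       bouton_peak_intensity = 400,
                       terminal_boutons = FALSE,
                       background_level = 10,
                       noise_sd = 5,
                       poisson_scale = 0,
                       tortuosity = 0.3,
                       seed = 1L) {
  p <- list(stack_shape = as.integer(stack_shape),
            voxel_size_um = voxel_size_um, n_axons = as.integer(n_axons),
            axon_radius_um = axon_radius_um,
            axon_peak_intensity = axon_peak_intensity,
            bouton_rate_per_um = bouton_rate_per_um,
            bouton_radius_um = bouton_radius_um,
            bouton_peak_intensity = bouton_peak_intensity,
            terminal_boutons = isTRUE(terminal_boutons),
            background_level = background_level,
            noise_sd = noise_sd, poisson_scale = poisson_scale,
            tortuosity = tortuosity, seed = as.integer(seed))
  if (length(p$stack_shape) != 3L || any(p$stack_shape < 1L))
    stop("`stack_shape` must be three positive voxel counts")
  pos <- c("voxel_size_um", "axon_radius_um", "bouton_radius_um")
  for (f in pos) if (!is.finite(p[[f]]) || p[[f]] <= 0)
    stop(sprintf("`%s` must be strictly positive", f))
  nonneg <- c("axon_peak_intensity", "bouton_rate_per_um",
              "bouton_peak_intensity", "background_level", "noise_sd",
              "poisson_scale", "tortuosity")
  for (f in nonneg) if (!is.finite(p[[f]]) || p[[f]] < 0)
    stop(sprintf("`%s` must be non-negative", f))
  if (p$n_axons < 0L) stop("`n_axons` must be >= 0")
  structure(p, class = "SimParams")
}

#' Total length of a polyline (or list of polylines) in its own units
#'
#' @param pts an n x 3 matrix of points, or a list of such matrices.
#' @return sum of Euclidean segment lengths.
#' @export
polyline_length <- function(pts) {
  if (is.list(pts) && !is.matrix(pts))
    return(sum(vapply(pts, polyline_length, numeric(1))))
  if (is.null(pts) || nrow(pts) < 2L) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

# Smooth random centerline traversing the box [0, extent] (um): from a
# random interior start, a unit-speed walk runs in both directions, the
# direction receiving a Gaussian kick of sd = tortuosity * sqrt(step)
# per step, until it exits; the exit segment is clipped to the face so
# the polyline ends exactly on the stack boundary (axons cross the
# imaged volume rather than terminating inside it).
random_centerline <- function(extent_um, step_um, tortuosity,
                              max_steps = 10000L) {
  lo <- rep(0, 3); hi <- extent_um
  start <- lo + stats::runif(3) * (hi - lo)
  dir0 <- stats::rnorm(3); dir0 <- dir0 / sqrt(sum(dir0^2))
  kick <- tortuosity * sqrt(step_um)
  walk <- function(dir) {
    pts <- matrix(NA_real_, max_steps, 3)
    cur <- start
    n <- 0L
    repeat {
      dir <- dir + stats::rnorm(3, sd = kick)
      dir <- dir / sqrt(sum(dir^2))
      nxt <- cur + step_um * dir
      if (any(nxt < lo) || any(nxt > hi)) {
        # clip the final segment to the box face
        t_exit <- 1
        for (d in 1:3) {
          if (nxt[d] < lo[d]) t_exit <- min(t_exit, (lo[d] - cur[d]) / (nxt[d] - cur[d]))
          if (nxt[d] > hi[d]) t_exit <- min(t_exit, (hi[d] - cur[d]) / (nxt[d] - cur[d]))
        }
        if (t_exit > 0) {
          n <- n + 1L
          pts[n, ] <- cur + t_exit * (nxt - cur)
        }
        break
      }
      n <- n + 1L
      pts[n, ] <- nxt
      cur <- nxt
      if (n >= max_steps) break
    }
    pts[seq_len(n), , drop = FALSE]
  }
  fwd <- walk(dir0)
  bwd <- walk(-dir0)
  pts <- rbind(bwd[rev(seq_len(nrow(bwd))), , drop = FALSE],
               matrix(start, 1), fwd)
  pts
}

# Resample a polyline at roughly `step_um` spacing (keeps vertices' path).
resample_polyline <- function(pts, step_um) {
  if (nrow(pts) < 2L) return(pts)
  seg <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total == 0) return(pts[1, , drop = FALSE])
  t_new <- seq(0, total, by = step_um)
  if (t_new[length(t_new)] < total) t_new <- c(t_new, total)
  out <- matrix(NA_real_, length(t_new), 3)
  for (d in 1:3) out[, d] <- stats::approx(s, pts[, d], xout = t_new)$y
  out
}

# Stamp a Gaussian blob (max-combined) centred at `center_um` into `acc`.
stamp_blob <- function(acc, center_um, peak, sd_um, voxel, reach = 3) {
  d <- dim(acc)
  cv <- center_um / voxel + 1          # world um -> 1-based voxel coords
  r <- max(1L, ceiling(reach * sd_um / voxel))
  rng <- lapply(1:3, function(ax) {
    seq(max(1L, floor(cv[ax] - r)), min(d[ax], ceiling(cv[ax] + r)))
  })
  if (any(lengths(rng) == 0L)) return(acc)
  dz <- (rng[[1]] - cv[1]) * voxel
  dy <- (rng[[2]] - cv[2]) * voxel
  dx <- (rng[[3]] - cv[3]) * voxel
  d2 <- outer(outer(dz^2, dy^2, `+`), dx^2, `+`)
  blob <- peak * exp(-d2 / (2 * sd_um^2))
  acc[rng[[1]], rng[[2]], rng[[3]]] <-
    pmax(acc[rng[[1]], rng[[2]], rng[[3]]], blob)
  acc
}

#' Generate a synthetic axon stack with exact ground truth
#'
#' Renders Gaussian-profile tubes along smooth random 3D centerlines
#' (optionally with bouton swellings at Poisson-distributed arc positions)
#' into a background + noise volume, and records the exact centerlines,
#' total arc length and bouton list.
#'
#' Tube cross-sections are isotropic Gaussians with sd = `axon_radius_um / 2`
#' so the stated radius corresponds to the visible (~2 sd) extent of the
#' blurred neurite. Foreground is max-combined, then added to the
#' background before noise.
#'
#' @param params a [sim_params()] object.
#' @param centerlines optional list of n x 3 matrices (points in um,
#'   z/y/x order) to render instead of random centerlines; lengths and
#'   bouton placement then refer to these.
#' @return list with elements `stack` (a [volume_stack()]) and `truth`
#'   (class `GroundTruth`: `centerlines`, `total_length_um`, `boutons`
#'   data frame with columns z/y/x/radius_um, `voxel_size_um`).
#' @export
generate_axon_stack <- function(params, centerlines = NULL) {
  stopifnot(inherits(params, "SimParams"))
  voxel <- params$voxel_size_um
  extent <- (params$stack_shape - 1) * voxel  # centre-to-centre extent
  if ((params$n_axons > 0L || !is.null(centerlines)) &&
      any(extent < 4 * params$axon_radius_um))
    stop("stack too small to contain an axon of radius ",
         params$axon_radius_um, " um")
  set.seed(params$seed)

  if (is.null(centerlines)) {
    centerlines <- replicate(params$n_axons, random_centerline(
      extent, step_um = voxel / 2, tortuosity = params$tortuosity
    ), simplify = FALSE)
    centerlines <- Filter(function(m) nrow(m) >= 2L, centerlines)
  } else {
    centerlines <- lapply(centerlines, function(m) {
      m <- as.matrix(m)
      stopifnot(ncol(m) == 3L)
      m
    })
  }

  fg <- array(0, params$stack_shape)
  sd_tube <- params$axon_radius_um / 2
  boutons <- list()
  for (cl in centerlines) {
    dense <- resample_polyline(cl, voxel / 2)
    for (i in seq_len(nrow(dense)))
      fg <- stamp_blob(fg, dense[i, ], params$axon_peak_intensity,
                       sd_tube, voxel)
    # boutons: Poisson process along arc length, en passant
    len <- polyline_length(cl)
    pos <- numeric(0)
    if (params$bouton_rate_per_um > 0 && len > 0) {
      nb <- stats::rpois(1L, params$bouton_rate_per_um * len)
      pos <- sort(stats::runif(nb, 0, len))
    }
    if (params$terminal_boutons && len > 0) pos <- c(0, pos, len)
    if (length(pos)) {
      seg <- sqrt(rowSums(diff(cl)^2))
      s <- c(0, cumsum(seg))
      for (p in pos) {
        ctr <- vapply(1:3, function(d) stats::approx(s, cl[, d], xout = p)$y,
                      numeric(1))
        fg <- stamp_blob(fg, ctr, params$bouton_peak_intensity,
                         params$bouton_radius_um / 2, voxel)
        boutons[[length(boutons) + 1L]] <-
          c(ctr, radius_um = params$bouton_radius_um)
      }
    }
  }

  vox <- fg + params$background_level
  if (params$poisson_scale > 0)
    vox <- array(stats::rpois(length(vox), vox * params$poisson_scale) /
                   params$poisson_scale, dim(vox))
  if (params$noise_sd > 0)
    vox <- vox + array(stats::rnorm(length(vox), sd = params$noise_sd),
                       dim(vox))
  vox <- pmax(vox, 0)

  bt <- if (length(boutons)) {
    m <- do.call(rbind, boutons)
    data.frame(z = m[, 1], y = m[, 2], x = m[, 3], radius_um = m[, 4])
  } else data.frame(z = numeric(0), y = numeric(0), x = numeric(0),
                    radius_um = numeric(0))
  truth <- structure(
    list(centerlines = centerlines,
         total_length_um = polyline_length(centerlines),
         boutons = bt, voxel_size_um = voxel),
    class = "GroundTruth"
  )
  list(stack = volume_stack(vox, voxel, channel = "synthetic"),
       truth = truth)
}

#' Synthetic region-intensity field (MDm / transition zone / core)
#'
#' Emulates a calretinin-like intensity gradient across three abutting
#' regions: a 2D image whose per-region mean intensities equal the given
#' levels (plus optional Gaussian noise) together with the exact label
#' map. Default geometry is three vertical bands, MDm | transition | core,
#' of equal width.
#'
#' @param shape c(ny, nx) pixel counts.
#' @param intensity_levels named numeric `c(MDm=, transition=, core=)`.
#'   The expected ordering is core > transition > MDm; a non-monotone set
#'   is accepted for negative-control experiments but flagged via the
#'   `nonmonotone` attribute and a warning.
#' @param noise_sd Gaussian noise sd (0 = noiseless).
#' @param pixel_size_um physical pixel size, um.
#' @param labels optional custom label matrix (values in
#'   MDm/transition/core/none) overriding the band geometry.
#' @param seed integer seed.
#' @return list of class `RegionField`: `image` (matrix), `labels`
#'   (character matrix), `pixel_size_um`, `levels`.
#' @export
generate_region_field <- function(shape = c(300L, 450L),
                                  intensity_levels = c(MDm = 10, transition = 20, core = 40),
                                  noise_sd = 0, pixel_size_um = 1,
                                  labels = NULL, seed = 1L) {
  need <- c("MDm", "transition", "core")
  if (!all(need %in% names(intensity_levels)))
    stop("`intensity_levels` must be named MDm, transition, core")
  lv <- intensity_levels[need]
  nonmono <- !(lv["core"] > lv["transition"] && lv["transition"] > lv["MDm"])
  if (nonmono)
    warning("intensity levels are not ordered core > transition > MDm")
  if (is.null(labels)) {
    ny <- shape[1]; nx <- shape[2]
    third <- ceiling(nx / 3)
    labels <- matrix("core", ny, nx)
    labels[, seq_len(min(third, nx))] <- "MDm"
    if (third + 1 <= nx)
      labels[, (third + 1):min(2 * third, nx)] <- "transition"
  }
  img <- matrix(0, nrow(labels), ncol(labels))
  for (r in need) img[labels == r] <- lv[[r]]
  if (noise_sd > 0) {
    set.seed(seed)
    img <- img + matrix(stats::rnorm(length(img), sd = noise_sd),
                        nrow(img), ncol(img))
  }
  structure(list(image = img, labels = labels,
                 pixel_size_um = pixel_size_um, levels = lv,
                 nonmonotone = nonmono),
            class = "RegionField")
}

#' Synthetic retrograde cell-count table
#'
#' Draws per-animal region counts from a multinomial with the given
#' per-genotype region fractions; mass not assigned to a named region
#' goes to a "scattered" remainder category.
#'
#' @param fractions named list, one element per genotype (e.g. `vGAT`,
#'   `vGLUT2`), each a named numeric vector of region fractions in
#'   \[0, 1\] summing to <= 1.
#' @param totals total labeled cells per animal: a single number, a
#'   vector recycled across animals, or a named list per genotype.
#' @param n_animals animals per genotype.
#' @param seed integer seed.
#' @return a [cell_count_table()] data frame
#'   (region, animal, genotype, count, excluded).
#' @export
generate_count_table <- function(fractions, totals, n_animals = 3L,
                                 seed = 1L) {
  stopifnot(is.list(fractions), length(fractions) >= 1L)
  if (any(unlist(fractions) < 0)) stop("fractions must be non-negative")
  if (any(vapply(fractions, sum, numeric(1)) > 1 + 1e-12))
    stop("fractions must sum to <= 1 per genotype")
  set.seed(seed)
  rows <- list()
  for (g in names(fractions)) {
    fr <- fractions[[g]]
    tot <- if (is.list(totals)) totals[[g]] else totals
    if (any(tot < 0)) stop("totals must be non-negative")
    tot <- rep_len(tot, n_animals)
    p <- c(fr, scattered = max(0, 1 - sum(fr)))
    for (a in seq_len(n_animals)) {
      cnt <- as.vector(stats::rmultinom(1L, round(tot[a]), p))
      rows[[length(rows) + 1L]] <- data.frame(
        region = names(p), animal = sprintf("%s_%d", g, a),
        genotype = g, count = cnt, excluded = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  cell_count_table(tab[tab$region != "scattered" | tab$count > 0, ])
}

#' Listed-region input fractions of the PVT afferent map
#'
#' The per-region mean percentages of retrogradely labeled cells (relative
#' to all subcortical labeled cells) for the regions above the 3 percent
#' reporting threshold, per genotype. These printed values are used as a
#' realistic generating profile for synthetic count tables and as the
#' worked arithmetic example for coverage summaries.
#'
#' @return named list with numeric vectors `vGLUT2` and `vGAT`
#'   (percentages).
#' @export
pvt_input_fractions <- function() {
  list(
    vGLUT2 = c(MnPO = 4.35, SUM = 4.92, PSTh = 3.60, PPTg = 5.1,
               MPL = 8.44, LPB = 14.49, AntMedAmy = 5.57, POA = 8.85,
               PAG = 16.13, DpMe = 6.30),
    vGAT = c(BNST = 10.95, LH = 12.53, DM = 4.70, TRN = 9.53, ZI = 7.54,
             DR = 6.04, AntMedAmy = 3.79, POA = 3.54, PAG = 8.58,
             DpMe = 11.43)
  )
}
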