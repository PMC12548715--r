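# Separable 3D filtering with mirrored boundaries, Hessians and the
# closed-form eigenvalues of symmetric 3x3 matrices, vectorised over voxels.
# These are the low-level primitives behind the feature stack and the
# tubeness score; everything operates in voxel units and callers convert
# physical scales (um) to voxels.

mirror_index <- function(n, r) {
  # index vector implementing reflect-without-repeat padding of width r
  if (n == 1L) return(rep(1L, n + 2L * r))
  left <- pmin(pmax(seq(r + 1L, 2L, by = -1L), 1L), n)
  right <- pmin(pmax(seq(n - 1L, n - r, by = -1L), 1L), n)
  c(left, seq_len(n), right)
}

# 1D convolution along one axis of a 3D array, mirrored boundary.
conv_axis3 <- function(a, kernel, axis) {
  stopifnot(length(dim(a)) == 3L, length(kernel) %% 2L == 1L)
  r <- (length(kernel) - 1L) %/% 2L
  if (r == 0L) return(a * kernel)
  perm <- switch(axis, `1` = c(1L, 2L, 3L), `2` = c(2L, 1L, 3L),
                 `3` = c(3L, 1L, 2L))
  ap <- aperm(a, perm)
  d <- dim(ap)
  if (d[1] < r + 1L)
    stop(sprintf("array extent %d along axis %d is too small for a kernel of half-width %d",
                 d[1], axis, r))
  pad <- ap[mirror_index(d[1], r), , , drop = FALSE]
  out <- array(0, d)
  for (k in seq_along(kernel)) {
    if (kernel[k] == 0) next
    out <- out + kernel[k] * pad[k:(k + d[1] - 1L), , , drop = FALSE]
  }
  aperm(out, order(perm))
}

gaussian_kernel <- function(sigma_vox) {
  stopifnot(sigma_vox > 0)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- stats::dnorm(seq(-r, r), sd = sigma_vox)
  k / sum(k)
}

#' Separable Gaussian smoothing of a 3D array
#'
#' @param a 3D numeric array.
#' @param sigma_vox Gaussian standard deviation in voxels (scalar).
#' @return smoothed array, same shape; boundaries are mirrored.
#' @keywords internal
gaussian_smooth3 <- function(a, sigma_vox) {
  k <- gaussian_kernel(sigma_vox)
  for (ax in 1:3) a <- conv_axis3(a, k, ax)
  a
}

D1 <- c(-0.5, 0, 0.5)   # central first difference
D2 <- c(1, -2, 1)       # central second difference

# All six unique Hessian components of a (pre-smoothed) 3D array, by
# central finite differences in voxel units.
hessian3 <- function(a) {
  g1 <- conv_axis3(a, D1, 1); g2 <- conv_axis3(a, D1, 2); g3 <- conv_axis3(a, D1, 3)
  list(
    h11 = conv_axis3(a, D2, 1),
    h22 = conv_axis3(a, D2, 2),
    h33 = conv_axis3(a, D2, 3),
    h12 = conv_axis3(g1, D1, 2),
    h13 = conv_axis3(g1, D1, 3),
    h23 = conv_axis3(g2, D1, 3)
  )
}

# Eigenvalues of symmetric 3x3 matrices, vectorised; returns a list
# (e1 >= e2 >= e3) of arrays shaped like the inputs. Trigonometric
# closed form; degenerate (near-spherical) tensors fall back to the
# triple eigenvalue q = trace/3.
eigen_sym3 <- function(h) {
  q <- (h$h11 + h$h22 + h$h33) / 3
  p1 <- h$h12^2 + h$h13^2 + h$h23^2
  p2 <- (h$h11 - q)^2 + (h$h22 - q)^2 + (h$h33 - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  b11 <- h$h11 - q; b22 <- h$h22 - q; b33 <- h$h33 - q
  detB <- b11 * (b22 * b33 - h$h23^2) -
    h$h12 * (h$h12 * b33 - h$h23 * h$h13) +
    h$h13 * (h$h12 * h$h23 - b22 * h$h13)
  ok <- p > 0
  r <- array(0, dim(q))
  r[ok] <- pmin(pmax(detB[ok] / (2 * p[ok]^3), -1), 1)
  phi <- acos(r) / 3
  e1 <- q + 2 * p * cos(phi)
  e3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  e2 <- 3 * q - e1 - e3
  dm <- dim(q)
  list(e1 = array(e1, dm), e2 = array(e2, dm), e3 = array(e3, dm))
}

# 3^3 box mean / variance (population variance, clamped at 0).
box_mean3 <- function(a) {
  k <- rep(1 / 3, 3)
  for (ax in 1:3) a <- conv_axis3(a, k, ax)
  a
}
box_var3 <- function(a) {
  m <- box_mean3(a)
  pmax(box_mean3(a^2) - m^2, 0)
}
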