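# Low-level grid sampling, rotation, warping and smoothing kernels.
#
# All volumes are dense base-R arrays with axis order (z, y, x) — z is the
# rotation axis and the fastest-varying index. Coordinates are 1-based voxel
# indices; the rotation/projection center is at (n + 1) / 2 on each axis.

.grid_center <- function(n) (n + 1) / 2

#' Linear interpolation along the columns of a matrix
#'
#' Samples `mat[, pos]` at fractional column positions `pos`, shared by all
#' rows. Positions outside `[1, ncol]` return `fill`.
#'
#' @param mat numeric matrix (rows are carried along unchanged).
#' @param pos numeric vector of fractional column positions.
#' @param fill value used outside the column range.
#' @return matrix of dim `nrow(mat) x length(pos)`.
#' @keywords internal
#' @noRd
.sample_cols <- function(mat, pos, fill = 0) {
  nr <- nrow(mat)
  nc <- ncol(mat)
  i0 <- floor(pos)
  w <- pos - i0
  inside <- pos >= 1 & pos <= nc
  i0c <- pmin(pmax(i0, 1L), nc)
  i1c <- pmin(i0c + 1L, nc)
  out <- mat[, i0c, drop = FALSE] * rep(1 - w, each = nr) +
    mat[, i1c, drop = FALSE] * rep(w, each = nr)
  if (!all(inside)) out[, !inside] <- fill
  out
}

# Bilinear gather in the (y, x) plane applied to every z-slice at once.
# vol: array (nz, ny, nx); ys, xs: fractional source coords (equal length).
# Returns a matrix (nz x length(ys)).
.sample_yx_slices <- function(vol, ys, xs, fill = 0) {
  d <- dim(vol)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  vm <- matrix(vol, nz, ny * nx)
  iy0 <- floor(ys); ix0 <- floor(xs)
  wy <- ys - iy0; wx <- xs - ix0
  inside <- ys >= 1 & ys <= ny & xs >= 1 & xs <= nx
  iy0 <- pmin(pmax(iy0, 1L), ny); ix0 <- pmin(pmax(ix0, 1L), nx)
  iy1 <- pmin(iy0 + 1L, ny);      ix1 <- pmin(ix0 + 1L, nx)
  col00 <- (ix0 - 1L) * ny + iy0
  col01 <- (ix1 - 1L) * ny + iy0
  col10 <- (ix0 - 1L) * ny + iy1
  col11 <- (ix1 - 1L) * ny + iy1
  e <- function(w) rep(w, each = nz)
  out <- vm[, col00, drop = FALSE] * e((1 - wy) * (1 - wx)) +
    vm[, col10, drop = FALSE] * e(wy * (1 - wx)) +
    vm[, col01, drop = FALSE] * e((1 - wy) * wx) +
    vm[, col11, drop = FALSE] * e(wy * wx)
  if (!all(inside)) out[, !inside] <- fill
  out
}

#' Rotate a volume about the z axis
#'
#' Resamples the (y, x) planes with bilinear interpolation after a CCW
#' rotation by `theta_deg` about the grid center; voxels sampled from outside
#' the grid become `fill`.
#'
#' @param vol 3D array `(z, y, x)`.
#' @param theta_deg rotation angle in degrees, counter-clockwise about z.
#' @param fill out-of-support fill value.
#' @return rotated array of the same dim.
#' @export
rotate_volume_z <- function(vol, theta_deg, fill = 0) {
  d <- dim(vol)
  ny <- d[2]; nx <- d[3]
  th <- theta_deg * pi / 180
  cy <- .grid_center(ny); cx <- .grid_center(nx)
  g <- expand.grid(y = seq_len(ny), x = seq_len(nx))
  # inverse map: target (y', x') samples source rotated by -theta
  dy <- g$y - cy; dx <- g$x - cx
  ys <- cy + cos(th) * dy + sin(th) * dx
  xs <- cx - sin(th) * dy + cos(th) * dx
  array(.sample_yx_slices(vol, ys, xs, fill = fill), dim = d)
}

#' Trilinear gather at fractional voxel coordinates
#'
#' @param vol 3D array `(z, y, x)`.
#' @param zs,ys,xs equal-length fractional coordinate vectors.
#' @param fill value outside the grid.
#' @return numeric vector of sampled values.
#' @export
trilinear_gather <- function(vol, zs, ys, xs, fill = 0) {
  d <- dim(vol)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  iz0 <- floor(zs); iy0 <- floor(ys); ix0 <- floor(xs)
  wz <- zs - iz0; wy <- ys - iy0; wx <- xs - ix0
  inside <- zs >= 1 & zs <= nz & ys >= 1 & ys <= ny & xs >= 1 & xs <= nx
  iz0 <- pmin(pmax(iz0, 1L), nz); iz1 <- pmin(iz0 + 1L, nz)
  iy0 <- pmin(pmax(iy0, 1L), ny); iy1 <- pmin(iy0 + 1L, ny)
  ix0 <- pmin(pmax(ix0, 1L), nx); ix1 <- pmin(ix0 + 1L, nx)
  lin <- function(iz, iy, ix) ((ix - 1) * ny + (iy - 1)) * nz + iz
  v <- vol[lin(iz0, iy0, ix0)] * (1 - wz) * (1 - wy) * (1 - wx) +
    vol[lin(iz1, iy0, ix0)] * wz * (1 - wy) * (1 - wx) +
    vol[lin(iz0, iy1, ix0)] * (1 - wz) * wy * (1 - wx) +
    vol[lin(iz1, iy1, ix0)] * wz * wy * (1 - wx) +
    vol[lin(iz0, iy0, ix1)] * (1 - wz) * (1 - wy) * wx +
    vol[lin(iz1, iy0, ix1)] * wz * (1 - wy) * wx +
    vol[lin(iz0, iy1, ix1)] * (1 - wz) * wy * wx +
    vol[lin(iz1, iy1, ix1)] * wz * wy * wx
  v[!inside] <- fill
  v
}

#' Warp a volume by a displacement field (pull-back convention)
#'
#' `out(x) = vol(x + u(x))`: the displacement, in voxels, tells each output
#' voxel where to *sample* the input. This is the gather convention used
#' throughout: a field `u` estimated between volumes `a` and `b` with
#' [estimate_flow()] satisfies `warp_volume(b, u) ~ a`.
#'
#' @param vol 3D array `(z, y, x)`.
#' @param field displacement field: list with 3D arrays `uz`, `uy`, `ux`
#'   (voxels), same dim as `vol`.
#' @param fill out-of-grid fill value.
#' @return warped array, same dim.
#' @export
warp_volume <- function(vol, field, fill = 0) {
  d <- dim(vol)
  if (!identical(dim(field$uz), d)) stop("field/volume shape mismatch")
  idx <- arrayInd(seq_along(vol), d)
  v <- trilinear_gather(vol,
                        idx[, 1] + as.vector(field$uz),
                        idx[, 2] + as.vector(field$uy),
                        idx[, 3] + as.vector(field$ux), fill = fill)
  array(v, dim = d)
}

# Zero displacement field of a given dim.
.zero_field <- function(d) {
  z <- array(0, dim = d)
  list(uz = z, uy = z, ux = z)
}

.field_norms <- function(field) {
  sqrt(field$uz^2 + field$uy^2 + field$ux^2)
}

#' Invert a displacement field by fixed-point iteration
#'
#' Finds `v` with `v(x) = -u(x + v(x))`, so that composing the warps by `u`
#' and `v` is close to the identity.
#'
#' @param field displacement field (`uz`, `uy`, `ux`).
#' @param iters fixed-point iterations (default 5).
#' @param tol early-exit tolerance on the max update, voxels (default 0.01).
#' @return inverted field.
#' @export
invert_displacement_field <- function(field, iters = 5, tol = 0.01) {
  d <- dim(field$uz)
  v <- .zero_field(d)
  idx <- arrayInd(seq_along(field$uz), d)
  for (i in seq_len(iters)) {
    zs <- idx[, 1] + as.vector(v$uz)
    ys <- idx[, 2] + as.vector(v$uy)
    xs <- idx[, 3] + as.vector(v$ux)
    new <- list(
      uz = array(-trilinear_gather(field$uz, zs, ys, xs), d),
      uy = array(-trilinear_gather(field$uy, zs, ys, xs), d),
      ux = array(-trilinear_gather(field$ux, zs, ys, xs), d))
    delta <- max(abs(new$uz - v$uz), abs(new$uy - v$uy), abs(new$ux - v$ux))
    v <- new
    if (delta < tol) break
  }
  v
}

# Periodic Gaussian smoothing of a 3D array via FFT. sigma in voxels,
# isotropic; sigma = 0 returns the input.
.gaussian_smooth3 <- function(vol, sigma) {
  if (sigma <= 0) return(vol)
  d <- dim(vol)
  k1 <- function(n) {
    x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
    g <- exp(-x^2 / (2 * sigma^2))
    g / sum(g)
  }
  K <- outer(outer(k1(d[1]), k1(d[2])), k1(d[3]))
  dim(K) <- d
  Re(fft(fft(vol) * fft(K), inverse = TRUE)) / prod(d)
}

# Subpixel 2D shift of an image by (dy, dx) with linear interpolation,
# zero fill. out(y, x) = img(y - dy, x - dx): positive dy moves content down.
.shift_image <- function(img, dy, dx, fill = 0) {
  ny <- nrow(img); nx <- ncol(img)
  g <- expand.grid(y = seq_len(ny), x = seq_len(nx))
  v <- trilinear_gather(array(img, c(1, ny, nx)),
                        rep(1, ny * nx), g$y - dy, g$x - dx, fill = fill)
  matrix(v, ny, nx)
}

# 2x box downsample of a 3D array (pads by edge replication for odd sizes).
.downsample2 <- function(vol) {
  d <- dim(vol)
  dpad <- d + d %% 2
  if (!all(dpad == d)) {
    vp <- array(0, dpad)
    vp[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- vol
    if (dpad[1] > d[1]) vp[dpad[1], , ] <- vp[d[1], , ]
    if (dpad[2] > d[2]) vp[, dpad[2], ] <- vp[, d[2], ]
    if (dpad[3] > d[3]) vp[, , dpad[3]] <- vp[, , d[3]]
    vol <- vp
    d <- dpad
  }
  h <- d %/% 2
  i1 <- seq(1, d[1], by = 2); i2 <- i1 + 1
  j1 <- seq(1, d[2], by = 2); j2 <- j1 + 1
  k1 <- seq(1, d[3], by = 2); k2 <- k1 + 1
  (vol[i1, j1, k1] + vol[i2, j1, k1] + vol[i1, j2, k1] + vol[i1, j1, k2] +
     vol[i2, j2, k1] + vol[i2, j1, k2] + vol[i1, j2, k2] +
     vol[i2, j2, k2]) / 8
}

# Trilinear upsample of a 3D array (and fields) to a target dim.
.upsample_to <- function(vol, dnew) {
  d <- dim(vol)
  sc <- (d - 1) / pmax(dnew - 1, 1)
  zs <- 1 + (seq_len(dnew[1]) - 1) * sc[1]
  ys <- 1 + (seq_len(dnew[2]) - 1) * sc[2]
  xs <- 1 + (seq_len(dnew[3]) - 1) * sc[3]
  g <- expand.grid(z = zs, y = ys, x = xs)
  array(trilinear_gather(vol, g$z, g$y, g$x), dnew)
}
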