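# Internal array helpers shared across modules. Volumes are numeric 3D arrays
# in (z, y, x) order; all public indices are 0-based and intervals half-open.

#' @useDynLib cellscaffold, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Normalized Gaussian kernel; length defaults to an odd window covering ~3 sigma.
gaussian_kernel <- function(sigma, len = NULL) {
  if (sigma <= 0) return(1)
  if (is.null(len)) len <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  stopifnot(len %% 2 == 1)
  h <- (len - 1L) / 2L
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k / sum(k)
}

# Reflected ("symmetric") 1D padding indices for a signal of length n.
reflect_index <- function(n, h) {
  if (h == 0) return(seq_len(n))
  left <- pmin(pmax(rev(seq_len(h)), 1L), n)
  right <- pmin(pmax(n - seq_len(h) + 1L, 1L), n)
  c(left, seq_len(n), right)
}

# Convolve a 1D signal with a symmetric kernel, reflected boundaries.
smooth1d <- function(x, kernel) {
  n <- length(x)
  h <- (length(kernel) - 1L) / 2L
  xp <- x[reflect_index(n, h)]
  out <- numeric(n)
  for (k in seq_along(kernel)) out <- out + kernel[k] * xp[(k - 1L) + seq_len(n)]
  out
}

# Separable convolution of a (z,y,x) volume along one axis (1 = z, 2 = y,
# 3 = x) with reflected boundaries. The axis is rotated to the front so the
# inner loop is over kernel taps only.
conv_axis <- function(vol, kernel, axis) {
  if (length(kernel) == 1L) return(vol * kernel)
  d <- dim(vol)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  v <- aperm(vol, perm)
  dp <- dim(v)
  n <- dp[1]
  m <- prod(dp[-1])
  dim(v) <- c(n, m)
  h <- (length(kernel) - 1L) / 2L
  vp <- v[reflect_index(n, h), , drop = FALSE]
  out <- matrix(0, n, m)
  for (k in seq_along(kernel))
    out <- out + kernel[k] * vp[(k - 1L) + seq_len(n), , drop = FALSE]
  dim(out) <- dp
  aperm(out, order(perm))
}

# Anisotropic Gaussian blur; sigma given in physical units (um) per axis,
# converted to voxel units via voxel_size = (dz, dy, dx).
gaussian_blur3 <- function(vol, sigma_um, voxel_size) {
  sig_vox <- sigma_um / voxel_size
  for (ax in 1:3)
    if (sig_vox[ax] > 1e-8) vol <- conv_axis(vol, gaussian_kernel(sig_vox[ax]), ax)
  vol
}

# Shift a volume by integer offsets, filling exposed cells with `fill`.
shift_volume <- function(vol, dz, dy, dx, fill = 0) {
  d <- dim(vol)
  out <- array(fill, d)
  src <- list(z = seq_len(d[1]) - dz, y = seq_len(d[2]) - dy, x = seq_len(d[3]) - dx)
  keep <- lapply(seq_along(d), function(i) src[[i]] >= 1 & src[[i]] <= d[i])
  out[keep[[1]], keep[[2]], keep[[3]]] <-
    vol[src$z[keep[[1]]], src$y[keep[[2]]], src$x[keep[[3]]]]
  out
}

neighbor_offsets <- function(connectivity = 26) {
  stopifnot(connectivity %in% c(6, 18, 26))
  g <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  m <- abs(g$dz) + abs(g$dy) + abs(g$dx)
  keep <- m > 0 & m <= switch(as.character(connectivity), `6` = 1, `18` = 2, `26` = 3)
  g[keep, , drop = FALSE]
}

# One-step binary dilation / erosion via neighbor shifts.
dilate_mask <- function(mask, connectivity = 26) {
  out <- mask
  off <- neighbor_offsets(connectivity)
  for (i in seq_len(nrow(off)))
    out <- out | shift_volume(mask, off$dz[i], off$dy[i], off$dx[i], fill = FALSE)
  out
}

erode_mask <- function(mask, connectivity = 26) {
  out <- mask
  off <- neighbor_offsets(connectivity)
  for (i in seq_len(nrow(off)))
    out <- out & shift_volume(mask, off$dz[i], off$dy[i], off$dx[i], fill = TRUE)
  out
}

close_mask <- function(mask, connectivity = 26) {
  erode_mask(dilate_mask(mask, connectivity), connectivity)
}

# Largest connected component of a binary volume (26-connectivity default).
largest_component <- function(mask, connectivity = 26) {
  lab <- cpp_label_components(mask, dim(mask), as.integer(connectivity))
  if (max(lab) == 0L) return(mask & FALSE)
  counts <- tabulate(lab[lab > 0L])
  keep <- which.max(counts)
  array(lab == keep, dim(mask))
}

# Drop connected components smaller than min_voxels.
remove_small_components <- function(mask, min_voxels, connectivity = 26) {
  lab <- cpp_label_components(mask, dim(mask), as.integer(connectivity))
  if (max(lab) == 0L) return(mask)
  counts <- tabulate(lab[lab > 0L])
  small <- which(counts < min_voxels)
  if (length(small)) mask[lab %in% small] <- FALSE
  mask
}

# Fill holes slice-by-slice along z: background pixels of a 2D slice not
# connected (4-connectivity) to the slice border are holes.
fill_holes_slices <- function(mask) {
  d <- dim(mask)
  for (z in seq_len(d[1])) {
    sl <- array(!mask[z, , ], c(1L, d[2], d[3]))
    lab <- cpp_label_components(sl, dim(sl), 6L)
    border <- unique(c(lab[1, 1, ], lab[1, d[2], ], lab[1, , 1], lab[1, , d[3]]))
    border <- border[border > 0L]
    hole <- sl & !array(lab %in% border, dim(sl))
    mask[z, , ] <- mask[z, , ] | hole[1, , ]
  }
  mask
}

jaccard_index <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
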