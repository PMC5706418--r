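#' Weighted total least-squares plane fit
#'
#' Fits `f(x, y, z) = a x + b y + c z + d` with unit normal `(a, b, c)` by
#' minimizing the weighted sum of squared plane residuals, and reports the
#' residual standard deviation in nanometers,
#' `STD_RES = sqrt( sum_i w_i f(x_i,y_i,z_i)^2 / (sum_i w_i - mean(w) p) )`
#' with `p = 3` independent plane parameters. Spun-coat scaffolds are flat
#' polymer films whose upper and lower surfaces are modeled this way; the
#' residual standard deviation is the goodness-of-fit that justifies the
#' planar model (it is of the order of 100 nm, below the voxel size).
#'
#' @param x either a numeric `n x 3` matrix of `(x, y, z)` point coordinates
#'   in micrometers, or a [zstack] (voxels with positive weight become
#'   points at their physical centers).
#' @param weights per-point weights (matrix input) or a per-voxel weight
#'   array congruent with the stack; `NULL` means unit weights.
#' @param surface `"upper"` or `"lower"`, recorded in the fit.
#' @return object of class `plane_fit`: `coeffs` `(a,b,c,d)` with `(a,b,c)`
#'   unit norm and coordinates in um, `residual_std_nm`, `n`, `weights_mean`.
#' @export
fit_plane_wls <- function(x, weights = NULL, surface = c("upper", "lower")) {
  surface <- match.arg(surface)
  if (inherits(x, "zstack")) {
    if (is.null(weights)) stop("stack input requires a per-voxel weight array")
    stopifnot(identical(dim(weights), dim(x$voxels)))
    g <- coord_grids(dim(x$voxels), x$voxel_size)
    keep <- weights > 0
    pts <- cbind(g$x[keep], g$y[keep], g$z[keep])
    w <- weights[keep]
  } else {
    pts <- as.matrix(x)
    stopifnot(ncol(pts) == 3)
    w <- if (is.null(weights)) rep(1, nrow(pts)) else as.numeric(weights)
    keep <- w > 0
    pts <- pts[keep, , drop = FALSE]
    w <- w[keep]
  }
  n <- nrow(pts)
  if (n < 4L) stop("plane fit needs at least 4 points with positive weight")
  ctr <- colSums(pts * w) / sum(w)
  cpts <- sweep(pts, 2, ctr)
  M <- crossprod(cpts * sqrt(w))
  eg <- eigen(M, symmetric = TRUE)
  # rank check: points must span a plane, not a line
  if (eg$values[2] <= 1e-9 * max(eg$values[1], 1))
    stop("rank-deficient point set: points are collinear")
  nrm <- eg$vectors[, 3]
  coeffs <- c(nrm, -sum(nrm * ctr))
  resid <- cpts %*% nrm
  p <- 3
  denom <- sum(w) - mean(w) * p
  if (denom <= 0) stop("not enough effective points for a residual estimate")
  std_nm <- sqrt(sum(w * resid^2) / denom) * 1000   # um -> nm
  structure(list(coeffs = coeffs, residual_std_nm = std_nm, n = n,
                 weights_mean = mean(w), surface = surface),
            class = "plane_fit")
}

#' @export
print.plane_fit <- function(x, ...) {
  cat(sprintf(
    "<plane_fit> %s surface  n = %d  STD_RES = %.2f nm\n  %.4f x + %.4f y + %.4f z + %.4f = 0 (um)\n",
    x$surface, x$n, x$residual_std_nm,
    x$coeffs[1], x$coeffs[2], x$coeffs[3], x$coeffs[4]))
  invisible(x)
}

#' Pooled residual standard deviation over plane fits
#'
#' Variance-weighted combination of per-stack residual standard deviations:
#' `sqrt( sum_k (n_k - 1) STD_k^2 / (sum_k n_k - K) )`. With a single fit it
#' reduces to that fit's residual standard deviation.
#'
#' @param fits list of [fit_plane_wls] results (each with `n >= 2`).
#' @return pooled standard deviation in nm.
#' @export
pooled_std <- function(fits) {
  if (inherits(fits, "plane_fit")) fits <- list(fits)
  K <- length(fits)
  stopifnot(K >= 1)
  n <- vapply(fits, function(f) f$n, 0)
  s <- vapply(fits, function(f) f$residual_std_nm, 0)
  if (any(n < 2)) stop("each fit needs n >= 2")
  if (sum(n) <= K) stop("sum of n_k must exceed K")
  sqrt(sum((n - 1) * s^2) / (sum(n) - K))
}

#' Frangi vesselness filter
#'
#' Enhances bright tubular structures at a chosen scale by eigen-analysis of
#' the Gaussian-scale Hessian. The volume is smoothed at scale `sigma`
#' (expressed in voxel units of the finest axis; the z derivatives are
#' rescaled by the axial/lateral spacing ratio so the Hessian is computed in
#' isotropic physical units), second derivatives are taken by central
#' differences, and per voxel the eigenvalues `|l1| <= |l2| <= |l3|` yield
#' the tube response
#' `(1 - exp(-Ra^2/2a^2)) exp(-Rb^2/2b^2) (1 - exp(-S^2/2c^2))`
#' with `Ra = |l2|/|l3|`, `Rb = |l1|/sqrt(|l2 l3|)` and `S` the Frobenius
#' norm; bright-tube polarity requires `l2, l3 < 0`.
#'
#' @param stack a [zstack] (or plain array, then unit voxel size).
#' @param sigma filter scale; 1.0 targets medium-fiber radii, 1.5 larger.
#' @param alpha,beta Frangi plate/blob discrimination constants (0.5, 0.5).
#' @param c structureness constant; default half the maximum Hessian norm.
#' @return numeric array of nonnegative responses, same shape as the input.
#' @export
vesselness <- function(stack, sigma = 1.0, alpha = 0.5, beta = 0.5, c = NULL) {
  stopifnot(sigma > 0)
  if (inherits(stack, "zstack")) {
    vox <- stack$voxels; vs <- stack$voxel_size
  } else {
    vox <- stack; vs <- c(1, 1, 1)
  }
  r <- vs / min(vs)                 # axis spacing in finest-axis units
  sm <- vox
  for (ax in 1:3) {
    s_ax <- sigma / r[ax]
    if (s_ax > 1e-3) sm <- conv_axis(sm, gaussian_kernel(s_ax), ax)
  }
  cd <- function(v, ax) {           # central difference, physical scaling
    k <- c(0.5, 0, -0.5) / r[ax]
    conv_axis(v, k, ax)
  }
  gz <- cd(sm, 1); gy <- cd(sm, 2); gx <- cd(sm, 3)
  hzz <- cd(gz, 1); hyy <- cd(gy, 2); hxx <- cd(gx, 3)
  hxy <- cd(gx, 2); hxz <- cd(gx, 1); hyz <- cd(gy, 1)
  s2 <- sigma^2                     # gamma = 2 scale normalization
  ev <- cpp_eig3_sym(s2 * hxx, s2 * hyy, s2 * hzz,
                     s2 * hxy, s2 * hxz, s2 * hyz)
  l1 <- ev[, 1]; l2 <- ev[, 2]; l3 <- ev[, 3]
  S2 <- l1^2 + l2^2 + l3^2
  if (is.null(c)) c <- sqrt(max(S2)) / 2
  out <- numeric(length(l1))
  ok <- l2 < 0 & l3 < 0
  if (any(ok) && c > 0) {
    Ra2 <- (l2[ok] / l3[ok])^2
    Rb2 <- l1[ok]^2 / abs(l2[ok] * l3[ok])
    out[ok] <- (1 - exp(-Ra2 / (2 * alpha^2))) *
               exp(-Rb2 / (2 * beta^2)) *
               (1 - exp(-S2[ok] / (2 * c^2)))
  }
  array(out, dim(vox))
}

#' Ad-hoc baseline scaffold segmentation
#'
#' Maximum-entropy threshold on the raw intensities followed by a 3x3x3
#' median filter and removal of connected components smaller than 27 voxels.
#' Serves as the reference baseline against the model-based methods.
#'
#' @param stack a [zstack] (non-constant).
#' @return logical scaffold mask.
#' @export
adhoc_segment <- function(stack) {
  vox <- if (inherits(stack, "zstack")) stack$voxels else stack
  th <- max_entropy_threshold(vox)
  m <- cpp_median_filter3(th$mask + 0, dim(th$mask)) >= 0.5
  remove_small_components(array(m, dim(vox)), 27L, connectivity = 26)
}

# surface voxels (largest/smallest z per (y,x) column) of a thresholded slab
slab_surface_weights <- function(stack, surface, background_mean = 0) {
  th <- max_entropy_threshold(stack$voxels)
  d <- dim(stack$voxels)
  w <- array(0, d)
  for (y in seq_len(d[2])) for (x in seq_len(d[3])) {
    zs <- which(th$mask[, y, x])
    if (!length(zs)) next
    z <- if (surface == "upper") max(zs) else min(zs)
    w[z, y, x] <- max(stack$voxels[z, y, x] - background_mean, 0)
  }
  mx <- max(w)
  if (mx > 0) w <- w / mx
  w
}

#' Geometry-based scaffold segmentation
#'
#' Dispatches on scaffold type and method: spun-coat films (`SC`) are
#' segmented by fitting upper and lower surface planes and keeping voxels
#' within one z-voxel of the chosen surface (the one nearer the cell
#' centroid when a cell mask is supplied, else the upper); fiber scaffolds
#' (`MF`, `MMF`) by maximum-entropy thresholding of the vesselness response
#' (`A6`: sigma 1.0, `A7`: sigma 1.5); `A8` is the ad-hoc baseline for any
#' type.
#'
#' @param stack scaffold-channel [zstack].
#' @param scaffold_type `"SC"`, `"MF"` or `"MMF"`.
#' @param method `"A6"`, `"A7"` or `"A8"`.
#' @param cell_mask optional logical cell mask (used for SC surface choice;
#'   contact extraction itself happens downstream and an empty mask simply
#'   means no contact-relevant region).
#' @return logical scaffold mask with attributes recording the fit
#'   (`plane_fits` for SC, `sigma` and `threshold` for fibers).
#' @export
geometric_scaffold_segment <- function(stack,
                                       scaffold_type = c("MF", "MMF", "SC"),
                                       method = c("A6", "A7", "A8"),
                                       cell_mask = NULL) {
  stopifnot(inherits(stack, "zstack"))
  scaffold_type <- match.arg(scaffold_type)
  method <- match.arg(method)
  d <- dim(stack$voxels)
  if (method == "A8") return(adhoc_segment(stack))
  if (scaffold_type == "SC") {
    bg <- estimate_background(stack)
    fits <- lapply(c("upper", "lower"), function(sf)
      fit_plane_wls(stack, slab_surface_weights(stack, sf, bg$mean),
                    surface = sf))
    names(fits) <- c("upper", "lower")
    pick <- "upper"
    if (!is.null(cell_mask) && any(cell_mask)) {
      g <- coord_grids(d, stack$voxel_size)
      ctr <- c(mean(g$x[cell_mask]), mean(g$y[cell_mask]), mean(g$z[cell_mask]))
      dist_to <- vapply(fits, function(f)
        abs(sum(f$coeffs[1:3] * ctr) + f$coeffs[4]), 0)
      pick <- names(which.min(dist_to))
    }
    cf <- fits[[pick]]$coeffs
    if (abs(cf[3]) < 1e-6) stop("fitted spun-coat plane is vertical")
    g <- coord_grids(d, stack$voxel_size)
    zpl <- -(cf[1] * g$x + cf[2] * g$y + cf[4]) / cf[3]
    mask <- abs(g$z - zpl) <= stack$voxel_size[1]
    attr(mask, "plane_fits") <- fits
    attr(mask, "surface") <- pick
    return(mask)
  }
  sigma <- if (method == "A6") 1.0 else 1.5
  v <- vesselness(stack, sigma = sigma)
  th <- max_entropy_threshold(v)
  mask <- th$mask
  attr(mask, "sigma") <- sigma
  attr(mask, "threshold") <- th$threshold
  mask
}

#' Object-based binary contact
#'
#' A voxel is a contact site iff cell and scaffold labels co-occur there, or
#' one label is present and the other occurs within its one-voxel
#' neighborhood. The neighborhood defaults to the full 26-neighbor cube and
#' is configurable to 6 or 18.
#'
#' @param cell_mask,scaffold_mask congruent logical 3D masks.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return logical contact mask.
#' @export
binary_contact <- function(cell_mask, scaffold_mask, connectivity = 26) {
  if (!identical(dim(cell_mask), dim(scaffold_mask)))
    stop("cell and scaffold masks must be congruent")
  ds <- dilate_mask(scaffold_mask, connectivity)
  dc <- dilate_mask(cell_mask, connectivity)
  (cell_mask & ds) | (scaffold_mask & dc)
}

#' Contact surface from a segmented volume
#'
#' Computes the central-difference 3D gradient of the (binary) segment and
#' reports the segment voxels with nonzero gradient magnitude - the
#' segment's surface shell. Volume-border voxels are excluded so the crop
#' boundary never shows up as spurious surface.
#'
#' @param segment logical or numeric 3D volume (typically the cell-masked,
#'   thresholded scaffold segment).
#' @param provenance `"statistical"` or `"geometrical"`, recorded on the
#'   result.
#' @return logical surface mask with attribute `provenance`.
#' @export
contact_surface <- function(segment, provenance = "geometrical") {
  v <- segment + 0
  d <- dim(v)
  grad2 <- array(0, d)
  k <- c(0.5, 0, -0.5)
  for (ax in 1:3) grad2 <- grad2 + conv_axis(v, k, ax)^2
  surf <- grad2 > 1e-12 & v != 0   # surface points lie on the segment itself
  # exclude the volume border
  surf[c(1, d[1]), , ] <- FALSE
  surf[, c(1, d[2]), ] <- FALSE
  surf[, , c(1, d[3])] <- FALSE
  attr(surf, "provenance") <- provenance
  surf
}
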