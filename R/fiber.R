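#' Medial-axis skeleton of a binary fiber volume
#'
#' Reduces a binary solid to a one-voxel-thick, 26-connected curve skeleton
#' by topology-preserving medial-axis thinning (simple-point deletion with
#' curve-endpoint retention), then decomposes the skeleton into branches and
#' assigns each point a unit tangent from central differences of points two
#' steps apart along its branch (physical coordinates, so anisotropic voxels
#' are handled). Points within three steps of a branch end or junction are
#' flagged non-interior; the medial radius is ill-defined there.
#'
#' Naive simple-point thinning of a rasterized cylinder is unstable: when
#' the medial axis falls between voxels the curve-endpoint condition cannot
#' stop a deletion front, and the solid collapses. The implementation
#' therefore anchors the medial voxels first - the local maxima of the
#' chamfer distance transform are never deleted - thins everything else by
#' topology-preserving simple-point deletion, and finishes with an
#' endpoint-protected subfield pass that reduces remaining two-voxel-wide
#' ties to a single-voxel curve. Residual short spurs are pruned by
#' iterative endpoint removal to a depth of the object's inradius plus two
#' voxels, which absorbs spurs (at most one radius long) while only trimming
#' the ends of true centerlines; components that would vanish are frozen.
#'
#' @param mask nonempty logical 3D volume.
#' @param voxel_size `(dz, dy, dx)` in um for tangent computation.
#' @param prune spur-pruning depth in voxels; `NULL` (default) uses the
#'   mask inradius + 2, `0` disables pruning.
#' @return object of class `fiber_skeleton`: data frame `points` with
#'   0-based voxel indices `z, y, x`, `component`, `degree` (number of
#'   26-adjacent skeleton neighbors) and `interior`; matrix `tangents`
#'   (`n x 3`, unit vectors in physical `(z, y, x)` components, `NA` at
#'   junctions); and the voxel grid `skeleton` itself.
#' @export
skeletonize <- function(mask, voxel_size = c(1, 1, 1), prune = NULL) {
  if (!any(mask)) stop("cannot skeletonize an empty mask")
  dt <- cpp_chamfer_dt(mask, dim(mask))
  nbmax <- array(0L, dim(mask))
  off26 <- neighbor_offsets(26)
  for (i in seq_len(nrow(off26)))
    nbmax <- pmax(nbmax, shift_volume(dt, off26$dz[i], off26$dy[i],
                                      off26$dx[i]))
  anchors <- mask & dt >= nbmax            # distance-transform ridge
  skel <- cpp_thin_skeleton(mask, dim(mask), anchors,
                            protect_endpoints = FALSE)
  skel <- cpp_thin_skeleton(skel, dim(skel), logical(0),
                            protect_endpoints = TRUE)
  if (is.null(prune)) {
    # inradius: erosions until the mask vanishes
    prune <- 2L
    m <- mask
    while (any(m) && prune < 64L) {
      m <- erode_mask(m, 26)
      prune <- prune + 1L
    }
  }
  if (prune > 0) {
    lab0 <- cpp_label_components(skel, dim(skel), 26L)
    off <- neighbor_offsets(26)
    for (pass in seq_len(prune)) {
      nb <- array(0L, dim(skel))
      for (i in seq_len(nrow(off)))
        nb <- nb + shift_volume(skel + 0L, off$dz[i], off$dy[i], off$dx[i])
      drop <- skel & nb == 1L
      if (!any(drop)) break
      # freeze components that the pass would erase completely
      remaining <- tabulate(lab0[skel], nbins = max(lab0))
      dropped <- tabulate(lab0[drop], nbins = max(lab0))
      gone <- which(dropped >= remaining & remaining > 0)
      if (length(gone)) drop[array(lab0 %in% gone, dim(drop))] <- FALSE
      if (!any(drop)) break
      skel <- skel & !drop
    }
  }
  comp <- cpp_label_components(skel, dim(skel), 26L)
  idx <- which(skel, arr.ind = TRUE)            # (z, y, x), 1-based
  n <- nrow(idx)
  key <- function(z, y, x) paste(z, y, x)
  lookup <- new.env(hash = TRUE, size = max(2L * n, 16L))
  for (i in seq_len(n)) assign(key(idx[i, 1], idx[i, 2], idx[i, 3]), i,
                               envir = lookup)
  off <- neighbor_offsets(26)
  nbrs <- vector("list", n)
  degree <- integer(n)
  for (i in seq_len(n)) {
    zs <- idx[i, 1] + off$dz; ys <- idx[i, 2] + off$dy; xs <- idx[i, 3] + off$dx
    hit <- integer(0)
    for (k in seq_along(zs)) {
      id <- mget(key(zs[k], ys[k], xs[k]), envir = lookup,
                 ifnotfound = list(NA_integer_))[[1]]
      if (!is.na(id)) hit <- c(hit, id)
    }
    nbrs[[i]] <- hit
    degree[i] <- length(hit)
  }
  phys <- cbind(z = (idx[, 1] - 0.5) * voxel_size[1],
                y = (idx[, 2] - 0.5) * voxel_size[2],
                x = (idx[, 3] - 0.5) * voxel_size[3])
  # trace branches between nodes of degree != 2 (or around pure cycles)
  tangents <- matrix(NA_real_, n, 3)
  dist_to_end <- rep(Inf, n)
  visited_edge <- new.env(hash = TRUE)
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  paths <- list()
  starts <- which(degree != 2L)
  walk <- function(from, nxt) {
    path <- c(from, nxt)
    while (degree[nxt] == 2L) {
      cand <- setdiff(nbrs[[nxt]], path[length(path) - 1L])
      if (!length(cand)) break
      nxt <- cand[1]
      path <- c(path, nxt)
      if (nxt == from) break                    # closed cycle
    }
    path
  }
  for (s in starts) for (nb in nbrs[[s]]) {
    if (!is.null(visited_edge[[ekey(s, nb)]])) next
    p <- walk(s, nb)
    for (q in seq_len(length(p) - 1L))
      visited_edge[[ekey(p[q], p[q + 1L])]] <- TRUE
    paths[[length(paths) + 1L]] <- p
  }
  if (!length(starts) && n > 1L) {              # pure cycle component(s)
    remaining <- which(degree == 2L)
    for (s in remaining) {
      if (length(nbrs[[s]]) && is.null(visited_edge[[ekey(s, nbrs[[s]][1])]])) {
        p <- walk(s, nbrs[[s]][1])
        for (q in seq_len(length(p) - 1L))
          visited_edge[[ekey(p[q], p[q + 1L])]] <- TRUE
        paths[[length(paths) + 1L]] <- p
      }
    }
  }
  for (p in paths) {
    m <- length(p)
    for (q in seq_len(m)) {
      i <- p[q]
      lo <- max(q - 2L, 1L); hi <- min(q + 2L, m)
      v <- phys[p[hi], ] - phys[p[lo], ]
      nv <- sqrt(sum(v^2))
      if (nv > 0 && degree[i] <= 2L) tangents[i, ] <- v / nv
      dist_to_end[i] <- min(dist_to_end[i], q - 1L, m - q)
    }
  }
  single <- degree == 0L
  interior <- degree == 2L & dist_to_end >= 3 & !single
  structure(list(
    points = data.frame(z = idx[, 1] - 1L, y = idx[, 2] - 1L,
                        x = idx[, 3] - 1L,
                        component = comp[skel], degree = degree,
                        interior = interior),
    tangents = tangents, skeleton = skel, voxel_size = voxel_size),
    class = "fiber_skeleton")
}

#' @export
print.fiber_skeleton <- function(x, ...) {
  cat(sprintf(
    "<fiber_skeleton> %d points, %d component(s), %d endpoint(s), %d branch point(s)\n",
    nrow(x$points), max(x$points$component), sum(x$points$degree == 1L),
    sum(x$points$degree >= 3L)))
  invisible(x)
}

#' In-plane radius from boundary crossings
#'
#' Core of the radius estimator: given the 2D coordinates of mask boundary
#' crossings sampled at equal angular spacing in the plane normal to the
#' fiber tangent, the radius is `sqrt(2 * lambda_min)` where `lambda_min` is
#' the smaller eigenvalue of the (population) covariance of the points. For
#' points on an ideal circle of radius r both in-plane eigenvalues equal
#' `r^2 / 2`, so the estimator is exact there; the `sqrt(2 * .)` calibration
#' makes the covariance-eigenvalue mechanism dimensionally a length.
#'
#' @param points2d numeric `n x 2` matrix of in-plane boundary coordinates.
#' @return radius (same units as the coordinates).
#' @export
radius_from_boundary_points <- function(points2d) {
  stopifnot(ncol(points2d) == 2, nrow(points2d) >= 3)
  ctr <- colMeans(points2d)
  cpts <- sweep(points2d, 2, ctr)
  cv <- crossprod(cpts) / nrow(cpts)            # population covariance
  ev <- eigen(cv, symmetric = TRUE, only.values = TRUE)$values
  sqrt(2 * min(ev))
}

#' Per-point fiber radius estimation
#'
#' For each interior skeleton point, casts `n_rays` rays at equal angular
#' spacing in the plane normal to the local tangent, records where each ray
#' crosses the mask boundary, and converts the boundary-point covariance
#' into a radius via [radius_from_boundary_points]. Points whose rays leave
#' the volume while still inside the mask are skipped and tallied.
#'
#' @param skeleton a [skeletonize] result.
#' @param mask the binary volume the skeleton came from.
#' @param voxel_size `(dz, dy, dx)` in um.
#' @param n_rays number of rays (>= 8; default 16).
#' @param subset `"ALL"` or `"Internal"`; `"Internal"` restricts skeleton
#'   points to a central sub-box (fraction `internal_fraction` per axis),
#'   the desk-scale analogue of keeping non-overlapping field-of-view cores.
#' @param internal_fraction central fraction per axis for `"Internal"`.
#' @return object of class `radius_histogram`: `radii` (um), `mean`,
#'   `stdev`, `count`, `subset`, `skipped`.
#' @export
estimate_radius <- function(skeleton, mask, voxel_size = skeleton$voxel_size,
                            n_rays = 16L, subset = c("ALL", "Internal"),
                            internal_fraction = 0.6) {
  stopifnot(inherits(skeleton, "fiber_skeleton"), n_rays >= 8L)
  subset <- match.arg(subset)
  d <- dim(mask)
  pts <- skeleton$points
  use <- which(pts$interior & is.finite(skeleton$tangents[, 1]))
  if (subset == "Internal") {
    lo <- (1 - internal_fraction) / 2 * d
    hi <- d - lo
    ok <- pts$z[use] + 0.5 >= lo[1] & pts$z[use] + 0.5 <= hi[1] &
          pts$y[use] + 0.5 >= lo[2] & pts$y[use] + 0.5 <= hi[2] &
          pts$x[use] + 0.5 >= lo[3] & pts$x[use] + 0.5 <= hi[3]
    use <- use[ok]
  }
  step <- min(voxel_size) / 2
  max_steps <- ceiling(2 * sqrt(sum((d * voxel_size)^2)) / step)
  theta <- 2 * pi * (seq_len(n_rays) - 1L) / n_rays
  radii <- numeric(0)
  skipped <- 0L
  inside <- function(pz, py, px) {
    iz <- floor(pz / voxel_size[1]) + 1L
    iy <- floor(py / voxel_size[2]) + 1L
    ix <- floor(px / voxel_size[3]) + 1L
    if (iz < 1L || iz > d[1] || iy < 1L || iy > d[2] || ix < 1L || ix > d[3])
      return(NA)
    mask[iz, iy, ix]
  }
  for (i in use) {
    t <- skeleton$tangents[i, ]                 # (z, y, x) components
    a <- if (abs(t[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- a - sum(a * t) * t; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(t[2] * e1[3] - t[3] * e1[2],
            t[3] * e1[1] - t[1] * e1[3],
            t[1] * e1[2] - t[2] * e1[1])
    ctr <- c((pts$z[i] + 0.5) * voxel_size[1],
             (pts$y[i] + 0.5) * voxel_size[2],
             (pts$x[i] + 0.5) * voxel_size[3])
    bpts <- matrix(NA_real_, n_rays, 2)
    ok <- TRUE
    for (k in seq_len(n_rays)) {
      dir <- cos(theta[k]) * e1 + sin(theta[k]) * e2
      s <- 0
      repeat {
        s <- s + step
        if (s / step > max_steps) { ok <- FALSE; break }
        p <- ctr + s * dir
        ins <- inside(p[1], p[2], p[3])
        if (is.na(ins)) { ok <- FALSE; break }  # ray left the volume
        if (!ins) break
      }
      if (!ok) break
      bpts[k, ] <- c(s - step / 2, theta[k])    # polar: (distance, angle)
    }
    if (!ok) { skipped <- skipped + 1L; next }
    xy <- cbind(bpts[, 1] * cos(bpts[, 2]), bpts[, 1] * sin(bpts[, 2]))
    radii <- c(radii, radius_from_boundary_points(xy))
  }
  structure(list(radii = radii, mean = mean(radii),
                 stdev = stats::sd(radii), count = length(radii),
                 subset = subset, skipped = skipped),
            class = "radius_histogram")
}

#' @export
print.radius_histogram <- function(x, ...) {
  cat(sprintf("<radius_histogram> %s: %.4f +/- %.4f um  (n = %d, skipped %d)\n",
              x$subset, x$mean, x$stdev, x$count, x$skipped))
  invisible(x)
}

#' Relative radius error against a reference
#'
#' `100 * |reference - estimate| / reference`, the percent deviation of a
#' fluorescence-derived mean fiber radius from an orthogonal (e.g. electron
#' microscopy) reference value.
#'
#' @param estimate_mean,reference_mean mean radii in um; the reference must
#'   be positive.
#' @return error in percent.
#' @export
radius_relative_error <- function(estimate_mean, reference_mean) {
  if (any(reference_mean <= 0)) stop("reference mean must be positive")
  100 * abs(reference_mean - estimate_mean) / reference_mean
}

#' Rank segmentation algorithms by radius accuracy
#'
#' Compares per-algorithm radius summaries against a reference radius
#' histogram and ranks algorithms by the relative error of their mean. Also
#' reports the ratio of estimate-to-reference standard deviations (which
#' should track the ratio of the two modalities' spatial resolutions).
#'
#' @param radii_by_algorithm named list of [estimate_radius] results (or
#'   lists with `mean`, `stdev`, `count`); empty entries are dropped with a
#'   warning.
#' @param reference a radius summary with positive `mean` (and optionally
#'   `stdev`).
#' @return data frame with one row per algorithm (`algorithm`, `mean`,
#'   `stdev`, `count`, `rel_error_pct`, `stdev_ratio`, `rank`), ordered by
#'   ascending relative error. The per-algorithm radius vectors, when
#'   available, are attached as attribute `histograms` for overlay plots.
#' @export
compare_algorithms <- function(radii_by_algorithm, reference) {
  stopifnot(length(radii_by_algorithm) >= 1, !is.null(names(radii_by_algorithm)))
  keep <- vapply(radii_by_algorithm,
                 function(h) isTRUE(h$count > 0) || is.finite(h$mean), TRUE)
  if (!all(keep)) {
    warning("dropping algorithms with empty radius histograms: ",
            paste(names(radii_by_algorithm)[!keep], collapse = ", "))
    radii_by_algorithm <- radii_by_algorithm[keep]
  }
  if (!length(radii_by_algorithm)) stop("no non-empty radius histograms")
  df <- data.frame(
    algorithm = names(radii_by_algorithm),
    mean = vapply(radii_by_algorithm, function(h) h$mean, 0),
    stdev = vapply(radii_by_algorithm, function(h)
      if (is.null(h$stdev) || is.na(h$stdev)) NA_real_ else h$stdev, 0),
    count = vapply(radii_by_algorithm, function(h)
      if (is.null(h$count)) NA_integer_ else as.integer(h$count), 0L),
    row.names = NULL)
  df$rel_error_pct <- radius_relative_error(df$mean, reference$mean)
  df$stdev_ratio <- if (!is.null(reference$stdev) && reference$stdev > 0)
    df$stdev / reference$stdev else NA_real_
  df <- df[order(df$rel_error_pct), ]
  df$rank <- seq_len(nrow(df))
  hists <- lapply(radii_by_algorithm, function(h) h$radii)
  attr(df, "histograms") <- hists[!vapply(hists, is.null, TRUE)]
  df
}
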