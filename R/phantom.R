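#' Synthetic phantom specification
#'
#' Describes a synthetic `[cell, scaffold]` scene with known ground truth:
#' scaffold geometry (a flat spun-coat slab or a set of cylindrical fibers),
#' an optional ellipsoidal cell, and an imaging model consisting of an
#' anisotropic Gaussian blur, symmetric linear cross-channel bleed-through,
#' a constant background offset and i.i.d. Gaussian noise. Phantoms are the
#' package's test bed: the study's real data are terabyte-scale confocal
#' stacks, so every algorithm is exercised on these small scenes instead.
#'
#' Geometry is expressed in physical micrometers; the voxel center of 0-based
#' index `(iz, iy, ix)` sits at `((ix+0.5)*dx, (iy+0.5)*dy, (iz+0.5)*dz)`.
#' A voxel is foreground iff its center lies inside the analytic solid; no
#' antialiasing is applied, so analytic oracles stay exact and sub-voxel
#' partial-volume effects come from the blur step alone.
#'
#' @param kind `"spun_coat"` or `"fiber_bundle"`.
#' @param plane for spun coat: list with `coeffs` `(a,b,c,d)` of the lower
#'   surface plane `a x + b y + c z + d = 0` (normal need not be unit; it is
#'   normalized internally) and `thickness` in um; the slab is
#'   `0 <= f(p) <= thickness`.
#' @param fibers list of fibers, each a list with `point` `(x,y,z)` um on the
#'   axis, `direction` `(x,y,z)`, `radius` um and `intensity`.
#' @param cell optional list with `center` `(x,y,z)` um, `semi_axes`
#'   `(x,y,z)` um, `intensity`.
#' @param background_offset constant detector offset added to both channels.
#' @param noise_sigma standard deviation of the additive Gaussian noise.
#' @param bleed_alpha symmetric linear mixing fraction in `[0, 1)`: the
#'   observed scaffold channel is `scaffold + bleed_alpha * cell` (before the
#'   offset) and vice versa, emulating fluorophore emission bleed-through.
#' @param blur_sigma `(sz, sy, sx)` Gaussian blur in um approximating the
#'   anisotropic confocal point-spread function; default `(0.6, 0.2, 0.2)`.
#' @param scaffold_intensity intensity of the spun-coat slab.
#' @param seed integer RNG seed; a fixed seed makes rendering bit-reproducible.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(kind = c("fiber_bundle", "spun_coat"),
                         plane = NULL, fibers = list(), cell = NULL,
                         background_offset = 150, noise_sigma = 30,
                         bleed_alpha = 0.05,
                         blur_sigma = c(0.6, 0.2, 0.2),
                         scaffold_intensity = 900, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(bleed_alpha >= 0, bleed_alpha < 1, noise_sigma >= 0,
            background_offset >= 0, all(blur_sigma >= 0))
  for (f in fibers) stopifnot(f$radius > 0)
  if (kind == "spun_coat") stopifnot(!is.null(plane), plane$thickness > 0)
  structure(list(kind = kind, plane = plane, fibers = fibers, cell = cell,
                 background_offset = background_offset,
                 noise_sigma = noise_sigma, bleed_alpha = bleed_alpha,
                 blur_sigma = blur_sigma,
                 scaffold_intensity = scaffold_intensity,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# physical coordinate grids for a (Z,Y,X) volume, voxel centers, um
coord_grids <- function(dims, voxel_size) {
  Z <- dims[1]; Y <- dims[2]; X <- dims[3]
  dz <- voxel_size[1]; dy <- voxel_size[2]; dx <- voxel_size[3]
  list(
    z = array(rep((seq_len(Z) - 0.5) * dz, times = Y * X), dims),
    y = array(rep(rep((seq_len(Y) - 0.5) * dy, each = Z), times = X), dims),
    x = array(rep((seq_len(X) - 0.5) * dx, each = Z * Y), dims))
}

#' Render a phantom into a z-stack pair with ground truth
#'
#' Rasterizes the geometry, applies the blur, mixes the channels with the
#' bleed-through coefficient, adds the background offset and finally the
#' Gaussian noise. The ground-truth contact mask is the co-occurrence of the
#' (pre-blur) cell and scaffold masks extended by one-voxel adjacency, i.e.
#' the object-based contact definition used throughout the package.
#'
#' @param spec a [phantom_spec].
#' @param dims `(Z, Y, X)` volume dimensions.
#' @param voxel_size `(dz, dy, dx)` in um.
#' @return list with `pair` (a [zstack_pair]), `truth` (logical masks `cell`,
#'   `scaffold`, `contact`) and `spec`.
#' @export
render_phantom <- function(spec, dims, voxel_size = c(0.25, 0.25, 0.25)) {
  stopifnot(inherits(spec, "phantom_spec"), all(dims >= 1))
  g <- coord_grids(dims, voxel_size)

  scaffold_mask <- array(FALSE, dims)
  scaffold_img <- array(0, dims)
  if (spec$kind == "spun_coat") {
    cf <- spec$plane$coeffs
    nrm <- sqrt(sum(cf[1:3]^2))
    f <- (cf[1] * g$x + cf[2] * g$y + cf[3] * g$z + cf[4]) / nrm
    scaffold_mask <- f >= 0 & f <= spec$plane$thickness
    scaffold_img[scaffold_mask] <- spec$scaffold_intensity
  }
  for (fb in spec$fibers) {
    u <- fb$direction / sqrt(sum(fb$direction^2))
    vx <- g$x - fb$point[1]; vy <- g$y - fb$point[2]; vz <- g$z - fb$point[3]
    t <- vx * u[1] + vy * u[2] + vz * u[3]
    d2 <- pmax(vx^2 + vy^2 + vz^2 - t^2, 0)
    m <- d2 <= fb$radius^2
    scaffold_mask <- scaffold_mask | m
    scaffold_img[m] <- pmax(scaffold_img[m], fb$intensity)
  }

  cell_mask <- array(FALSE, dims)
  cell_img <- array(0, dims)
  if (!is.null(spec$cell)) {
    ce <- spec$cell
    q <- ((g$x - ce$center[1]) / ce$semi_axes[1])^2 +
         ((g$y - ce$center[2]) / ce$semi_axes[2])^2 +
         ((g$z - ce$center[3]) / ce$semi_axes[3])^2
    cell_mask <- q <= 1
    cell_img[cell_mask] <- ce$intensity
  }
  if (!any(scaffold_mask) && !any(cell_mask))
    stop("phantom geometry does not intersect the volume")

  if (any(spec$blur_sigma > 0)) {
    scaffold_img <- gaussian_blur3(scaffold_img, spec$blur_sigma, voxel_size)
    cell_img <- gaussian_blur3(cell_img, spec$blur_sigma, voxel_size)
  }
  a <- spec$bleed_alpha
  scaffold_obs <- scaffold_img + a * cell_img + spec$background_offset
  cell_obs <- cell_img + a * scaffold_img + spec$background_offset
  if (spec$noise_sigma > 0) {
    n <- prod(dims)
    noise <- with_seed(spec$seed,
                       stats::rnorm(2L * n, sd = spec$noise_sigma))
    cell_obs <- cell_obs + array(noise[seq_len(n)], dims)
    scaffold_obs <- scaffold_obs + array(noise[n + seq_len(n)], dims)
  }

  contact <- (cell_mask & dilate_mask(scaffold_mask)) |
             (scaffold_mask & dilate_mask(cell_mask))
  list(pair = zstack_pair(zstack(cell_obs, voxel_size, "cell"),
                          zstack(scaffold_obs, voxel_size, "scaffold")),
       truth = list(cell = cell_mask, scaffold = scaffold_mask,
                    contact = contact),
       spec = spec)
}

#' Deterministic suite of small test phantoms
#'
#' Renders a fixed set of scenes (all at most 64 voxels per axis) that cover
#' the geometries the measurement pipeline must handle: a bare spun-coat
#' slab, a single fiber, two crossing fibers, a cell resting on a plane, a
#' cell draped on a fiber, a cell far from any scaffold (empty true contact),
#' and a strong bleed-through case. Each fixture carries its ground truth.
#'
#' @param seed integer; the same seed yields byte-identical fixtures.
#' @return named list of rendered phantoms (see [render_phantom]).
#' @export
sample_fixture_suite <- function(seed = 1L) {
  seed <- as.integer(seed)
  iso <- c(0.25, 0.25, 0.25)
  conf <- c(0.462, 0.12, 0.12)
  out <- list()

  # flat spun-coat slab, confocal anisotropy; slab spans z in [20, 26) frames
  out$spun_coat <- render_phantom(
    phantom_spec("spun_coat",
                 plane = list(coeffs = c(0.01, -0.008, 1, -20 * conf[1]),
                              thickness = 6 * conf[1]),
                 seed = seed),
    dims = c(48L, 40L, 40L), voxel_size = conf)

  # one straight fiber along x, MF-like radius 1.3 um
  out$single_fiber <- render_phantom(
    phantom_spec(fibers = list(list(point = c(0, 5, 4), direction = c(1, 0, 0),
                                    radius = 1.3, intensity = 900)),
                 seed = seed + 1L),
    dims = c(32L, 40L, 56L), voxel_size = iso)

  # two fibers crossing at the volume center
  out$crossing_fibers <- render_phantom(
    phantom_spec(fibers = list(
      list(point = c(0, 6, 5), direction = c(1, 0, 0), radius = 1.0,
           intensity = 900),
      list(point = c(6, 0, 5), direction = c(0, 1, 0), radius = 1.0,
           intensity = 900)), seed = seed + 2L),
    dims = c(40L, 48L, 48L), voxel_size = iso)

  # ellipsoidal cell resting on a spun-coat slab
  out$cell_on_plane <- render_phantom(
    phantom_spec("spun_coat",
                 plane = list(coeffs = c(0, 0, 1, -12 * conf[1]),
                              thickness = 5 * conf[1]),
                 cell = list(center = c(2.4, 2.4, (12 + 5) * conf[1] + 0.8),
                             semi_axes = c(1.6, 1.4, 1.0), intensity = 1400),
                 seed = seed + 3L),
    dims = c(48L, 40L, 40L), voxel_size = conf)

  # cell draped on a single fiber
  out$cell_on_fiber <- render_phantom(
    phantom_spec(fibers = list(list(point = c(0, 5, 3.5),
                                    direction = c(1, 0, 0),
                                    radius = 1.3, intensity = 900)),
                 cell = list(center = c(7, 5, 3.5 + 1.3 + 1.4),
                             semi_axes = c(3.2, 2.6, 1.8), intensity = 1400),
                 seed = seed + 4L),
    dims = c(40L, 40L, 56L), voxel_size = iso)

  # cell well separated from the fiber: true contact set is empty
  out$cell_far <- render_phantom(
    phantom_spec(fibers = list(list(point = c(0, 2, 1.5),
                                    direction = c(1, 0, 0),
                                    radius = 1.0, intensity = 900)),
                 cell = list(center = c(6, 8, 7),
                             semi_axes = c(2.2, 1.8, 1.4), intensity = 1400),
                 seed = seed + 5L),
    dims = c(40L, 44L, 48L), voxel_size = iso)

  # strong bleed-through: a bright cell leaks into the scaffold channel
  out$bleed <- render_phantom(
    phantom_spec(fibers = list(list(point = c(0, 2.5, 2), direction = c(1, 0, 0),
                                    radius = 1.0, intensity = 800)),
                 cell = list(center = c(7, 8, 6),
                             semi_axes = c(3.0, 2.4, 2.0), intensity = 2500),
                 bleed_alpha = 0.3, seed = seed + 6L),
    dims = c(40L, 44L, 56L), voxel_size = iso)

  out
}
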