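#' Volumetric z-stack container
#'
#' A `zstack` wraps a 3D voxel grid in `(z, y, x)` order together with the
#' physical voxel size and a channel name. It is the raw measurement unit of
#' the package: every segmentation and contact operation consumes and returns
#' these objects. Intensities are stored as doubles in memory; on disk the
#' canonical representation is 16-bit unsigned multi-page TIFF.
#'
#' @param voxels numeric 3D array in `(z, y, x)` order with finite,
#'   nonnegative intensities.
#' @param voxel_size numeric length-3 vector `(dz, dy, dx)` in micrometers.
#'   The default `c(0.462, 0.12, 0.12)` matches a 63x confocal acquisition
#'   with 0.12 um lateral and 0.462 um axial sampling.
#' @param channel channel name, e.g. `"cell"` or `"scaffold"`.
#' @return an object of class `zstack`.
#' @export
zstack <- function(voxels, voxel_size = c(0.462, 0.12, 0.12), channel = "") {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array in (z, y, x) order")
  if (any(dim(voxels) < 1L)) stop("all dimensions must be >= 1")
  if (!all(is.finite(voxels))) stop("intensities must be finite")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be three positive values (dz, dy, dx) in um")
  structure(list(voxels = voxels, voxel_size = voxel_size,
                 channel = as.character(channel)[1]),
            class = "zstack")
}

#' @export
print.zstack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<zstack> %s  %d x %d x %d (z,y,x)  voxel %g x %g x %g um\n",
              if (nzchar(x$channel)) x$channel else "(unnamed)",
              d[1], d[2], d[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  intensity range [%g, %g]\n", min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' @export
dim.zstack <- function(x) dim(x$voxels)

#' Co-registered cell/scaffold z-stack pair
#'
#' Both channels must share grid dimensions and voxel size; they are imaged
#' simultaneously through two detection bands and are therefore voxel-wise
#' co-registered.
#'
#' @param cell,scaffold `zstack` objects.
#' @return an object of class `zstack_pair`.
#' @export
zstack_pair <- function(cell, scaffold) {
  stopifnot(inherits(cell, "zstack"), inherits(scaffold, "zstack"))
  if (!identical(dim(cell$voxels), dim(scaffold$voxels)))
    stop("cell and scaffold stacks must have identical dimensions")
  if (!isTRUE(all.equal(cell$voxel_size, scaffold$voxel_size)))
    stop("cell and scaffold stacks must share voxel_size")
  structure(list(cell = cell, scaffold = scaffold), class = "zstack_pair")
}

#' @export
print.zstack_pair <- function(x, ...) {
  cat("<zstack_pair>\n")
  print(x$cell); print(x$scaffold)
  invisible(x)
}

sidecar_path <- function(path) paste0(path, ".json")

#' Read a z-stack from multi-page TIFF
#'
#' Accepts a single multi-page TIFF or a z-ordered character vector of
#' single-frame TIFF files. Voxel size is taken from a JSON sidecar
#' (`<path>.json` with fields `voxel_size`, `channel`) when present,
#' otherwise from the `voxel_size` argument.
#'
#' @param path file path, or ordered vector of frame paths.
#' @param voxel_size fallback `(dz, dy, dx)` in um.
#' @param channel fallback channel name.
#' @return a [zstack].
#' @export
read_zstack <- function(path, voxel_size = c(0.462, 0.12, 0.12), channel = "") {
  frames <- list()
  for (p in path) {
    if (!file.exists(p)) stop("cannot read file: ", p)
    f <- tiff::readTIFF(p, all = TRUE, as.is = TRUE)
    if (!is.list(f)) f <- list(f)
    frames <- c(frames, f)
  }
  shapes <- vapply(frames, function(m) paste(dim(m), collapse = "x"), "")
  if (length(unique(shapes)) != 1L)
    stop("frames have mixed shapes: ", paste(unique(shapes), collapse = ", "))
  d2 <- dim(frames[[1]])
  vox <- array(0, c(length(frames), d2[1], d2[2]))
  for (z in seq_along(frames)) vox[z, , ] <- frames[[z]]
  sc <- sidecar_path(path[1])
  if (length(path) == 1L && file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$voxel_size)) voxel_size <- as.numeric(meta$voxel_size)
    if (!is.null(meta$channel)) channel <- meta$channel
  }
  zstack(vox, voxel_size = voxel_size, channel = channel)
}

#' Write a z-stack as 16-bit multi-page TIFF
#'
#' Values are rounded to integers and clipped to the 16-bit range; a JSON
#' sidecar with voxel size and channel name is written next to the image so
#' that [read_zstack] round-trips metadata.
#'
#' @param stack a [zstack].
#' @param path output TIFF path.
#' @param sidecar write the JSON metadata sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_zstack <- function(stack, path, sidecar = TRUE) {
  stopifnot(inherits(stack, "zstack"))
  vox <- pmin(pmax(round(stack$voxels), 0), 65535)
  frames <- lapply(seq_len(dim(vox)[1]), function(z) vox[z, , ] / 65535)
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  if (sidecar)
    jsonlite::write_json(
      list(voxel_size = stack$voxel_size, channel = stack$channel),
      sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a NIfTI volume as a z-stack
#'
#' Interoperability reader for NIfTI-1 files (requires the RNifti package).
#' The on-disk (x, y, z) axis order is transposed to the package's (z, y, x)
#' convention and the pixel dimensions are carried over as voxel size.
#'
#' @param path NIfTI file path.
#' @param channel channel name.
#' @return a [zstack].
#' @export
read_zstack_nifti <- function(path, channel = "") {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("NIfTI support requires the RNifti package")
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L) stop("expected a 3D NIfTI volume")
  pd <- attr(RNifti::niftiHeader(img), "pixdim")
  pix <- RNifti::pixdim(img)
  vox <- aperm(as.array(img), c(3, 2, 1))
  zstack(vox, voxel_size = rev(pix[1:3]), channel = channel)
}

#' Maximum-intensity projection
#'
#' Collapses one axis of the volume by taking the per-element maximum, the
#' standard 2D rendering of confocal stacks. Projecting along `"y"` gives the
#' `[X, Z]` view used to build z-profiles for crop-boundary selection.
#'
#' @param stack a [zstack] or 3D array.
#' @param axis one of `"z"`, `"y"`, `"x"`: the axis collapsed.
#' @return a 2D matrix; rows/cols follow the retained axes in (z,y,x) order.
#' @export
max_projection <- function(stack, axis = c("z", "y", "x")) {
  axis <- match.arg(axis)
  vox <- if (inherits(stack, "zstack")) stack$voxels else stack
  margin <- switch(axis, z = c(2, 3), y = c(1, 3), x = c(1, 2))
  apply(vox, margin, max)
}
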