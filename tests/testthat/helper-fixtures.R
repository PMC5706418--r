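# Shared phantom fixtures, rendered once per test run.

.fixture_cache <- new.env(parent = emptyenv())

fixtures <- function(seed = 1L) {
  key <- paste0("suite_", seed)
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- sample_fixture_suite(seed)
  .fixture_cache[[key]]
}

# noiseless, unblurred axis-aligned cylinder along x (isotropic unit voxels)
clean_cylinder <- function(radius_vox = 5, dims = c(16L, 24L, 24L),
                           axis_y = 12, axis_z = 8) {
  render_phantom(
    phantom_spec(fibers = list(list(point = c(0, axis_y + 0.5, axis_z + 0.5),
                                    direction = c(1, 0, 0),
                                    radius = radius_vox, intensity = 1000)),
                 background_offset = 100, noise_sigma = 0, bleed_alpha = 0,
                 blur_sigma = c(0, 0, 0), seed = 1),
    dims = dims, voxel_size = c(1, 1, 1))
}

# the anisotropic confocal-sampling cell-on-fiber scene used for end-to-end
# contact recovery (voxel 0.462 x 0.12 x 0.12 um, MF-like fiber)
confocal_cell_on_fiber <- function(seed = 5L) {
  render_phantom(
    phantom_spec(fibers = list(list(point = c(0, 4.8, 4.5),
                                    direction = c(1, 0, 0),
                                    radius = 1.3, intensity = 900)),
                 cell = list(center = c(4.8, 4.8, 4.5 + 1.3 + 1.2),
                             semi_axes = c(3.2, 2.6, 1.6), intensity = 1400),
                 seed = seed),
    dims = c(40L, 80L, 80L), voxel_size = c(0.462, 0.12, 0.12))
}

expect_same_mask <- function(a, b) {
  expect_identical(dim(a), dim(b))
  expect_equal(sum(xor(a, b)), 0)
}
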