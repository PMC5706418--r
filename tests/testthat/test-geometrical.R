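test_that("plane fit is exact on noiseless data and honest about rank", {
  # horizontal plane of voxels at a single z, unit weights
  vox <- array(0, c(20, 6, 6)); vox[10, , ] <- 1000
  st <- zstack(vox, voxel_size = c(0.462, 0.12, 0.12))
  w <- array(0, dim(vox)); w[10, , ] <- 1
  f <- fit_plane_wls(st, w)
  expect_equal(f$residual_std_nm, 0, tolerance = 1e-6)
  expect_equal(abs(f$coeffs[3]), 1, tolerance = 1e-9)
  expect_equal(abs(f$coeffs[4]), 9.5 * 0.462, tolerance = 1e-9)
  expect_equal(f$n, 36)
  # too few / collinear points are rejected
  expect_error(fit_plane_wls(cbind(0:1, 0:1, 0:1)), "at least 4")
  expect_error(fit_plane_wls(cbind(0:9, 0:9, 0:9)), "collinear")
})

test_that("residual standard deviation recovers injected surface noise", {
  set.seed(21)
  n <- 2e4
  x <- runif(n, 0, 50); y <- runif(n, 0, 50)
  z <- 0.02 * x - 0.01 * y + 5 + rnorm(n, sd = 0.1)   # 100 nm in um units
  f <- fit_plane_wls(cbind(x, y, z))
  expect_lt(abs(f$residual_std_nm - 100), 15)
  truth <- c(-0.02, 0.01, 1); truth <- truth / sqrt(sum(truth^2))
  angle <- acos(min(abs(sum(f$coeffs[1:3] * truth)), 1)) * 180 / pi
  expect_lt(angle, 1)
})

test_that("pooled standard deviation follows the variance-weighted formula", {
  fit <- function(n, s) list(n = n, residual_std_nm = s)
  expect_equal(pooled_std(list(fit(3, 1), fit(3, 3))), sqrt(5))
  expect_equal(pooled_std(rep(list(fit(100, 105.1)), 7)), 105.1)
  # K = 1 closed-form limit: pooled reduces to the single residual SD
  expect_equal(pooled_std(list(fit(50, 87.3))), 87.3)
  expect_error(pooled_std(list(fit(1, 5))), "n >= 2")
})

test_that("vesselness prefers tubes over plates and localizes the axis", {
  expect_true(all(vesselness(array(5, c(10, 10, 10))) == 0))
  vs <- c(1, 1, 1)
  # equal-intensity cylinder and slab, no noise
  cyl <- clean_cylinder(radius_vox = 2, dims = c(20L, 24L, 24L),
                        axis_y = 12, axis_z = 10)
  slab <- render_phantom(
    phantom_spec("spun_coat", plane = list(coeffs = c(0, 0, 1, -10),
                                           thickness = 4),
                 background_offset = 100, noise_sigma = 0, bleed_alpha = 0,
                 blur_sigma = c(0, 0, 0), scaffold_intensity = 1000,
                 seed = 1),
    c(24, 24, 24), vs)
  v_cyl <- vesselness(zstack(cyl$pair$scaffold$voxels, vs), sigma = 1.5)
  v_slab <- vesselness(zstack(slab$pair$scaffold$voxels, vs), sigma = 1.5)
  expect_gt(max(v_cyl), max(v_slab))
  # response peak sits on the cylinder axis (y = 12.5, z = 10.5 in um)
  peak <- which(v_cyl == max(v_cyl), arr.ind = TRUE)[1, ]
  expect_lte(abs(peak[2] - 0.5 - 12.5), 1)
  expect_lte(abs(peak[1] - 0.5 - 10.5), 1)
})

test_that("ad-hoc segmentation keeps fibers and drops salt noise", {
  f <- clean_cylinder(radius_vox = 8, dims = c(24L, 30L, 32L),
                      axis_y = 15, axis_z = 11)
  vox <- f$pair$scaffold$voxels
  set.seed(30)
  salt <- sample(which(vox < 500), 40)
  vox[salt] <- 1000                       # isolated foreground-bright voxels
  mask <- adhoc_segment(zstack(vox))
  expect_gte(sum(mask & f$truth$scaffold) / sum(f$truth$scaffold), 0.95)
  expect_true(all(!mask[salt]))
  expect_error(adhoc_segment(zstack(array(7, c(5, 5, 5)))), "constant")
})

test_that("spun-coat geometric segmentation tracks the slab surface", {
  f <- fixtures()$spun_coat
  mask <- geometric_scaffold_segment(f$pair$scaffold, "SC", "A6")
  expect_true(any(mask))
  # every segmented voxel lies within one z-voxel of the true upper surface
  cf <- f$spec$plane$coeffs
  nrm <- sqrt(sum(cf[1:3]^2))
  vs <- f$pair$scaffold$voxel_size
  idx <- which(mask, arr.ind = TRUE)
  zs <- (idx[, 1] - 0.5) * vs[1]
  ys <- (idx[, 2] - 0.5) * vs[2]
  xs <- (idx[, 3] - 0.5) * vs[3]
  f_up <- (cf[1] * xs + cf[2] * ys + cf[3] * zs + cf[4]) / nrm -
          f$spec$plane$thickness
  expect_lt(max(abs(f_up)), 2 * vs[1])
  fits <- attr(mask, "plane_fits")
  expect_lt(fits$upper$residual_std_nm, vs[1] * 1000)
})

test_that("the vesselness scale closest to the fiber radius segments best", {
  vs <- c(0.25, 0.25, 0.25)
  thin_f <- render_phantom(
    phantom_spec(fibers = list(list(point = c(0, 4, 3.5),
                                    direction = c(1, 0, 0),
                                    radius = 0.3, intensity = 900)),
                 seed = 2),
    c(28, 32, 40), vs)
  masks <- lapply(c(A6 = "A6", A7 = "A7"), function(m)
    geometric_scaffold_segment(thin_f$pair$scaffold, "MF", m))
  jac <- vapply(masks, cellscaffold:::jaccard_index,
                0, b = thin_f$truth$scaffold)
  expect_true(all(vapply(masks, any, TRUE)))
  expect_gte(jac["A6"], jac["A7"])     # sigma = 1.0 matches a ~1-voxel tube
})

test_that("binary contact matches a brute-force double loop", {
  # co-occurrence and 1-voxel adjacency trivials
  a <- array(FALSE, c(8, 8, 8)); b <- array(FALSE, c(8, 8, 8))
  a[5, 5, 5] <- TRUE; b[5, 5, 5] <- TRUE
  expect_equal(sum(binary_contact(a, b)), 1)
  b[5, 5, 5] <- FALSE; b[5, 5, 6] <- TRUE
  ct <- binary_contact(a, b)
  expect_true(ct[5, 5, 5] && ct[5, 5, 6] && sum(ct) == 2)
  b[5, 5, 6] <- FALSE; b[2, 2, 2] <- TRUE
  expect_equal(sum(binary_contact(a, b)), 0)
  expect_error(binary_contact(a, array(FALSE, c(2, 2, 2))), "congruent")
  # randomized oracle, both connectivities, symmetry
  brute <- function(cm, sm, conn) {
    d <- dim(cm)
    out <- array(FALSE, d)
    lim <- if (conn == 26) function(dz, dy, dx) TRUE
           else function(dz, dy, dx) abs(dz) + abs(dy) + abs(dx) <= 1
    for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
      if (!cm[z, y, x] && !sm[z, y, x]) next
      near_c <- FALSE; near_s <- FALSE
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (!lim(dz, dy, dx)) next
        z2 <- z + dz; y2 <- y + dy; x2 <- x + dx
        if (z2 < 1 || z2 > d[1] || y2 < 1 || y2 > d[2] ||
            x2 < 1 || x2 > d[3]) next
        if (cm[z2, y2, x2]) near_c <- TRUE
        if (sm[z2, y2, x2]) near_s <- TRUE
      }
      out[z, y, x] <- (cm[z, y, x] && near_s) || (sm[z, y, x] && near_c)
    }
    out
  }
  for (s in 1:3) {
    set.seed(s)
    cm <- array(runif(10^3) < 0.08, c(10, 10, 10))
    sm <- array(runif(10^3) < 0.08, c(10, 10, 10))
    for (conn in c(6, 26)) {
      got <- binary_contact(cm, sm, conn)
      expect_same_mask(got, brute(cm, sm, conn))
      expect_identical(got, binary_contact(sm, cm, conn))
    }
  }
})

test_that("contact surface equals the gradient-support oracle", {
  surf_oracle <- function(seg) {
    d <- dim(seg); v <- seg + 0
    out <- array(FALSE, d)
    for (z in 2:(d[1] - 1)) for (y in 2:(d[2] - 1)) for (x in 2:(d[3] - 1)) {
      if (!seg[z, y, x]) next
      g <- c(v[z + 1, y, x] - v[z - 1, y, x],
             v[z, y + 1, x] - v[z, y - 1, x],
             v[z, y, x + 1] - v[z, y, x - 1]) / 2
      out[z, y, x] <- any(g != 0)
    }
    out
  }
  seg <- array(FALSE, c(9, 9, 9)); seg[3:7, 3:7, 3:7] <- TRUE
  got <- contact_surface(seg)
  expect_same_mask(got, surf_oracle(seg))
  expect_equal(sum(got), 5^3 - 3^3)          # the 98 cube boundary voxels
  # a single voxel has zero central-difference gradient at itself
  single <- array(FALSE, c(5, 5, 5)); single[3, 3, 3] <- TRUE
  expect_same_mask(contact_surface(single), surf_oracle(single))
  # an all-foreground volume has no interior gradient support
  expect_equal(sum(contact_surface(array(TRUE, c(6, 6, 6)))), 0)
})
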