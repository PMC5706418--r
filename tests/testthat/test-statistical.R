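# independent exhaustive oracle for the entropy criterion
kapur_oracle <- function(x, n_bins = 256L) {
  breaks <- seq(min(x), max(x), length.out = n_bins + 1L)
  counts <- tabulate(findInterval(x, breaks, all.inside = TRUE),
                     nbins = n_bins)
  p <- counts / sum(counts)
  best <- -Inf; best_t <- NA
  for (t in 1:(n_bins - 1L)) {
    pb <- p[1:t]; pf <- p[(t + 1):n_bins]
    if (sum(pb) == 0 || sum(pf) == 0) next
    qb <- pb[pb > 0] / sum(pb); qf <- pf[pf > 0] / sum(pf)
    h <- -sum(qb * log(qb)) - sum(qf * log(qf))
    if (h > best) { best <- h; best_t <- t }
  }
  breaks[best_t + 1L]
}

test_that("entropy threshold separates a two-valued volume", {
  set.seed(1)
  v <- array(sample(c(0.1, 0.9), 4^3, replace = TRUE), c(4, 4, 4))
  th <- max_entropy_threshold(v)
  expect_same_mask(th$mask, array(v == 0.9, dim(v)))
  expect_error(max_entropy_threshold(array(1, c(3, 3, 3))), "constant")
})

test_that("entropy threshold equals the exhaustive-search oracle", {
  # 8-bin histogram with prescribed counts
  counts <- c(5, 10, 20, 5, 0, 5, 20, 10)
  x <- rep(seq(0, 7) + 0.5, times = counts)
  x[1] <- -0.01; x[length(x)] <- 8.01      # pin the range
  th <- max_entropy_threshold(array(x, c(1, 1, length(x))), n_bins = 8L)
  expect_equal(th$threshold, kapur_oracle(x, 8L))
  # random volumes at full resolution
  for (s in 1:3) {
    set.seed(s)
    v <- array(rgamma(12^3, shape = 2), c(12, 12, 12))
    th <- max_entropy_threshold(v)
    expect_equal(th$threshold, kapur_oracle(as.vector(v)))
  }
})

test_that("entropy threshold is translation-equivariant", {
  set.seed(4)
  v <- array(rnorm(10^3, 100, 20), c(10, 10, 10))
  t0 <- max_entropy_threshold(v)$threshold
  t1 <- max_entropy_threshold(v + 250)$threshold
  expect_equal(t1, t0 + 250, tolerance = 1e-10)
})

test_that("the single-pixel model is symmetric at the background mean", {
  bg <- structure(list(mean = 100, std = 10, source_frame = "first"),
                  class = "background_model")
  st <- zstack(array(c(100, 90, 110, 100), c(1, 2, 2)))
  p <- foreground_probability(st, bg, "A1")
  expect_equal(p$values[1, 1, 1], 0.5)
  expect_equal(p$values[1, 2, 2], 0.5)
  expect_equal(p$values[1, 1, 2], pnorm(1))
})

test_that("all five models separate a noiseless two-level phantom", {
  ph <- render_phantom(
    phantom_spec(fibers = list(list(point = c(0, 3, 2.5),
                                    direction = c(1, 0, 0),
                                    radius = 1.2, intensity = 900)),
                 background_offset = 100, noise_sigma = 0, bleed_alpha = 0,
                 blur_sigma = c(0, 0, 0), seed = 1),
    c(24, 24, 32), c(0.25, 0.25, 0.25))
  st <- ph$pair$scaffold
  bg <- estimate_background(st)
  truth <- ph$truth$scaffold
  # evaluate away from the 1-voxel partial-volume shell the A2 pooling spans
  core <- cellscaffold:::erode_mask(truth)
  far_bg <- !cellscaffold:::dilate_mask(truth)
  for (m in paste0("A", 1:5)) {
    p <- foreground_probability(st, bg, m, partner = ph$pair$cell)
    expect_true(all(p$values[core] > 0.99), label = paste(m, "foreground"))
    expect_true(all(p$values[far_bg] < 0.01), label = paste(m, "background"))
  }
})

test_that("the channel model recovers the bleed coefficient", {
  b <- fixtures()$bleed                     # rendered with bleed_alpha = 0.3
  bg <- estimate_background(b$pair$scaffold)
  p <- foreground_probability(b$pair$scaffold, bg, "A3",
                              partner = b$pair$cell)
  est <- p$params$bleed_alpha_hat
  expect_lt(abs(est - 0.3), 0.05)
  # regression oracle restricted to ground-truth pure-cell voxels
  pure <- b$truth$cell & !cellscaffold:::dilate_mask(b$truth$scaffold)
  mu_c <- estimate_background(b$pair$cell)$mean
  fit <- lm(I(b$pair$scaffold$voxels[pure] - bg$mean) ~
              I(b$pair$cell$voxels[pure] - mu_c) - 1)
  expect_lt(abs(est - coef(fit)[[1]]), 0.03)
})

test_that("mixed-pixel probability is monotone in the voxel's own intensity", {
  set.seed(8)
  vox <- array(rnorm(8^3, 100, 10), c(8, 8, 8))
  vox[4, 4, 4] <- 400                      # ensure a foreground reference
  bg <- structure(list(mean = 100, std = 10, source_frame = "first"),
                  class = "background_model")
  for (target in list(c(2, 3, 5), c(6, 6, 2))) {
    vals <- seq(80, 420, by = 20)
    probs <- vapply(vals, function(v) {
      vv <- vox; vv[target[1], target[2], target[3]] <- v
      p <- foreground_probability(zstack(vv), bg, "A2")
      p$values[target[1], target[2], target[3]]
    }, 0)
    expect_true(all(diff(probs) >= -1e-12))
  }
})

test_that("k-means priors satisfy the probability axioms", {
  # three tight, well-separated clouds + probe points
  set.seed(10)
  n <- 1000
  pts <- rbind(
    cbind(rnorm(n, 10, 1), rnorm(n, 10, 1)),       # background
    cbind(rnorm(n, 500, 1), rnorm(n, 30, 1)),      # cell
    cbind(rnorm(n, 30, 1), rnorm(n, 500, 1)))      # scaffold
  probe_eq <- c(265, 265)    # roughly equidistant from all three centroids
  pts <- rbind(pts, probe_eq)
  m <- nrow(pts)
  pair <- zstack_pair(zstack(array(pts[, 1], c(1, 1, m))),
                      zstack(array(pts[, 2], c(1, 1, m))))
  pr <- kmeans_priors(pair, seed = 2)
  total <- pr$p_cell + pr$p_scaffold + pr$p_bkg
  expect_lt(max(abs(total - 1)), 1e-9)
  lab_true <- rep(c("bkg", "cell", "scaffold"), each = n)
  p <- cbind(bkg = pr$p_bkg[seq_len(3 * n)],
             cell = pr$p_cell[seq_len(3 * n)],
             scaffold = pr$p_scaffold[seq_len(3 * n)])
  winner <- colnames(p)[max.col(p)]
  expect_gte(mean(winner == lab_true), 0.99)
  # a voxel exactly on a centroid gets probability one
  cen <- pr$model$centroids[pr$model$classes["cell"], ]
  pair2 <- zstack_pair(zstack(array(c(pts[, 1], cen[1]), c(1, 1, m + 1))),
                       zstack(array(c(pts[, 2], cen[2]), c(1, 1, m + 1))))
  pr2 <- kmeans_priors(pair2, seed = 2)
  expect_equal(pr2$p_cell[1, 1, m + 1], 1)
  # near-equidistant probe: all three probabilities close to 1/3
  i <- 3 * n + 1
  expect_lt(max(abs(c(pr$p_cell[i], pr$p_scaffold[i], pr$p_bkg[i]) - 1 / 3)),
            0.05)
  expect_error(kmeans_priors(zstack_pair(zstack(array(1, c(1, 1, 8))),
                                         zstack(array(2, c(1, 1, 8))))),
               "distinct")
})

test_that("total-probability contact follows the voxelwise formula", {
  f <- fixtures()$cell_on_fiber
  cr <- crop_roi(f$pair, f$truth$cell)
  pr <- kmeans_priors(cr$pair, seed = 1)
  dims <- dim(cr$pair$cell$voxels)
  zeros <- array(0, dims); ones <- array(1, dims)
  expect_true(all(contact_probability(zeros, zeros, pr)$values == 0))
  expect_equal(contact_probability(ones, ones, pr)$values, 1 - pr$p_bkg)
  set.seed(3)
  a <- array(runif(prod(dims)), dims); b <- array(runif(prod(dims)), dims)
  got <- contact_probability(a, b, pr)$values
  # scalar-loop oracle on a corner block
  for (z in 1:3) for (y in 1:4) for (x in 1:4)
    expect_equal(got[z, y, x],
                 a[z, y, x] * pr$p_cell[z, y, x] +
                 b[z, y, x] * pr$p_scaffold[z, y, x])
  # P(Contact) <= 1 - P(BKG) everywhere
  expect_true(all(got <= 1 - pr$p_bkg + 1e-12))
  expect_error(contact_probability(array(0, c(2, 2, 2)), b, pr),
               "congruent")
})

test_that("the mixed-pixel channel pair is the most similar model pair", {
  f <- fixtures()$cell_on_fiber
  cr <- crop_roi(f$pair, f$truth$cell)
  bg <- estimate_background(cr$pair$scaffold)
  maps <- lapply(setNames(nm = paste0("A", 1:5)), function(m)
    foreground_probability(cr$pair$scaffold, bg, m, partner = cr$pair$cell))
  dm <- distance_matrix(maps)
  expect_equal(min(dm[upper.tri(dm)]), dm["A2", "A3"])
})
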