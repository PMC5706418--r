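#' Maximum-entropy (Kapur) threshold
#'
#' Adaptive binarization by entropy maximization: the intensity histogram is
#' split at a candidate threshold T, the below-T and at-or-above-T halves are
#' renormalized, and the optimal threshold maximizes the sum of the Shannon
#' entropies of foreground and background,
#' `T_opt = argmax { H_FRG(T) + H_BKG(T) }`. Candidates where either side has
#' zero mass are excluded; ties resolve to the lowest cut.
#'
#' @param volume numeric array (any shape); must be non-constant.
#' @param n_bins histogram resolution (default 256).
#' @return list with `threshold` (intensity value; the mask is
#'   `volume >= threshold`), `criterion` (the `H_FRG + H_BKG` trace over the
#'   `n_bins - 1` candidate cuts), `mask` (logical, same shape), and
#'   `breaks`.
#' @export
max_entropy_threshold <- function(volume, n_bins = 256L) {
  x <- if (inherits(volume, "zstack")) volume$voxels else volume
  lo <- min(x); hi <- max(x)
  if (!is.finite(lo) || lo == hi)
    stop("no valid threshold: volume is constant")
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  bin <- findInterval(x, breaks, all.inside = TRUE)
  p <- tabulate(bin, nbins = n_bins)
  p <- p / sum(p)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  crit <- rep(-Inf, n_bins - 1L)
  cum <- cumsum(p)
  for (t in seq_len(n_bins - 1L)) {
    wb <- cum[t]; wf <- 1 - wb
    if (wb <= 0 || wf <= 0) next
    crit[t] <- ent(p[seq_len(t)] / wb) + ent(p[(t + 1L):n_bins] / wf)
  }
  if (!any(is.finite(crit))) stop("no valid threshold: degenerate histogram")
  t_opt <- which.max(crit)
  thr <- breaks[t_opt + 1L]
  mask <- array(x >= thr, dim(x))
  list(threshold = thr, criterion = crit, mask = mask, breaks = breaks)
}

#' Per-voxel probability volume
#'
#' Thin wrapper marking a 3D grid of values in `[0, 1]` with its semantics
#' (e.g. `P(Contact|Cell)`, `P(Contact|Scaffold)`, `P(Contact)`).
#'
#' @param values numeric 3D array in `[0, 1]`.
#' @param semantics free-text description of what the probability means.
#' @param params optional list of model parameters recorded for provenance.
#' @return object of class `prob_volume`.
#' @export
prob_volume <- function(values, semantics = "", params = list()) {
  stopifnot(min(values) >= 0, max(values) <= 1)
  structure(list(values = values, semantics = semantics, params = params),
            class = "prob_volume")
}

prob_values <- function(x) if (inherits(x, "prob_volume")) x$values else x

#' @export
print.prob_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<prob_volume> %s  %d x %d x %d  range [%.4g, %.4g]\n",
              x$semantics, d[1], d[2], d[3], min(x$values), max(x$values)))
  invisible(x)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# A1: Gaussian upper-tail posterior against the background model.
fg_prob_a1 <- function(vox, background) {
  mu <- background$mean; sd <- background$std
  if (sd == 0) {
    if (min(vox) == max(vox)) {
      warning("constant stack with zero background spread; returning zeros")
      return(array(0, dim(vox)))
    }
    # zero-spread limit of the Gaussian tail rule: only strictly brighter
    # voxels are foreground
    return(array((vox > mu) + 0, dim(vox)))
  }
  array(stats::pnorm((vox - mu) / sd), dim(vox))
}

# A2: partial-volume (mixed-pixel) fraction, mean-pooled over 3x3x1.
fg_prob_a2 <- function(vox, background) {
  p1 <- fg_prob_a1(vox, background)
  pos <- p1 >= 0.5
  if (!any(pos)) {
    warning("no foreground candidates for the mixed-pixel model")
    return(array(0, dim(vox)))
  }
  i_frg <- stats::quantile(vox[pos], 0.99, names = FALSE)
  if (i_frg <= background$mean) return(array(0, dim(vox)))
  alpha <- clamp01((vox - background$mean) / (i_frg - background$mean))
  box <- c(1, 1, 1) / 3
  alpha <- conv_axis(conv_axis(alpha, box, 2L), box, 3L)
  clamp01(alpha)
}

# A3: subtract the estimated cross-channel bleed, then the mixed-pixel model.
# The mixing coefficient is the median of per-voxel background-subtracted
# intensity ratios over strongly partner-positive voxels; on pure-partner
# voxels that ratio equals the bleed coefficient exactly, and the median is
# robust to the minority of voxels where both structures overlap.
fg_prob_a3 <- function(vox, background, partner_vox, partner_background) {
  mu_p <- partner_background$mean
  sd_p <- max(partner_background$std, .Machine$double.eps)
  strong <- (partner_vox - mu_p) > 4 * sd_p
  if (sum(strong) < 10) {
    warning("too few partner-positive voxels; bleed coefficient set to 0")
    alpha_hat <- 0
  } else {
    r <- (vox[strong] - background$mean) / (partner_vox[strong] - mu_p)
    alpha_hat <- stats::median(r)
    alpha_hat <- min(max(alpha_hat, 0), 0.95)
  }
  corrected <- vox - alpha_hat * pmax(partner_vox - mu_p, 0)
  p <- fg_prob_a2(array(corrected, dim(vox)), background)
  attr(p, "bleed_alpha_hat") <- alpha_hat
  p
}

# A4: two-component Gaussian mixture, background component fixed, foreground
# fitted by EM; returns the foreground responsibility.
fg_prob_a4 <- function(vox, background, max_iter = 100L, tol = 1e-8) {
  x <- as.vector(vox)
  rng <- max(x) - min(x)
  mu0 <- background$mean
  sd0 <- max(background$std, 1e-6 * max(rng, 1))
  mu1 <- stats::quantile(x, 0.99, names = FALSE)
  sd1 <- sd0
  pi1 <- min(max(mean(x > mu0 + 2 * sd0), 0.01), 0.9)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    d1 <- pi1 * stats::dnorm(x, mu1, sd1)
    d0 <- (1 - pi1) * stats::dnorm(x, mu0, sd0)
    tot <- d1 + d0
    tot[tot == 0] <- .Machine$double.xmin
    r1 <- d1 / tot
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll_old) + 1)) break
    ll_old <- ll
    w <- sum(r1)
    if (w < 1e-12) break
    mu1 <- sum(r1 * x) / w
    sd1 <- sqrt(max(sum(r1 * (x - mu1)^2) / w, (1e-6 * max(rng, 1))^2))
    pi1 <- min(max(w / length(x), 1e-6), 1 - 1e-6)
    if (mu1 < mu0) mu1 <- mu0 + sd0   # keep the foreground component above
  }
  array(r1, dim(vox))
}

# A5: Ising-regularized A1 posterior via iterated conditional modes on the
# 6-neighborhood; returns the smoothed soft posterior.
fg_prob_a5 <- function(vox, background, beta = 1.0, max_iter = 10L) {
  p1 <- fg_prob_a1(vox, background)
  p1 <- pmin(pmax(p1, 1e-6), 1 - 1e-6)
  u <- log(p1 / (1 - p1))
  labels <- p1 >= 0.5
  off <- neighbor_offsets(6)
  field <- function(lab) {
    s <- array(0, dim(lab))
    for (i in seq_len(nrow(off))) {
      nb <- shift_volume(lab + 0, off$dz[i], off$dy[i], off$dx[i], fill = NA)
      s <- s + ifelse(is.na(nb), 0, 2 * nb - 1)   # +1 fg, -1 bg, 0 outside
    }
    s
  }
  for (it in seq_len(max_iter)) {
    new_labels <- (u + beta * field(labels)) >= 0
    if (identical(new_labels, labels)) break
    labels <- new_labels
  }
  array(stats::plogis(u + beta * field(labels)), dim(vox))
}

#' Statistical foreground probability (models A1-A5)
#'
#' Five per-voxel foreground models of increasing structure, applied to one
#' channel given its background intensity model:
#' \describe{
#'   \item{A1 single-pixel}{Gaussian upper-tail posterior
#'     `P = Phi((I - mu_BKG) / sigma_BKG)`.}
#'   \item{A2 mixed-pixel spatial}{partial-volume fraction
#'     `(I - mu_BKG) / (I_FRG - mu_BKG)` clamped to `[0,1]` (with `I_FRG`
#'     the 99th percentile of A1-positive intensities), mean-pooled over an
#'     in-plane 3x3 neighborhood.}
#'   \item{A3 mixed-pixel channel}{estimates the cross-channel bleed-through
#'     coefficient from strongly partner-positive voxels, subtracts the
#'     leaked signal, then applies A2. Requires `partner`.}
#'   \item{A4 additive noise}{two-component Gaussian mixture with the
#'     background component fixed at the background model; returns the
#'     foreground responsibility.}
#'   \item{A5 Markov random field}{A1 posterior regularized by an Ising
#'     prior (6-neighborhood, smoothing weight `beta = 1`, iterated
#'     conditional modes, at most 10 sweeps).}
#' }
#'
#' @param stack a [zstack] of the channel to model.
#' @param background its [estimate_background] model.
#' @param model `"A1"` to `"A5"`.
#' @param partner the co-registered other channel ([zstack]); required for
#'   A3, whose partner background is estimated from the same frame.
#' @return a [prob_volume] of `P(foreground)`; for A3 the estimated bleed
#'   coefficient is in `$params$bleed_alpha_hat`.
#' @export
foreground_probability <- function(stack, background,
                                   model = c("A1", "A2", "A3", "A4", "A5"),
                                   partner = NULL) {
  stopifnot(inherits(stack, "zstack"), inherits(background, "background_model"))
  model <- match.arg(model)
  vox <- stack$voxels
  params <- list(model = model)
  p <- switch(model,
    A1 = fg_prob_a1(vox, background),
    A2 = fg_prob_a2(vox, background),
    A3 = {
      if (is.null(partner)) stop("model A3 requires the partner channel")
      pb <- estimate_background(partner, background$source_frame)
      pp <- fg_prob_a3(vox, background, partner$voxels, pb)
      params$bleed_alpha_hat <- attr(pp, "bleed_alpha_hat")
      pp
    },
    A4 = fg_prob_a4(vox, background),
    A5 = fg_prob_a5(vox, background))
  prob_volume(clamp01(p), semantics = paste0("P(foreground|", model, ")"),
              params = params)
}

#' K-means priors from the two-channel intensity scatter
#'
#' Partitions the 2D scatter of `(cell intensity, scaffold intensity)` voxel
#' pairs into K = 3 clusters (background, cell, scaffold) and converts each
#' voxel's distances to the three centroids into class probabilities by
#' inverse-distance weighting, so that
#' `P(Cell) + P(Scaffold) + P(BKG) = 1` at every voxel and a voxel lying on
#' a centroid gets probability 1 for that class. The background centroid is
#' the one nearest the origin; of the remaining two, the one with the larger
#' cell-channel coordinate is the cell.
#'
#' @param pair a [zstack_pair].
#' @param seed RNG seed for the clustering initialization (recorded in the
#'   result).
#' @param max_points clustering subsample cap; volumes larger than this are
#'   subsampled (the per-voxel probabilities always use all voxels).
#' @return list with `model` (centroids and class assignment), and numeric
#'   arrays `p_cell`, `p_scaffold`, `p_bkg`.
#' @export
kmeans_priors <- function(pair, seed = 1L, max_points = 2^22) {
  stopifnot(inherits(pair, "zstack_pair"))
  ci <- as.vector(pair$cell$voxels)
  si <- as.vector(pair$scaffold$voxels)
  pts <- cbind(cell = ci, scaffold = si)
  if (nrow(unique(pts)) < 3L)
    stop("need at least 3 distinct (cell, scaffold) intensity pairs")
  fit_pts <- pts
  if (nrow(pts) > max_points)
    fit_pts <- pts[with_seed(seed, sample.int(nrow(pts), max_points)), ]
  km <- NULL
  for (try in 0:4) {
    km <- tryCatch(
      with_seed(seed + try,
                suppressWarnings(stats::kmeans(fit_pts, centers = 3L,
                                               nstart = 5L, iter.max = 100L))),
      error = function(e) NULL)
    if (!is.null(km) && all(km$size > 0)) break
    km <- NULL
  }
  if (is.null(km)) stop("k-means failed to produce 3 nonempty clusters")
  cen <- km$centers
  bkg <- which.min(rowSums(cen^2))
  rest <- setdiff(1:3, bkg)
  cell <- rest[which.max(cen[rest, 1])]
  scaffold <- setdiff(rest, cell)
  d <- sapply(1:3, function(k)
    sqrt((ci - cen[k, 1])^2 + (si - cen[k, 2])^2))
  inv <- 1 / d
  hit <- !is.finite(inv)                       # exact centroid hits
  if (any(hit)) {
    first_hit <- max.col(hit, ties.method = "first")
    rows <- which(rowSums(hit) > 0)
    inv[rows, ] <- 0
    inv[cbind(rows, first_hit[rows])] <- 1
  }
  p <- inv / rowSums(inv)
  dm <- dim(pair$cell$voxels)
  list(model = structure(list(centroids = cen,
                              classes = c(bkg = bkg, cell = cell,
                                          scaffold = scaffold),
                              seed = seed),
                         class = "cluster_model"),
       p_cell = array(p[, cell], dm),
       p_scaffold = array(p[, scaffold], dm),
       p_bkg = array(p[, bkg], dm))
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("<cluster_model> K = 3 centroids (cell, scaffold intensity):\n")
  lab <- names(x$classes)[match(1:3, x$classes)]
  for (k in 1:3)
    cat(sprintf("  %-9s (%.2f, %.2f)\n", lab[k],
                x$centroids[k, 1], x$centroids[k, 2]))
  invisible(x)
}

#' Total-probability contact map
#'
#' Combines the two conditional foreground probabilities with the K-means
#' class priors by the law of total probability, voxelwise:
#' `P(Contact) = P(Contact|Cell) P(Cell) + P(Contact|Scaffold) P(Scaffold)`.
#'
#' @param p_cell_cond `P(Contact|Cell)`: foreground probability of the cell
#'   channel ([prob_volume] or array).
#' @param p_scaffold_cond `P(Contact|Scaffold)`: same for the scaffold
#'   channel.
#' @param priors output of [kmeans_priors].
#' @return a [prob_volume] of `P(Contact)`.
#' @export
contact_probability <- function(p_cell_cond, p_scaffold_cond, priors) {
  a <- prob_values(p_cell_cond)
  b <- prob_values(p_scaffold_cond)
  if (!identical(dim(a), dim(b)) ||
      !identical(dim(a), dim(priors$p_cell)))
    stop("probability grids are not congruent")
  prob_volume(clamp01(a * priors$p_cell + b * priors$p_scaffold),
              semantics = "P(Contact)")
}
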