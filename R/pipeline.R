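#' Run configuration
#'
#' Bundles every tunable of the end-to-end measurement into one serializable
#' object. Defaults follow the down-selected methods: the mixed-pixel
#' statistical model (A2) and the sigma = 1.0 vesselness geometrical method
#' (A6), which gave the closest single-fiber radius estimates to the
#' electron-microscopy reference.
#'
#' @param scaffold_type `"SC"`, `"MF"` or `"MMF"`.
#' @param statistical_model `"A1"` to `"A5"`.
#' @param geometrical_method `"A6"`, `"A7"` or `"A8"`.
#' @param margin_fraction ROI margin fraction (x and y), default 0.10.
#' @param n_bins histogram bins for maximum-entropy thresholding.
#' @param connectivity contact adjacency connectivity (6, 18 or 26).
#' @param background_frame `"first"` or `"last"`.
#' @param seed RNG seed used by all stochastic stages (k-means seeding).
#' @return object of class `run_config`.
#' @export
run_config <- function(scaffold_type = c("MF", "MMF", "SC"),
                       statistical_model = "A2",
                       geometrical_method = "A6",
                       margin_fraction = 0.10, n_bins = 256L,
                       connectivity = 26L,
                       background_frame = c("first", "last"),
                       seed = 1L) {
  scaffold_type <- match.arg(scaffold_type)
  stopifnot(statistical_model %in% paste0("A", 1:5),
            geometrical_method %in% paste0("A", 6:8),
            connectivity %in% c(6, 18, 26))
  structure(list(scaffold_type = scaffold_type,
                 statistical_model = statistical_model,
                 geometrical_method = geometrical_method,
                 margin_fraction = margin_fraction,
                 n_bins = as.integer(n_bins),
                 connectivity = as.integer(connectivity),
                 background_frame = match.arg(background_frame),
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Read or write a run configuration as YAML
#'
#' Every run's effective configuration is serializable so it can be archived
#' alongside the outputs and replayed later.
#'
#' @param config a [run_config].
#' @param path YAML file path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config`
#'   returns a [run_config].
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(run_config, v)
}

#' End-to-end contact measurement for one z-stack pair
#'
#' Executes the full methodology on a co-registered pair: background
#' estimation, cell segmentation (or a supplied verified mask), ROI
#' cropping, the chosen statistical contact model (foreground probabilities,
#' K-means priors, total-probability contact map, maximum-entropy
#' binarization), the chosen geometrical method, object-based contact masks
#' for both routes, the contact surface, and the RMS distance between the
#' two contact-probability maps. All randomness is controlled by
#' `config$seed`, so repeated runs are identical.
#'
#' @param pair a [zstack_pair].
#' @param config a [run_config].
#' @param cell_mask optional verified cell mask (full volume); segmented
#'   automatically when `NULL`.
#' @param truth optional ground-truth mask list (as from [render_phantom]);
#'   when given, contact Jaccard indices against the truth are reported.
#' @param out_dir optional directory: masks are written as TIFF and the
#'   report as JSON.
#' @param pair_id identifier used in reports and filenames.
#' @return report list (configuration, ROI, thresholds, voxel counts,
#'   distances, optional Jaccard indices, output paths).
#' @export
run_pair <- function(pair, config = run_config(), cell_mask = NULL,
                     truth = NULL, out_dir = NULL, pair_id = "pair") {
  stopifnot(inherits(pair, "zstack_pair"), inherits(config, "run_config"))
  if (is.null(cell_mask)) {
    seg <- segment_cell(pair$cell)
    if (seg$status == "missed")
      stop("cell segmentation missed: no foreground detected")
    cell_mask <- seg$mask
  }
  cropped <- crop_roi(pair, cell_mask, config$margin_fraction)
  roi <- cropped$roi
  cm <- cell_mask[(roi$z[1] + 1):roi$z[2], (roi$y[1] + 1):roi$y[2],
                  (roi$x[1] + 1):roi$x[2], drop = FALSE]
  cp <- cropped$pair

  # statistical route
  bg_cell <- estimate_background(cp$cell, config$background_frame)
  bg_scaf <- estimate_background(cp$scaffold, config$background_frame)
  p_cell <- foreground_probability(cp$cell, bg_cell, config$statistical_model,
                                   partner = cp$scaffold)
  p_scaf <- foreground_probability(cp$scaffold, bg_scaf,
                                   config$statistical_model,
                                   partner = cp$cell)
  priors <- kmeans_priors(cp, seed = config$seed)
  p_contact <- contact_probability(p_cell, p_scaf, priors)
  scaf_stat_mask <- tryCatch(
    max_entropy_threshold(p_scaf$values, config$n_bins)$mask,
    error = function(e) array(FALSE, dim(cm)))
  stat_contact <- binary_contact(cm, scaf_stat_mask, config$connectivity)

  # geometrical route
  scaf_geom_mask <- geometric_scaffold_segment(
    cp$scaffold, config$scaffold_type, config$geometrical_method,
    cell_mask = cm)
  geom_contact <- binary_contact(cm, scaf_geom_mask, config$connectivity)
  surf <- contact_surface(scaf_geom_mask & dilate_mask(cm,
                                                       config$connectivity))

  d_stat_geom <- probability_distance(p_contact$values, geom_contact + 0)

  report <- list(
    pair_id = pair_id,
    config = unclass(config),
    roi = roi,
    roi_voxels = prod(dim(cp$cell$voxels)),
    bleed_alpha_hat = p_scaf$params$bleed_alpha_hat,
    stat_contact_voxels = sum(stat_contact),
    geom_contact_voxels = sum(geom_contact),
    contact_surface_voxels = sum(surf),
    stat_geom_distance = d_stat_geom)
  if (!is.null(truth)) {
    tc <- truth$contact[(roi$z[1] + 1):roi$z[2], (roi$y[1] + 1):roi$y[2],
                        (roi$x[1] + 1):roi$x[2], drop = FALSE]
    report$stat_contact_jaccard <- jaccard_index(stat_contact, tc)
    report$geom_contact_jaccard <- jaccard_index(geom_contact, tc)
  }
  masks <- list(stat_contact = stat_contact, geom_contact = geom_contact,
                scaffold_geom = scaf_geom_mask, contact_surface = surf,
                cell = cm)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    vs <- cp$cell$voxel_size
    write_zstack(zstack(p_contact$values * 65535, vs, "P(Contact)"),
                 file.path(out_dir, paste0(pair_id, "_pcontact.tif")))
    for (nm in names(masks))
      write_zstack(zstack(masks[[nm]] * 65535, vs, nm),
                   file.path(out_dir, paste0(pair_id, "_", nm, ".tif")))
    jsonlite::write_json(report,
                         file.path(out_dir, paste0(pair_id, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  c(report, list(p_contact = p_contact, masks = masks))
}
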