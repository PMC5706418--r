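#' Root-mean-square distance between probability maps
#'
#' The per-voxel Euclidean distance between two contact-probability
#' estimates, `sqrt( sum (p_i - p_j)^2 / (X Y Z) )`. It is an L2 metric (up
#' to the constant volume normalization), so identical maps give 0 and maps
#' that disagree maximally on `[0, 1]` give 1.
#'
#' @param p_i,p_j congruent [prob_volume] objects or numeric arrays.
#' @return scalar distance.
#' @export
probability_distance <- function(p_i, p_j) {
  a <- prob_values(p_i); b <- prob_values(p_j)
  if (!identical(dim(a), dim(b))) stop("probability grids are not congruent")
  sqrt(sum((a - b)^2) / length(a))
}

#' Pairwise distance matrix over algorithm outputs
#'
#' @param maps named list of congruent probability volumes.
#' @return symmetric matrix of [probability_distance] values with zero
#'   diagonal.
#' @export
distance_matrix <- function(maps) {
  n <- length(maps)
  m <- matrix(0, n, n, dimnames = list(names(maps), names(maps)))
  if (n < 2) return(m)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- m[j, i] <- probability_distance(maps[[i]], maps[[j]])
  }
  m
}

#' Expert verification label table
#'
#' Validates a long-format table of expert labels: one row per
#' `(item, expert)` with a label from the task vocabulary (cells:
#' good/correct/incorrect/missed; contacts: excellent/acceptable/bad).
#'
#' @param rows data frame with columns `item_id`, `expert_id`, `label`.
#' @param vocabulary optional allowed label set.
#' @return the validated data frame (class `verification_table`).
#' @export
verification_table <- function(rows, vocabulary = NULL) {
  stopifnot(all(c("item_id", "expert_id", "label") %in% names(rows)))
  if (anyDuplicated(rows[c("item_id", "expert_id")]))
    stop("each (item, expert) may appear at most once")
  if (!is.null(vocabulary) && !all(rows$label %in% vocabulary))
    stop("labels outside the declared vocabulary: ",
         paste(setdiff(unique(rows$label), vocabulary), collapse = ", "))
  class(rows) <- c("verification_table", class(rows))
  rows
}

#' Label groupings for verification statistics
#'
#' The combined positive/negative groupings: cell segmentation labels
#' good/correct count as positive against incorrect/missed; contact labels
#' excellent/acceptable count as positive against bad.
#'
#' @param task `"cells"` or `"contacts"`.
#' @return named character vector mapping label to `"positive"`/`"negative"`.
#' @export
label_grouping <- function(task = c("cells", "contacts")) {
  task <- match.arg(task)
  if (task == "cells")
    c(good = "positive", correct = "positive",
      incorrect = "negative", missed = "negative")
  else
    c(excellent = "positive", acceptable = "positive", bad = "negative")
}

#' Verification accuracy
#'
#' Fraction of items that at least one expert labeled with a positive label
#' - e.g. a contact counts as correct if any expert called it excellent or
#' acceptable.
#'
#' @param table a [verification_table] (or plain data frame with the same
#'   columns).
#' @param positive_labels set of labels counted as positive.
#' @return fraction in `[0, 1]`.
#' @export
verification_accuracy <- function(table,
                                  positive_labels = c("excellent",
                                                      "acceptable")) {
  stopifnot(nrow(table) >= 1)
  if (any(is.na(table$label))) stop("item with no label")
  pos <- tapply(table$label %in% positive_labels, table$item_id, any)
  mean(pos)
}

#' Verification precision (inter-expert agreement)
#'
#' The average, over expert pairs, of the fraction of shared items on which
#' the two experts assign the same (grouped) label. Given a numeric vector
#' it is interpreted as already-computed pairwise agreement ratios and their
#' mean is returned, which is how published pairwise ratios are combined
#' into a single precision figure.
#'
#' @param x a [verification_table] or a numeric vector of pairwise
#'   agreement ratios.
#' @param ... passed to methods.
#' @return precision in `[0, 1]`.
#' @export
verification_precision <- function(x, ...) UseMethod("verification_precision")

#' @rdname verification_precision
#' @export
verification_precision.numeric <- function(x, ...) {
  stopifnot(length(x) >= 1, all(x >= 0 & x <= 1))
  mean(x)
}

#' @rdname verification_precision
#' @param grouping named map from label to group, e.g. [label_grouping];
#'   `NULL` compares raw labels.
#' @export
verification_precision.data.frame <- function(x, grouping = NULL, ...) {
  experts <- unique(x$expert_id)
  if (length(experts) < 2) stop("need at least 2 experts")
  grp <- function(lab) if (is.null(grouping)) lab else unname(grouping[lab])
  ratios <- c()
  for (i in seq_len(length(experts) - 1)) for (j in (i + 1):length(experts)) {
    a <- x[x$expert_id == experts[i], ]
    b <- x[x$expert_id == experts[j], ]
    shared <- intersect(a$item_id, b$item_id)
    if (!length(shared)) {
      warning("experts ", experts[i], " and ", experts[j],
              " share no items; pair excluded")
      next
    }
    la <- grp(a$label[match(shared, a$item_id)])
    lb <- grp(b$label[match(shared, b$item_id)])
    ratios <- c(ratios, mean(la == lb))
  }
  if (!length(ratios)) stop("no expert pair shares any items")
  mean(ratios)
}

#' Reconstruct a label table from summary counts
#'
#' Builds a minimal long-format verification table consistent with the two
#' published counts: the total number of items and the number of items that
#' received no positive label from any expert (those are labeled negative by
#' every expert; all remaining items positive).
#'
#' @param n_items total number of items.
#' @param n_no_positive items with no positive label from any expert.
#' @param n_experts number of experts (default 3).
#' @param positive,negative label values used.
#' @return a [verification_table].
#' @export
verification_table_from_counts <- function(n_items, n_no_positive,
                                           n_experts = 3L,
                                           positive = "excellent",
                                           negative = "bad") {
  stopifnot(n_no_positive <= n_items)
  lab <- rep(c(negative, positive),
             c(n_no_positive, n_items - n_no_positive))
  verification_table(data.frame(
    item_id = rep(seq_len(n_items), times = n_experts),
    expert_id = rep(seq_len(n_experts), each = n_items),
    label = rep(lab, times = n_experts)))
}

#' Mean and sample standard deviation of roughness values
#'
#' Summarizes a set of per-spot RMS surface-roughness measurements (e.g.
#' atomic force microscopy scans of a spun-coat film) into the mean and
#' sample standard deviation used to compare roughness against the imaging
#' voxel size.
#'
#' @param rms numeric vector of per-spot RMS roughness values (nm).
#' @return list with `mean`, `stdev`, `n`.
#' @export
roughness_summary <- function(rms) {
  stopifnot(length(rms) >= 2, all(is.finite(rms)))
  list(mean = mean(rms), stdev = stats::sd(rms), n = length(rms))
}

#' Aggregate per-pair run reports
#'
#' Reads the JSON reports written by [run_pair] from a directory and builds
#' a summary table (one row per pair plus an aggregate row). Malformed
#' reports are skipped with a message.
#'
#' @param results_dir directory containing `*.json` run reports.
#' @param out optional path to write the summary CSV.
#' @return data frame of per-pair summaries (aggregate row last).
#' @export
summarize_run <- function(results_dir, out = NULL) {
  files <- list.files(results_dir, pattern = "\\.json$", full.names = TRUE)
  rows <- list()
  for (f in files) {
    r <- tryCatch(jsonlite::read_json(f, simplifyVector = TRUE),
                  error = function(e) NULL)
    if (is.null(r) || is.null(r$pair_id)) {
      message("skipping malformed report: ", basename(f))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      pair_id = r$pair_id,
      statistical_model = r$config$statistical_model,
      geometrical_method = r$config$geometrical_method,
      stat_contact_voxels = r$stat_contact_voxels,
      geom_contact_voxels = r$geom_contact_voxels,
      stat_geom_distance = r$stat_geom_distance,
      roi_voxels = r$roi_voxels,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no valid run reports in ", results_dir)
  df <- do.call(rbind, rows)
  agg <- df[1, ]
  agg$pair_id <- "AGGREGATE"
  for (cn in c("stat_contact_voxels", "geom_contact_voxels", "roi_voxels"))
    agg[[cn]] <- sum(df[[cn]])
  agg$stat_geom_distance <- mean(df$stat_geom_distance)
  df <- rbind(df, agg)
  if (!is.null(out)) utils::write.csv(df, out, row.names = FALSE)
  df
}
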