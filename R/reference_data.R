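# Bundled validation-measurement tables: small published summary tables
# (AFM roughness spots, SEM/CLSM single-fiber radius summaries, expert
# verification counts and pairwise agreement ratios) shipped as plain CSV so
# the worked-example statistics can be recomputed without the terabyte-scale
# imaging collection.

ref_path <- function(name)
  system.file("extdata", name, package = "cellscaffold", mustWork = TRUE)

#' Bundled reference measurement tables
#'
#' Accessors for the plain-text reference tables shipped with the package:
#' \describe{
#'   \item{`afm_reference()`}{per-spot AFM RMS roughness of a spun-coat film
#'     (nm), six 50 um x 50 um spots.}
#'   \item{`verification_counts()`}{per task: total verified items and items
#'     with no positive expert label.}
#'   \item{`expert_agreement_ratios()`}{published pairwise expert agreement
#'     ratios per verification task.}
#'   \item{`contact_bad_counts()`}{per scaffold type and expert: contacts
#'     labeled bad, out of the pairs of that type.}
#'   \item{`radius_reference()`}{single-fiber radius summaries (mean, stdev,
#'     point count) per segmentation algorithm from fluorescence stacks,
#'     plus the electron-microscopy reference row.}
#'   \item{`modality_resolutions()`}{lateral spatial resolution (um) of the
#'     two imaging modalities.}
#' }
#'
#' @return a data frame.
#' @name reference_tables
NULL

#' @rdname reference_tables
#' @export
afm_reference <- function()
  utils::read.csv(ref_path("afm_rms_nm.csv"))

#' @rdname reference_tables
#' @export
verification_counts <- function()
  utils::read.csv(ref_path("verification_counts.csv"))

#' @rdname reference_tables
#' @export
expert_agreement_ratios <- function()
  utils::read.csv(ref_path("expert_agreement_ratios.csv"))

#' @rdname reference_tables
#' @export
contact_bad_counts <- function()
  utils::read.csv(ref_path("contact_bad_counts.csv"))

#' @rdname reference_tables
#' @export
radius_reference <- function()
  utils::read.csv(ref_path("single_fiber_radius_summary.csv"))

#' @rdname reference_tables
#' @export
modality_resolutions <- function()
  utils::read.csv(ref_path("modality_resolution_um.csv"))
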