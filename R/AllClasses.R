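#' @useDynLib BreastPhantom, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' MRIVolume: a 3D MRI intensity grid with voxel geometry
#'
#' Container for a breast MRI volume. Intensities are stored as a 3D array
#' in (row, column, slice) index order; the first index varies fastest in
#' memory. \code{spacing} holds the physical voxel extent in millimetres
#' as (in-plane row, in-plane column, slice thickness). \code{meta}
#' optionally records acquisition parameters (repetition time, echo
#' times, flip angle, field strength, sequence name).
#'
#' @slot intensities 3D numeric array of non-negative, finite intensities.
#' @slot spacing numeric(3), positive voxel spacing in mm.
#' @slot meta list of acquisition metadata, or NULL.
#'
#' @seealso [MRIVolume()], [readDicomSeries()], [generateBreastVolume()]
#' @export
setClass("MRIVolume",
  representation(intensities = "array", spacing = "numeric",
                 meta = "listOrNULL"),
  prototype(meta = NULL))

setValidity("MRIVolume", function(object) {
  msg <- character()
  d <- dim(object@intensities)
  if (length(d) != 3L || any(d < 1L))
    msg <- c(msg, "intensities must be a 3D array with all dimensions >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive finite values (mm)")
  if (anyNA(object@intensities) || any(!is.finite(object@intensities)))
    msg <- c(msg, "intensities must be finite")
  else if (min(object@intensities) < 0)
    msg <- c(msg, "intensities must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct an MRIVolume
#'
#' @param intensities 3D numeric array, (row, column, slice) order.
#' @param spacing numeric(3) voxel spacing in mm
#'   (in-plane row, in-plane column, slice thickness).
#' @param meta optional list of acquisition metadata; see
#'   [acquisitionMeta()].
#' @return An [MRIVolume-class] object.
#' @examples
#' vol <- MRIVolume(array(runif(8 * 8 * 4), c(8, 8, 4)), c(1, 1, 1.5))
#' dim(vol)
#' @export
MRIVolume <- function(intensities, spacing, meta = NULL) {
  new("MRIVolume", intensities = intensities,
      spacing = as.numeric(spacing), meta = meta)
}

#' Acquisition metadata for an MRI volume
#'
#' Records the pulse-sequence parameters of the acquisition emulated or
#' read by the package: a gradient-recalled-echo fat-suppressed breast
#' protocol (dual-echo, short TR, low flip angle, 3 T).
#'
#' @param repetition_time_ms repetition time TR in ms.
#' @param echo_times_ms echo time(s) TE in ms (non-empty).
#' @param flip_angle_deg flip angle in degrees, in (0, 90].
#' @param field_strength_T static field strength in tesla.
#' @param sequence_name free-text sequence identifier.
#' @return A named list with the validated fields.
#' @examples
#' acquisitionMeta()
#' @export
acquisitionMeta <- function(repetition_time_ms = 4.654,
                            echo_times_ms = c(2.66, 1.392),
                            flip_angle_deg = 10,
                            field_strength_T = 3.0,
                            sequence_name = "GRE dual-echo fat-suppressed") {
  stopifnot(is.numeric(repetition_time_ms), repetition_time_ms > 0,
            length(echo_times_ms) >= 1L, all(echo_times_ms > 0),
            flip_angle_deg > 0, flip_angle_deg <= 90,
            field_strength_T > 0,
            all(is.finite(c(repetition_time_ms, echo_times_ms,
                            flip_angle_deg, field_strength_T))))
  list(repetition_time_ms = repetition_time_ms,
       echo_times_ms = as.numeric(echo_times_ms),
       flip_angle_deg = flip_angle_deg,
       field_strength_T = field_strength_T,
       sequence_name = as.character(sequence_name))
}

#' BreastMask: binary breast-region mask
#'
#' @slot mask 3D logical array congruent with the source volume.
#' @slot spacing numeric(3) voxel spacing in mm.
#' @slot threshold the background intensity threshold used to build it.
#' @seealso [buildBreastMask()]
#' @export
setClass("BreastMask",
  representation(mask = "array", spacing = "numeric",
                 threshold = "numeric"))

setValidity("BreastMask", function(object) {
  msg <- character()
  if (length(dim(object@mask)) != 3L || !is.logical(object@mask))
    msg <- c(msg, "mask must be a 3D logical array")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive values")
  if (length(object@threshold) != 1L || !is.finite(object@threshold) ||
      object@threshold < 0)
    msg <- c(msg, "threshold must be one non-negative finite value")
  if (length(msg)) msg else TRUE
})

#' TissueLabelMap: integer tissue labels on the voxel grid
#'
#' Partition of the voxel grid into background (0), skin, fat, one or
#' more fibroglandular clusters and optionally a tumour. The legend maps
#' tissue-role names (\code{"background"}, \code{"skin"}, \code{"fat"},
#' \code{"fgt_1"} ... \code{"fgt_K"}, \code{"tumour"}) to the integer
#' codes used in the grid.
#'
#' @slot labels 3D integer array.
#' @slot legend named integer vector, role name -> label code.
#' @slot spacing numeric(3) voxel spacing in mm.
#' @seealso [segmentTissues()], [subclusterFgt()]
#' @export
setClass("TissueLabelMap",
  representation(labels = "array", legend = "integer",
                 spacing = "numeric"))

setValidity("TissueLabelMap", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "labels must be a 3D array")
  if (is.null(names(object@legend)) || anyDuplicated(names(object@legend)) ||
      anyDuplicated(object@legend))
    msg <- c(msg, "legend must be uniquely named with unique codes")
  present <- unique(as.integer(object@labels))
  if (!all(present %in% object@legend))
    msg <- c(msg, "every label code in the grid must appear in the legend")
  fgt <- sort(object@legend[grepl("^fgt_", names(object@legend))])
  if (length(fgt) > 1L && any(diff(fgt) != 1L))
    msg <- c(msg, "fgt label codes must be contiguous integers")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three positive values")
  if (length(msg)) msg else TRUE
})

#' Construct a TissueLabelMap
#' @param labels 3D integer array of label codes.
#' @param legend named integer vector mapping role names to codes; must
#'   cover every code present in \code{labels}.
#' @param spacing numeric(3) voxel spacing in mm.
#' @return A [TissueLabelMap-class] object.
#' @export
TissueLabelMap <- function(labels, legend, spacing) {
  storage.mode(labels) <- "integer"
  new("TissueLabelMap", labels = labels,
      legend = structure(as.integer(legend), names = names(legend)),
      spacing = as.numeric(spacing))
}

#' DebyeParameters: single-pole Debye description of one model element
#'
#' The complex relative permittivity of each model element follows the
#' single-pole Debye dispersion
#' \deqn{\varepsilon^*(\omega) = \varepsilon_\infty +
#'   \frac{\Delta\varepsilon}{1 + j\omega\tau} +
#'   \frac{\sigma_s}{j\omega\varepsilon_0}}
#' with \eqn{\Delta\varepsilon = \varepsilon_s - \varepsilon_\infty}. The
#' loss convention is \eqn{\varepsilon^* = \varepsilon' - j\varepsilon''}
#' with \eqn{\varepsilon'' \ge 0} for physical parameters.
#'
#' @slot eps_inf high-frequency relative permittivity, >= 1.
#' @slot delta_eps static minus high-frequency permittivity, >= 0.
#' @slot tau_s relaxation time in seconds, > 0.
#' @slot sigma_s static conductivity in S/m, >= 0.
#' @seealso [debyePermittivity()], [applyPropertyLevel()]
#' @export
setClass("DebyeParameters",
  representation(eps_inf = "numeric", delta_eps = "numeric",
                 tau_s = "numeric", sigma_s = "numeric"))

setValidity("DebyeParameters", function(object) {
  v <- c(object@eps_inf, object@delta_eps, object@tau_s, object@sigma_s)
  msg <- character()
  if (length(v) != 4L || any(!is.finite(v)))
    msg <- c(msg, "all four Debye parameters must be single finite values")
  else {
    if (object@eps_inf < 1) msg <- c(msg, "eps_inf must be >= 1")
    if (object@delta_eps < 0) msg <- c(msg, "delta_eps must be >= 0")
    if (object@tau_s <= 0) msg <- c(msg, "tau_s must be > 0")
    if (object@sigma_s < 0) msg <- c(msg, "sigma_s must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct DebyeParameters
#' @param eps_inf high-frequency relative permittivity (>= 1).
#' @param delta_eps permittivity increment \eqn{\varepsilon_s -
#'   \varepsilon_\infty} (>= 0).
#' @param tau_s relaxation time in seconds (> 0).
#' @param sigma_s static conductivity in S/m (>= 0).
#' @return A [DebyeParameters-class] object.
#' @examples
#' debyeParameters(7, 10, 13e-12, 0.2)
#' @export
debyeParameters <- function(eps_inf, delta_eps, tau_s, sigma_s) {
  new("DebyeParameters", eps_inf = as.numeric(eps_inf),
      delta_eps = as.numeric(delta_eps), tau_s = as.numeric(tau_s),
      sigma_s = as.numeric(sigma_s))
}

#' PropertyLevel: fibroglandular dielectric contrast level
#'
#' The fibroglandular property curves are provided at three contrast
#' levels: \code{high} (scale 1.0), \code{med} (0.85) and \code{low}
#' (0.75). The medium and low levels scale the whole complex property
#' curve (both permittivity parts and conductivity) by the stated factor
#' at every frequency.
#'
#' @slot name one of "high", "med", "low".
#' @slot scale scale factor in (0, 1].
#' @seealso [propertyLevel()], [applyPropertyLevel()]
#' @export
setClass("PropertyLevel",
  representation(name = "character", scale = "numeric"))

setValidity("PropertyLevel", function(object) {
  if (!object@name %in% c("high", "med", "low"))
    return("name must be one of 'high', 'med', 'low'")
  if (object@scale <= 0 || object@scale > 1)
    return("scale must be in (0, 1]")
  TRUE
})

#' Construct a PropertyLevel
#' @param name "high", "med" or "low".
#' @return A [PropertyLevel-class] with scale 1.0, 0.85 or 0.75.
#' @examples
#' propertyLevel("med")
#' @export
propertyLevel <- function(name = c("high", "med", "low")) {
  name <- match.arg(name)
  new("PropertyLevel", name = name,
      scale = c(high = 1.0, med = 0.85, low = 0.75)[[name]])
}

#' ReferencePropertyTable: tissue property curves and intensity ranges
#'
#' Holds a single-pole Debye parameter set per tissue role (skin, fat,
#' tumour, and the lower/upper bounding curves of the fibroglandular
#' property range) together with the scan-intensity range per role used
#' by the linear intensity-to-property mapping.
#'
#' @slot entries named list of [DebyeParameters-class]; must contain
#'   skin, fat, fgt_lower, fgt_upper, tumour.
#' @slot ranges named list of numeric(2) intensity ranges (lower < upper).
#' @seealso [defaultPropertyTable()], [assignProperties()]
#' @export
setClass("ReferencePropertyTable",
  representation(entries = "list", ranges = "list"))

setValidity("ReferencePropertyTable", function(object) {
  need <- c("skin", "fat", "fgt_lower", "fgt_upper", "tumour")
  msg <- character()
  if (!all(need %in% names(object@entries)))
    msg <- c(msg, paste("entries must cover:", paste(need, collapse = ", ")))
  if (!all(vapply(object@entries, is, TRUE, "DebyeParameters")))
    msg <- c(msg, "every entry must be a DebyeParameters object")
  bad <- vapply(object@ranges, function(r)
    length(r) != 2L || !all(is.finite(r)) || r[1] >= r[2], TRUE)
  if (any(bad))
    msg <- c(msg, "every range must be numeric(2) with lower < upper")
  if (length(msg)) msg else TRUE
})

#' BreastModel: labelled anatomy plus dielectric property assignments
#'
#' The complete numerical breast model: a [TissueLabelMap-class], one
#' [DebyeParameters-class] per non-background label, and descriptive
#' attributes (breast health, radiological class, density, model name,
#' number of fibroglandular clusters, property level, voxel size).
#'
#' @slot labelmap a [TissueLabelMap-class].
#' @slot properties named list of [DebyeParameters-class], one per
#'   non-background legend role.
#' @slot attributes named list of model attributes.
#' @seealso [buildModel()], [assignProperties()], [writeHdf5Model()]
#' @export
setClass("BreastModel",
  representation(labelmap = "TissueLabelMap", properties = "list",
                 attributes = "list"))

setValidity("BreastModel", function(object) {
  msg <- character()
  roles <- setdiff(names(labelLegend(object@labelmap)), "background")
  if (!all(roles %in% names(object@properties)))
    msg <- c(msg, "every non-background label needs a property entry")
  need <- c("breast_health", "breast_class", "density_percent",
            "model_name", "n_fgt_clusters", "property_level",
            "voxel_size_mm")
  if (!all(need %in% names(object@attributes)))
    msg <- c(msg, paste("attributes must cover:", paste(need, collapse = ", ")))
  else {
    nf <- sum(grepl("^fgt_", names(labelLegend(object@labelmap))))
    if (object@attributes$n_fgt_clusters != nf)
      msg <- c(msg, "n_fgt_clusters must equal the number of fgt labels")
  }
  if (length(msg)) msg else TRUE
})

#' TumourModel: a parametric tumour inclusion
#'
#' Voxelized spherical tumour (the repository-style inclusion is a 10 mm
#' malignant tumour) with its dielectric properties, ready to embed into
#' a healthy [BreastModel-class].
#'
#' @slot mask 3D logical array.
#' @slot spacing numeric(3) voxel spacing in mm.
#' @slot properties [DebyeParameters-class] of the tumour tissue.
#' @slot nominal_diameter_mm requested sphere diameter in mm.
#' @seealso [generateTumour()], [embedTumour()]
#' @export
setClass("TumourModel",
  representation(mask = "array", spacing = "numeric",
                 properties = "DebyeParameters",
                 nominal_diameter_mm = "numeric"))

setValidity("TumourModel", function(object) {
  msg <- character()
  if (!is.logical(object@mask) || length(dim(object@mask)) != 3L)
    msg <- c(msg, "mask must be a 3D logical array")
  else if (!any(object@mask)) msg <- c(msg, "mask must be non-empty")
  if (object@nominal_diameter_mm <= 0)
    msg <- c(msg, "nominal_diameter_mm must be positive")
  if (length(msg)) msg else TRUE
})

#' SyntheticGroundTruth: generator truth for pipeline validation
#'
#' @slot labels the true [TissueLabelMap-class] emitted by the generator.
#' @slot true_fgt_fraction fibroglandular voxels over interior
#'   (fat + fibroglandular) voxels, in [0, 1].
#' @seealso [generateBreastVolume()]
#' @export
setClass("SyntheticGroundTruth",
  representation(labels = "TissueLabelMap", true_fgt_fraction = "numeric"))

setValidity("SyntheticGroundTruth", function(object) {
  lg <- labelLegend(object@labels)
  nfg <- sum(object@labels@labels %in%
               lg[grepl("^fgt_", names(lg))])
  nfat <- sum(object@labels@labels == lg[["fat"]])
  frac <- if (nfg + nfat > 0) nfg / (nfg + nfat) else 0
  if (abs(frac - object@true_fgt_fraction) > 1e-12)
    return("true_fgt_fraction must equal the fraction recomputed from labels")
  TRUE
})
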