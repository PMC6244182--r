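#' Accessors for BreastPhantom classes
#'
#' Small accessor generics used throughout the package instead of direct
#' slot access: \code{intensities} (the 3D intensity array),
#' \code{voxelSpacing} (voxel spacing in mm), \code{maskArray} (binary
#' mask array), \code{labelArray} and \code{labelLegend} (label grid and
#' its role legend), \code{modelProperties} and \code{modelAttributes}
#' (per-label Debye parameters and descriptive attributes of a model).
#'
#' @param x an object of the documented class.
#' @return The slot value; see each method.
#' @name accessors
#' @aliases intensities voxelSpacing maskArray labelArray labelLegend
#'   modelProperties modelAttributes
#' @examples
#' vol <- MRIVolume(array(0, c(4, 4, 2)), c(1, 1, 1))
#' voxelSpacing(vol)
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setMethod("intensities", "MRIVolume", function(x) x@intensities)

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "MRIVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "BreastMask", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "TissueLabelMap", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "TumourModel", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "BreastModel", function(x) x@labelmap@spacing)

#' @rdname accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))
#' @rdname accessors
#' @export
setMethod("maskArray", "BreastMask", function(x) x@mask)
#' @rdname accessors
#' @export
setMethod("maskArray", "TumourModel", function(x) x@mask)

#' @rdname accessors
#' @export
setGeneric("labelArray", function(x) standardGeneric("labelArray"))
#' @rdname accessors
#' @export
setMethod("labelArray", "TissueLabelMap", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("labelArray", "BreastModel", function(x) x@labelmap@labels)

#' @rdname accessors
#' @export
setGeneric("labelLegend", function(x) standardGeneric("labelLegend"))
#' @rdname accessors
#' @export
setMethod("labelLegend", "TissueLabelMap", function(x) x@legend)
#' @rdname accessors
#' @export
setMethod("labelLegend", "BreastModel", function(x) x@labelmap@legend)

#' @rdname accessors
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))
#' @rdname accessors
#' @export
setMethod("labelMap", "BreastModel", function(x) x@labelmap)
#' @rdname accessors
#' @export
setMethod("labelMap", "SyntheticGroundTruth", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("modelProperties", function(x) standardGeneric("modelProperties"))
#' @rdname accessors
#' @export
setMethod("modelProperties", "BreastModel", function(x) x@properties)

#' @rdname accessors
#' @export
setGeneric("modelAttributes", function(x) standardGeneric("modelAttributes"))
#' @rdname accessors
#' @export
setMethod("modelAttributes", "BreastModel", function(x) x@attributes)

#' @rdname accessors
#' @export
setGeneric("trueFgtFraction", function(x) standardGeneric("trueFgtFraction"))
#' @rdname accessors
#' @export
setMethod("trueFgtFraction", "SyntheticGroundTruth",
          function(x) x@true_fgt_fraction)

#' @rdname accessors
#' @export
setGeneric("debyeVector", function(x) standardGeneric("debyeVector"))
#' @rdname accessors
#' @export
setMethod("debyeVector", "DebyeParameters", function(x)
  c(eps_inf = x@eps_inf, delta_eps = x@delta_eps,
    tau_s = x@tau_s, sigma_s = x@sigma_s))

#' @export
setMethod("dim", "MRIVolume", function(x) dim(x@intensities))
#' @export
setMethod("dim", "BreastMask", function(x) dim(x@mask))
#' @export
setMethod("dim", "TissueLabelMap", function(x) dim(x@labels))

setMethod("show", "MRIVolume", function(object) {
  d <- dim(object)
  cat(sprintf("MRIVolume: %d x %d x %d voxels, spacing %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@intensities), max(object@intensities)))
  if (!is.null(object@meta) && !is.null(object@meta$sequence_name))
    cat("  sequence:", object@meta$sequence_name, "\n")
})

setMethod("show", "BreastMask", function(object) {
  d <- dim(object)
  cat(sprintf("BreastMask: %d x %d x %d, %d breast voxels (%.1f%%), threshold %.4g\n",
              d[1], d[2], d[3], sum(object@mask),
              100 * mean(object@mask), object@threshold))
})

setMethod("show", "TissueLabelMap", function(object) {
  d <- dim(object)
  cat(sprintf("TissueLabelMap: %d x %d x %d voxels\n", d[1], d[2], d[3]))
  counts <- tabulate(object@labels + 1L, nbins = max(object@legend) + 1L)
  for (i in seq_along(object@legend))
    cat(sprintf("  %-12s (label %d): %d voxels\n", names(object@legend)[i],
                object@legend[i], counts[object@legend[i] + 1L]))
})

setMethod("show", "DebyeParameters", function(object) {
  cat(sprintf(
    "DebyeParameters: eps_inf=%.4g, delta_eps=%.4g, tau=%.4g ps, sigma_s=%.4g S/m\n",
    object@eps_inf, object@delta_eps, 1e12 * object@tau_s, object@sigma_s))
})

setMethod("show", "PropertyLevel", function(object) {
  cat(sprintf("PropertyLevel '%s' (scale %.2f)\n", object@name, object@scale))
})

setMethod("show", "ReferencePropertyTable", function(object) {
  cat("ReferencePropertyTable with entries:",
      paste(names(object@entries), collapse = ", "), "\n")
})

setMethod("show", "BreastModel", function(object) {
  a <- object@attributes
  cat(sprintf("BreastModel '%s': %s, class %s, density %.1f%%\n",
              a$model_name, a$breast_health, a$breast_class,
              a$density_percent))
  cat(sprintf("  %d fibroglandular cluster(s), property level %s\n",
              a$n_fgt_clusters, a$property_level))
  d <- dim(object@labelmap)
  cat(sprintf("  grid %d x %d x %d, voxel %.4g x %.4g x %.4g mm\n",
              d[1], d[2], d[3], a$voxel_size_mm[1], a$voxel_size_mm[2],
              a$voxel_size_mm[3]))
})

setMethod("show", "TumourModel", function(object) {
  cat(sprintf("TumourModel: nominal diameter %.3g mm, %d voxels at %.3g x %.3g x %.3g mm\n",
              object@nominal_diameter_mm, sum(object@mask),
              object@spacing[1], object@spacing[2], object@spacing[3]))
})

setMethod("show", "SyntheticGroundTruth", function(object) {
  cat(sprintf("SyntheticGroundTruth: true fibroglandular fraction %.4f\n",
              object@true_fgt_fraction))
})

# internal: run code under a temporary RNG state, restoring the caller's
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
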