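#' Estimate the background intensity threshold
#'
#' Samples the corner margins of the grid (margin width 5\% of each
#' dimension, assumed to contain only air/background) and returns
#' \code{mean + k * sd} of the sampled intensities. When the margins have
#' zero mean and zero variance the threshold is 0 (with a warning). A
#' warning is also emitted when the resulting threshold separates almost
#' nothing (under 2\% of voxels above it), the signature of an object
#' filling the grid corners.
#'
#' @param volume an [MRIVolume-class].
#' @param k number of background standard deviations above the
#'   background mean.
#' @param margin_fraction margin width as a fraction of each dimension.
#' @return A non-negative scalar threshold.
#' @examples
#' p <- syntheticParams(grid = c(32, 32, 16), spacing = c(2, 2, 2),
#'                      breast_semi_axes_mm = c(30, 24, 14),
#'                      skin_thickness_mm = 3)
#' estimateBackgroundThreshold(generateBreastVolume(p)$volume)
#' @seealso [buildBreastMask()]
#' @export
estimateBackgroundThreshold <- function(volume, k = 3,
                                        margin_fraction = 0.05) {
  stopifnot(is(volume, "MRIVolume"))
  src <- intensities(volume)
  d <- dim(src)
  m <- pmax(1L, floor(margin_fraction * d))
  if (any(2L * m >= d))
    stop("cannot estimate background: grid too small for corner margins")
  inmar <- function(n, w) {
    v <- logical(n)
    v[seq_len(w)] <- TRUE
    v[seq.int(n - w + 1L, n)] <- TRUE
    v
  }
  corner <- outer(outer(inmar(d[1], m[1]), inmar(d[2], m[2]), `&`),
                  inmar(d[3], m[3]), `&`)
  bg <- src[corner]
  mu <- mean(bg)
  sdv <- stats::sd(bg)
  if (mu == 0 && sdv == 0) {
    warning("corner margins are identically zero; returning threshold 0")
    return(0)
  }
  thr <- mu + k * sdv
  if (mean(src > thr) < 0.02)
    warning(paste("threshold separates <2% of voxels;",
                  "corner margins may contain object, not background"))
  max(thr, 0)
}

#' Detect the breast surface along one axis
#'
#' For every 1-D ray of the volume along \code{axis}, marks as breast all
#' voxels from the start of the first to the end of the last run of at
#' least \code{min_run} consecutive above-threshold voxels, filling any
#' interior gaps along the ray. Rays without a qualifying run stay
#' background. This is the per-plane surface sensing step whose three
#' per-axis results are intersected by [buildBreastMask()].
#'
#' @param volume an [MRIVolume-class].
#' @param axis one of \code{"row"}, \code{"column"}, \code{"slice"}.
#' @param threshold intensity threshold.
#' @param min_run minimum run length of above-threshold voxels that
#'   counts as surface (rejects isolated noise voxels).
#' @return A 3D logical array.
#' @examples
#' vol <- MRIVolume(array(c(0, 0, 9, 9, 9, 0, 0, 9, 9, 9, 0, 0),
#'                        c(12, 1, 1)), c(1, 1, 1))
#' which(detectSurfaceAlongAxis(vol, "row", 5, min_run = 3))
#' @export
detectSurfaceAlongAxis <- function(volume, axis = c("row", "column", "slice"),
                                   threshold, min_run = 3L) {
  stopifnot(is(volume, "MRIVolume"), is.finite(threshold), min_run >= 1L)
  axis <- match.arg(axis)
  ax <- match(axis, c("row", "column", "slice"))
  src <- intensities(volume)
  array(cpp_ray_fill(src, dim(src), threshold, ax, as.integer(min_run)),
        dim(src))
}

#' Build the 3D breast mask
#'
#' Stage one of the modelling method: the volume is traversed along the
#' three orthogonal plane normals, the surface-filled region is computed
#' per axis ([detectSurfaceAlongAxis()]), and the voxelwise intersection
#' of the three regions is taken. Stray blobs are then removed by
#' keeping the largest connected component(s) (6-connectivity); set
#' \code{keep_components = 2} for bilateral volumes.
#'
#' @param volume an [MRIVolume-class].
#' @param threshold background threshold; defaults to
#'   [estimateBackgroundThreshold()].
#' @param min_run minimum above-threshold run length per ray.
#' @param keep_components number of largest connected components kept
#'   (1 for a single breast, 2 for bilateral scans).
#' @return A [BreastMask-class].
#' @examples
#' p <- syntheticParams(grid = c(32, 32, 16), spacing = c(2, 2, 2),
#'                      breast_semi_axes_mm = c(30, 24, 14),
#'                      skin_thickness_mm = 3)
#' buildBreastMask(generateBreastVolume(p)$volume)
#' @export
buildBreastMask <- function(volume, threshold = NULL, min_run = 3L,
                            keep_components = 1L) {
  stopifnot(is(volume, "MRIVolume"), keep_components >= 1L)
  if (is.null(threshold)) threshold <- estimateBackgroundThreshold(volume)
  m <- detectSurfaceAlongAxis(volume, "row", threshold, min_run) &
    detectSurfaceAlongAxis(volume, "column", threshold, min_run) &
    detectSurfaceAlongAxis(volume, "slice", threshold, min_run)
  if (!any(m)) stop("no breast region found")
  lab <- cpp_label_components(as.vector(m), dim(m))
  counts <- tabulate(lab)
  keep <- order(counts, decreasing = TRUE)[seq_len(min(keep_components,
                                                       length(counts)))]
  m <- array(lab %in% keep, dim(intensities(volume)))
  new("BreastMask", mask = m, spacing = voxelSpacing(volume),
      threshold = as.numeric(max(threshold, 0)))
}
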