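#' Extract the geometric skin layer of a breast mask
#'
#' Returns the mask voxels whose spacing-aware Euclidean distance to the
#' nearest exterior (non-mask) voxel centre is at most
#' \code{thickness_mm}. Faces of the mask flush with the grid boundary
#' have no adjacent exterior and therefore grow no skin (the chest-wall
#' face of a breast volume).
#'
#' @param mask a [BreastMask-class].
#' @param thickness_mm shell thickness in mm; a warning is emitted when
#'   it is below the smallest voxel spacing (the shell may then be empty
#'   on some faces).
#' @return A 3D logical array.
#' @examples
#' m <- array(FALSE, c(10, 10, 10)); m[3:8, 3:8, 3:8] <- TRUE
#' bm <- new("BreastMask", mask = m, spacing = c(1, 1, 1), threshold = 0)
#' sum(extractSkinLayer(bm, 1.5))
#' @seealso [segmentTissues()]
#' @export
extractSkinLayer <- function(mask, thickness_mm = 1.5) {
  stopifnot(is(mask, "BreastMask"), thickness_mm > 0)
  m <- maskArray(mask)
  if (!any(m)) stop("mask is empty")
  sp <- voxelSpacing(mask)
  if (thickness_mm < min(sp))
    warning("skin thickness below the smallest voxel spacing; the shell may be empty on some faces")
  dist <- array(cpp_edt3d(as.numeric(m), dim(m), sp), dim(m))
  m & dist <= thickness_mm
}

#' Segment the breast into skin, fat and fibroglandular tissue
#'
#' Stage two of the modelling method. Skin is assigned geometrically via
#' [extractSkinLayer()]; the remaining interior voxels are partitioned
#' into fat and fibroglandular classes by two-class k-means on voxel
#' intensity, with the higher-mean class taken as fibroglandular (the
#' bright class under fat-suppressed contrast). A degenerate interior
#' with fewer than two distinct intensities is assigned entirely to fat
#' with a warning.
#'
#' @param volume an [MRIVolume-class].
#' @param mask a congruent [BreastMask-class].
#' @param skin_thickness_mm skin shell thickness in mm.
#' @param seed RNG seed for the k-means restarts (deterministic output).
#' @return A [TissueLabelMap-class] with legend background/skin/fat and,
#'   when present, \code{fgt_1}.
#' @examples
#' p <- syntheticParams(grid = c(32, 32, 16), spacing = c(2, 2, 2),
#'                      breast_semi_axes_mm = c(30, 24, 14),
#'                      skin_thickness_mm = 3)
#' gen <- generateBreastVolume(p)
#' bm <- buildBreastMask(gen$volume)
#' segmentTissues(gen$volume, bm, skin_thickness_mm = 3)
#' @export
segmentTissues <- function(volume, mask, skin_thickness_mm = 1.5,
                           seed = 1L) {
  stopifnot(is(volume, "MRIVolume"), is(mask, "BreastMask"))
  if (!identical(dim(volume), dim(mask)))
    stop("volume and mask are not congruent")
  src <- intensities(volume)
  m <- maskArray(mask)
  skin <- extractSkinLayer(mask, skin_thickness_mm)
  interior <- m & !skin
  if (!any(interior)) stop("no interior: mask is all skin")

  labels <- array(0L, dim(src))
  labels[skin] <- 1L
  iv <- src[interior]
  legend <- c(background = 0L, skin = 1L, fat = 2L)
  if (length(unique(iv)) < 2L) {
    warning("interior intensities are degenerate; assigning a single fat class")
    labels[interior] <- 2L
  } else {
    km <- with_seed(seed, stats::kmeans(iv, centers = 2L, nstart = 10L,
                                        iter.max = 100L,
                                        algorithm = "MacQueen"))
    fgt_cl <- which.max(km$centers)
    assign_lab <- ifelse(km$cluster == fgt_cl, 3L, 2L)
    labels[interior] <- assign_lab
    if (any(assign_lab == 3L)) legend <- c(legend, fgt_1 = 3L)
  }
  TissueLabelMap(labels, legend, voxelSpacing(volume))
}

#' Sub-cluster the fibroglandular tissue into K intensity clusters
#'
#' Splits the fibroglandular class of a label map into \code{K} clusters
#' by one-dimensional k-means on voxel intensity, relabelled so that the
#' cluster index increases with cluster mean intensity
#' (\code{fgt_1} darkest ... \code{fgt_K} brightest). \code{K = 1}
#' returns the label map unchanged. Increasing K adds model complexity
#' (tissue heterogeneity) without changing the anatomy.
#'
#' @param volume the [MRIVolume-class] the labels were derived from.
#' @param labelmap a [TissueLabelMap-class] containing a fibroglandular
#'   class.
#' @param K number of fibroglandular clusters (>= 1).
#' @param seed RNG seed for the k-means restarts.
#' @return A [TissueLabelMap-class] with legend
#'   \code{fgt_1 ... fgt_K}.
#' @examples
#' p <- syntheticParams(grid = c(32, 32, 16), spacing = c(2, 2, 2),
#'                      breast_semi_axes_mm = c(30, 24, 14),
#'                      skin_thickness_mm = 3)
#' gen <- generateBreastVolume(p)
#' bm <- buildBreastMask(gen$volume)
#' lm <- segmentTissues(gen$volume, bm, skin_thickness_mm = 3)
#' subclusterFgt(gen$volume, lm, K = 4)
#' @export
subclusterFgt <- function(volume, labelmap, K, seed = 1L) {
  stopifnot(is(volume, "MRIVolume"), is(labelmap, "TissueLabelMap"),
            K >= 1L)
  K <- as.integer(K)
  lg <- labelLegend(labelmap)
  fgt_codes <- lg[grepl("^fgt_", names(lg))]
  if (length(fgt_codes) == 0L)
    stop("labelmap contains no fibroglandular class")
  labels <- labelArray(labelmap)
  sel <- labels %in% fgt_codes
  if (K == 1L && length(fgt_codes) == 1L) return(labelmap)

  iv <- intensities(volume)[sel]
  if (K > length(unique(iv)))
    stop("K too large: more clusters than distinct fibroglandular intensities")

  base <- min(fgt_codes)
  if (K == 1L) {
    labels[sel] <- base
    new_legend <- c(lg[!grepl("^fgt_", names(lg))], fgt_1 = base)
  } else {
    km <- with_seed(seed, stats::kmeans(iv, centers = K, nstart = 10L,
                                        iter.max = 100L,
                                        algorithm = "MacQueen"))
    ord <- order(km$centers)                 # ascending mean intensity
    rank_of <- integer(K)
    rank_of[ord] <- seq_len(K)
    labels[sel] <- base + rank_of[km$cluster] - 1L
    new_legend <- c(lg[!grepl("^fgt_", names(lg))],
                    structure(base + seq_len(K) - 1L,
                              names = paste0("fgt_", seq_len(K))))
  }
  TissueLabelMap(labels, new_legend, voxelSpacing(labelmap))
}

#' Per-cluster voxel counts and mean intensities
#'
#' Computes, for every legend entry of the label map, the voxel count
#' and the mean source intensity. Legend entries absent from the grid
#' are reported with count 0 and mean \code{NA}.
#'
#' @param volume the source [MRIVolume-class].
#' @param labelmap a congruent [TissueLabelMap-class].
#' @return A data.frame with columns \code{tissue}, \code{label},
#'   \code{voxel_count}, \code{mean_intensity}.
#' @examples
#' lm <- TissueLabelMap(array(c(0L, 1L, 1L, 2L), c(4, 1, 1)),
#'                      c(background = 0, skin = 1, fat = 2), c(1, 1, 1))
#' vol <- MRIVolume(array(c(0, 10, 20, 30), c(4, 1, 1)), c(1, 1, 1))
#' clusterStatistics(vol, lm)
#' @export
clusterStatistics <- function(volume, labelmap) {
  stopifnot(is(volume, "MRIVolume"), is(labelmap, "TissueLabelMap"))
  if (!identical(dim(volume), dim(labelmap)))
    stop("volume and labelmap are not congruent")
  lg <- labelLegend(labelmap)
  labels <- labelArray(labelmap)
  src <- intensities(volume)
  counts <- vapply(lg, function(code) sum(labels == code), numeric(1))
  means <- vapply(lg, function(code)
    if (any(labels == code)) mean(src[labels == code]) else NA_real_,
    numeric(1))
  data.frame(tissue = names(lg), label = as.integer(lg),
             voxel_count = as.integer(counts), mean_intensity = means,
             row.names = NULL, stringsAsFactors = FALSE)
}
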