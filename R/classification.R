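#' Compute breast density from a tissue label map
#'
#' Breast density is the percentage of fibroglandular tissue over the
#' soft interior tissue: \eqn{100 \times n_{fgt} / (n_{fat} + n_{fgt})}.
#' Skin, tumour and background are excluded from both numerator and
#' denominator by default; set \code{include_skin_in_denominator} to
#' count skin voxels in the denominator instead.
#'
#' @param labelmap a [TissueLabelMap-class].
#' @param include_skin_in_denominator logical, default FALSE.
#' @return Density in percent, in [0, 100].
#' @examples
#' lm <- TissueLabelMap(array(c(rep(2L, 70), rep(3L, 30)), c(100, 1, 1)),
#'                      c(background = 0, skin = 1, fat = 2, fgt_1 = 3),
#'                      c(1, 1, 1))
#' computeDensity(lm)  # 30
#' @seealso [classifyBreast()]
#' @export
computeDensity <- function(labelmap, include_skin_in_denominator = FALSE) {
  stopifnot(is(labelmap, "TissueLabelMap"))
  lg <- labelLegend(labelmap)
  labels <- labelArray(labelmap)
  n_fgt <- sum(labels %in% lg[grepl("^fgt_", names(lg))])
  n_fat <- if ("fat" %in% names(lg)) sum(labels == lg[["fat"]]) else 0L
  denom <- n_fat + n_fgt
  if (include_skin_in_denominator && "skin" %in% names(lg))
    denom <- denom + sum(labels == lg[["skin"]])
  if (denom == 0L) stop("no interior tissue: fat + fibroglandular count is zero")
  100 * n_fgt / denom
}

#' Classify a breast by its density
#'
#' The four radiological classes by fibroglandular percentage:
#' fatty (< 25), scattered ([25, 50)), heterogeneously dense
#' ([50, 75)), dense (>= 75). Boundaries go to the upper class
#' ("less than 25\%" is strict).
#'
#' @param density_percent density in percent, in [0, 100].
#' @return One of \code{"fatty"}, \code{"scattered"},
#'   \code{"heterogeneously dense"}, \code{"dense"}.
#' @examples
#' classifyBreast(13)   # fatty
#' classifyBreast(47)   # scattered
#' classifyBreast(87)   # dense
#' @export
classifyBreast <- function(density_percent) {
  if (!is.numeric(density_percent) || length(density_percent) != 1L ||
      !is.finite(density_percent) || density_percent < 0 ||
      density_percent > 100)
    stop("invalid density: must be a single value in [0, 100]")
  if (density_percent < 25) "fatty"
  else if (density_percent < 50) "scattered"
  else if (density_percent < 75) "heterogeneously dense"
  else "dense"
}
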