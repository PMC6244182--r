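#' Build a complete breast model from an MRI volume
#'
#' Runs the default end-to-end pipeline: breast-mask construction on the
#' original intensities, PCA denoising of the slice stack,
#' skin/fat/fibroglandular segmentation of the denoised intensities
#' inside the mask, fibroglandular
#' sub-clustering into \code{K} clusters, per-cluster statistics,
#' dielectric property assignment at the requested level, and density /
#' class computation. Errors from individual stages are re-raised with a
#' stage tag.
#'
#' @param volume an [MRIVolume-class].
#' @param K number of fibroglandular clusters (>= 1).
#' @param level a [PropertyLevel-class].
#' @param table a [ReferencePropertyTable-class].
#' @param model_name model identifier, repository-style
#'   \code{BM_Class_ID}.
#' @param variance_fraction PCA variance fraction retained.
#' @param skin_thickness_mm geometric skin shell thickness in mm.
#' @param threshold background threshold; NULL to estimate it.
#' @param keep_components connected components kept by the mask cleanup.
#' @param seed RNG seed for the clustering stages.
#' @return A [BreastModel-class].
#' @examples
#' p <- syntheticParams(grid = c(48, 48, 24), spacing = c(2, 2, 2),
#'                      breast_semi_axes_mm = c(45, 36, 20),
#'                      skin_thickness_mm = 3)
#' gen <- generateBreastVolume(p)
#' model <- buildModel(gen$volume, K = 2, skin_thickness_mm = 3)
#' modelAttributes(model)$breast_class
#' @seealso [embedTumour()], [generateModelReport()], [writeHdf5Model()]
#' @export
buildModel <- function(volume, K = 1L,
                       level = propertyLevel("high"),
                       table = defaultPropertyTable(),
                       model_name = "BM_Model_001",
                       variance_fraction = 0.99,
                       skin_thickness_mm = 1.5,
                       threshold = NULL,
                       keep_components = 1L,
                       seed = 1L) {
  stopifnot(is(volume, "MRIVolume"), K >= 1L)
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))

  # the mask is estimated on the original intensities: slice-basis PCA
  # reconstruction can ghost faint breast structure into background
  # voxels along the slice axis, which would dilate a mask built from
  # the denoised volume; segmentation then runs on the denoised
  # intensities inside that mask
  mask <- stage("masking",
                buildBreastMask(volume, threshold = threshold,
                                keep_components = keep_components))
  den <- stage("preprocessing",
               pcaDenoise(volume, variance_fraction = variance_fraction))
  lm <- stage("segmentation",
              segmentTissues(den, mask, skin_thickness_mm = skin_thickness_mm,
                             seed = seed))
  if (K > 1L)
    lm <- stage("segmentation", subclusterFgt(den, lm, K = K, seed = seed))
  st <- stage("segmentation", clusterStatistics(den, lm))
  stage("dielectrics",
        assignProperties(lm, st, table, level, model_name = model_name))
}

#' Embed a tumour inclusion into a breast model
#'
#' Places the tumour mask at \code{centre_mm} (physical coordinates of
#' the host grid, mm) and overwrites host fat/fibroglandular voxels with
#' a new tumour label. Skin and background voxels are never overwritten;
#' if more than 10\% of the tumour volume would fall on them the
#' placement is rejected. The tumour grid is resampled to the host
#' spacing when the spacings differ. Breast health becomes
#' \code{"diseased"}.
#'
#' @param model a [BreastModel-class].
#' @param tumour a [TumourModel-class].
#' @param centre_mm numeric(3), tumour centre in host physical
#'   coordinates (voxel centre of index i is at (i - 0.5) * spacing).
#' @return A [BreastModel-class] with one additional label.
#' @examples
#' p <- syntheticParams(grid = c(48, 48, 24), spacing = c(2, 2, 2),
#'                      breast_semi_axes_mm = c(45, 36, 20),
#'                      skin_thickness_mm = 3, target_fgt_fraction = 0.4)
#' gen <- generateBreastVolume(p)
#' model <- buildModel(gen$volume, skin_thickness_mm = 3)
#' tum <- generateTumour(10, c(2, 2, 2))
#' diseased <- embedTumour(model, tum, centre_mm = c(30, 48, 24))
#' modelAttributes(diseased)$breast_health
#' @export
embedTumour <- function(model, tumour, centre_mm) {
  stopifnot(is(model, "BreastModel"), is(tumour, "TumourModel"),
            length(centre_mm) == 3L)
  lm <- labelMap(model)
  sp <- voxelSpacing(lm)
  labels <- labelArray(lm)
  lg <- labelLegend(lm)
  d <- dim(labels)

  # nearest host voxel centre (voxel i is centred at (i - 0.5) * spacing)
  ci <- floor(centre_mm / sp + 0.5 + 0.5)
  if (any(ci < 1L) || any(ci > d))
    stop("tumour outside breast: centre is outside the grid")
  if (labels[ci[1], ci[2], ci[3]] == lg[["background"]])
    stop("tumour outside breast: centre lies in background")

  tmask <- maskArray(tumour)
  tsp <- voxelSpacing(tumour)
  if (any(abs(tsp - sp) > 1e-9)) {
    tv <- resampleVolume(MRIVolume(array(as.numeric(tmask), dim(tmask)),
                                   tsp), sp)
    tmask <- intensities(tv) >= 0.5
    if (!any(tmask))
      stop("tumour vanishes when resampled to the host grid")
    tsp <- sp
  }

  # voxel indices of tumour voxels, recentred on centre_mm
  td <- dim(tmask)
  idx <- which(tmask, arr.ind = TRUE)
  centre_t <- round((td + 1) / 2)              # generator centres on a voxel
  # rigid shift by integer voxel offsets onto the snapped centre
  host_idx <- sweep(idx, 2L, centre_t - ci)
  inside <- host_idx[, 1] >= 1 & host_idx[, 1] <= d[1] &
    host_idx[, 2] >= 1 & host_idx[, 2] <= d[2] &
    host_idx[, 3] >= 1 & host_idx[, 3] <= d[3]
  host_lin <- host_idx[inside, 1] +
    (host_idx[inside, 2] - 1) * d[1] +
    (host_idx[inside, 3] - 1) * d[1] * d[2]
  host_lab <- labels[host_lin]

  soft <- c(lg[["fat"]], lg[grepl("^fgt_", names(lg))])
  replaceable <- host_lab %in% soft
  bad <- sum(!inside) + sum(!replaceable)
  if (bad / nrow(idx) > 0.10)
    stop(sprintf(
      "invalid placement: %.0f%% of the tumour overlaps skin or background",
      100 * bad / nrow(idx)))

  new_code <- max(lg) + 1L
  labels[host_lin[replaceable]] <- new_code
  new_lg <- c(lg, tumour = new_code)
  new_lm <- TissueLabelMap(labels, new_lg, sp)

  props <- modelProperties(model)
  props$tumour <- tumour@properties
  att <- modelAttributes(model)
  att$breast_health <- "diseased"
  att$density_percent <- computeDensity(new_lm)
  att$breast_class <- classifyBreast(att$density_percent)
  new("BreastModel", labelmap = new_lm, properties = props,
      attributes = att)
}

#' Generate a markdown report for a breast model
#'
#' Produces the four-section model description: general information
#' (name, health, class, density, and an intensity histogram summary
#' when the source volume is supplied), model elements (legend, voxel
#' counts, grid), dielectric properties (\eqn{\varepsilon'} and
#' \eqn{\sigma} at 1/3/6/10 GHz per cluster, with all three
#' fibroglandular property levels), and visualization (a central-slice
#' label image written next to the report when \code{path} is given).
#'
#' @param model a [BreastModel-class].
#' @param volume optional source [MRIVolume-class] for the intensity
#'   histogram summary.
#' @param path optional file path; when given the markdown is written
#'   there and a PNG of the central slice is saved alongside.
#' @return The markdown document as a character scalar (invisibly when
#'   \code{path} is given).
#' @examples
#' p <- syntheticParams(grid = c(48, 48, 24), spacing = c(2, 2, 2),
#'                      breast_semi_axes_mm = c(45, 36, 20),
#'                      skin_thickness_mm = 3)
#' gen <- generateBreastVolume(p)
#' model <- buildModel(gen$volume, skin_thickness_mm = 3)
#' report <- generateModelReport(model, gen$volume)
#' substr(report, 1, 60)
#' @export
generateModelReport <- function(model, volume = NULL, path = NULL) {
  stopifnot(is(model, "BreastModel"))
  a <- modelAttributes(model)
  lm <- labelMap(model)
  lg <- labelLegend(lm)
  d <- dim(lm)
  counts <- vapply(lg, function(code) sum(labelArray(lm) == code),
                   numeric(1))

  lines <- c(sprintf("# Model Report: %s", a$model_name), "")

  lines <- c(lines, "## General Information", "",
             sprintf("- Breast health: %s", a$breast_health),
             sprintf("- Breast classification: %s", a$breast_class),
             sprintf("- Breast density: %.1f%% fibroglandular", a$density_percent),
             sprintf("- Fibroglandular clusters: %d", a$n_fgt_clusters),
             sprintf("- Property level: %s", a$property_level))
  if (!is.null(volume)) {
    q <- stats::quantile(intensities(volume), c(0, 0.25, 0.5, 0.75, 1))
    lines <- c(lines, sprintf(
      "- Intensity histogram: min %.4g, q25 %.4g, median %.4g, q75 %.4g, max %.4g",
      q[1], q[2], q[3], q[4], q[5]))
  }
  lines <- c(lines, "")

  lines <- c(lines, "## Model Elements", "",
             sprintf("- Grid size: %d x %d x %d voxels", d[1], d[2], d[3]),
             sprintf("- Voxel size: %.4g x %.4g x %.4g mm",
                     a$voxel_size_mm[1], a$voxel_size_mm[2],
                     a$voxel_size_mm[3]), "",
             "| Element | Label | Voxels |", "|---|---|---|",
             sprintf("| %s | %d | %d |", names(lg), lg, counts), "")

  freqs <- c(1e9, 3e9, 6e9, 10e9)
  lines <- c(lines, "## Dielectric Properties", "",
             "| Element | Level | f (GHz) | eps' | sigma (S/m) |",
             "|---|---|---|---|---|")
  for (role in setdiff(names(lg), "background")) {
    par <- modelProperties(model)[[role]]
    levels_here <- if (grepl("^fgt_", role)) c("high", "med", "low") else "-"
    for (lev in levels_here) {
      p <- par
      if (lev %in% c("med", "low")) {
        # properties are stored at the model's own level; re-derive the
        # other levels from the high-equivalent curve
        base <- 1 / c(high = 1, med = 0.85,
                      low = 0.75)[[a$property_level]]
        p <- suppressWarnings(applyPropertyLevel(
          debyeParameters(par@eps_inf * base, par@delta_eps * base,
                          par@tau_s, par@sigma_s * base),
          propertyLevel(lev)))
      } else if (lev == "high" && grepl("^fgt_", role) &&
                 a$property_level != "high") {
        base <- 1 / c(high = 1, med = 0.85,
                      low = 0.75)[[a$property_level]]
        p <- debyeParameters(par@eps_inf * base, par@delta_eps * base,
                             par@tau_s, par@sigma_s * base)
      }
      spec <- debyeSpectrum(p, freqs)
      lines <- c(lines, sprintf("| %s | %s | %g | %.2f | %.3f |",
                                role, lev, freqs / 1e9, spec$eps_real,
                                spec$sigma_S_m))
    }
  }
  lines <- c(lines, "")

  lines <- c(lines, "## Visualization", "")
  if (!is.null(path)) {
    png_path <- sub("\\.md$", "", path)
    png_path <- paste0(png_path, "_central_slice.png")
    k <- max(1L, d[3] %/% 2L)
    sl <- labelArray(lm)[, , k]
    img <- sl / max(1L, max(sl))
    png::writePNG(t(img), png_path)
    lines <- c(lines, sprintf("Central slice (slice %d) label image: `%s`",
                              k, basename(png_path)), "")
  } else {
    lines <- c(lines, sprintf(
      "Central slice: %d; supply `path` to save the label image.",
      max(1L, d[3] %/% 2L)), "")
  }

  doc <- paste(lines, collapse = "\n")
  if (!is.null(path)) {
    writeLines(doc, path)
    return(invisible(doc))
  }
  doc
}
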