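#' Parameters for the synthetic breast MRI generator
#'
#' Defines the acquisition geometry and tissue statistics emulated by
#' [generateBreastVolume()]. Defaults reproduce the emulated acquisition:
#' a 256 x 256 x 240 matrix at 0.9375 x 0.9375 x 1.1 mm voxels, with the
#' fat-suppressed contrast in which fibroglandular tissue is the bright
#' class. Intensity means are arbitrary units; only their ordering and
#' separation matter downstream.
#'
#' @param grid integer(3) matrix size (rows, columns, slices).
#' @param spacing numeric(3) voxel spacing in mm.
#' @param breast_semi_axes_mm numeric(3) semi-axes of the half-ellipsoid
#'   breast (protrusion from chest wall, in-plane lateral, cranio-caudal).
#' @param skin_thickness_mm skin shell thickness in mm.
#' @param target_fgt_fraction target fibroglandular fraction of the
#'   interior (fat + fibroglandular) volume, in [0, 1].
#' @param fat_intensity_mean,fat_intensity_sd fat class intensity stats.
#' @param fgt_intensity_mean,fgt_intensity_sd fibroglandular stats; the
#'   mean must exceed the fat mean (fat-suppressed contrast).
#' @param skin_intensity_mean,skin_intensity_sd skin class stats.
#' @param background_noise_sd background (air) noise level.
#' @param ringing logical; apply in-plane Gibbs ringing to the final
#'   intensities (see [addGibbsRinging()]).
#' @param ringing_truncation k-space truncation fraction when
#'   \code{ringing} is TRUE.
#' @param fgt_correlation_mm correlation length of the fibroglandular
#'   texture field in mm (controls blob size).
#' @param seed integer RNG seed; fixed seed gives bit-identical output.
#' @return A validated list of class \code{SyntheticParams}.
#' @examples
#' p <- syntheticParams(grid = c(32, 32, 16), spacing = c(2, 2, 2),
#'                      breast_semi_axes_mm = c(20, 18, 14))
#' @seealso [generateBreastVolume()]
#' @export
syntheticParams <- function(grid = c(256L, 256L, 240L),
                            spacing = c(0.9375, 0.9375, 1.1),
                            breast_semi_axes_mm = c(90, 85, 95),
                            skin_thickness_mm = 1.5,
                            target_fgt_fraction = 0.30,
                            fat_intensity_mean = 60, fat_intensity_sd = 10,
                            fgt_intensity_mean = 200, fgt_intensity_sd = 25,
                            skin_intensity_mean = 120, skin_intensity_sd = 15,
                            background_noise_sd = 5,
                            ringing = TRUE, ringing_truncation = 0.7,
                            fgt_correlation_mm = 12,
                            seed = 1L) {
  p <- list(grid = as.integer(grid), spacing = as.numeric(spacing),
            breast_semi_axes_mm = as.numeric(breast_semi_axes_mm),
            skin_thickness_mm = skin_thickness_mm,
            target_fgt_fraction = target_fgt_fraction,
            fat_intensity_mean = fat_intensity_mean,
            fat_intensity_sd = fat_intensity_sd,
            fgt_intensity_mean = fgt_intensity_mean,
            fgt_intensity_sd = fgt_intensity_sd,
            skin_intensity_mean = skin_intensity_mean,
            skin_intensity_sd = skin_intensity_sd,
            background_noise_sd = background_noise_sd,
            ringing = isTRUE(ringing),
            ringing_truncation = ringing_truncation,
            fgt_correlation_mm = fgt_correlation_mm,
            seed = as.integer(seed))
  stopifnot(length(p$grid) == 3L, all(p$grid >= 1L),
            length(p$spacing) == 3L, all(p$spacing > 0),
            length(p$breast_semi_axes_mm) == 3L,
            all(p$breast_semi_axes_mm > 0),
            p$skin_thickness_mm > 0,
            p$target_fgt_fraction >= 0, p$target_fgt_fraction <= 1,
            p$fat_intensity_mean > 0, p$fat_intensity_sd > 0,
            p$fgt_intensity_mean > p$fat_intensity_mean,
            p$fgt_intensity_sd > 0,
            p$skin_intensity_mean > 0, p$skin_intensity_sd > 0,
            p$background_noise_sd > 0,
            p$ringing_truncation > 0, p$ringing_truncation <= 1,
            p$fgt_correlation_mm > 0)
  class(p) <- c("SyntheticParams", "list")
  p
}

# smooth correlated random field: coarse white noise, light separable
# smoothing, trilinear upsampling to the full grid
correlated_field <- function(grid, spacing, correlation_mm) {
  factor <- pmax(1, pmin(floor(correlation_mm / (2 * spacing)), grid))
  cg <- pmax(2L, as.integer(ceiling(grid / factor)))
  f <- array(stats::rnorm(prod(cg)), cg)
  k <- c(0.25, 0.5, 0.25)
  smooth1 <- function(a, axis) {
    perm <- switch(axis, `1` = 1:3, `2` = c(2, 1, 3), `3` = c(3, 2, 1))
    a <- aperm(a, perm)
    d <- dim(a)
    m <- matrix(a, nrow = d[1])
    up <- rbind(m[1, , drop = FALSE], m[-d[1], , drop = FALSE])
    dn <- rbind(m[-1, , drop = FALSE], m[d[1], , drop = FALSE])
    aperm(array(k[1] * up + k[2] * m + k[3] * dn, d), order(perm))
  }
  for (ax in 1:3) f <- smooth1(f, ax)
  coarse <- MRIVolume(f - min(f) + 1, spacing * grid / cg)
  field <- intensities(resampleVolume(coarse, spacing))
  d <- dim(field)
  # pad/crop rounding differences back to the requested grid
  out <- array(stats::median(field), grid)
  cp <- pmin(d, grid)
  out[seq_len(cp[1]), seq_len(cp[2]), seq_len(cp[3])] <-
    field[seq_len(cp[1]), seq_len(cp[2]), seq_len(cp[3])]
  out
}

#' Generate a synthetic breast MRI volume with ground truth
#'
#' Builds a half-ellipsoid breast resting with its flat face on the
#' chest-wall side of the grid (row index 1), wraps it in a geometric
#' skin shell, fills the interior with fat, and places fibroglandular
#' tissue by thresholding a smooth correlated random field at the
#' interior quantile that meets \code{target_fgt_fraction}. Class
#' intensities are drawn from the configured normal distributions,
#' background is low-level noise, and (optionally) in-plane Gibbs
#' ringing is applied. Intensities are quantized to integers, matching
#' magnitude MR data. Output is reproducible bit-for-bit under a fixed
#' seed.
#'
#' @param params a [syntheticParams()] list.
#' @return A list with elements \code{volume} ([MRIVolume-class]) and
#'   \code{truth} ([SyntheticGroundTruth-class]).
#' @examples
#' p <- syntheticParams(grid = c(32, 32, 16), spacing = c(2, 2, 2),
#'                      breast_semi_axes_mm = c(30, 24, 14),
#'                      skin_thickness_mm = 3, seed = 7)
#' gen <- generateBreastVolume(p)
#' trueFgtFraction(gen$truth)
#' @seealso [syntheticParams()], [addGibbsRinging()], [writeDicomSeries()]
#' @export
generateBreastVolume <- function(params = syntheticParams()) {
  stopifnot(inherits(params, "SyntheticParams"))
  p <- params
  with_seed(p$seed, {
    d <- p$grid
    sp <- p$spacing
    ax <- p$breast_semi_axes_mm

    # voxel-centre coordinates; chest wall at the row = 1 face
    x <- (seq_len(d[1]) - 0.5) * sp[1]               # protrusion
    y <- (seq_len(d[2]) - 0.5) * sp[2] - d[2] * sp[2] / 2
    z <- (seq_len(d[3]) - 0.5) * sp[3] - d[3] * sp[3] / 2
    r2 <- outer(outer((x / ax[1])^2, (y / ax[2])^2, `+`), (z / ax[3])^2, `+`)
    breast <- r2 <= 1

    if (!any(breast)) stop("infeasible density: breast geometry is empty")

    # skin: shell within skin_thickness of the curved surface (distance
    # to background voxel centres; the flat chest-wall face has no
    # adjacent background, hence no skin there)
    dist <- array(cpp_edt3d(as.numeric(breast), dim(breast), sp),
                  dim(breast))
    skin <- breast & dist <= p$skin_thickness_mm
    interior <- breast & !skin
    n_int <- sum(interior)
    if (n_int == 0L)
      stop("infeasible density: no interior voxels inside the skin shell")

    # fibroglandular placement by field-quantile thresholding: exact to
    # voxel resolution and monotone in the target fraction
    labels <- array(0L, d)
    labels[skin] <- 1L
    labels[interior] <- 2L
    if (p$target_fgt_fraction > 0) {
      field <- correlated_field(d, sp, p$fgt_correlation_mm)
      fv <- field[interior]
      thr <- stats::quantile(fv, 1 - p$target_fgt_fraction, names = FALSE,
                             type = 1)
      fgt <- interior & field >= thr
      labels[fgt] <- 3L
    }
    n_fgt <- sum(labels == 3L)
    true_frac <- n_fgt / n_int
    if (p$target_fgt_fraction > 0 &&
        abs(true_frac - p$target_fgt_fraction) > 0.02)
      stop(sprintf(
        "infeasible density: achieved fraction %.3f vs target %.3f",
        true_frac, p$target_fgt_fraction))

    vol <- array(0, d)
    n_bg <- sum(labels == 0L)
    vol[labels == 0L] <- abs(stats::rnorm(n_bg, 0, p$background_noise_sd))
    vol[labels == 1L] <- stats::rnorm(sum(labels == 1L),
                                      p$skin_intensity_mean,
                                      p$skin_intensity_sd)
    vol[labels == 2L] <- stats::rnorm(sum(labels == 2L),
                                      p$fat_intensity_mean,
                                      p$fat_intensity_sd)
    vol[labels == 3L] <- stats::rnorm(n_fgt, p$fgt_intensity_mean,
                                      p$fgt_intensity_sd)
    vol[vol < 0] <- 0

    volume <- MRIVolume(vol, sp, acquisitionMeta())
    if (p$ringing)
      volume <- addGibbsRinging(volume, p$ringing_truncation)
    volume <- MRIVolume(round(intensities(volume)), sp, acquisitionMeta())

    legend <- c(background = 0L, skin = 1L, fat = 2L)
    if (n_fgt > 0) legend <- c(legend, fgt_1 = 3L)
    truth <- new("SyntheticGroundTruth",
                 labels = TissueLabelMap(labels, legend, sp),
                 true_fgt_fraction = true_frac)
    list(volume = volume, truth = truth)
  })
}

#' Apply in-plane Gibbs ringing by k-space truncation
#'
#' Emulates the ringing artefact of truncated MR acquisition: each slice
#' is Fourier transformed, only the central \code{truncation_fraction} of
#' spatial frequencies per in-plane axis is retained, and the magnitude
#' of the inverse transform is returned. \code{truncation_fraction = 1}
#' leaves the volume unchanged up to numerical tolerance.
#'
#' @param volume an [MRIVolume-class].
#' @param truncation_fraction fraction of k-space kept per axis, in (0, 1].
#' @return An [MRIVolume-class] with edge ripples near sharp boundaries.
#' @examples
#' vol <- MRIVolume(array(runif(32 * 32), c(32, 32, 1)), c(1, 1, 1))
#' rng <- addGibbsRinging(vol, 0.5)
#' @export
addGibbsRinging <- function(volume, truncation_fraction) {
  stopifnot(is(volume, "MRIVolume"))
  if (!is.numeric(truncation_fraction) || length(truncation_fraction) != 1L ||
      truncation_fraction <= 0 || truncation_fraction > 1)
    stop("truncation_fraction must be a single value in (0, 1]")
  src <- intensities(volume)
  d <- dim(src)
  keep1 <- function(n) {
    m <- max(1L, round(truncation_fraction * n))
    cf <- ifelse(seq_len(n) - 1 < n / 2, seq_len(n) - 1, seq_len(n) - 1 - n)
    rank(abs(cf) + (cf < 0) * 0.25, ties.method = "first") <= m
  }
  kmask <- outer(keep1(d[1]), keep1(d[2]), `&`)
  out <- array(0, d)
  for (k in seq_len(d[3])) {
    F <- stats::fft(src[, , k])
    F[!kmask] <- 0
    out[, , k] <- Mod(stats::fft(F, inverse = TRUE)) / (d[1] * d[2])
  }
  MRIVolume(out, voxelSpacing(volume), volume@meta)
}

#' Generate a voxelized spherical tumour inclusion
#'
#' Voxelizes a sphere of the requested diameter (default 10 mm, the
#' repository-style malignant inclusion) on an isotropic or anisotropic
#' grid: a voxel belongs to the tumour when its centre lies inside the
#' sphere. The grid is sized to the sphere with a one-voxel margin and
#' the sphere centre sits on a voxel centre.
#'
#' @param diameter_mm sphere diameter in mm; must be at least twice the
#'   largest spacing.
#' @param spacing_mm numeric(3) voxel spacing of the tumour grid in mm.
#' @param properties [DebyeParameters-class] of the tumour tissue;
#'   defaults to the tumour entry of [defaultPropertyTable()].
#' @return A [TumourModel-class].
#' @examples
#' tum <- generateTumour(10, c(0.5, 0.5, 0.5))
#' sum(maskArray(tum))
#' @seealso [embedTumour()], [sphericalEquivalentDiameter()]
#' @export
generateTumour <- function(diameter_mm = 10,
                           spacing_mm = c(0.25, 0.25, 0.25),
                           properties = NULL) {
  sp <- as.numeric(spacing_mm)
  stopifnot(length(sp) == 3L, all(sp > 0), diameter_mm > 0)
  if (diameter_mm < 2 * max(sp))
    stop("diameter too small for grid: need diameter >= 2x max spacing")
  if (is.null(properties)) properties <- defaultPropertyTable()@entries$tumour
  r <- diameter_mm / 2
  half <- ceiling(r / sp) + 1L
  n <- 2L * half + 1L
  centre <- (half + 1L)
  dist2 <- function(i, s, c0) ((i - c0) * s)^2
  r2 <- outer(outer(dist2(seq_len(n[1]), sp[1], centre[1]),
                    dist2(seq_len(n[2]), sp[2], centre[2]), `+`),
              dist2(seq_len(n[3]), sp[3], centre[3]), `+`)
  mask <- r2 <= r^2
  new("TumourModel", mask = mask, spacing = sp, properties = properties,
      nominal_diameter_mm = diameter_mm)
}

#' Spherical-equivalent diameter of a voxel mask
#'
#' \eqn{(6V/\pi)^{1/3}} where \eqn{V} is voxel count times voxel volume.
#'
#' @param x a [TumourModel-class], or a logical array (then
#'   \code{spacing} is required).
#' @param spacing numeric(3) voxel spacing in mm when \code{x} is an array.
#' @return Diameter in mm.
#' @examples
#' sphericalEquivalentDiameter(generateTumour(10, c(0.25, 0.25, 0.25)))
#' @export
sphericalEquivalentDiameter <- function(x, spacing = NULL) {
  if (is(x, "TumourModel")) {
    v <- sum(x@mask) * prod(x@spacing)
  } else {
    stopifnot(!is.null(spacing))
    v <- sum(x != 0) * prod(spacing)
  }
  (6 * v / pi)^(1 / 3)
}

#' Write a volume to disk as a DICOM slice series
#'
#' Emits one single-frame explicit-VR little-endian DICOM file per slice
#' with the geometry tags (matrix size, pixel spacing, slice thickness,
#' image position/orientation) and the acquisition metadata carried by
#' the volume, so that [readDicomSeries()] can rebuild the volume
#' end-to-end. Intensities are rounded to uint16.
#'
#' @param volume an [MRIVolume-class].
#' @param directory output directory (created if absent).
#' @param prefix file-name prefix.
#' @return Invisibly, the written file paths.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' vol <- MRIVolume(array(100, c(8, 8, 3)), c(1, 1, 2))
#' writeDicomSeries(vol, dir)
#' @export
writeDicomSeries <- function(volume, directory, prefix = "slice") {
  stopifnot(is(volume, "MRIVolume"))
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  src <- intensities(volume)
  if (max(src) > 65535)
    stop("intensities exceed the uint16 range of the DICOM writer")
  d <- dim(src)
  sp <- voxelSpacing(volume)
  paths <- character(d[3])
  for (k in seq_len(d[3])) {
    paths[k] <- file.path(directory, sprintf("%s_%04d.dcm", prefix, k))
    write_dicom_slice(src[, , k], paths[k],
                      pixel_spacing = sp[1:2], slice_thickness = sp[3],
                      position = c(0, 0, (k - 1) * sp[3]),
                      instance = k, meta = volume@meta)
  }
  invisible(paths)
}
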