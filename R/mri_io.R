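#' Read a DICOM slice series into a 3D volume
#'
#' Reads every DICOM file in \code{directory}, sorts the slices by their
#' spatial position along the slice axis (image position, not file name),
#' and merges them into a single [MRIVolume-class]. In-plane spacing is
#' taken from the pixel-spacing tag; slice spacing from the inter-slice
#' position differences, falling back to the declared slice thickness
#' when only one slice is present. If positions and declared thickness
#' disagree by more than 1\%, a warning is emitted and positions win.
#' Rescale slope/intercept tags are applied when present.
#'
#' @param directory path to a directory of single-frame DICOM slices.
#' @return An [MRIVolume-class] of shape (rows, columns, slices).
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' p <- syntheticParams(grid = c(16, 16, 4), spacing = c(1, 1, 2),
#'                      breast_semi_axes_mm = c(8, 6, 5), seed = 1)
#' gen <- generateBreastVolume(p)
#' writeDicomSeries(gen$volume, dir)
#' vol <- readDicomSeries(dir)
#' dim(vol)
#' @seealso [writeDicomSeries()], [resampleVolume()]
#' @export
readDicomSeries <- function(directory) {
  files <- list.files(directory, full.names = TRUE, no.. = TRUE)
  files <- files[!dir.exists(files)]
  slices <- list()
  for (f in files) {
    s <- tryCatch(decode_dicom_slice(read_dicom_file(f), f),
                  error = function(e) NULL)
    if (!is.null(s)) slices[[length(slices) + 1L]] <- s
  }
  if (length(slices) == 0L)
    stop("no slices: directory contains no readable DICOM files")

  dims <- vapply(slices, function(s) c(s$rows, s$cols), numeric(2))
  sp <- vapply(slices, function(s) s$pixel_spacing, numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]) ||
      any(abs(sp - sp[, 1]) > 1e-9))
    stop("inconsistent series: slices differ in matrix size or pixel spacing")

  z <- vapply(slices, function(s) s$z, numeric(1))
  if (anyNA(z)) stop("ambiguous ordering: slice(s) without image position")
  ord <- order(z)
  z <- z[ord]
  slices <- slices[ord]
  if (length(z) > 1L && any(diff(z) < 1e-9))
    stop("ambiguous ordering: duplicate slice positions in series")

  thick <- slices[[1]]$slice_thickness
  if (length(z) > 1L) {
    dz <- diff(z)
    slice_spacing <- stats::median(dz)
    if (!is.null(thick) && abs(slice_spacing - thick) > 0.01 * thick)
      warning(sprintf(
        "slice positions imply spacing %.4g mm but declared thickness is %.4g mm; using positions",
        slice_spacing, thick))
  } else {
    if (is.null(thick)) stop("single slice without slice thickness tag")
    slice_spacing <- thick
  }

  vol <- array(0, c(dims[1, 1], dims[2, 1], length(slices)))
  for (k in seq_along(slices)) vol[, , k] <- slices[[k]]$pixels
  vol[vol < 0] <- 0

  s1 <- slices[[1]]
  meta <- NULL
  if (!is.null(s1$tr) && !is.null(s1$te)) {
    te <- unique(unlist(lapply(slices, `[[`, "te")))
    meta <- acquisitionMeta(
      repetition_time_ms = s1$tr, echo_times_ms = te,
      flip_angle_deg = if (is.null(s1$flip)) 10 else s1$flip,
      field_strength_T = if (is.null(s1$field)) 3 else s1$field,
      sequence_name = if (is.null(s1$series)) "unknown" else s1$series)
  }
  MRIVolume(vol, c(sp[1, 1], sp[2, 1], slice_spacing), meta)
}

#' Resample a volume to a new voxel spacing
#'
#' Trilinear interpolation onto a grid with the requested spacing. The
#' physical extent of the volume is preserved to within one voxel per
#' axis; samples outside the source voxel-centre hull are clamped to the
#' border value.
#'
#' @param volume an [MRIVolume-class].
#' @param target_spacing_mm numeric(3) of positive spacings in mm.
#' @return A resampled [MRIVolume-class].
#' @examples
#' vol <- MRIVolume(array(runif(8 * 8 * 8), c(8, 8, 8)), c(1, 1, 1))
#' dim(resampleVolume(vol, c(0.5, 0.5, 0.5)))
#' @export
resampleVolume <- function(volume, target_spacing_mm) {
  stopifnot(is(volume, "MRIVolume"))
  ts <- as.numeric(target_spacing_mm)
  if (length(ts) != 3L || any(!is.finite(ts)) || any(ts <= 0))
    stop("invalid spacing: target spacing must be three positive values")
  src <- intensities(volume)
  ss <- voxelSpacing(volume)
  d <- dim(src)
  nd <- pmax(1L, as.integer(round(d * ss / ts)))
  if (all(nd == d) && all(abs(ts - ss) < 1e-12))
    return(MRIVolume(src, ss, volume@meta))

  # voxel centres: x_i = (i - 0.5) * spacing; interpolate in source
  # fractional index space, clamped at the borders
  coord <- function(n_new, s_new, s_old, n_old) {
    x <- (seq_len(n_new) - 0.5) * s_new
    pmin(pmax(x / s_old + 0.5, 1), n_old)
  }
  fx <- coord(nd[1], ts[1], ss[1], d[1])
  fy <- coord(nd[2], ts[2], ss[2], d[2])
  fz <- coord(nd[3], ts[3], ss[3], d[3])

  i0 <- pmin(floor(fx), d[1] - ifelse(d[1] > 1, 1, 0)); wx <- fx - i0
  j0 <- pmin(floor(fy), d[2] - ifelse(d[2] > 1, 1, 0)); wy <- fy - j0
  k0 <- pmin(floor(fz), d[3] - ifelse(d[3] > 1, 1, 0)); wz <- fz - k0
  i1 <- pmin(i0 + 1, d[1]); j1 <- pmin(j0 + 1, d[2]); k1 <- pmin(k0 + 1, d[3])

  out <- array(0, nd)
  IX0 <- rep(i0, times = nd[2]); IX1 <- rep(i1, times = nd[2])
  JX0 <- rep(j0, each = nd[1]); JX1 <- rep(j1, each = nd[1])
  WX <- rep(wx, times = nd[2]); WY <- rep(wy, each = nd[1])
  n_in <- d[1]
  for (k in seq_len(nd[3])) {
    s0 <- src[, , k0[k]]
    s1 <- src[, , k1[k]]
    bilin <- function(sl) {
      v00 <- sl[IX0 + (JX0 - 1) * n_in]
      v10 <- sl[IX1 + (JX0 - 1) * n_in]
      v01 <- sl[IX0 + (JX1 - 1) * n_in]
      v11 <- sl[IX1 + (JX1 - 1) * n_in]
      (1 - WY) * ((1 - WX) * v00 + WX * v10) +
        WY * ((1 - WX) * v01 + WX * v11)
    }
    out[, , k] <- (1 - wz[k]) * bilin(s0) + wz[k] * bilin(s1)
  }
  MRIVolume(out, ts, volume@meta)
}
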