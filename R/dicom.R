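# Minimal single-frame DICOM slice I/O (explicit VR, little endian).
#
# Scope is deliberately narrow: the monochrome 16-bit single-frame slice
# series this pipeline consumes and the synthetic generator emits. Long
# binary VRs other than the pixel data, sequences, and implicit-VR or
# big-endian transfer syntaxes are out of scope and rejected with an
# explicit error.

DICOM_LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

dicom_tag_key <- function(group, element) sprintf("%04X,%04X", group, element)

# parse one DICOM file into a named list of elements (key "GGGG,EEEE")
read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 140L || rawToChar(raw[129:132]) != "DICM")
    stop("not a DICOM file (missing DICM magic): ", path)
  pos <- 133L
  out <- list()
  n <- length(raw)
  u16 <- function(i) as.integer(raw[i]) + 256L * as.integer(raw[i + 1L])
  u32 <- function(i) u16(i) + 65536 * u16(i + 2L)
  while (pos + 7L <= n) {
    group <- u16(pos); element <- u16(pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop("unsupported transfer syntax (expected explicit VR): ", path)
    if (vr %in% DICOM_LONG_VRS) {
      len <- u32(pos + 8L)
      pos <- pos + 12L
    } else {
      len <- u16(pos + 6L)
      pos <- pos + 8L
    }
    if (pos + len - 1L > n) stop("truncated DICOM element in ", path)
    val_raw <- if (len > 0L) raw[pos:(pos + len - 1L)] else raw(0)
    pos <- pos + len
    key <- dicom_tag_key(group, element)
    out[[key]] <- list(vr = vr, raw = val_raw)
  }
  out
}

dicom_string <- function(el) {
  if (is.null(el)) return(NULL)
  trimws(rawToChar(el$raw))
}

dicom_numeric <- function(el) {
  if (is.null(el)) return(NULL)
  s <- dicom_string(el)
  as.numeric(strsplit(s, "\\\\")[[1]])
}

dicom_uint16s <- function(el) {
  if (is.null(el)) return(NULL)
  readBin(el$raw, "integer", n = length(el$raw) / 2L, size = 2L,
          signed = FALSE, endian = "little")
}

# decode one parsed slice into list(pixels = matrix[row, col], ...)
decode_dicom_slice <- function(elems, path) {
  rows <- dicom_uint16s(elems[["0028,0010"]])
  cols <- dicom_uint16s(elems[["0028,0011"]])
  ps <- dicom_numeric(elems[["0028,0030"]])
  pix <- elems[["7FE0,0010"]]
  if (is.null(rows) || is.null(cols) || is.null(ps) || is.null(pix))
    stop("DICOM slice missing Rows/Columns/PixelSpacing/PixelData: ", path)
  v <- dicom_uint16s(pix)[seq_len(rows * cols)]
  slope <- dicom_numeric(elems[["0028,1053"]])
  inter <- dicom_numeric(elems[["0028,1052"]])
  if (!is.null(slope)) v <- v * slope
  if (!is.null(inter)) v <- v + inter
  # DICOM pixel data is row-by-row (column index fastest)
  pixels <- t(matrix(v, nrow = cols, ncol = rows))
  ipp <- dicom_numeric(elems[["0020,0032"]])
  list(pixels = pixels,
       rows = rows, cols = cols,
       # PixelSpacing is (row spacing, column spacing)
       pixel_spacing = ps,
       slice_thickness = dicom_numeric(elems[["0018,0050"]]),
       position = ipp,
       z = if (is.null(ipp)) NA_real_ else ipp[3],
       instance = dicom_numeric(elems[["0020,0013"]]),
       tr = dicom_numeric(elems[["0018,0080"]]),
       te = dicom_numeric(elems[["0018,0081"]]),
       flip = dicom_numeric(elems[["0018,1314"]]),
       field = dicom_numeric(elems[["0018,0087"]]),
       series = dicom_string(elems[["0008,103E"]]))
}

# ---- writing -------------------------------------------------------------

dicom_pad <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2L == 1L) c(bytes, pad) else bytes
}

dicom_element <- function(group, element, vr, value_raw) {
  head <- writeBin(as.integer(c(group, element)), raw(), size = 2L,
                   endian = "little")
  vrb <- charToRaw(vr)
  if (vr %in% DICOM_LONG_VRS) {
    len <- writeBin(length(value_raw), raw(), size = 4L, endian = "little")
    c(head, vrb, as.raw(c(0, 0)), len, value_raw)
  } else {
    if (length(value_raw) > 65534L) stop("value too long for short VR")
    len <- writeBin(length(value_raw), raw(), size = 2L, endian = "little")
    c(head, vrb, len, value_raw)
  }
}

dicom_str_element <- function(group, element, vr, s, pad = as.raw(0x20)) {
  dicom_element(group, element, vr, dicom_pad(charToRaw(s), pad))
}

dicom_us_element <- function(group, element, v) {
  dicom_element(group, element, "US",
                writeBin(as.integer(v), raw(), size = 2L, endian = "little"))
}

# write one uint16 monochrome slice; pixels is matrix[row, col]
write_dicom_slice <- function(pixels, path, pixel_spacing, slice_thickness,
                              position, instance, meta = NULL) {
  if (any(pixels < 0) || any(pixels > 65535))
    stop("pixel values out of uint16 range")
  num <- function(x) paste(format(x, digits = 10, trim = TRUE,
                                  scientific = FALSE), collapse = "\\")
  body <- c(
    dicom_str_element(0x0002, 0x0010, "UI",
                      "1.2.840.10008.1.2.1", as.raw(0)),
    dicom_str_element(0x0008, 0x0060, "CS", "MR"),
    if (!is.null(meta$sequence_name))
      dicom_str_element(0x0008, 0x103E, "LO", meta$sequence_name),
    dicom_str_element(0x0018, 0x0050, "DS", num(slice_thickness)),
    if (!is.null(meta$repetition_time_ms))
      dicom_str_element(0x0018, 0x0080, "DS", num(meta$repetition_time_ms)),
    if (!is.null(meta$echo_times_ms))
      dicom_str_element(0x0018, 0x0081, "DS", num(meta$echo_times_ms[1])),
    if (!is.null(meta$field_strength_T))
      dicom_str_element(0x0018, 0x0087, "DS", num(meta$field_strength_T)),
    if (!is.null(meta$flip_angle_deg))
      dicom_str_element(0x0018, 0x1314, "DS", num(meta$flip_angle_deg)),
    dicom_str_element(0x0020, 0x0013, "IS", num(instance)),
    dicom_str_element(0x0020, 0x0032, "DS", num(position)),
    dicom_str_element(0x0020, 0x0037, "DS", num(c(1, 0, 0, 0, 1, 0))),
    dicom_us_element(0x0028, 0x0002, 1L),
    dicom_str_element(0x0028, 0x0004, "CS", "MONOCHROME2"),
    dicom_us_element(0x0028, 0x0010, nrow(pixels)),
    dicom_us_element(0x0028, 0x0011, ncol(pixels)),
    dicom_str_element(0x0028, 0x0030, "DS", num(pixel_spacing)),
    dicom_us_element(0x0028, 0x0100, 16L),
    dicom_us_element(0x0028, 0x0101, 16L),
    dicom_us_element(0x0028, 0x0102, 15L),
    dicom_us_element(0x0028, 0x0103, 0L),
    dicom_element(0x7FE0, 0x0010, "OW", {
      ints <- as.integer(round(t(pixels)))
      # writeBin size=2 takes signed shorts; wrap the upper uint16 range
      ints[ints > 32767L] <- ints[ints > 32767L] - 65536L
      writeBin(ints, raw(), size = 2L, endian = "little")
    })
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), body), con)
  invisible(path)
}
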