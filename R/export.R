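# repository-style element names for legend roles (Skin_Layer,
# Fat_Cluster, FGT_Cluster_k, Tumour)
role_to_element <- function(role) {
  if (role == "skin") return("Skin_Layer")
  if (role == "fat") return("Fat_Cluster")
  if (role == "tumour") return("Tumour")
  if (grepl("^fgt_", role))
    return(sub("^fgt_", "FGT_Cluster_", role))
  role
}

element_to_role <- function(el) {
  if (el == "Skin_Layer") return("skin")
  if (el == "Fat_Cluster") return("fat")
  if (el == "Tumour") return("tumour")
  if (grepl("^FGT_Cluster_", el))
    return(sub("^FGT_Cluster_", "fgt_", el))
  el
}

#' Write / read a label map as a raw binary voxel grid
#'
#' One unsigned byte per voxel, rows fastest, then columns, then slices
#' (the array's native memory order). A mandatory plain-text sidecar
#' (\code{<path>.txt}) records dimensions, spacing, axis order and the
#' label legend, making the RAW file self-describing.
#'
#' @param labelmap a [TissueLabelMap-class] with at most 255 labels.
#' @param path output file path (sidecar written at \code{<path>.txt}).
#' @return \code{writeRaw} returns the sidecar path invisibly;
#'   \code{readRaw} returns the [TissueLabelMap-class].
#' @examples
#' lm <- TissueLabelMap(array(0:1, c(4, 4, 2)),
#'                      c(background = 0, skin = 1), c(1, 1, 1))
#' f <- tempfile(fileext = ".raw")
#' writeRaw(lm, f)
#' identical(labelArray(readRaw(f)), labelArray(lm))
#' @export
writeRaw <- function(labelmap, path) {
  stopifnot(is(labelmap, "TissueLabelMap"))
  labels <- labelArray(labelmap)
  if (max(labels) > 255L)
    stop("label overflow: RAW supports at most 255 labels")
  con <- file(path, "wb")
  writeBin(as.raw(as.vector(labels)), con)
  close(con)
  lg <- labelLegend(labelmap)
  d <- dim(labels)
  sidecar <- paste0(path, ".txt")
  writeLines(c(
    sprintf("dimensions: %d %d %d", d[1], d[2], d[3]),
    sprintf("spacing_mm: %.10g %.10g %.10g", voxelSpacing(labelmap)[1],
            voxelSpacing(labelmap)[2], voxelSpacing(labelmap)[3]),
    "axis_order: row column slice (row fastest)",
    "datatype: uint8",
    sprintf("label: %d %s", lg, names(lg))), sidecar)
  invisible(sidecar)
}

#' @rdname writeRaw
#' @export
readRaw <- function(path) {
  sidecar <- paste0(path, ".txt")
  if (!file.exists(sidecar)) stop("missing RAW sidecar file: ", sidecar)
  meta <- readLines(sidecar)
  field <- function(key) {
    ln <- grep(paste0("^", key, ":"), meta, value = TRUE)
    trimws(sub(paste0("^", key, ":"), "", ln))
  }
  d <- as.integer(strsplit(field("dimensions"), "\\s+")[[1]])
  sp <- as.numeric(strsplit(field("spacing_mm"), "\\s+")[[1]])
  lab_lines <- strsplit(field("label"), "\\s+")
  legend <- structure(vapply(lab_lines, function(x) as.integer(x[1]), 1L),
                      names = vapply(lab_lines, `[`, "", 2L))
  bytes <- readBin(path, "raw", n = prod(d))
  if (length(bytes) != prod(d)) stop("RAW file size does not match sidecar")
  TissueLabelMap(array(as.integer(bytes), d), legend, sp)
}

#' Write / read a breast model as an HDF5 container
#'
#' Layout mirrors the repository convention: group \code{modelData}
#' holds one 3D uint8 binary dataset per model element
#' (\code{Skin_Layer}, \code{Fat_Cluster}, \code{FGT_Cluster_k},
#' \code{Tumour}), each carrying its integer label code as a dataset
#' attribute; group \code{modelProps} holds a 4-vector of Debye
#' parameters (eps_inf, delta_eps, tau_s, sigma_s) per element; root
#' attributes record breastHealth, breastClass, density, modelName,
#' nClusters and voxelSize. \code{readHdf5Model} is the exact inverse.
#'
#' @param model a [BreastModel-class].
#' @param path HDF5 file path (overwritten).
#' @return \code{writeHdf5Model} returns \code{path} invisibly;
#'   \code{readHdf5Model} returns the [BreastModel-class].
#' @examples
#' p <- syntheticParams(grid = c(32, 32, 16), spacing = c(2, 2, 2),
#'                      breast_semi_axes_mm = c(30, 24, 14),
#'                      skin_thickness_mm = 3)
#' model <- buildModel(generateBreastVolume(p)$volume,
#'                     skin_thickness_mm = 3)
#' f <- tempfile(fileext = ".h5")
#' writeHdf5Model(model, f)
#' readHdf5Model(f)
#' @export
writeHdf5Model <- function(model, path) {
  stopifnot(is(model, "BreastModel"))
  if (file.exists(path)) unlink(path)
  lm <- labelMap(model)
  lg <- labelLegend(lm)
  labels <- labelArray(lm)
  a <- modelAttributes(model)

  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "modelData")
  rhdf5::h5createGroup(path, "modelProps")

  for (role in setdiff(names(lg), "background")) {
    el <- role_to_element(role)
    mask <- array(as.integer(labels == lg[[role]]), dim(labels))
    rhdf5::h5createDataset(path, paste0("modelData/", el), dim(mask),
                           storage.mode = "integer", chunk = dim(mask),
                           level = 4)
    rhdf5::h5write(mask, path, paste0("modelData/", el))
    fid <- rhdf5::H5Fopen(path)
    did <- rhdf5::H5Dopen(fid, paste0("modelData/", el))
    rhdf5::h5writeAttribute(lg[[role]], did, "label")
    rhdf5::H5Dclose(did)
    rhdf5::H5Fclose(fid)
    par <- modelProperties(model)[[role]]
    rhdf5::h5write(unname(debyeVector(par)), path,
                   paste0("modelProps/", el))
  }

  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(a$breast_health, fid, "breastHealth")
  rhdf5::h5writeAttribute(a$breast_class, fid, "breastClass")
  rhdf5::h5writeAttribute(a$density_percent, fid, "density")
  rhdf5::h5writeAttribute(a$model_name, fid, "modelName")
  rhdf5::h5writeAttribute(as.integer(a$n_fgt_clusters), fid, "nClusters")
  rhdf5::h5writeAttribute(a$property_level, fid, "propertyLevel")
  rhdf5::h5writeAttribute(as.numeric(a$voxel_size_mm), fid, "voxelSize")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' @rdname writeHdf5Model
#' @export
readHdf5Model <- function(path) {
  if (!file.exists(path)) stop("malformed model file: file not found")
  contents <- rhdf5::h5ls(path)
  if (!"modelData" %in% contents$name[contents$otype == "H5I_GROUP"] ||
      !"modelProps" %in% contents$name[contents$otype == "H5I_GROUP"])
    stop("malformed model file: missing modelData/modelProps groups")
  att <- rhdf5::h5readAttributes(path, "/")
  need <- c("breastHealth", "breastClass", "density", "modelName",
            "nClusters", "propertyLevel", "voxelSize")
  if (!all(need %in% names(att)))
    stop("malformed model file: missing root attribute(s) ",
         paste(setdiff(need, names(att)), collapse = ", "))

  els <- contents$name[contents$group == "/modelData"]
  if (length(els) == 0L) stop("malformed model file: no model elements")
  labels <- NULL
  legend <- c(background = 0L)
  props <- list()
  sp <- as.numeric(att$voxelSize)
  for (el in els) {
    mask <- rhdf5::h5read(path, paste0("modelData/", el))
    code <- as.integer(rhdf5::h5readAttributes(
      path, paste0("modelData/", el))$label)
    role <- element_to_role(el)
    if (is.null(labels)) labels <- array(0L, dim(mask))
    labels[mask != 0] <- code
    legend[role] <- code
    dp <- as.numeric(rhdf5::h5read(path, paste0("modelProps/", el)))
    props[[role]] <- debyeParameters(dp[1], dp[2], dp[3], dp[4])
  }
  lm <- TissueLabelMap(labels, legend, sp)
  new("BreastModel", labelmap = lm, properties = props,
      attributes = list(
        breast_health = as.character(att$breastHealth),
        breast_class = as.character(att$breastClass),
        density_percent = as.numeric(att$density),
        model_name = as.character(att$modelName),
        n_fgt_clusters = as.integer(att$nClusters),
        property_level = as.character(att$propertyLevel),
        voxel_size_mm = sp))
}

#' Write / read model properties as XML
#'
#' Root node \code{modelProps} carries the model attributes; one element
#' node per tissue (repository-style names) holds the four Debye
#' parameter children \code{eps_inf}, \code{del_eps}, \code{tau},
#' \code{sigma_s}, serialized with 15 significant digits.
#'
#' @param model a [BreastModel-class].
#' @param path XML file path.
#' @return \code{writeXmlProperties} returns \code{path} invisibly;
#'   \code{readXmlProperties} returns a named list of
#'   [DebyeParameters-class] keyed by tissue role, with the model
#'   attributes in \code{attr(, "model_attributes")}.
#' @examples
#' p <- syntheticParams(grid = c(32, 32, 16), spacing = c(2, 2, 2),
#'                      breast_semi_axes_mm = c(30, 24, 14),
#'                      skin_thickness_mm = 3)
#' model <- buildModel(generateBreastVolume(p)$volume,
#'                     skin_thickness_mm = 3)
#' f <- tempfile(fileext = ".xml")
#' writeXmlProperties(model, f)
#' names(readXmlProperties(f))
#' @export
writeXmlProperties <- function(model, path) {
  stopifnot(is(model, "BreastModel"))
  a <- modelAttributes(model)
  num <- function(x) sprintf("%.15g", x)
  doc <- xml2::xml_new_root("modelProps",
    breastHealth = a$breast_health,
    breastClass = a$breast_class,
    density = num(a$density_percent),
    modelName = a$model_name,
    nClusters = as.character(a$n_fgt_clusters),
    propertyLevel = a$property_level,
    voxelSize = paste(num(a$voxel_size_mm), collapse = " "))
  for (role in names(modelProperties(model))) {
    par <- modelProperties(model)[[role]]
    node <- xml2::xml_add_child(doc, role_to_element(role))
    xml2::xml_add_child(node, "eps_inf", num(par@eps_inf))
    xml2::xml_add_child(node, "del_eps", num(par@delta_eps))
    xml2::xml_add_child(node, "tau", num(par@tau_s))
    xml2::xml_add_child(node, "sigma_s", num(par@sigma_s))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' @rdname writeXmlProperties
#' @export
readXmlProperties <- function(path) {
  doc <- xml2::read_xml(path)
  if (xml2::xml_name(doc) != "modelProps")
    stop("malformed property file: root node is not modelProps")
  out <- list()
  for (node in xml2::xml_children(doc)) {
    role <- element_to_role(xml2::xml_name(node))
    get <- function(tag) {
      child <- xml2::xml_find_first(node, tag)
      if (is.na(xml2::xml_name(child)))
        stop("incomplete property entry: ", role, " lacks <", tag, ">")
      as.numeric(xml2::xml_text(child))
    }
    out[[role]] <- debyeParameters(get("eps_inf"), get("del_eps"),
                                   get("tau"), get("sigma_s"))
  }
  ats <- xml2::xml_attrs(doc)
  attr(out, "model_attributes") <- as.list(ats)
  out
}

#' Write one model element as a binary STL surface mesh
#'
#' Triangulates the 0.5-level surface of the element's binary mask as a
#' watertight voxel-face mesh: every boundary voxel face between the
#' element and its exterior contributes two triangles with consistent
#' outward normals, in millimetre coordinates honouring the voxel
#' spacing. The enclosed volume of this mesh equals voxel count times
#' voxel volume exactly. Output is binary little-endian STL.
#'
#' @param labelmap a [TissueLabelMap-class].
#' @param label tissue role name (e.g. \code{"fgt_1"}) or integer code.
#' @param path output STL path.
#' @return A list with \code{n_triangles} and \code{volume_mm3} (signed
#'   volume from the divergence theorem; positive for outward normals).
#' @examples
#' lm <- TissueLabelMap(array(1L, c(5, 5, 5)), c(cube = 1), c(1, 1, 1))
#' f <- tempfile(fileext = ".stl")
#' writeStl(lm, "cube", f)
#' @export
writeStl <- function(labelmap, label, path) {
  stopifnot(is(labelmap, "TissueLabelMap"))
  lg <- labelLegend(labelmap)
  code <- if (is.character(label)) {
    if (!label %in% names(lg)) stop("unknown label: ", label)
    lg[[label]]
  } else as.integer(label)
  mask <- labelArray(labelmap) == code
  if (!any(mask)) stop("empty cluster: label has no voxels")
  sp <- voxelSpacing(labelmap)
  d <- dim(mask)

  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- mask

  tris <- list()
  # exposed faces in each of the 6 directions; voxel i spans
  # [(i-1)*s, i*s] in mm
  shifts <- list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0),
                 c(0, 1, 0), c(0, 0, -1), c(0, 0, 1))
  for (s in shifts) {
    nb <- pad[(2:(d[1] + 1)) + s[1], (2:(d[2] + 1)) + s[2],
              (2:(d[3] + 1)) + s[3], drop = FALSE]
    exposed <- which(mask & !nb, arr.ind = TRUE)
    if (nrow(exposed) == 0) next
    tris[[length(tris) + 1L]] <- face_triangles(exposed, s, sp)
  }
  tri <- do.call(rbind, tris)
  n_tri <- as.integer(nrow(tri) / 3L)

  # signed volume via divergence theorem
  v1 <- tri[seq(1, nrow(tri), 3), , drop = FALSE]
  v2 <- tri[seq(2, nrow(tri), 3), , drop = FALSE]
  v3 <- tri[seq(3, nrow(tri), 3), , drop = FALSE]
  vol <- sum(v1[, 1] * (v2[, 2] * v3[, 3] - v3[, 2] * v2[, 3]) -
             v2[, 1] * (v1[, 2] * v3[, 3] - v3[, 2] * v1[, 3]) +
             v3[, 1] * (v1[, 2] * v2[, 3] - v2[, 2] * v1[, 3])) / 6

  # face normals
  e1 <- v2 - v1; e2 <- v3 - v1
  nrm <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
               e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
               e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  nl <- sqrt(rowSums(nrm^2))
  nrm <- nrm / pmax(nl, 1e-30)

  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "BreastPhantom voxel-face STL"))
  writeBin(header[1:80], con)
  writeBin(as.integer(n_tri), con, size = 4L, endian = "little")
  block <- matrix(0, nrow = n_tri, ncol = 12)
  block[, 1:3] <- nrm
  block[, 4:6] <- v1
  block[, 7:9] <- v2
  block[, 10:12] <- v3
  flat <- as.vector(t(block))
  # interleave the 2-byte attribute count after every 12 floats
  raw_f <- writeBin(flat, raw(), size = 4L, endian = "little")
  raw_mat <- matrix(raw_f, nrow = 48L)
  zeros <- matrix(as.raw(0), nrow = 2L, ncol = n_tri)
  writeBin(as.vector(rbind(raw_mat, zeros)), con)
  list(n_triangles = n_tri, volume_mm3 = vol)
}

# triangles (two per face, CCW from outside) for exposed voxel faces;
# returns a 3-column matrix of vertices, 3 rows per triangle
face_triangles <- function(idx, dir, sp) {
  n <- nrow(idx)
  lo <- sweep(idx - 1, 2L, sp, `*`)
  hi <- sweep(idx, 2L, sp, `*`)
  ax <- which(dir != 0)
  # the exposed face sits at the low or high side along `ax`
  fc <- if (dir[ax] < 0) lo[, ax] else hi[, ax]
  others <- setdiff(1:3, ax)
  a <- others[1]; b <- others[2]
  corner <- function(ua, ub) {
    m <- matrix(0, n, 3)
    m[, ax] <- fc
    m[, a] <- if (ua) hi[, a] else lo[, a]
    m[, b] <- if (ub) hi[, b] else lo[, b]
    m
  }
  c00 <- corner(FALSE, FALSE); c10 <- corner(TRUE, FALSE)
  c01 <- corner(FALSE, TRUE); c11 <- corner(TRUE, TRUE)
  # winding: outward = dir; CCW seen from outside
  # along +ax the CCW order is c00, c10, c11 / c00, c11, c01 when
  # (a, b, ax) is a right-handed triple; flip for the other cases
  righthand <- (ax %% 3) + 1 == a || (a %% 3) + 1 == b
  flip <- xor(dir[ax] < 0, !righthand)
  t1 <- if (flip) rbind(c00, c11, c10) else rbind(c00, c10, c11)
  t2 <- if (flip) rbind(c00, c01, c11) else rbind(c00, c11, c01)
  # interleave per-face triangles: rows (face1 v1,v2,v3, face2 v1,...)
  reorder <- function(m) m[rep(seq_len(n), each = 3) + (0:2) * n, , drop = FALSE]
  rbind(reorder(t1), reorder(t2))
}

#' Write / read a model as a neutral single-file array container
#'
#' A flat HDF5 layout (datasets \code{labels}, \code{spacing},
#' \code{legend_names}, \code{legend_codes}, \code{properties} plus the
#' model attributes as root attributes) intended as the generic
#' voxelized-model container: lossless roundtrip, readable from any
#' language with an HDF5 binding.
#'
#' @param model a [BreastModel-class].
#' @param path output file path.
#' @return \code{writeVoxelContainer} returns \code{path} invisibly;
#'   \code{readVoxelContainer} the reconstructed [BreastModel-class].
#' @examples
#' p <- syntheticParams(grid = c(32, 32, 16), spacing = c(2, 2, 2),
#'                      breast_semi_axes_mm = c(30, 24, 14),
#'                      skin_thickness_mm = 3)
#' model <- buildModel(generateBreastVolume(p)$volume,
#'                     skin_thickness_mm = 3)
#' f <- tempfile(fileext = ".h5")
#' writeVoxelContainer(model, f)
#' readVoxelContainer(f)
#' @export
writeVoxelContainer <- function(model, path) {
  stopifnot(is(model, "BreastModel"))
  if (file.exists(path)) unlink(path)
  lm <- labelMap(model)
  lg <- labelLegend(lm)
  a <- modelAttributes(model)
  rhdf5::h5createFile(path)
  labels <- labelArray(lm)
  rhdf5::h5createDataset(path, "labels", dim(labels),
                         storage.mode = "integer", chunk = dim(labels),
                         level = 4)
  rhdf5::h5write(labels, path, "labels")
  rhdf5::h5write(voxelSpacing(lm), path, "spacing")
  rhdf5::h5write(names(lg), path, "legend_names")
  rhdf5::h5write(as.integer(lg), path, "legend_codes")
  roles <- names(modelProperties(model))
  pm <- vapply(modelProperties(model), function(p) unname(debyeVector(p)),
               numeric(4))
  rhdf5::h5write(pm, path, "properties")
  rhdf5::h5write(roles, path, "property_roles")
  fid <- rhdf5::H5Fopen(path)
  rhdf5::h5writeAttribute(a$breast_health, fid, "breastHealth")
  rhdf5::h5writeAttribute(a$breast_class, fid, "breastClass")
  rhdf5::h5writeAttribute(a$density_percent, fid, "density")
  rhdf5::h5writeAttribute(a$model_name, fid, "modelName")
  rhdf5::h5writeAttribute(as.integer(a$n_fgt_clusters), fid, "nClusters")
  rhdf5::h5writeAttribute(a$property_level, fid, "propertyLevel")
  rhdf5::h5writeAttribute(as.numeric(a$voxel_size_mm), fid, "voxelSize")
  rhdf5::H5Fclose(fid)
  invisible(path)
}

#' @rdname writeVoxelContainer
#' @export
readVoxelContainer <- function(path) {
  labels <- rhdf5::h5read(path, "labels")
  sp <- as.numeric(rhdf5::h5read(path, "spacing"))
  legend <- structure(as.integer(rhdf5::h5read(path, "legend_codes")),
                      names = as.character(rhdf5::h5read(path,
                                                         "legend_names")))
  pm <- rhdf5::h5read(path, "properties")
  roles <- as.character(rhdf5::h5read(path, "property_roles"))
  props <- lapply(seq_along(roles), function(i)
    debyeParameters(pm[1, i], pm[2, i], pm[3, i], pm[4, i]))
  names(props) <- roles
  att <- rhdf5::h5readAttributes(path, "/")
  lm <- TissueLabelMap(labels, legend, sp)
  new("BreastModel", labelmap = lm, properties = props,
      attributes = list(
        breast_health = as.character(att$breastHealth),
        breast_class = as.character(att$breastClass),
        density_percent = as.numeric(att$density),
        model_name = as.character(att$modelName),
        n_fgt_clusters = as.integer(att$nClusters),
        property_level = as.character(att$propertyLevel),
        voxel_size_mm = as.numeric(att$voxelSize)))
}

#' Read a binary STL file
#'
#' Minimal binary STL reader used to verify written meshes: returns the
#' triangle vertices and the signed enclosed volume.
#'
#' @param path STL file path.
#' @return A list with \code{n_triangles}, \code{vertices} (3 rows per
#'   triangle) and \code{volume_mm3}.
#' @examples
#' lm <- TissueLabelMap(array(1L, c(3, 3, 3)), c(cube = 1), c(1, 1, 1))
#' f <- tempfile(fileext = ".stl")
#' writeStl(lm, "cube", f)
#' readStl(f)$n_triangles
#' @export
readStl <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)
  n_tri <- readBin(con, "integer", size = 4L, endian = "little")
  rec <- readBin(con, "raw", n = n_tri * 50L)
  m <- matrix(rec, nrow = 50L)
  floats <- readBin(as.vector(m[1:48, ]), "numeric", size = 4L,
                    n = 12L * n_tri, endian = "little")
  fm <- matrix(floats, ncol = 12L, byrow = TRUE)
  v1 <- fm[, 4:6, drop = FALSE]
  v2 <- fm[, 7:9, drop = FALSE]
  v3 <- fm[, 10:12, drop = FALSE]
  vol <- sum(v1[, 1] * (v2[, 2] * v3[, 3] - v3[, 2] * v2[, 3]) -
             v2[, 1] * (v1[, 2] * v3[, 3] - v3[, 2] * v1[, 3]) +
             v3[, 1] * (v1[, 2] * v2[, 3] - v2[, 2] * v1[, 3])) / 6
  verts <- matrix(0, nrow = 3L * n_tri, ncol = 3L)
  verts[seq(1, 3 * n_tri, 3), ] <- v1
  verts[seq(2, 3 * n_tri, 3), ] <- v2
  verts[seq(3, 3 * n_tri, 3), ] <- v3
  list(n_triangles = n_tri, vertices = verts, volume_mm3 = vol)
}
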