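small_model <- function(K = 2, target = 0.4, seed = 91) {
  gen <- small_phantom(target = target, seed = seed,
                       grid = c(32L, 32L, 16L),
                       spacing = c(2, 2, 2))
  buildModel(gen$volume, K = K, skin_thickness_mm = 4)
}

test_that("RAW export writes one byte per voxel and round-trips", {
  m <- small_model()
  lm <- labelMap(m)
  f <- withr::local_tempfile(fileext = ".raw")
  writeRaw(lm, f)
  expect_identical(file.size(f), prod(dim(lm)) * 1)
  back <- readRaw(f)
  expect_identical(labelArray(back), labelArray(lm))
  expect_identical(labelLegend(back), labelLegend(lm))
  expect_equal(voxelSpacing(back), voxelSpacing(lm))

  zeros <- TissueLabelMap(array(0L, c(6, 5, 4)), c(background = 0),
                          c(1, 1, 1))
  fz <- withr::local_tempfile(fileext = ".raw")
  writeRaw(zeros, fz)
  expect_identical(file.size(fz), 120)
  expect_true(all(readBin(fz, "raw", 120) == as.raw(0)))

  big <- TissueLabelMap(array(300L, c(2, 2, 2)), c(huge = 300), c(1, 1, 1))
  expect_error(writeRaw(big, withr::local_tempfile()), "label overflow")
})

test_that("HDF5 model container round-trips a K=8 model exactly", {
  m <- small_model(K = 8)
  f <- withr::local_tempfile(fileext = ".h5")
  writeHdf5Model(m, f)
  back <- readHdf5Model(f)
  expect_identical(labelArray(back), labelArray(m))
  expect_identical(sort(labelLegend(back)), sort(labelLegend(m)))
  for (role in names(modelProperties(m)))
    expect_debye_equal(modelProperties(back)[[role]],
                       modelProperties(m)[[role]])
  ab <- modelAttributes(back); am <- modelAttributes(m)
  expect_equal(ab[order(names(ab))], am[order(names(am))])

  # layout: modelData/modelProps groups, breastHealth attribute
  ls <- rhdf5::h5ls(f)
  expect_true(all(c("modelData", "modelProps") %in%
                    ls$name[ls$otype == "H5I_GROUP"]))
  expect_true("breastHealth" %in%
                names(rhdf5::h5readAttributes(f, "/")))
  rhdf5::h5closeAll()
})

test_that("a model with a tumour has n_fgt + 3 element datasets", {
  m <- small_model(K = 2, target = 0.45)
  tum <- generateTumour(10, c(2, 2, 2))
  sp <- voxelSpacing(m); d <- dim(labelMap(m))
  dm <- embedTumour(m, tum, c(16, d[2] * sp[2] / 2, d[3] * sp[3] / 2))
  f <- withr::local_tempfile(fileext = ".h5")
  writeHdf5Model(dm, f)
  ls <- rhdf5::h5ls(f)
  expect_identical(sum(ls$group == "/modelData"), 2L + 3L)
  rhdf5::h5closeAll()

  expect_error(readHdf5Model(withr::local_tempfile(fileext = ".h5")),
               "malformed model file")
})

test_that("XML property files follow the documented layout and precision", {
  m <- small_model(K = 3)
  f <- withr::local_tempfile(fileext = ".xml")
  writeXmlProperties(m, f)

  doc <- xml2::read_xml(f)
  expect_identical(xml2::xml_name(doc), "modelProps")
  expect_true("breastHealth" %in% names(xml2::xml_attrs(doc)))
  for (node in xml2::xml_children(doc))
    expect_identical(length(xml2::xml_children(node)), 4L)

  back <- readXmlProperties(f)
  expect_setequal(names(back), names(modelProperties(m)))
  for (role in names(back))
    expect_debye_equal(back[[role]], modelProperties(m)[[role]],
                       tol = 1e-10)

  # a missing Debye child is rejected
  node <- xml2::xml_find_first(doc, "//Skin_Layer/tau")
  xml2::xml_remove(node)
  f2 <- withr::local_tempfile(fileext = ".xml")
  xml2::write_xml(doc, f2)
  expect_error(readXmlProperties(f2), "incomplete property entry")
})

test_that("STL meshes are watertight with analytic volumes", {
  # 10 mm cube at 1 mm spacing -> exactly 1000 mm^3
  cube <- TissueLabelMap(array(0L, c(12, 12, 12)), c(background = 0),
                         c(1, 1, 1))
  arr <- labelArray(cube); arr[2:11, 2:11, 2:11] <- 1L
  cube <- TissueLabelMap(arr, c(background = 0, cube = 1), c(1, 1, 1))
  f <- withr::local_tempfile(fileext = ".stl")
  st <- writeStl(cube, "cube", f)
  expect_lt(abs(st$volume_mm3 - 1000) / 1000, 0.05)
  expect_identical(st$n_triangles, 6L * 100L * 2L)
  expect_equal(readStl(f)$volume_mm3, st$volume_mm3, tolerance = 1e-6)

  # single voxel: closed mesh with positive volume
  single <- TissueLabelMap(array(c(1L, rep(0L, 26)), c(3, 3, 3)),
                           c(vox = 1, background = 0), c(0.5, 0.5, 0.5))
  st1 <- writeStl(single, "vox", withr::local_tempfile(fileext = ".stl"))
  expect_identical(st1$n_triangles, 12L)
  expect_equal(st1$volume_mm3, 0.125, tolerance = 1e-9)

  # sphere at two spacings: volume within 3% of pi d^3 / 6 and equal to
  # voxel count x voxel volume (convergence to the voxel volume)
  v_analytic <- pi * 10^3 / 6
  for (h in c(0.5, 0.25)) {
    tum <- generateTumour(10, rep(h, 3))
    lmt <- TissueLabelMap(array(as.integer(maskArray(tum)),
                                dim(maskArray(tum))),
                          c(background = 0, tumour = 1), rep(h, 3))
    sts <- writeStl(lmt, "tumour", withr::local_tempfile(fileext = ".stl"))
    expect_equal(sts$volume_mm3, sum(maskArray(tum)) * h^3,
                 tolerance = 1e-9)
    expect_lt(abs(sts$volume_mm3 - v_analytic) / v_analytic, 0.03)
  }

  empty <- TissueLabelMap(array(0L, c(4, 4, 4)), c(background = 0, ghost = 9),
                          c(1, 1, 1))
  expect_error(writeStl(empty, "ghost", withr::local_tempfile()),
               "empty cluster")
})

test_that("writers are pure: two writes of one model are byte-identical", {
  m <- small_model(K = 2)
  f1 <- withr::local_tempfile(fileext = ".xml")
  f2 <- withr::local_tempfile(fileext = ".xml")
  writeXmlProperties(m, f1); writeXmlProperties(m, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  r1 <- withr::local_tempfile(fileext = ".raw")
  r2 <- withr::local_tempfile(fileext = ".raw")
  writeRaw(labelMap(m), r1); writeRaw(labelMap(m), r2)
  expect_identical(readBin(r1, "raw", file.size(r1)),
                   readBin(r2, "raw", file.size(r2)))
})

test_that("the generic voxel container preserves everything, including relabelled legends", {
  m <- small_model(K = 2)
  f <- withr::local_tempfile(fileext = ".h5")
  writeVoxelContainer(m, f)
  back <- readVoxelContainer(f)
  expect_identical(labelArray(back), labelArray(m))
  expect_identical(labelLegend(back), labelLegend(m))
  ab <- modelAttributes(back); am <- modelAttributes(m)
  expect_equal(ab[order(names(ab))], am[order(names(am))])
  expect_true("spacing" %in% rhdf5::h5ls(f)$name)
  rhdf5::h5closeAll()

  # permuted label codes survive the roundtrip (fgt codes stay contiguous)
  lm <- labelMap(m)
  lg <- labelLegend(lm)
  perm <- c(background = 7L, skin = 9L, fat = 8L, fgt_1 = 10L, fgt_2 = 11L)
  perm <- perm[names(lg)]
  relab <- labelArray(lm)
  for (role in names(lg)) relab[labelArray(lm) == lg[[role]]] <- perm[[role]]
  lm2 <- TissueLabelMap(relab, perm, voxelSpacing(lm))
  m2 <- new("BreastModel", labelmap = lm2,
            properties = modelProperties(m),
            attributes = modelAttributes(m))
  f2 <- withr::local_tempfile(fileext = ".h5")
  writeVoxelContainer(m2, f2)
  back2 <- readVoxelContainer(f2)
  expect_identical(labelLegend(back2), labelLegend(lm2))
  expect_identical(labelArray(back2), relab)
})
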