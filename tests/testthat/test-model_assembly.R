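test_that("end-to-end build yields a coherent fatty model", {
  gen <- small_phantom(target = 0.12, seed = 81)
  m <- buildModel(gen$volume, K = 1, skin_thickness_mm = 4,
                  model_name = "BM_Fatty_T01")
  a <- modelAttributes(m)
  expect_identical(a$breast_class, "fatty")
  expect_identical(a$breast_health, "healthy")
  expect_identical(a$n_fgt_clusters, 1L)
  lg <- labelLegend(m)
  expect_setequal(names(lg), c("background", "skin", "fat", "fgt_1"))
  # attributes recompute from the label map
  expect_equal(a$density_percent, computeDensity(labelMap(m)))
  expect_identical(a$breast_class, classifyBreast(a$density_percent))
})

test_that("K changes only the fibroglandular sub-clustering", {
  gen <- small_phantom(target = 0.4, seed = 82)
  m8 <- buildModel(gen$volume, K = 8, skin_thickness_mm = 4)
  m16 <- buildModel(gen$volume, K = 16, skin_thickness_mm = 4)
  lg8 <- labelLegend(m8); lg16 <- labelLegend(m16)
  expect_identical(sum(grepl("^fgt_", names(lg8))), 8L)
  expect_identical(sum(grepl("^fgt_", names(lg16))), 16L)
  # identical breast masks and identical fgt unions
  breast8 <- labelArray(m8) != 0L
  breast16 <- labelArray(m16) != 0L
  expect_identical(breast8, breast16)
  fgt8 <- labelArray(m8) %in% lg8[grepl("^fgt_", names(lg8))]
  fgt16 <- labelArray(m16) %in% lg16[grepl("^fgt_", names(lg16))]
  expect_identical(fgt8, fgt16)
})

test_that("med level rescales every fgt spectrum by 0.85, nothing else", {
  gen <- small_phantom(target = 0.4, seed = 83)
  mh <- buildModel(gen$volume, K = 3, skin_thickness_mm = 4,
                   level = propertyLevel("high"))
  mm <- buildModel(gen$volume, K = 3, skin_thickness_mm = 4,
                   level = propertyLevel("med"))
  expect_identical(labelArray(mh), labelArray(mm))
  freqs <- c(1e9, 3e9, 9e9)
  for (role in names(modelProperties(mh))) {
    r <- debyePermittivity(modelProperties(mm)[[role]], freqs) /
      debyePermittivity(modelProperties(mh)[[role]], freqs)
    want <- if (grepl("^fgt_", role)) 0.85 else 1
    expect_equal(Re(r), rep(want, 3), tolerance = 1e-12)
    expect_equal(Im(r), rep(0, 3), tolerance = 1e-12)
  }
})

test_that("pipeline is deterministic under a fixed seed", {
  gen <- small_phantom(target = 0.3, seed = 84)
  m1 <- buildModel(gen$volume, K = 4, skin_thickness_mm = 4, seed = 9)
  m2 <- buildModel(gen$volume, K = 4, skin_thickness_mm = 4, seed = 9)
  expect_identical(labelArray(m1), labelArray(m2))
  expect_equal(modelAttributes(m1), modelAttributes(m2))
})

test_that("tumour embedding adds one label and respects anatomy", {
  gen <- small_phantom(target = 0.4, seed = 85)
  m <- buildModel(gen$volume, K = 1, skin_thickness_mm = 4)
  tum <- generateTumour(10, c(2, 2, 2))
  sp <- voxelSpacing(m)
  d <- dim(labelMap(m))
  centre <- c(20, d[2] * sp[2] / 2, d[3] * sp[3] / 2)

  before <- labelArray(m)
  dm <- embedTumour(m, tum, centre)
  lg <- labelLegend(dm)
  expect_true("tumour" %in% names(lg))
  expect_identical(length(lg), length(labelLegend(m)) + 1L)
  expect_identical(modelAttributes(dm)$breast_health, "diseased")

  # voxel volume near the analytic sphere volume
  n_tum <- sum(labelArray(dm) == lg[["tumour"]])
  v_analytic <- pi * 10^3 / 6
  expect_lt(abs(n_tum * prod(sp) - sum(maskArray(tum)) * prod(sp)) /
              (sum(maskArray(tum)) * prod(sp)), 0.03)
  expect_lt(abs(n_tum * prod(sp) - v_analytic) / v_analytic, 0.25)

  # non-tumour voxels untouched; skin never replaced
  changed <- labelArray(dm) != before
  expect_true(all(labelArray(dm)[changed] == lg[["tumour"]]))
  expect_true(all(before[changed] %in%
                    c(lg[["fat"]], lg[grepl("^fgt_", names(lg))])))

  # relabelling the tumour voxels back restores the original model
  restored <- labelArray(dm)
  restored[changed] <- before[changed]
  expect_identical(restored, before)

  expect_error(embedTumour(m, tum, c(90, 4, 4)), "tumour outside breast")
})

test_that("model report has the four sections and consistent numbers", {
  gen <- small_phantom(target = 0.4, seed = 86)
  m <- buildModel(gen$volume, K = 8, skin_thickness_mm = 4)
  report <- generateModelReport(m, gen$volume)
  rl <- strsplit(report, "\n")[[1]]
  sections <- grep("^## ", rl, value = TRUE)
  expect_length(sections, 4L)
  expect_identical(sections,
                   c("## General Information", "## Model Elements",
                     "## Dielectric Properties", "## Visualization"))
  # 8 fgt clusters x 3 levels x 4 frequencies of property rows
  expect_length(grep("^\\| fgt_[0-9]+ \\| (high|med|low) \\|", rl),
                8L * 3L * 4L)
  dens <- sub(".*Breast density: ([0-9.]+)%.*", "\\1",
              grep("Breast density", rl, value = TRUE))
  expect_equal(as.numeric(dens), round(computeDensity(labelMap(m)), 1),
               tolerance = 0.051)

  # writing to disk also drops the slice image alongside
  dir <- withr::local_tempdir()
  path <- file.path(dir, "Model_Info.md")
  generateModelReport(m, gen$volume, path = path)
  expect_true(file.exists(path))
  expect_true(file.exists(file.path(dir, "Model_Info_central_slice.png")))
})
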