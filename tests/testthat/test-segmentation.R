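# brute-force spacing-aware distance from each mask voxel to the
# nearest exterior voxel centre
brute_force_shell <- function(mask, spacing, thickness) {
  d <- dim(mask)
  inside <- which(mask, arr.ind = TRUE)
  outside <- which(!mask, arr.ind = TRUE)
  out <- array(FALSE, d)
  if (nrow(outside) == 0) return(out)
  om <- sweep(outside, 2L, spacing, `*`)
  for (i in seq_len(nrow(inside))) {
    p <- inside[i, ] * spacing
    d2 <- (om[, 1] - p[1])^2 + (om[, 2] - p[2])^2 + (om[, 3] - p[3])^2
    if (sqrt(min(d2)) <= thickness)
      out[inside[i, 1], inside[i, 2], inside[i, 3]] <- TRUE
  }
  out
}

test_that("skin shell matches the brute-force distance transform", {
  # 20 mm cube on a 1 mm grid (embedded with background margin)
  m <- array(FALSE, c(26, 26, 26))
  m[4:23, 4:23, 4:23] <- TRUE
  bm <- new("BreastMask", mask = m, spacing = c(1, 1, 1), threshold = 0)
  got <- extractSkinLayer(bm, 1.5)
  expect_identical(got, brute_force_shell(m, c(1, 1, 1), 1.5))

  # anisotropic spacing
  m2 <- array(FALSE, c(14, 12, 10))
  m2[4:11, 4:9, 3:8] <- TRUE
  bm2 <- new("BreastMask", mask = m2, spacing = c(1, 2, 1.5), threshold = 0)
  got2 <- extractSkinLayer(bm2, 2.2)
  expect_identical(got2, brute_force_shell(m2, c(1, 2, 1.5), 2.2))
})

test_that("skin shell saturates and handles single voxels", {
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  bm <- new("BreastMask", mask = m, spacing = c(1, 1, 1), threshold = 0)
  expect_identical(extractSkinLayer(bm, 1.5), m)   # the voxel is skin

  m2 <- array(FALSE, c(8, 8, 8)); m2[3:6, 3:6, 3:6] <- TRUE
  bm2 <- new("BreastMask", mask = m2, spacing = c(1, 1, 1), threshold = 0)
  expect_identical(extractSkinLayer(bm2, 1e6), m2) # thickness -> Inf

  expect_warning(extractSkinLayer(bm2, 0.5), "below the smallest")
})

test_that("tissue segmentation recovers the generator labels", {
  gen <- small_phantom(target = 0.35, seed = 41)
  mask <- buildBreastMask(gen$volume)
  lm <- segmentTissues(gen$volume, mask, skin_thickness_mm = 4)
  truth <- labelMap(gen$truth)
  # compare fat/fgt on voxels both call interior
  tl <- labelArray(truth); gl <- labelArray(lm)
  both <- tl %in% c(2L, 3L) & gl %in% c(2L, 3L)
  agreement <- mean(tl[both] == gl[both])
  expect_gte(agreement, 0.95)
})

test_that("degenerate interiors fall back to a single fat class", {
  m <- array(FALSE, c(12, 12, 12)); m[3:10, 3:10, 3:10] <- TRUE
  vol <- MRIVolume(array(50, c(12, 12, 12)), c(1, 1, 1))
  bm <- new("BreastMask", mask = m, spacing = c(1, 1, 1), threshold = 10)
  expect_warning(lm <- segmentTissues(vol, bm, skin_thickness_mm = 1.5),
                 "degenerate")
  lg <- labelLegend(lm)
  expect_false(any(grepl("^fgt_", names(lg))))
  expect_gt(sum(labelArray(lm) == lg[["fat"]]), 0)
})

test_that("perfectly separated intensities are recovered exactly", {
  m <- array(FALSE, c(12, 12, 12)); m[3:10, 3:10, 3:10] <- TRUE
  arr <- array(0, c(12, 12, 12))
  arr[3:10, 3:10, 3:10] <- 50
  arr[5:8, 5:8, 5:8] <- 200
  vol <- MRIVolume(arr, c(1, 1, 1))
  bm <- new("BreastMask", mask = m, spacing = c(1, 1, 1), threshold = 10)
  lm <- segmentTissues(vol, bm, skin_thickness_mm = 1.5)
  lg <- labelLegend(lm)
  interior <- labelArray(lm) %in% c(lg[["fat"]], lg[["fgt_1"]])
  expect_true(all((labelArray(lm) == lg[["fgt_1"]])[interior] ==
                    (arr == 200)[interior]))
})

# exhaustive optimal 2-class 1-D split by within-class sum of squares
best_split_1d <- function(x) {
  xs <- sort(unique(x))
  sse <- function(v) if (length(v) <= 1) 0 else sum((v - mean(v))^2)
  costs <- vapply(xs[-length(xs)], function(cut)
    sse(x[x <= cut]) + sse(x[x > cut]), numeric(1))
  xs[which.min(costs)]
}

test_that("two-cluster fgt split matches the exhaustive 1-D optimum", {
  gen <- small_phantom(target = 0.4, seed = 51)
  mask <- buildBreastMask(gen$volume)
  lm <- segmentTissues(gen$volume, mask, skin_thickness_mm = 4)
  # make the fgt intensities bimodal by construction
  vol <- intensities(gen$volume)
  sel <- labelArray(lm) == labelLegend(lm)[["fgt_1"]]
  set.seed(8)
  vol[sel] <- sample(c(150, 250), sum(sel), replace = TRUE) +
    rnorm(sum(sel), 0, 5)
  vol[vol < 0] <- 0
  v2 <- MRIVolume(vol, voxelSpacing(gen$volume))
  two <- subclusterFgt(v2, lm, K = 2)
  lg <- labelLegend(two)
  boundary_lo <- max(vol[labelArray(two) == lg[["fgt_1"]]])
  boundary_hi <- min(vol[labelArray(two) == lg[["fgt_2"]]])
  opt <- best_split_1d(vol[sel])
  expect_true(opt >= boundary_lo - 1e-9 && opt <= boundary_hi + 1e-9)
})

test_that("sub-clustering contracts hold: identity, partition, ordering", {
  gen <- small_phantom(target = 0.4, seed = 52)
  mask <- buildBreastMask(gen$volume)
  lm <- segmentTissues(gen$volume, mask, skin_thickness_mm = 4)

  expect_identical(subclusterFgt(gen$volume, lm, K = 1), lm)

  k8 <- subclusterFgt(gen$volume, lm, K = 8, seed = 2)
  lg8 <- labelLegend(k8)
  fgt_codes <- lg8[grepl("^fgt_", names(lg8))]
  expect_length(fgt_codes, 8L)
  # union of sub-clusters equals the original fgt set
  expect_identical(which(labelArray(k8) %in% fgt_codes),
                   which(labelArray(lm) == labelLegend(lm)[["fgt_1"]]))
  # all clusters non-empty, means increase with the label index
  st <- clusterStatistics(gen$volume, k8)
  fgt_rows <- st[grepl("^fgt_", st$tissue), ]
  fgt_rows <- fgt_rows[order(fgt_rows$label), ]
  expect_true(all(fgt_rows$voxel_count > 0))
  expect_true(all(diff(fgt_rows$mean_intensity) > 0))

  # determinism under a fixed seed
  k8b <- subclusterFgt(gen$volume, lm, K = 8, seed = 2)
  expect_identical(labelArray(k8), labelArray(k8b))

  expect_error(subclusterFgt(gen$volume, lm, K = 1e6), "K too large")
})

test_that("cluster statistics match a naive accumulation oracle", {
  gen <- small_phantom(target = 0.3, seed = 61)
  mask <- buildBreastMask(gen$volume)
  lm <- segmentTissues(gen$volume, mask, skin_thickness_mm = 4)
  st <- clusterStatistics(gen$volume, lm)

  arr <- intensities(gen$volume)
  for (i in seq_len(nrow(st))) {
    sel <- labelArray(lm) == st$label[i]
    expect_identical(st$voxel_count[i], sum(sel))
    if (st$voxel_count[i] > 0)
      expect_equal(st$mean_intensity[i], mean(arr[sel]))
  }
  expect_identical(sum(st$voxel_count), length(arr))

  # legend entry absent from the grid: count 0, mean NA
  lg <- labelLegend(lm)
  lm2 <- TissueLabelMap(labelArray(lm), c(lg, ghost = max(lg) + 5L),
                        voxelSpacing(lm))
  st2 <- clusterStatistics(gen$volume, lm2)
  expect_identical(st2$voxel_count[st2$tissue == "ghost"], 0L)
  expect_true(is.na(st2$mean_intensity[st2$tissue == "ghost"]))
})
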