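# small phantom presets used across tests: same physical proportions as
# the default acquisition, coarser sampling so unit tests stay fast.
# skin thickness is raised to 2x the largest spacing so the geometric
# shell is at least one voxel thick everywhere.
small_params <- function(target = 0.30, seed = 1L,
                         grid = c(48L, 48L, 24L),
                         spacing = c(2, 2, 2), ...) {
  syntheticParams(grid = grid, spacing = spacing,
                  breast_semi_axes_mm = c(45, 36, 20),
                  skin_thickness_mm = 2 * max(spacing),
                  target_fgt_fraction = target, seed = seed, ...)
}

small_phantom <- function(target = 0.30, seed = 1L, ...) {
  generateBreastVolume(small_params(target = target, seed = seed, ...))
}

# mask built directly from generator truth (any non-background label)
truth_breast_mask <- function(truth) {
  lm <- labelMap(truth)
  labelArray(lm) != labelLegend(lm)[["background"]]
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

expect_debye_equal <- function(a, b, tol = 1e-12) {
  expect_equal(debyeVector(a), debyeVector(b), tolerance = tol)
}
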