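# independently coded evaluation in real/imaginary parts
oracle_debye <- function(eps_inf, delta_eps, tau, sigma, f) {
  eps0 <- 8.8541878128e-12
  w <- 2 * pi * f
  re <- eps_inf + delta_eps / (1 + (w * tau)^2)
  im <- delta_eps * w * tau / (1 + (w * tau)^2) + sigma / (w * eps0)
  complex(real = re, imaginary = -im)
}

test_that("Debye evaluation matches the independent oracle and limits", {
  set.seed(1)
  for (i in 1:20) {
    ei <- runif(1, 1, 30); de <- runif(1, 0, 40)
    tau <- runif(1, 5e-12, 30e-12); sg <- runif(1, 0, 2)
    p <- debyeParameters(ei, de, tau, sg)
    for (f in c(5e8, 3e9, 1e10)) {
      got <- debyePermittivity(p, f)
      want <- oracle_debye(ei, de, tau, sg, f)
      expect_lt(Mod(got - want) / Mod(want), 1e-12)
    }
  }

  # analytic limits: sigma = 0, omega*tau >> 1 -> eps_inf
  p <- debyeParameters(5, 20, 1e-12, 0)
  hi <- debyePermittivity(p, 1e18)
  expect_equal(Re(hi), 5, tolerance = 1e-6)
  # omega = 1/tau -> real part eps_inf + delta/2
  mid <- debyePermittivity(p, 1 / (2 * pi * 1e-12))
  expect_equal(Re(mid), 5 + 10, tolerance = 1e-12)

  expect_error(debyePermittivity(p, 0), "invalid frequency")
  expect_error(debyePermittivity(p, -1), "invalid frequency")
})

test_that("intensity-to-weight mapping is linear with clamping", {
  expect_equal(mapIntensityToWeight(120, c(120, 260)), 0)
  expect_equal(mapIntensityToWeight(260, c(120, 260)), 1)
  expect_equal(mapIntensityToWeight(190, c(120, 260)), 0.5)
  expect_equal(mapIntensityToWeight(-50, c(120, 260)), 0)
  expect_equal(mapIntensityToWeight(999, c(120, 260)), 1)
  expect_error(mapIntensityToWeight(1, c(5, 5)))
})

test_that("curve combination interpolates between the endpoint spectra", {
  tab <- defaultPropertyTable()
  lo <- tab@entries$fgt_lower
  hi <- tab@entries$fgt_upper
  expect_debye_equal(combinePropertyCurves(0, lo, hi), lo)
  expect_debye_equal(combinePropertyCurves(1, lo, hi), hi)

  midp <- combinePropertyCurves(0.5, lo, hi)
  freqs <- seq(5e8, 1e10, length.out = 25)
  re_lo <- Re(debyePermittivity(lo, freqs))
  re_hi <- Re(debyePermittivity(hi, freqs))
  re_mid <- Re(debyePermittivity(midp, freqs))
  expect_true(all(re_mid >= pmin(re_lo, re_hi) - 1e-12))
  expect_true(all(re_mid <= pmax(re_lo, re_hi) + 1e-12))

  # monotone in w when upper >= lower componentwise
  ws <- seq(0, 1, by = 0.1)
  eps_s <- vapply(ws, function(w) {
    p <- combinePropertyCurves(w, lo, hi)
    p@eps_inf + p@delta_eps
  }, numeric(1))
  expect_true(all(diff(eps_s) >= 0))
})

test_that("property levels scale the whole complex spectrum exactly", {
  p <- debyeParameters(16, 25, 13e-12, 0.7)
  freqs <- seq(5e8, 1e10, length.out = 40)
  base <- debyePermittivity(p, freqs)
  for (lev in c("med", "low")) {
    s <- c(med = 0.85, low = 0.75)[[lev]]
    scaled <- applyPropertyLevel(p, propertyLevel(lev))
    got <- debyePermittivity(scaled, freqs)
    expect_equal(Re(got), s * Re(base), tolerance = 1e-12)
    expect_equal(Im(got), s * Im(base), tolerance = 1e-12)
    expect_equal(scaled@tau_s, p@tau_s)
  }
  expect_debye_equal(applyPropertyLevel(p, propertyLevel("high")), p)
  expect_warning(applyPropertyLevel(debyeParameters(1.1, 1, 1e-12, 0),
                                    propertyLevel("low")), "unphysical")
})

test_that("default table parameters are physical over 0.5-10 GHz", {
  tab <- defaultPropertyTable()
  freqs <- seq(5e8, 1e10, length.out = 50)
  for (role in names(tab@entries)) {
    eps <- debyePermittivity(tab@entries[[role]], freqs)
    expect_true(all(Re(eps) >= 1), info = role)
    expect_true(all(-Im(eps) >= 0), info = role)
  }
})

test_that("property table round-trips through its YAML config", {
  tab <- defaultPropertyTable()
  f <- withr::local_tempfile(fileext = ".yaml")
  writePropertyTable(tab, f)
  tab2 <- readPropertyTable(f)
  for (role in names(tab@entries))
    expect_debye_equal(tab2@entries[[role]], tab@entries[[role]], tol = 1e-10)
  expect_equal(tab2@ranges, tab@ranges)
})

make_stats <- function(means) {
  data.frame(tissue = names(means), label = seq_along(means),
             voxel_count = 10L, mean_intensity = unname(means),
             stringsAsFactors = FALSE)
}

test_that("property assignment maps cluster means monotonically", {
  tab <- defaultPropertyTable()
  labels <- array(0L, c(4, 4, 4))
  labels[1, 1, 1] <- 1L; labels[2, 1, 1] <- 2L
  labels[3, 1, 1] <- 3L; labels[4, 1, 1] <- 4L
  lm <- TissueLabelMap(labels, c(background = 0, skin = 1, fat = 2,
                                 fgt_1 = 3, fgt_2 = 4), c(1, 1, 1))
  st <- make_stats(c(skin = 120, fat = 60, fgt_1 = 150, fgt_2 = 240))
  m <- assignProperties(lm, st, tab, propertyLevel("high"))
  pr <- modelProperties(m)
  expect_debye_equal(pr$skin, tab@entries$skin)
  expect_debye_equal(pr$fat, tab@entries$fat)
  # higher mean intensity -> higher static permittivity
  eps_s <- function(p) p@eps_inf + p@delta_eps
  expect_gt(eps_s(pr$fgt_2), eps_s(pr$fgt_1))

  # clamping: all means below the range lower bound share the lower curve
  st_lo <- make_stats(c(skin = 120, fat = 60, fgt_1 = 10, fgt_2 = 20))
  m_lo <- assignProperties(lm, st_lo, tab, propertyLevel("high"))
  expect_debye_equal(modelProperties(m_lo)$fgt_1, tab@entries$fgt_lower)
  expect_debye_equal(modelProperties(m_lo)$fgt_2, tab@entries$fgt_lower)

  # med vs high: every fgt spectrum scaled by 0.85, skin/fat untouched
  m_med <- assignProperties(lm, st, tab, propertyLevel("med"))
  freqs <- c(1e9, 3e9, 6e9)
  for (role in c("fgt_1", "fgt_2")) {
    r <- debyePermittivity(modelProperties(m_med)[[role]], freqs) /
      debyePermittivity(modelProperties(m)[[role]], freqs)
    expect_equal(Re(r), rep(0.85, 3), tolerance = 1e-12)
    expect_equal(Im(r), rep(0, 3), tolerance = 1e-12)
  }
  expect_debye_equal(modelProperties(m_med)$skin, tab@entries$skin)

  # incomplete table (bypass the class validity to exercise the check)
  tab2 <- tab
  slot(tab2, "entries", check = FALSE) <-
    tab@entries[setdiff(names(tab@entries), "skin")]
  expect_error(assignProperties(lm, st, tab2, propertyLevel("high")),
               "incomplete property table")
})
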