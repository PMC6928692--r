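# Peak metrology: background subtraction, centroid of the top half, FWHM,
# spacing changes.

gaussOn <- function(Z, c0, fwhm, height = 1) {
  s <- fwhm / (2 * sqrt(2 * log(2)))
  height * exp(-(Z - c0)^2 / (2 * s^2))
}

test_that("linear background subtraction is exact for flat and sloped baselines", {
  Z <- seq(0.35, 0.38, length.out = 2001)
  peak <- gaussOn(Z, 0.365, 1.5e-3, height = 100)
  for (base in list(rep(7, length(Z)), 3 + 40 * Z)) {
    p <- meridionalProfile(Z, peak + base)
    ps <- subtractBackground(p, range(Z))
    expect_equal(max(ps@intensity), 100, tolerance = 1e-3)
    expect_equal(ps@intensity, peak, tolerance = 1e-6 * 100)
  }
})

test_that("polynomial background recovers a curved baseline", {
  Z <- seq(0.35, 0.38, length.out = 2001)
  peak <- gaussOn(Z, 0.365, 1.2e-3, height = 50)
  base <- 5 + 200 * (Z - 0.36)^2
  p <- meridionalProfile(Z, peak + base)
  ps <- subtractBackground(p, range(Z), method = "polynomial_k", degree = 2)
  expect_equal(max(ps@intensity), 50, tolerance = 0.01)
})

test_that("pure-noise windows leave a near-zero residual", {
  set.seed(21)
  Z <- seq(0.35, 0.38, length.out = 1501)
  resid <- replicate(20, {
    p <- meridionalProfile(Z, pmax(10 + rnorm(length(Z), 0, 0.5), 0))
    mean(subtractBackground(p, range(Z), clip = FALSE)@intensity)
  })
  se <- sd(resid) / sqrt(length(resid))
  expect_lt(abs(mean(resid)), 3 * se + 0.02)
})

test_that("windows that cut into the peak are rejected", {
  Z <- seq(0.35, 0.38, length.out = 2001)
  p <- meridionalProfile(Z, gaussOn(Z, 0.365, 4e-3))
  expect_error(subtractBackground(p, c(0.3642, 0.3658)), "peak core")
})

test_that("centroid of the top half is exact for symmetric peaks", {
  Z <- seq(0.36, 0.373, length.out = 4001)
  tri <- pmax(0, 1 - abs(Z - 0.36630) / 2e-3)    # symmetric triangle
  m <- peakTopHalfCentroid(meridionalProfile(Z, tri), range(Z), 1)
  expect_equal(m@zCenter, 0.36630, tolerance = 1e-9)
  # invariant to intensity scaling
  m2 <- peakTopHalfCentroid(meridionalProfile(Z, 137 * tri), range(Z), 1)
  expect_equal(m2@zCenter, m@zCenter, tolerance = 1e-12)
  expect_error(peakTopHalfCentroid(meridionalProfile(Z, rep(0, length(Z))),
                                   range(Z)), "no peak")
})

test_that("metrology error on noiseless uniform helices is far below 0.05%", {
  for (ord in 1:2) {
    p <- meridionalIntensity(uniformFilament(364, 2.73), orderGrid(ord))
    m <- peakTopHalfCentroid(p, peakOrderWindow(ord), ord)
    truth <- 2.73 / ord
    expect_lt(abs(m@spacing - truth) / truth, 5e-4)
    expect_lt(abs(m@spacing - truth) / truth, 5e-6)  # actual performance
  }
})

test_that("order-2 spacing of the relaxed filament is 1.365 nm", {
  p <- meridionalIntensity(uniformFilament(364, 2.73), orderGrid(2))
  m <- peakTopHalfCentroid(p, peakOrderWindow(2), 2)
  expect_equal(m@spacing, 1.365, tolerance = 1e-4 / 1.365)
})

test_that("an imposed 0.325% strain moves the order-1 spacing as printed", {
  base <- 2.73037
  p0 <- meridionalIntensity(uniformFilament(364, base), orderGrid(1, base))
  p1 <- meridionalIntensity(uniformFilament(364, base * 1.00325),
                            orderGrid(1, base))
  m0 <- peakTopHalfCentroid(p0, peakOrderWindow(1, base), 1)
  m1 <- peakTopHalfCentroid(p1, peakOrderWindow(1, base), 1)
  expect_lt(abs(m0@spacing - 2.73037), 5e-4)
  expect_lt(abs(m1@spacing - 2.73924), 5e-4)
})

test_that("spacing changes reproduce the reported strains", {
  mk <- function(s) new("PeakMetrics", order = 1L, zCenter = 1 / s,
                        spacing = s, fwhmZ = 1e-3, height = 1,
                        window = c(0.3, 0.4))
  d2 <- deltaSpacing(mk(2.73037), mk(2.73924))
  expect_equal(d2$delH, 0.00887, tolerance = 1e-5 / 0.00887)
  expect_equal(d2$strainPercent, 0.325, tolerance = 1e-3)
  d5 <- deltaSpacing(mk(2.73171), mk(2.74124))
  expect_equal(d5$delH, 0.00953, tolerance = 1e-5 / 0.00953)
  expect_equal(d5$strainPercent, 0.349, tolerance = 1e-3)
  dz <- deltaSpacing(mk(2.73), mk(2.73))
  expect_equal(dz$delH, 0)
  expect_equal(dz$strainPercent, 0)
  m2 <- new("PeakMetrics", order = 2L, zCenter = 2 / 2.73, spacing = 1.365,
            fwhmZ = 1e-3, height = 1, window = c(0.7, 0.8))
  expect_error(deltaSpacing(mk(2.73), m2), "order")
})
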