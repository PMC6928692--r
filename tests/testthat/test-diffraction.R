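# Meridional diffraction: lattice sums, closed-form agreement, dilation and
# order-sensitivity laws, beam convolution.

test_that("uniform filament reproduces the finite-lattice closed form", {
  z <- uniformFilament(364, 2.73)
  for (ord in 1:2) {
    Z <- orderGrid(ord)
    p <- meridionalIntensity(z, Z)
    expect_equal(p@intensity, dirichletIntensity(364, 2.73, Z),
                 tolerance = 1e-8)
  }
  # on-reflection intensity is N^2 for point scatterers
  pk <- meridionalIntensity(z, c(1 / 2.73, 2 / 2.73))
  expect_equal(pk@intensity, c(364^2, 364^2), tolerance = 1e-6)
})

test_that("profiles are invariant under rigid translation", {
  Z <- orderGrid(1)
  a <- meridionalIntensity(uniformFilament(200, 2.73), Z)
  b <- meridionalIntensity(uniformFilament(200, 2.73) + 5, Z)
  expect_equal(a@intensity, b@intensity, tolerance = 1e-9)
})

test_that("ensemble intensity is the exact incoherent sum over filaments", {
  set.seed(3)
  Z <- orderGrid(2, halfwidth = 0.01)
  fils <- lapply(1:4, function(i) (0:199) * 2.73 + cumsum(rnorm(200, 0, 0.02)))
  pAll <- meridionalIntensity(fils, Z)
  pSum <- Reduce(`+`, lapply(fils, function(f)
    meridionalIntensity(f, Z)@intensity))
  expect_equal(pAll@intensity, pSum, tolerance = 1e-12)
  expect_error(meridionalIntensity(list(), Z), "at least one")
  expect_error(meridionalIntensity(as.numeric(1:5), c(0.3, 0.2)),
               "increasing")
})

test_that("reflection windows sit at the printed actin spacings", {
  w1 <- peakOrderWindow(1)
  expect_equal(attr(w1, "center"), 0.36630, tolerance = 1e-4)
  expect_equal(attr(peakOrderWindow(2), "center"), 0.73260, tolerance = 1e-4)
  expect_equal(1 / attr(peakOrderWindow(2), "center"), 1.365,
               tolerance = 1e-4)
  expect_equal(1 / attr(peakOrderWindow(3), "center"), 0.91,
               tolerance = 1e-3)
  expect_error(peakOrderWindow(0), "order")
})

test_that("uniform dilation shifts the order-n reflection by the strain", {
  for (eps in c(0.001, 0.00325, 0.005)) {
    h <- 2.73 * (1 + eps)
    p <- meridionalIntensity(uniformFilament(364, h), orderGrid(1))
    m <- peakTopHalfCentroid(p, peakOrderWindow(1), 1)
    recovered <- m@spacing / 2.73 - 1
    expect_lt(abs(recovered - eps), 1e-4)
  }
})

test_that("random segmentwise jitter broadens higher orders more, relatively", {
  relWidth <- function(ord, fils) {
    p <- meridionalIntensity(fils, orderGrid(ord))
    m <- peakTopHalfCentroid(p, peakOrderWindow(ord), ord)
    m@fwhmZ / m@zCenter
  }
  for (seed in 1:3) {
    set.seed(seed)
    fils <- lapply(1:40, function(i)
      c(0, cumsum(2.73 + rnorm(363, 0, 0.08))))
    expect_gt(relWidth(2, fils), relWidth(1, fils))
  }
})

test_that("beam convolution conserves intensity and widens peaks", {
  # delta-like peak: a narrow Gaussian on a fine grid
  Z <- seq(0.36, 0.373, length.out = 6001)
  dZ <- Z[2] - Z[1]
  g <- function(s) exp(-(Z - 0.3665)^2 / (2 * s^2))
  pin <- meridionalProfile(Z, g(1e-5))
  beam <- beamModel(4e-4)
  pout <- convolveBeam(pin, beam)
  expect_equal(sum(pout@intensity), sum(pin@intensity), tolerance = 1e-9)
  m <- peakTopHalfCentroid(pout, range(Z), 1)
  expect_equal(m@fwhmZ, beam@fwhm, tolerance = 0.02)
  # two Gaussians: FWHM adds in quadrature within 1%
  a <- 6e-4
  pa <- meridionalProfile(Z, g(a / (2 * sqrt(2 * log(2)))))
  pc <- convolveBeam(pa, beam)
  mc <- peakTopHalfCentroid(pc, range(Z), 1)
  expect_equal(mc@fwhmZ, sqrt(a^2 + beam@fwhm^2), tolerance = 0.01)
  # peak is lower and wider
  expect_lt(max(pc@intensity), max(pa@intensity))
  # coarse grids are rejected
  expect_error(convolveBeam(meridionalProfile(seq(0.3, 0.4, 5e-4),
                                              rep(1, 201)),
                            beamModel(1e-3)), "too coarse")
  expect_error(beamModel(-1), "fwhm")
})

test_that("the sphere form factor damps intensity away from the origin", {
  z <- uniformFilament(364, 2.73)
  p1 <- meridionalIntensity(z, orderGrid(1), subunitDiameter = 5.5)
  p2 <- meridionalIntensity(z, orderGrid(2), subunitDiameter = 5.5)
  q1 <- meridionalIntensity(z, orderGrid(1))
  q2 <- meridionalIntensity(z, orderGrid(2))
  # relative attenuation is stronger at the second order
  expect_lt(max(p2@intensity) / max(q2@intensity),
            max(p1@intensity) / max(q1@intensity))
})
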