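# Synthetic fixtures: uniform and stepwise-strained filaments, seeded
# pseudo-experiments, truth serialization.

test_that("uniform filaments are plain arithmetic sequences", {
  z <- uniformFilament(364, 2.73)
  expect_equal(tail(z, 1), 363 * 2.73, tolerance = 1e-12)  # 991.0 nm
  expect_equal(uniformFilament(2, 1), c(0, 1))
  expect_equal(unique(round(diff(z), 12)), 2.73)
  expect_error(uniformFilament(1, 2.73), "n >= 2")
  expect_error(uniformFilament(10, 0), "spacing")
})

test_that("stepwise loads stretch exactly the segments below them", {
  # a single 312.8 pN load at 0-based monomer 182 (1-based 183)
  z <- stepwiseStrainedFilament(364, 2.73,
                                data.frame(index = 183L, force = 312.8))
  sp <- diff(z)
  expect_equal(sp[1:182], rep(2.73 * (1 + 312.8 / 65000), 182),
               tolerance = 1e-12)
  expect_equal(sp[1], 2.74314, tolerance = 1e-5 / 2.74314)
  expect_equal(sp[183:363], rep(2.73, 181), tolerance = 1e-12)
  # no loads degenerates to the uniform filament
  expect_equal(stepwiseStrainedFilament(50, 2.73, data.frame(
    index = integer(), force = numeric())), uniformFilament(50, 2.73))
  # total elongation balances the load integral
  lp <- data.frame(index = c(100L, 250L), force = c(120, 80))
  z2 <- stepwiseStrainedFilament(364, 2.73, lp, Ka = 65000)
  elong <- sum(diff(z2) - 2.73)
  expect_equal(elong, 2.73 / 65000 * (200 * 99 + 80 * 150),
               tolerance = 1e-9)
  expect_error(stepwiseStrainedFilament(364, 2.73,
                                        data.frame(index = 999L, force = 1)),
               "out of range")
})

test_that("synthetic experiments are reproducible and respect their truth", {
  a <- syntheticExperiment(250, 30, nFilaments = 25, seed = 5)
  b <- syntheticExperiment(250, 30, nFilaments = 25, seed = 5)
  expect_identical(a$contracted@intensity, b$contracted@intensity)
  expect_identical(a$truth@forces, b$truth@forces)
  expect_true(all(a$truth@forces >= 0))
  # zero force: contracted profile equals the relaxed one
  z <- syntheticExperiment(0, 0, nFilaments = 10, noiseRelSd = 0, seed = 2)
  expect_equal(z$relaxed@intensity, z$contracted@intensity,
               tolerance = 1e-12)
  expect_error(syntheticExperiment(100, -1), "sdForce")
})

test_that("force heterogeneity broadens the second order", {
  fw2 <- vapply(c(0, 80), function(sdF) {
    xp <- syntheticExperiment(300, sdF, nFilaments = 60, noiseRelSd = 0,
                              seed = 9)
    m <- peakTopHalfCentroid(xp$contracted, peakOrderWindow(2), 2)
    m@fwhmZ
  }, numeric(1))
  expect_gt(fw2[2], fw2[1])
})

test_that("truth sidecars round-trip through JSON at double precision", {
  xp <- syntheticExperiment(280, 25, nFilaments = 6, seed = 13)
  f <- tempfile(fileext = ".json")
  writeTruth(xp$truth, f)
  back <- readTruth(f)
  expect_equal(back@forces, xp$truth@forces, tolerance = 1e-14)
  expect_equal(back@positions, xp$truth@positions, tolerance = 1e-14)
  expect_equal(back@loads, xp$truth@loads, tolerance = 1e-14)
  expect_identical(back@seed, xp$truth@seed)
  unlink(f)
})
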