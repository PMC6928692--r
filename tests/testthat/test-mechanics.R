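# Spring-network equilibrium: closed-form case, dense-solver agreement,
# force balance, linearity, profiles.

test_that("relaxed lattice stays relaxed under the solver", {
  lat <- solveEquilibrium(tinyLattice())
  expect_equal(as.vector(apply(lat@actinZ, 2, diff)),
               rep(2.73, 363 * 4), tolerance = 1e-12)
  expect_equal(nrow(crossbridgeStrains(lat)), 0L)
})

test_that("single post-stroke crossbridge matches the 3-spring hand solution", {
  ts <- threeSpringLattice()
  lat <- attachHead(ts$lattice, ts$head, monomer = 201L, state = 3L)
  lat <- solveEquilibrium(lat)
  xs <- crossbridgeStrains(lat)
  # series compliance: crossbridge + 500 nm of actin + 200 nm of myosin
  fExp <- 10.5 / (1 / 1.3 + 500 / 65000 + 200 / 132000)  # 13.49 pN
  expect_equal(xs$force, fExp, tolerance = 1e-6)
  # tension profile: constant from the Z-disc up to the attachment, 0 beyond
  prof <- filamentTensionProfile(lat, xs$thin)
  expect_equal(prof$tension[1:199], rep(fExp, 199), tolerance = 1e-6)
  expect_equal(prof$tension[210], 0, tolerance = 1e-8)
  # spacing follows s = s0 (1 + F/Ka) segment-wise
  expect_equal(prof$spacing, 2.5 * (1 + prof$tension / 65000),
               tolerance = 1e-9)
})

test_that("stiffer filaments transmit more of the stroke", {
  ts <- threeSpringLattice()
  f <- vapply(c(1, 2), function(sc) {
    lat <- buildHalfSarcomere(threeSpringGeometry(),
                              elasticParams(Ka = sc * 0.65e5,
                                            Km = sc * 1.32e5), nThick = 1)
    lat <- attachHead(lat, ts$head, monomer = 201L, state = 3L)
    crossbridgeStrains(solveEquilibrium(lat))$force
  }, numeric(1))
  expect_gt(f[2], f[1])
})

test_that("sparse solver agrees with a dense brute-force solve", {
  for (seed in 1:3) {
    set.seed(seed)
    lat <- tinyLattice()
    # up to 5 random attachments on reachable heads
    heads <- sample(seq_along(lat@headThin))
    n <- 0L
    for (h in heads) {
      if (n == 5L) break
      cs <- candidateSites(h, lat, reach = 6)
      cs <- cs[!cs$occupied, ]
      if (!nrow(cs)) next
      pick <- cs[sample(nrow(cs), 1), ]
      ok <- tryCatch({
        lat <- attachHead(lat, h, pick$monomer, sample(2:3, 1))
        TRUE
      }, error = function(e) FALSE)
      if (ok) n <- n + 1L
    }
    expect_gte(n, 3L)
    solved <- solveEquilibrium(lat, tol = 1e-7)
    oracle <- denseEquilibriumOracle(lat)
    expect_equal(solved@actinZ, oracle@actinZ, tolerance = 1e-10)
    expect_equal(solved@myosinZ, oracle@myosinZ, tolerance = 1e-10)
  }
})

test_that("global force balance holds on plateau snapshots", {
  lat <- tinyLattice()
  tr <- runIsometric(lat, rateParams(), duration = 0.03, seed = 5,
                     snapshotDt = 0, tol = 1e-8)
  final <- tr@lattice
  xs <- crossbridgeStrains(final, checkTol = 1e-6)
  nrec <- length(tr@times)
  zdisc <- sum(tr@thinForce[nrec, ])
  mband <- sum(tr@thickForce[nrec, ])
  expect_equal(zdisc, sum(xs$force), tolerance = 1e-6)
  expect_equal(mband, sum(xs$force), tolerance = 1e-6)
  # per-filament: sum of crossbridge forces = that filament's Z-disc reaction
  for (t in unique(xs$thin))
    expect_equal(sum(xs$force[xs$thin == t]), tr@thinForce[nrec, t],
                 tolerance = 1e-6)
})

test_that("displacements scale linearly with the stroke offset", {
  ts <- threeSpringLattice()
  lat <- attachHead(ts$lattice, ts$head, monomer = 201L, state = 3L)
  u <- function(d) {
    s <- solveEquilibrium(lat, strokeD = d, tol = 1e-7)
    c(s@actinZ - lat@actinZ, s@myosinZ - lat@myosinZ)
  }
  expect_equal(u(8), 2 * u(4), tolerance = 1e-7)
})

test_that("unsolved lattices are rejected by strain extraction", {
  ts <- threeSpringLattice()
  lat <- attachHead(ts$lattice, ts$head, monomer = 201L, state = 3L)
  expect_error(crossbridgeStrains(lat), "equilibrium")
  expect_error(filamentTensionProfile(solveEquilibrium(lat), 99),
               "invalid thin filament")
})

test_that("ensemble spacing statistics: degenerate and plateau behaviour", {
  lat <- solveEquilibrium(tinyLattice())
  st <- ensembleSpacingStats(lat)
  expect_equal(st$sdSpacing, rep(0, 363))
  expect_equal(st$meanSpacing, rep(2.73, 363))
  # plateau run: ensemble mean spacing non-increasing from Z-disc to tip
  tr <- runIsometric(buildHalfSarcomere(nThick = 4), rateParams(),
                     duration = 0.12, seed = 2, snapshotDt = 0.02,
                     snapshotStart = 0.06, logEvents = FALSE)
  st2 <- ensembleSpacingStats(tr)
  bins <- cut(st2$position, 8)
  m <- tapply(st2$meanSpacing, bins, mean)
  expect_true(all(diff(m) <= 1e-5))
  # I-band spacing exceeds tip spacing clearly
  expect_gt(m[1], m[8] + 1e-3)
  expect_error(ensembleSpacingStats(
    runIsometric(lat, rateParams(kBind = 0), duration = 0.001,
                 snapshotDt = 0)), "no snapshots")
})
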