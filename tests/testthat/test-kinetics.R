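# Strain-dependent three-state rates and the Monte Carlo engine.

test_that("state free energies match the closed forms", {
  p <- rateParams()
  expect_equal(stateFreeEnergy(1, 3.2, p), 0)
  expect_equal(stateFreeEnergy(2, 0, p), -3)
  expect_equal(stateFreeEnergy(2, 2, p), -3 + 1.3 * 4 / (2 * 3.96),
               tolerance = 1e-12)  # -2.3434
  expect_equal(stateFreeEnergy(3, -10.5, p), -18)  # strain after stroke zero
})

test_that("zero-strain rates reproduce the binding equilibrium constant ~20", {
  r <- transitionRates(0)
  expect_equal(r$k12, 134)
  expect_equal(r$k21, 134 / exp(3), tolerance = 1e-12)  # 6.672 1/s
  expect_equal(r$k12 / r$k21, exp(3), tolerance = 1e-12)
  expect_equal(r$k13, 0)
})

test_that("detailed balance holds for every strain, capped regions included", {
  p <- rateParams()
  x <- seq(-8, 8, by = 0.25)
  r <- transitionRates(x, p)
  G2 <- stateFreeEnergy(2, x, p)
  G3 <- stateFreeEnergy(3, x, p)
  expect_equal(r$k12 / r$k21, exp(-G2), tolerance = 1e-12)
  expect_equal(r$k23 / r$k32, exp(-(G3 - G2)), tolerance = 1e-12)
  # the k32 cap must actually engage somewhere on this grid
  expect_true(any(abs(r$k32 - p@capK32) < 1e-9))
})

test_that("rate caps bound the rates on a dense strain grid", {
  x <- seq(-15, 15, length.out = 4001)
  r <- transitionRates(x)
  expect_true(all(r$k23 <= 1000 + 1e-9))
  expect_true(all(r$k32 <= 100 + 1e-9))
  expect_true(all(r$k31 <= 1e4 + 1e-9))
  expect_true(all(as.matrix(r) >= 0))
  expect_true(all(is.finite(as.matrix(r))))
  expect_error(transitionRates(NaN), "finite")
})

test_that("too-large time steps are rejected with the violated product", {
  lat <- tinyLattice()
  expect_error(runIsometric(lat, rateParams(dt = 1e-4), duration = 1e-3),
               "capK31.*dt")
})

test_that("per-step binding probability follows 1 - exp(-k dt)", {
  lat <- tinyLattice()
  rp <- rateParams()
  n <- 1000L
  # expected bind count over n steps from the fully detached lattice:
  # heads are independent under rigid filaments, each with constant total
  # binding rate over its free candidate sites
  pHead <- vapply(seq_along(lat@headThin), function(h) {
    cs <- candidateSites(h, lat, reach = rp@bindingReach)
    -expm1(-sum(transitionRates(cs$x, rp)$k12) * rp@dt)
  }, numeric(1))
  q <- 1 - (1 - pHead)^n          # P(head bound at least once)
  # rebinding after an early unbind is negligible at these rates; count
  # heads that ever bound
  res <- mcUpdate(lat, rp, nSteps = n, seed = 42, rigid = TRUE)
  binds <- length(unique(res$events$head[res$events$from == 1]))
  mu <- sum(q); se <- sqrt(sum(q * (1 - q)))
  expect_lt(abs(binds - mu), 3.5 * se + 3)
})

test_that("identical seeds give identical event logs", {
  lat <- tinyLattice()
  a <- mcUpdate(lat, rateParams(), nSteps = 20000L, seed = 9)
  b <- mcUpdate(lat, rateParams(), nSteps = 20000L, seed = 9)
  expect_identical(a$events, b$events)
  expect_identical(a$lattice@actinZ, b$lattice@actinZ)
  c <- mcUpdate(lat, rateParams(), nSteps = 20000L, seed = 10)
  expect_false(identical(a$events, c$events))
})

test_that("zero binding rate leaves the lattice relaxed with zero force", {
  lat <- tinyLattice()
  r0 <- rateParams(kBind = 0)
  tr <- runIsometric(lat, r0, duration = 0.02, seed = 1, snapshotDt = 0)
  expect_equal(nrow(tr@events), 0L)
  expect_true(all(tr@thinForce == 0))
  expect_equal(boundFraction(tr, window = 0.01)$fraction, 0)
})

test_that("single-head occupancy matches the analytic stationary cycle", {
  # isolate one head on its own thin filament (crowns of different thick
  # filaments are axially in register, so facing heads would otherwise
  # compete for the same monomer) and keep the reach short enough that it
  # sees a single site: the three-state chain at fixed strain is then exact
  lat <- buildHalfSarcomere(nThick = 1)
  rp <- rateParams(bindingReach = 1.2)
  h <- which(vapply(seq_along(lat@headThin), function(hh)
    nrow(candidateSites(hh, lat, 1.2)) == 1L, logical(1)))[1]
  t0 <- lat@headThin[h]
  lat@headThin[] <- if (t0 == 1L) 2L else 1L
  lat@headThin[h] <- t0
  x <- candidateSites(h, lat, 1.2)$x
  piA <- analyticStationary3(x, rp)
  occ <- vapply(1:3, function(seed) {
    res <- mcUpdate(lat, rp, nSteps = 500000L, seed = seed, rigid = TRUE)
    ev <- res$events[res$events$head == h, ]
    # time-weighted occupancy of the head's state sequence
    steps <- c(0, ev$step, 500000L)
    states <- c(1L, ev$to)
    w <- diff(steps)
    vapply(1:3, function(s) sum(w[states == s]) / 500000, numeric(1))
  }, numeric(3))
  m <- rowMeans(occ)
  se <- apply(occ, 1, sd) / sqrt(3)
  for (s in 1:3)
    expect_lt(abs(m[s] - piA[s]), 3 * se[s] + 0.02)
})

test_that("plateau force orders monotonically with the binding rate", {
  lat <- buildHalfSarcomere(nThick = 4)
  f <- vapply(c(30, 70, 134), function(kb) {
    r <- rateParams(kBind = kb)
    mean(vapply(1:2, function(s) {
      tr <- runIsometric(lat, r, duration = 0.12, seed = s, snapshotDt = 0,
                         logEvents = FALSE)
      sarcoXray:::plateauMeanForce(tr, window = 0.05)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(f) > 0))
})

test_that("bound fraction arithmetic and bounds", {
  lat <- tinyLattice()
  tr <- runIsometric(lat, rateParams(kBind = 0), duration = 0.01, seed = 1,
                     snapshotDt = 0)
  expect_equal(boundFraction(tr, 0.005)$fraction, 0)
  # synthetic trace with a constant 108/150 bound heads (~72.5% as printed)
  tr2 <- tr
  tr2@nState2 <- matrix(60L, nrow(tr@nState2), ncol(tr@nState2))
  tr2@nState3 <- matrix(48L, nrow(tr@nState3), ncol(tr@nState3))
  bf <- boundFraction(tr2, 0.005)
  expect_equal(bf$fraction, 108 / 150)
  expect_equal(bf$fraction, 0.725, tolerance = 0.01)
  expect_true(all(bf$perFilament >= 0 & bf$perFilament <= 1))
  expect_error(boundFraction(tr, window = 5), "exceeds")
})
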