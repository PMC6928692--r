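# Half-sarcomere geometry: filament chains, overlap interval, head wiring
# and candidate binding sites.

test_that("default geometry reproduces the printed half-sarcomere constants", {
  geo <- sarcomereGeometry()
  expect_equal(geo@nCrowns * geo@headsPerCrown, 150L)
  expect_equal(geo@nMonomers * geo@monomerSpacing, 993.72, tolerance = 1e-6)
  # monomer count x relaxed spacing reproduces the thin length within 1%
  expect_lt(abs(geo@nMonomers * geo@monomerSpacing - 1000 * geo@thinLength) /
              (1000 * geo@thinLength), 0.01)
  # crown span is the maximum possible overlap, ~0.70 um
  expect_equal((geo@nCrowns - 1L) * geo@crownSpacing, 700.7, tolerance = 1e-6)
  lat <- buildHalfSarcomere(geo, elasticParams(), nThick = 2)
  expect_equal(length(lat@headThin), 2L * 150L)
  expect_equal(ncol(lat@actinZ), 4L)  # 2:1 thin:thick
})

test_that("elastic defaults give 65 pN/nm per micrometre of actin filament", {
  e <- elasticParams()
  expect_equal(e@Ka / 1000, 65)   # pN/nm for a 1000 nm filament
  expect_error(elasticParams(Ka = -1), "positive")
})

test_that("overlap interval follows from direct geometric construction", {
  ob <- overlapBounds(sarcomereGeometry())
  # crown region [360, 1060.7] nm clipped to the thin filament [0, 993.72]
  expect_equal(ob$zLo, 360, tolerance = 1e-6)
  expect_equal(ob$zHi, 993.72, tolerance = 1e-6)
  expect_equal(ob$overlapLength, 633.72, tolerance = 1e-6)
  expect_equal(ob$nonOverlapLength + ob$overlapLength, 993.72,
               tolerance = 1e-6)
})

test_that("shrinking sarcomere length grows the overlap up to the crown span", {
  sls <- seq(2.9, 2.0, by = -0.05)
  ov <- vapply(sls, function(sl)
    overlapBounds(sarcomereGeometry(sarcomereLength = sl))$overlapLength,
    numeric(1))
  expect_true(all(diff(ov) >= -1e-9))
  expect_lte(max(ov), 700.7 + 1e-9)
  expect_equal(max(ov), 700.7, tolerance = 1e-6)
})

test_that("degenerate lattices are rejected", {
  expect_error(buildHalfSarcomere(nThick = 0), "empty lattice")
  # sarcomere so long that crowns never face the thin filament
  expect_error(overlapBounds(sarcomereGeometry(sarcomereLength = 4.2)),
               "no thick-thin filament overlap")
  expect_error(buildHalfSarcomere(sarcomereGeometry(sarcomereLength = 1.5)),
               "Z-disc|M-band")
})

test_that("lattice construction is deterministic and wiring is balanced", {
  a <- buildHalfSarcomere(nThick = 3, seed = 7)
  b <- buildHalfSarcomere(nThick = 3, seed = 7)
  expect_identical(a@actinZ, b@actinZ)
  expect_identical(a@headThin, b@headThin)
  # every thin filament faces exactly 75 heads (25 from each of 3 thicks)
  expect_true(all(table(a@headThin) == 75L))
})

test_that("candidate sites obey reach, occupancy and frame consistency", {
  lat <- tinyLattice()
  # a head in the overlap with reach s0/2 sees exactly one site
  s0 <- lat@geometry@monomerSpacing
  h <- which(vapply(seq_along(lat@headThin), function(hh) {
    info <- sarcoXray:::headInfo(hh, lat@geometry)
    lat@myosinZ[info$crown, info$thick] < 900
  }, logical(1)))[1]
  cs <- candidateSites(h, lat, reach = s0 / 2)
  expect_equal(nrow(cs), 1L)
  expect_lte(abs(cs$x), s0 / 2)
  # a head whose crown lies beyond the thin filament tip sees nothing
  hb <- which(vapply(seq_along(lat@headThin), function(hh) {
    info <- sarcoXray:::headInfo(hh, lat@geometry)
    lat@myosinZ[info$crown, info$thick] > 993.72 + 8
  }, logical(1)))[1]
  expect_equal(nrow(candidateSites(hb, lat, reach = 8)), 0L)
  # rigid +1 nm shift of the thin filament shifts all offsets by -1 nm
  cs8 <- candidateSites(h, lat, reach = 8)
  lat2 <- lat
  lat2@actinZ[, cs8$thin[1]] <- lat2@actinZ[, cs8$thin[1]] + 1
  cs8b <- candidateSites(h, lat2, reach = 8)
  shared <- intersect(cs8$monomer, cs8b$monomer)
  expect_equal(cs8b$x[match(shared, cs8b$monomer)],
               cs8$x[match(shared, cs8$monomer)] - 1)
})

test_that("attachments are validated against the lattice", {
  lat <- tinyLattice()
  expect_error(attachHead(lat, head = 10^6, monomer = 1), "out of range")
  lat2 <- attachHead(lat, head = 1, monomer = 300, state = 2L)
  expect_error(attachHead(lat2, head = 1, monomer = 301), "already attached")
  # head 7 (crown 3, same azimuthal direction) targets the same thin filament
  expect_identical(lat@headThin[7], lat@headThin[1])
  expect_error(attachHead(lat2, head = 7, monomer = 300), "occupied")
  expect_error(attachHead(lat, head = 2, monomer = 300, state = 5L),
               "state")
})
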