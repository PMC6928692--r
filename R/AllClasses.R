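#' @useDynLib sarcoXray, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom methods new validObject is slotNames slot
#' @importFrom stats rnorm sd
#' @importFrom graphics hist
#' @importFrom utils head tail read.table write.table packageVersion
NULL

# ---------------------------------------------------------------------------
# Parameter containers
# ---------------------------------------------------------------------------

#' Sarcomere lattice geometry
#'
#' Printed geometric constants of the vertebrate half sarcomere used to build
#' the explicit filament lattice: sarcomere length, thin/thick filament
#' lengths, monomer and crown spacings, filament counts and the hexagonal
#' lattice spacing d10. Lengths of whole filaments are in micrometres, local
#' spacings in nanometres.
#'
#' @slot sarcomereLength sarcomere length, um (default 2.3)
#' @slot thinLength thin (actin) filament length, um (1.0)
#' @slot nMonomers actin monomers per thin filament (364)
#' @slot monomerSpacing relaxed inter-monomer spacing s0, nm (2.73)
#' @slot strandHalfPeriod half period of one actin strand, nm (35.5)
#' @slot thickLength thick (myosin) filament length, um (1.58)
#' @slot nCrowns myosin crowns per half-thick filament (50)
#' @slot crownSpacing axial crown spacing, nm (14.3)
#' @slot headsPerCrown myosin heads per crown (3)
#' @slot d10Sim lattice spacing d10 at simulation sarcomere length, nm (36.5)
#' @slot d10Slack lattice spacing d10 at slack length, nm (37)
#' @slot myofibrilOccupancy fraction of muscle cross-section occupied by
#'   myofibrils (0.8)
#' @slot nThick number of thick filaments in the simulated lattice
#' @slot nThin number of thin filaments (always 2 x nThick)
#' @export
setClass("SarcomereGeometry", representation(
  sarcomereLength = "numeric", thinLength = "numeric", nMonomers = "integer",
  monomerSpacing = "numeric", strandHalfPeriod = "numeric",
  thickLength = "numeric", nCrowns = "integer", crownSpacing = "numeric",
  headsPerCrown = "integer", d10Sim = "numeric", d10Slack = "numeric",
  myofibrilOccupancy = "numeric", nThick = "integer", nThin = "integer"
))

setValidity("SarcomereGeometry", function(object) {
  msg <- character()
  pos <- c(sarcomereLength = object@sarcomereLength,
           thinLength = object@thinLength, nMonomers = object@nMonomers,
           monomerSpacing = object@monomerSpacing,
           thickLength = object@thickLength, nCrowns = object@nCrowns,
           crownSpacing = object@crownSpacing,
           headsPerCrown = object@headsPerCrown, d10Sim = object@d10Sim,
           d10Slack = object@d10Slack, nThick = object@nThick)
  if (any(pos <= 0)) {
    msg <- c(msg, paste("nonpositive geometry parameter(s):",
                        paste(names(pos)[pos <= 0], collapse = ", ")))
  }
  if (object@myofibrilOccupancy <= 0 || object@myofibrilOccupancy > 1)
    msg <- c(msg, "myofibrilOccupancy must be in (0, 1]")
  if (object@nThin != 2L * object@nThick)
    msg <- c(msg, "nThin must equal 2 * nThick (vertebrate lattice stoichiometry)")
  # monomer count times relaxed spacing must reproduce the thin length (1%)
  lthin <- object@nMonomers * object@monomerSpacing
  if (abs(lthin - 1000 * object@thinLength) / (1000 * object@thinLength) > 0.01)
    msg <- c(msg, "nMonomers * monomerSpacing must match thinLength within 1%")
  if (length(msg)) msg else TRUE
})

#' @param sarcomereLength,thinLength,nMonomers,monomerSpacing,strandHalfPeriod,thickLength,nCrowns,crownSpacing,headsPerCrown,d10Sim,d10Slack,myofibrilOccupancy,nThick
#'   see the corresponding slots of \linkS4class{SarcomereGeometry}.
#' @return `sarcomereGeometry()` returns a validated
#'   \linkS4class{SarcomereGeometry} object.
#' @rdname SarcomereGeometry-class
#' @examples
#' geo <- sarcomereGeometry()
#' geo@nCrowns * geo@headsPerCrown   # 150 heads per half-thick filament
#' @export
sarcomereGeometry <- function(sarcomereLength = 2.3, thinLength = 1.0,
                              nMonomers = 364L, monomerSpacing = 2.73,
                              strandHalfPeriod = 35.5, thickLength = 1.58,
                              nCrowns = 50L, crownSpacing = 14.3,
                              headsPerCrown = 3L, d10Sim = 36.5,
                              d10Slack = 37, myofibrilOccupancy = 0.8,
                              nThick = 500L) {
  new("SarcomereGeometry", sarcomereLength = sarcomereLength,
      thinLength = thinLength, nMonomers = as.integer(nMonomers),
      monomerSpacing = monomerSpacing, strandHalfPeriod = strandHalfPeriod,
      thickLength = thickLength, nCrowns = as.integer(nCrowns),
      crownSpacing = crownSpacing, headsPerCrown = as.integer(headsPerCrown),
      d10Sim = d10Sim, d10Slack = d10Slack,
      myofibrilOccupancy = myofibrilOccupancy, nThick = as.integer(nThick),
      nThin = 2L * as.integer(nThick))
}

#' Filament and crossbridge elasticity
#'
#' Filament moduli are stiffness times length products (pN): the stiffness of
#' a segment of length L nm is modulus / L pN/nm. The default actin modulus
#' 0.65e5 pN corresponds to 65 pN/nm for a 1 um filament.
#'
#' @slot Ka actin filament modulus, pN (0.65e5)
#' @slot Km myosin filament modulus, pN (1.32e5)
#' @slot kappaXb crossbridge spring stiffness, pN/nm (1.3)
#' @slot titinStiffness optional linear titin spring per half-thick filament,
#'   pN/nm, anchored between the thick filament tip and the Z-disc (default 0)
#' @export
setClass("ElasticParams", representation(
  Ka = "numeric", Km = "numeric", kappaXb = "numeric",
  titinStiffness = "numeric"))

setValidity("ElasticParams", function(object) {
  if (object@Ka <= 0 || object@Km <= 0 || object@kappaXb <= 0)
    return("filament moduli and crossbridge stiffness must be strictly positive")
  if (object@titinStiffness < 0) return("titinStiffness must be >= 0")
  TRUE
})

#' @param Ka,Km,kappaXb,titinStiffness see slots.
#' @return `elasticParams()` returns an \linkS4class{ElasticParams} object.
#' @rdname ElasticParams-class
#' @export
elasticParams <- function(Ka = 0.65e5, Km = 1.32e5, kappaXb = 1.3,
                          titinStiffness = 0) {
  new("ElasticParams", Ka = Ka, Km = Km, kappaXb = kappaXb,
      titinStiffness = titinStiffness)
}

#' Three-state crossbridge rate parameters
#'
#' Parameters of the strain-dependent three-state crossbridge cycle
#' (detached, weakly attached / pre-power stroke, post-power stroke).
#' Energies are in kBT units, rates in 1/s, lengths in nm. `exp(-dGbind)` is
#' the zero-strain binding equilibrium constant (about 20 at the default -3).
#'
#' @slot dGbind binding free energy drop, kBT (-3)
#' @slot dGstroke power-stroke free energy drop, kBT (-15)
#' @slot kBind zero-strain binding rate, 1/s (134; titratable)
#' @slot kAdp0 unstrained ADP-release/detachment rate, 1/s (70)
#' @slot strokeD power stroke distance d, nm (10.5)
#' @slot delta2 second power stroke distance delta, nm (1)
#' @slot k13 reverse binding rate from detached to post-stroke, 1/s (0)
#' @slot capK23,capK32,capK31 rate caps, 1/s (1000, 100, 1e4)
#' @slot kBT thermal energy, pN nm (3.96, i.e. 14 C)
#' @slot dt Monte Carlo time step, s (1e-6)
#' @slot bindingReach candidate-site search half width, nm (8)
#' @export
setClass("RateParams", representation(
  dGbind = "numeric", dGstroke = "numeric", kBind = "numeric",
  kAdp0 = "numeric", strokeD = "numeric", delta2 = "numeric",
  k13 = "numeric", capK23 = "numeric", capK32 = "numeric",
  capK31 = "numeric", kBT = "numeric", dt = "numeric",
  bindingReach = "numeric"))

setValidity("RateParams", function(object) {
  msg <- character()
  if (object@kBind < 0 || object@kAdp0 < 0 || object@k13 < 0)
    msg <- c(msg, "rates must be >= 0")
  if (object@kBT <= 0) msg <- c(msg, "kBT must be > 0")
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  if (object@bindingReach <= 0) msg <- c(msg, "bindingReach must be > 0")
  # caps must not truncate the zero-strain forward rates
  if (object@capK31 < object@kAdp0)
    msg <- c(msg, "capK31 below the zero-strain detachment rate")
  if (length(msg)) msg else TRUE
})

#' @param dGbind,dGstroke,kBind,kAdp0,strokeD,delta2,k13,capK23,capK32,capK31,kBT,dt,bindingReach
#'   see slots.
#' @return `rateParams()` returns a \linkS4class{RateParams} object.
#' @rdname RateParams-class
#' @export
rateParams <- function(dGbind = -3, dGstroke = -15, kBind = 134, kAdp0 = 70,
                       strokeD = 10.5, delta2 = 1, k13 = 0, capK23 = 1000,
                       capK32 = 100, capK31 = 1e4, kBT = 3.96, dt = 1e-6,
                       bindingReach = 8) {
  new("RateParams", dGbind = dGbind, dGstroke = dGstroke, kBind = kBind,
      kAdp0 = kAdp0, strokeD = strokeD, delta2 = delta2, k13 = k13,
      capK23 = capK23, capK32 = capK32, capK31 = capK31, kBT = kBT, dt = dt,
      bindingReach = bindingReach)
}

# ---------------------------------------------------------------------------
# Lattice state
# ---------------------------------------------------------------------------

#' Explicit half-sarcomere lattice state
#'
#' Axial positions of every actin monomer node and myosin crown node in the
#' half sarcomere, the head-to-thin-filament wiring, and the current set of
#' attached crossbridges. The frame has z = 0 at the Z-disc, increasing
#' toward the M-band; each thin filament occupies [0, nMonomers * s0] nm at
#' rest and each thick filament hangs from a fixed anchor at the M-band.
#'
#' Attachments are rows of a data.frame with columns `head` (1-based global
#' head index), `thin`, `monomer` and `state` (2 = weakly attached /
#' pre-stroke, 3 = post-stroke).
#'
#' @slot geometry a \linkS4class{SarcomereGeometry}
#' @slot elastic an \linkS4class{ElasticParams}
#' @slot actinZ numeric matrix, nMonomers x nThin, monomer axial positions nm
#' @slot myosinZ numeric matrix, nCrowns x nThick, crown axial positions nm
#'   (row 1 is the crown nearest the M-band)
#' @slot anchorZ M-band anchor position of the thick filaments, nm
#' @slot bareLength bare-zone length between the anchor and the first crown, nm
#' @slot headThin integer vector, length nThick*nCrowns*headsPerCrown, target
#'   thin filament of each head (azimuthal wiring)
#' @slot attachments data.frame of current crossbridge attachments
#' @slot seed integer seed recorded at construction
#' @export
setClass("HalfSarcomereLattice", representation(
  geometry = "SarcomereGeometry", elastic = "ElasticParams",
  actinZ = "matrix", myosinZ = "matrix", anchorZ = "numeric",
  bareLength = "numeric", headThin = "integer", attachments = "data.frame",
  seed = "integer"))

setValidity("HalfSarcomereLattice", function(object) {
  msg <- character()
  if (any(apply(object@actinZ, 2, function(z) any(diff(z) <= 0))))
    msg <- c(msg, "actin node positions must be strictly increasing (segment inversion)")
  if (any(apply(object@myosinZ, 2, function(z) any(diff(z) >= 0))))
    msg <- c(msg, "myosin crown positions must strictly decrease from the M-band")
  att <- object@attachments
  if (nrow(att)) {
    H <- length(object@headThin)
    if (any(att$head < 1 | att$head > H))
      msg <- c(msg, "attachment references a non-existent head")
    if (any(att$monomer < 1 | att$monomer > nrow(object@actinZ)))
      msg <- c(msg, "attachment references a non-existent monomer site")
    if (!all(att$state %in% c(2L, 3L)))
      msg <- c(msg, "attachment state must be 2 or 3")
    if (anyDuplicated(att$head)) msg <- c(msg, "head attached more than once")
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Simulation trace
# ---------------------------------------------------------------------------

#' Time series output of an isometric Monte Carlo run
#'
#' @slot times recorded times, s
#' @slot thinForce matrix (times x nThin) of Z-disc reaction forces, pN
#' @slot thickForce matrix (times x nThick) of M-band reaction forces, pN
#' @slot nState2,nState3 integer matrices (times x nThick) of bound-head
#'   counts per half-thick filament
#' @slot xbForceSum total axial crossbridge force at each record, pN
#' @slot xbCount number of attached heads at each record
#' @slot snapshotTimes,snapshots monomer-position snapshots (list of
#'   nMonomers x nThin matrices)
#' @slot events event log: data.frame(step, head, from, to, thin, monomer)
#' @slot lattice final \linkS4class{HalfSarcomereLattice}
#' @slot rates the \linkS4class{RateParams} used
#' @slot seed RNG seed
#' @slot duration simulated time, s
#' @export
setClass("SimulationTrace", representation(
  times = "numeric", thinForce = "matrix", thickForce = "matrix",
  nState2 = "matrix", nState3 = "matrix", xbForceSum = "numeric",
  xbCount = "numeric", snapshotTimes = "numeric", snapshots = "list",
  events = "data.frame", lattice = "HalfSarcomereLattice",
  rates = "RateParams", seed = "integer", duration = "numeric"))

# ---------------------------------------------------------------------------
# Diffraction containers
# ---------------------------------------------------------------------------

#' Meridional intensity profile
#'
#' Intensity versus reciprocal axial coordinate Z (1/nm) on the meridian
#' (R = 0) of a fiber diffraction pattern. Intensities are in arbitrary
#' units; `metadata` carries provenance (filament count, beam convolution,
#' normalization).
#'
#' @slot Z reciprocal axial coordinate grid, 1/nm, strictly increasing
#' @slot intensity nonnegative intensities, arbitrary units
#' @slot metadata named list
#' @export
setClass("MeridionalProfile", representation(
  Z = "numeric", intensity = "numeric", metadata = "list"))

setValidity("MeridionalProfile", function(object) {
  msg <- character()
  if (length(object@Z) != length(object@intensity))
    msg <- c(msg, "Z and intensity lengths differ")
  if (length(object@Z) > 1 && any(diff(object@Z) <= 0))
    msg <- c(msg, "Z grid must be strictly increasing")
  # diffraction intensities are nonnegative (enforced by the constructor);
  # background-subtracted residuals with clip = FALSE may dip below zero
  if (any(!is.finite(object@intensity)))
    msg <- c(msg, "intensity must be finite")
  if (length(msg)) msg else TRUE
})

#' @param Z,intensity,metadata see slots.
#' @return a \linkS4class{MeridionalProfile}
#' @rdname MeridionalProfile-class
#' @export
meridionalProfile <- function(Z, intensity, metadata = list()) {
  new("MeridionalProfile", Z = as.numeric(Z),
      intensity = pmax(as.numeric(intensity), 0), metadata = metadata)
}

#' Axial beam profile model
#'
#' Gaussian axial profile of the X-ray beam, used to smear predicted
#' meridional profiles before comparing them with observed ones. The width
#' is given as FWHM in reciprocal nm.
#'
#' @slot shape currently only "gaussian"
#' @slot fwhm full width at half maximum, 1/nm
#' @export
setClass("BeamModel", representation(shape = "character", fwhm = "numeric"))

setValidity("BeamModel", function(object) {
  if (!identical(object@shape, "gaussian")) return("shape must be 'gaussian'")
  if (object@fwhm <= 0) return("beam fwhm must be > 0")
  TRUE
})

#' @param fwhm beam FWHM in 1/nm.
#' @param shape profile shape; only "gaussian".
#' @return a \linkS4class{BeamModel}
#' @rdname BeamModel-class
#' @export
beamModel <- function(fwhm, shape = "gaussian") {
  new("BeamModel", shape = shape, fwhm = fwhm)
}

#' Meridional peak metrics
#'
#' Peak position (centroid of the top half), spacing n/Z, FWHM and height of
#' one meridional reflection.
#'
#' @slot order reflection order n
#' @slot zCenter peak position, 1/nm
#' @slot spacing reflection d-spacing 1 / zCenter, nm (the monomer repeat
#'   inferred from order n is n * spacing)
#' @slot fwhmZ full width at half maximum, 1/nm
#' @slot height peak height above background, a.u.
#' @slot window the (Zlo, Zhi) search window used
#' @export
setClass("PeakMetrics", representation(
  order = "integer", zCenter = "numeric", spacing = "numeric",
  fwhmZ = "numeric", height = "numeric", window = "numeric"))

setValidity("PeakMetrics", function(object) {
  msg <- character()
  if (object@spacing <= 0) msg <- c(msg, "spacing must be > 0")
  if (object@fwhmZ <= 0) msg <- c(msg, "fwhmZ must be > 0")
  if (object@zCenter < object@window[1] || object@zCenter > object@window[2])
    msg <- c(msg, "zCenter outside the search window")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Pipeline results
# ---------------------------------------------------------------------------

#' Estimated per-filament force and tension
#'
#' Result of the five-step estimation from relaxed/contracted meridional
#' profiles: mean and SD of the per-thin-filament force in the I-band,
#' a histogram of the distribution, the derived muscle tension, the matched
#' binding rate (when titration was run) and the mean-to-plateau strain
#' ratio g used in step (ii).
#'
#' @slot meanForce mean I-band force per thin filament, pN
#' @slot sdForce SD across filaments, pN
#' @slot histBreaks,histCounts force histogram (pN bins)
#' @slot tension muscle tension, kPa
#' @slot kbindMatched titrated binding rate, 1/s (NA when not titrated)
#' @slot g mean-to-plateau strain ratio used
#' @slot details named list of intermediate quantities
#' @export
setClass("ForceEstimate", representation(
  meanForce = "numeric", sdForce = "numeric", histBreaks = "numeric",
  histCounts = "numeric", tension = "numeric", kbindMatched = "numeric",
  g = "numeric", details = "list"))

setValidity("ForceEstimate", function(object) {
  if (!is.na(object@sdForce) && object@sdForce < 0)
    return("sdForce must be >= 0")
  TRUE
})

#' Ground truth of a synthetic diffraction experiment
#'
#' @slot forces imposed per-filament I-band forces, pN
#' @slot loads list of per-filament load tables (monomer index, force pN)
#' @slot positions list of per-filament monomer position vectors, nm
#' @slot beamFwhm beam FWHM used, 1/nm
#' @slot noiseRelSd relative SD of the multiplicative intensity noise
#' @slot seed RNG seed
#' @export
setClass("SyntheticTruth", representation(
  forces = "numeric", loads = "list", positions = "list",
  beamFwhm = "numeric", noiseRelSd = "numeric", seed = "integer"))

# ---------------------------------------------------------------------------
# show methods
# ---------------------------------------------------------------------------

setMethod("show", "SarcomereGeometry", function(object) {
  cat("SarcomereGeometry: SL", object@sarcomereLength, "um,",
      object@nMonomers, "monomers x", object@monomerSpacing, "nm,",
      object@nCrowns, "crowns x", object@crownSpacing, "nm,",
      object@nThick, "thick /", object@nThin, "thin filaments\n")
})

setMethod("show", "HalfSarcomereLattice", function(object) {
  cat("HalfSarcomereLattice:", ncol(object@myosinZ), "thick +",
      ncol(object@actinZ), "thin filaments,",
      length(object@headThin), "heads,",
      nrow(object@attachments), "attached\n")
})

setMethod("show", "SimulationTrace", function(object) {
  cat("SimulationTrace:", format(object@duration), "s,",
      length(object@times), "records,", nrow(object@events), "events, seed",
      object@seed, "\n")
})

setMethod("show", "MeridionalProfile", function(object) {
  cat("MeridionalProfile:", length(object@Z), "points, Z in [",
      format(min(object@Z), digits = 5), ",",
      format(max(object@Z), digits = 5), "] 1/nm\n")
})

setMethod("show", "PeakMetrics", function(object) {
  cat(sprintf("PeakMetrics: order %d, Z = %.6f 1/nm, spacing = %.5f nm, FWHM = %.3g 1/nm\n",
              object@order, object@zCenter, object@spacing, object@fwhmZ))
})

setMethod("show", "ForceEstimate", function(object) {
  cat(sprintf("ForceEstimate: mean %.1f pN (SD %.1f), tension %.1f kPa, g = %.3f\n",
              object@meanForce, object@sdForce, object@tension, object@g))
})
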