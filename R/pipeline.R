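# Force estimation pipeline: meridional profiles -> mean spacing -> plateau
# strain -> mean per-filament force -> binding-rate titration -> force
# distribution and muscle tension.

#' Filaments per unit muscle cross-section
#'
#' Hexagonal lattice: the cross-sectional area per thick filament is
#' `(2/sqrt(3)) d10^2`; thin filaments are twice as numerous. The d10 at
#' slack sarcomere length is used because that is where muscle
#' cross-sectional areas are measured.
#'
#' @param d10Slack lattice spacing at slack length, nm (default 37)
#' @param occupancy fraction of the cross-section occupied by myofibrils
#'   (default 0.8)
#' @return list with `thickPerUm2` and `actinPerUm2` (counts per um^2)
#' @examples
#' filamentDensity()   # ~506 thick, ~1012 actin per um^2
#' @export
filamentDensity <- function(d10Slack = 37, occupancy = 0.8) {
  if (d10Slack <= 0) stop("d10 must be > 0")
  if (occupancy <= 0 || occupancy > 1) stop("occupancy must be in (0, 1]")
  cell <- (2 / sqrt(3)) * d10Slack^2        # nm^2 per thick filament
  thick <- occupancy * 1e6 / cell
  list(thickPerUm2 = thick, actinPerUm2 = 2 * thick)
}

#' Muscle tension from the mean actin filament force
#'
#' `tension[kPa] = F[pN] * actin filaments per um^2 * 1e-3`
#' (pN/um^2 = 1e-3 kPa). With the default lattice, 297 pN per thin filament
#' corresponds to ~300 kPa.
#'
#' @param F mean force per thin filament, pN
#' @param density result of [filamentDensity()]
#' @return tension in kPa
#' @examples
#' tensionFromActinForce(297)    # ~300 kPa
#' @export
tensionFromActinForce <- function(F, density = filamentDensity()) {
  if (any(F < 0)) stop("force must be >= 0")
  F * density$actinPerUm2 * 1e-3
}

#' Plateau strain from the mean filament strain
#'
#' The first-order reflection reports the mean monomer strain over the whole
#' filament; the I-band (plateau) strain near the Z-disc is larger because
#' tension decays across the overlap region. The mean-to-plateau ratio g is
#' taken from a simulated ensemble spacing profile when one is supplied
#' (self-consistent route); otherwise a geometric fallback assumes linear
#' tension decay across the overlap: `g = (L_I + L_ov/2) / L_thin`.
#'
#' @param meanStrain mean filament strain (fraction, not percent)
#' @param spacingProfile optional data.frame from [ensembleSpacingStats()]
#' @param geometry a \linkS4class{SarcomereGeometry} (for the fallback and
#'   the I-band definition)
#' @return list with `plateauStrain` (fraction) and the ratio `g` used
#' @export
plateauStrainFromMean <- function(meanStrain, spacingProfile = NULL,
                                  geometry = sarcomereGeometry()) {
  ob <- overlapBounds(geometry)   # errors on zero overlap
  if (!is.null(spacingProfile)) {
    g <- gRatioFromProfile(spacingProfile, geometry)
    if (is.na(g)) stop("spacing profile has no positive plateau; cannot form g")
  } else {
    lThin <- geometry@nMonomers * geometry@monomerSpacing
    g <- (ob$nonOverlapLength + ob$overlapLength / 2) / lThin
  }
  list(plateauStrain = meanStrain / g, g = g)
}

#' Mean filament force from the plateau strain
#'
#' Linear filament elasticity: `F = Ka * strain`.
#'
#' @param strain plateau strain (fraction)
#' @param Ka actin filament modulus, pN
#' @return force, pN
#' @export
forceFromPlateauStrain <- function(strain, Ka = 0.65e5) {
  if (any(strain < 0)) stop("strain must be >= 0")
  Ka * strain
}

# plateau-averaged mean per-thin-filament Z-disc force of a trace
plateauMeanForce <- function(trace, window = 0.1) {
  tt <- trace@times
  sel <- tt >= max(tt) - window
  mean(trace@thinForce[sel, , drop = FALSE])
}

#' Titrate the binding rate to a target mean filament force
#'
#' Monotone bisection of `kBind` (on a log scale) against the seed-averaged
#' plateau mean force per thin filament, until the relative error is below
#' `tol`. This is the activation-matching step of the estimation procedure:
#' activation level is represented entirely by the effective binding rate.
#'
#' @param targetMeanForce target plateau force per thin filament, pN
#' @param lattice a \linkS4class{HalfSarcomereLattice}
#' @param rates a \linkS4class{RateParams}; `kBind` is the titrated slot
#' @param duration simulated time per trial, s
#' @param seeds integer vector of seeds averaged per trial (>= 1)
#' @param tol relative force tolerance (default 0.03)
#' @param bracket initial kBind bracket, 1/s
#' @param maxIter bisection iterations
#' @param window plateau averaging window, s
#' @return list with `kbind`, the achieved `force`, and `traces` (the
#'   matched ensemble, one trace per seed)
#' @export
titrateKbind <- function(targetMeanForce, lattice, rates = rateParams(),
                         duration = 0.3, seeds = 1:3, tol = 0.03,
                         bracket = c(5, 2000), maxIter = 12,
                         window = min(0.1, duration / 3)) {
  if (targetMeanForce < 0) stop("target force must be >= 0")
  evalAt <- function(kb) {
    r <- rates; r@kBind <- kb
    traces <- lapply(seeds, function(s)
      runIsometric(lattice, r, duration, seed = s, snapshotDt = duration / 10,
                   snapshotStart = duration - window, logEvents = FALSE))
    list(force = mean(vapply(traces, plateauMeanForce, numeric(1),
                             window = window)), traces = traces)
  }
  if (targetMeanForce == 0)
    return(list(kbind = 0, force = 0, traces = list()))
  lo <- bracket[1]; hi <- bracket[2]
  flo <- evalAt(lo); fhi <- evalAt(hi)
  if (targetMeanForce < flo$force || targetMeanForce > fhi$force)
    stop(sprintf(
      "target %.1f pN outside the achievable bracket [%.1f, %.1f] pN",
      targetMeanForce, flo$force, fhi$force))
  best <- if (abs(flo$force - targetMeanForce) <
              abs(fhi$force - targetMeanForce))
    c(list(kbind = lo), flo) else c(list(kbind = hi), fhi)
  for (i in seq_len(maxIter)) {
    if (abs(best$force - targetMeanForce) / targetMeanForce <= tol) break
    mid <- sqrt(lo * hi)
    fm <- evalAt(mid)
    if (abs(fm$force - targetMeanForce) < abs(best$force - targetMeanForce))
      best <- c(list(kbind = mid), fm)
    if (fm$force < targetMeanForce) lo <- mid else hi <- mid
  }
  best
}

#' Per-filament force statistics of a plateau ensemble
#'
#' Distribution of the instantaneous Z-disc (I-band) force across thin
#' filaments over the plateau window, pooled over one or more traces: every
#' (record time, filament) pair is a sample, so the SD reflects the
#' filament-to-filament force heterogeneity at any instant of the plateau.
#'
#' @param traces a \linkS4class{SimulationTrace} or list of traces
#' @param window plateau window counted back from the end of each run, s
#' @param breaks histogram bin control (passed to [hist()])
#' @return a \linkS4class{ForceEstimate} (tension left `NA`; fill in via
#'   [tensionFromActinForce()])
#' @export
forceStatistics <- function(traces, window = 0.1, breaks = "Sturges") {
  if (is(traces, "SimulationTrace")) traces <- list(traces)
  if (!length(traces)) stop("empty ensemble")
  perFil <- unlist(lapply(traces, function(tr) {
    tt <- tr@times
    sel <- tt >= max(tt) - window
    as.vector(tr@thinForce[sel, , drop = FALSE])
  }))
  h <- graphics::hist(perFil, breaks = breaks, plot = FALSE)
  new("ForceEstimate", meanForce = mean(perFil),
      sdForce = if (length(perFil) > 1) sd(perFil) else 0,
      histBreaks = h$breaks, histCounts = as.numeric(h$counts),
      tension = NA_real_, kbindMatched = NA_real_, g = NA_real_,
      details = list(nSamples = length(perFil), window = window))
}

#' Diffraction-calibrated mean-to-plateau strain ratio
#'
#' The centroid of the first-order reflection of a nonuniformly strained
#' ensemble does not report the plain real-space mean strain: the uniformly
#' strained I-band plateau diffracts coherently and pulls the centroid
#' toward the plateau spacing. This function calibrates the mapping by
#' running the same metrology on a forward-modelled ensemble of stepwise
#' strained filaments at a reference plateau force, returning
#' `g = measured strain / plateau strain` so that
#' `plateau strain = measured strain / g` is unbiased under the assumed
#' load model.
#'
#' @param geometry a \linkS4class{SarcomereGeometry}
#' @param Ka actin filament modulus, pN
#' @param refForce reference plateau force, pN (the operating point of the
#'   calibration)
#' @param nFilaments,nLoads surrogate ensemble size and loads per filament
#' @param seed RNG seed of the surrogate ensemble
#' @param halfwidth metrology window relative half-width
#' @return the calibrated ratio g
#' @export
calibratedGRatio <- function(geometry = sarcomereGeometry(), Ka = 0.65e5,
                             refForce = 300, nFilaments = 100, nLoads = 54L,
                             seed = 101L, halfwidth = 0.02) {
  if (refForce <= 0) stop("refForce must be > 0")
  set.seed(seed)
  h0 <- geometry@monomerSpacing
  nm <- geometry@nMonomers
  ob <- overlapBounds(geometry)
  idxR <- which((0:(nm - 1)) * h0 >= ob$zLo & (0:(nm - 1)) * h0 <= ob$zHi)
  pos <- lapply(seq_len(nFilaments), function(i) {
    idx <- sort(sample(idxR, min(nLoads, length(idxR))))
    stepwiseStrainedFilament(nm, h0, data.frame(
      index = idx, force = rep(refForce / length(idx), length(idx))), Ka)
  })
  p1 <- meridionalIntensity(pos, orderGrid(1, h0, halfwidth))
  m1 <- peakTopHalfCentroid(p1, peakOrderWindow(1, h0, halfwidth), 1L)
  ((m1@spacing - h0) / h0) / (refForce / Ka)
}

# peak-local normalized overlay residual between two profiles on a window:
# both are scaled to unit peak height, compared where the reference exceeds
# 10% of its peak
overlayResidual <- function(predicted, observed, window) {
  wp <- windowSubset(predicted, window)
  wo <- windowSubset(observed, window)
  pi <- stats::approx(wp$Z, wp$I / max(wp$I), xout = wo$Z, rule = 2)$y
  oi <- wo$I / max(wo$I)
  sel <- oi > 0.1
  sqrt(mean((pi[sel] - oi[sel])^2))
}

#' Estimate filament forces and tension from a relaxed/contracted profile pair
#'
#' The five-step estimation: (i) mean inter-monomer spacings of both states
#' from the first-order peak (centroid of the top half; the second-order
#' width is recorded); (ii) mean strain scaled to the I-band plateau strain
#' through the mean-to-plateau ratio g; (iii) mean per-filament force
#' `Ka * plateau strain`; (iv) optionally, titration of the binding rate
#' until the simulated plateau force matches, giving the matched ensemble;
#' (v) force distribution (histogram) from the matched ensemble, and the
#' muscle tension from the filament areal density.
#'
#' @param relaxed,contracted \linkS4class{MeridionalProfile}s containing the
#'   first and second order actin reflections
#' @param geometry a \linkS4class{SarcomereGeometry}
#' @param elastic an \linkS4class{ElasticParams}
#' @param gSource how the mean-to-plateau ratio g is obtained:
#'   `"calibrated"` (default) runs the metrology on a forward-modelled
#'   stepwise-load ensemble at the estimated operating force
#'   ([calibratedGRatio()]); `"profile"` uses the real-space mean/plateau
#'   ratio of `spacingProfile`; `"geometric"` uses the linear-decay fallback
#' @param spacingProfile simulated ensemble spacing profile for
#'   `gSource = "profile"`
#' @param titrate run the simulation titration step (slow); when FALSE the
#'   estimate is purely metrological and the histogram is empty
#' @param rates,nThick,duration,seeds,titrationTol simulation controls for
#'   the titration step
#' @param beam optional \linkS4class{BeamModel} used to smear the matched
#'   ensemble's predicted profiles for the overlay check
#' @param halfwidth metrology window relative half-width
#' @param background background subtraction method applied to both profiles
#'   (`"linear_endpoints"`, `"polynomial_k"` or `"none"`)
#' @return a \linkS4class{ForceEstimate}; `details` carries the per-order
#'   \linkS4class{PeakMetrics}, relative widths, Del H, strains and (when
#'   titration ran) the overlay residuals
#' @export
estimateFromProfiles <- function(relaxed, contracted,
                                 geometry = sarcomereGeometry(),
                                 elastic = elasticParams(),
                                 gSource = c("calibrated", "profile",
                                             "geometric"),
                                 spacingProfile = NULL, titrate = FALSE,
                                 rates = rateParams(), nThick = 8L,
                                 duration = 0.25, seeds = 1:2,
                                 titrationTol = 0.03, beam = NULL,
                                 halfwidth = 0.02,
                                 background = "linear_endpoints") {
  gSource <- match.arg(gSource)
  s0 <- geometry@monomerSpacing
  metro <- function(profile, order) {
    w <- peakOrderWindow(order, s0, halfwidth)
    p <- if (identical(background, "none")) profile else
      subtractBackground(profile, w, method = background)
    peakTopHalfCentroid(p, w, order = order)
  }
  mRel1 <- metro(relaxed, 1L); mCon1 <- metro(contracted, 1L)
  mRel2 <- metro(relaxed, 2L); mCon2 <- metro(contracted, 2L)
  dsp <- deltaSpacing(mRel1, mCon1)
  meanStrain <- max(0, dsp$strainPercent / 100)
  if (gSource == "profile" && is.null(spacingProfile))
    stop("gSource = 'profile' needs a spacingProfile")
  ps <- plateauStrainFromMean(
    meanStrain, if (gSource == "profile") spacingProfile else NULL, geometry)
  if (gSource == "calibrated" && meanStrain > 0) {
    # two-pass: calibrate at the geometric first guess, then at the refined
    # operating force
    g <- ps$g
    for (pass in 1:2) {
      F0 <- elastic@Ka * meanStrain / g
      g <- calibratedGRatio(geometry, elastic@Ka, refForce = F0,
                            halfwidth = halfwidth)
    }
    ps <- list(plateauStrain = meanStrain / g, g = g)
  }
  meanForce <- forceFromPlateauStrain(ps$plateauStrain, elastic@Ka)
  dens <- filamentDensity(geometry@d10Slack, geometry@myofibrilOccupancy)
  tension <- tensionFromActinForce(meanForce, dens)
  details <- list(
    relaxedOrder1 = mRel1, contractedOrder1 = mCon1,
    relaxedOrder2 = mRel2, contractedOrder2 = mCon2,
    delH = dsp$delH, meanStrainPercent = dsp$strainPercent,
    plateauStrainPercent = 100 * ps$plateauStrain,
    relWidthOrder1 = mCon1@fwhmZ / mCon1@zCenter,
    relWidthOrder2 = mCon2@fwhmZ / mCon2@zCenter,
    density = dens)
  est <- new("ForceEstimate", meanForce = meanForce, sdForce = NA_real_,
             histBreaks = numeric(), histCounts = numeric(),
             tension = tension, kbindMatched = NA_real_, g = ps$g,
             details = details)
  if (!titrate) return(est)
  lat <- buildHalfSarcomere(geometry, elastic, nThick = nThick)
  tit <- titrateKbind(meanForce, lat, rates, duration = duration,
                      seeds = seeds, tol = titrationTol)
  stats <- forceStatistics(tit$traces, window = min(0.1, duration / 3))
  est@sdForce <- stats@sdForce
  est@histBreaks <- stats@histBreaks
  est@histCounts <- stats@histCounts
  est@kbindMatched <- tit$kbind
  # self-consistent g: run the same metrology on the matched ensemble's
  # monomer positions and anchor it to the ensemble's known plateau force
  snaps <- do.call(c, lapply(tit$traces, function(tr) tr@snapshots))
  if (length(snaps) && tit$force > 0) {
    pos <- do.call(cbind, snaps)
    pSim <- meridionalIntensity(pos, orderGrid(1, s0, halfwidth))
    mSim <- peakTopHalfCentroid(pSim, peakOrderWindow(1, s0, halfwidth), 1L)
    gSim <- ((mSim@spacing - s0) / s0) / (tit$force / elastic@Ka)
    if (is.finite(gSim) && gSim > 0) {
      est@g <- gSim
      est@meanForce <- elastic@Ka * meanStrain / gSim
      est@tension <- tensionFromActinForce(est@meanForce, dens)
    }
  }
  snaps <- tit$traces[[1]]@snapshots
  if (length(snaps)) {
    pos <- snaps[[length(snaps)]]
    ov <- vapply(c(1L, 2L), function(ord) {
      Zg <- orderGrid(ord, s0, halfwidth)
      pred <- meridionalIntensity(pos, Zg)
      if (!is.null(beam)) pred <- convolveBeam(pred, beam)
      overlayResidual(pred, contracted, peakOrderWindow(ord, s0, halfwidth))
    }, numeric(1))
    est@details$overlayResidual <- stats::setNames(ov, c("order1", "order2"))
  }
  est
}
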