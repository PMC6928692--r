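# Synthetic inputs with known ground truth: uniform and stepwise-strained
# filaments, and noisy pseudo-experimental relaxed/contracted profile pairs.

#' Uniformly spaced filament
#'
#' @param n number of monomers (>= 2)
#' @param h spacing, nm (> 0)
#' @return monomer positions `(0:(n-1)) * h`, nm
#' @examples
#' tail(uniformFilament(364, 2.73), 1)   # 991.0 nm
#' @export
uniformFilament <- function(n, h) {
  if (n < 2) stop("need n >= 2 monomers")
  if (h <= 0) stop("spacing must be > 0")
  (0:(n - 1)) * h
}

#' Filament with stepwise tension-induced spacing increases
#'
#' Point loads at given monomer indices (1-based, Z-disc end is index 1)
#' put segment j (between monomers j and j+1) under tension equal to the sum
#' of loads applied above it, so its spacing is `h0 (1 + F_j / Ka)`: the
#' staircase profile produced by randomly attached crossbridges.
#'
#' @param n number of monomers
#' @param h0 relaxed spacing, nm
#' @param loadPoints data.frame with columns `index` (monomer, 1-based) and
#'   `force` (pN, >= 0)
#' @param Ka actin filament modulus, pN
#' @return monomer positions, nm
#' @export
stepwiseStrainedFilament <- function(n, h0, loadPoints, Ka = 0.65e5) {
  if (!nrow(loadPoints)) return(uniformFilament(n, h0))
  if (any(loadPoints$index < 1 | loadPoints$index > n))
    stop("load index out of range")
  if (any(loadPoints$force < 0)) stop("loads must be >= 0")
  load <- numeric(n)
  for (i in seq_len(nrow(loadPoints)))
    load[loadPoints$index[i]] <- load[loadPoints$index[i]] +
      loadPoints$force[i]
  tension <- rev(cumsum(rev(load)))[-1]   # segment j: loads at indices > j
  spacing <- h0 * (1 + tension / Ka)
  c(0, cumsum(spacing))
}

#' Synthetic relaxed/contracted diffraction experiment with known truth
#'
#' Draws per-filament I-band forces from a normal distribution truncated at
#' zero, distributes each filament's force over random stepwise loads inside
#' the overlap region, computes beam-convolved first and second order
#' meridional profiles of the relaxed (uniform) and contracted (stepwise
#' strained) ensembles, and applies multiplicative Gaussian intensity noise.
#' Regeneration from the same parameters and seed is bit-identical.
#'
#' @param meanForce,sdForce mean and SD of the per-filament force, pN
#' @param nFilaments ensemble size
#' @param beam a \linkS4class{BeamModel}
#' @param noiseRelSd relative SD of the multiplicative intensity noise
#' @param seed RNG seed
#' @param geometry a \linkS4class{SarcomereGeometry}
#' @param Ka actin filament modulus, pN
#' @param nLoads loads per filament (default 54, the expected number of
#'   bound heads per thin filament at full activation)
#' @param halfwidth window relative half-width for the profile grids
#' @return list with `relaxed` and `contracted`
#'   \linkS4class{MeridionalProfile}s (orders 1 and 2 concatenated) and
#'   `truth`, a \linkS4class{SyntheticTruth}
#' @export
syntheticExperiment <- function(meanForce, sdForce = 0, nFilaments = 250,
                                beam = beamModel(3e-4), noiseRelSd = 5e-4,
                                seed = 1L, geometry = sarcomereGeometry(),
                                Ka = 0.65e5, nLoads = 54L,
                                halfwidth = 0.02) {
  if (meanForce < 0) stop("meanForce must be >= 0")
  if (sdForce < 0) stop("sdForce must be >= 0")
  set.seed(seed)
  nm <- geometry@nMonomers
  h0 <- geometry@monomerSpacing
  ob <- overlapBounds(geometry)
  idxRange <- which((0:(nm - 1)) * h0 >= ob$zLo &
                      (0:(nm - 1)) * h0 <= ob$zHi)
  forces <- numeric(nFilaments)
  for (i in seq_len(nFilaments)) {
    f <- rnorm(1, meanForce, sdForce)
    while (f < 0) f <- rnorm(1, meanForce, sdForce)
    forces[i] <- f
  }
  loads <- vector("list", nFilaments)
  positions <- vector("list", nFilaments)
  for (i in seq_len(nFilaments)) {
    idx <- sort(sample(idxRange, min(nLoads, length(idxRange))))
    loads[[i]] <- data.frame(index = idx,
                             force = rep(forces[i] / length(idx),
                                         length(idx)))
    positions[[i]] <- stepwiseStrainedFilament(nm, h0, loads[[i]], Ka)
  }
  relaxedPos <- lapply(seq_len(nFilaments), function(i)
    uniformFilament(nm, h0))
  mkProfile <- function(pos) {
    parts <- lapply(c(1L, 2L), function(ord) {
      Zg <- orderGrid(ord, h0, halfwidth)
      convolveBeam(meridionalIntensity(pos, Zg), beam)
    })
    Z <- c(parts[[1]]@Z, parts[[2]]@Z)
    I <- c(parts[[1]]@intensity, parts[[2]]@intensity)
    if (noiseRelSd > 0)
      I <- pmax(I * (1 + rnorm(length(I), 0, noiseRelSd)), 0)
    meridionalProfile(Z, I, metadata = list(
      nFilaments = nFilaments, beam = TRUE, beamFwhm = beam@fwhm,
      noiseRelSd = noiseRelSd, windows = "orders 1,2"))
  }
  contracted <- mkProfile(positions)
  relaxed <- mkProfile(relaxedPos)
  truth <- new("SyntheticTruth", forces = forces, loads = loads,
               positions = positions, beamFwhm = beam@fwhm,
               noiseRelSd = noiseRelSd, seed = as.integer(seed))
  list(relaxed = relaxed, contracted = contracted, truth = truth)
}

#' Write / read a synthetic-truth sidecar
#'
#' Lossless JSON serialization of a \linkS4class{SyntheticTruth} (full
#' double precision).
#'
#' @param truth a \linkS4class{SyntheticTruth}
#' @param path file path
#' @return `readTruth` returns the reconstructed
#'   \linkS4class{SyntheticTruth}
#' @export
writeTruth <- function(truth, path) {
  obj <- list(forces = truth@forces,
              loads = lapply(truth@loads, as.list),
              positions = truth@positions, beamFwhm = truth@beamFwhm,
              noiseRelSd = truth@noiseRelSd, seed = truth@seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  loads <- lapply(obj$loads, function(l)
    data.frame(index = as.integer(unlist(l$index)),
               force = as.numeric(unlist(l$force))))
  new("SyntheticTruth", forces = as.numeric(unlist(obj$forces)),
      loads = loads,
      positions = lapply(obj$positions, function(p) as.numeric(unlist(p))),
      beamFwhm = as.numeric(obj$beamFwhm),
      noiseRelSd = as.numeric(obj$noiseRelSd),
      seed = as.integer(obj$seed))
}
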