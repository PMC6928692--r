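# Strain-dependent three-state crossbridge kinetics and the fixed-step
# Monte Carlo driver.
#
# States: 1 detached, 2 weakly attached / pre-power stroke, 3 post-power
# stroke. The strain coordinate x is the axial offset between the head's
# crown anchor and its actin site (positive when the site lies Z-disc-ward
# of the head); the state-3 spring has its rest position shifted by the
# power stroke d, so a head that strokes at x = 0 pulls its actin site
# toward the M-band with force kappa * d.

#' Crossbridge state free energies
#'
#' G1 = 0; G2(x) = dGbind + kappa x^2 / (2 kBT);
#' G3(x) = dGbind + dGstroke + kappa (x + d)^2 / (2 kBT). Energies in kBT.
#'
#' @param state 1, 2 or 3 (vectorized)
#' @param x crossbridge strain, nm (vectorized)
#' @param params a \linkS4class{RateParams}
#' @param kappaXb crossbridge stiffness, pN/nm
#' @return free energy in kBT units
#' @examples
#' stateFreeEnergy(2, 0, rateParams())    # -3
#' stateFreeEnergy(3, -10.5, rateParams())  # -18: strain after stroke zero
#' @export
stateFreeEnergy <- function(state, x, params = rateParams(), kappaXb = 1.3) {
  if (!all(state %in% 1:3)) stop("state must be 1, 2 or 3")
  n <- max(length(state), length(x))
  state <- rep_len(state, n)
  x <- rep_len(x, n)
  el <- kappaXb * x^2 / (2 * params@kBT)
  el3 <- kappaXb * (x + params@strokeD)^2 / (2 * params@kBT)
  ifelse(state == 1, 0,
         ifelse(state == 2, params@dGbind + el,
                params@dGbind + params@dGstroke + el3))
}

ratesList <- function(params, kappaXb) {
  c(sapply(slotNames(params), function(s) slot(params, s),
           simplify = FALSE), list(kappaXb = kappaXb))
}

#' Strain-dependent transition rates
#'
#' Computes all six rates of the three-state cycle at strain x:
#' `k12(x) = kBind exp(-kappa x^2 / 2kBT)` with `k21 = k12 / K12(x)`;
#' the power-stroke rate `k23(x) = capK23 / (1 + exp(dG23(x)))` with
#' `k32 = k23 / K23(x)`; when the reverse rate would exceed its cap the pair
#' is re-anchored at the cap so detailed balance
#' `kij / kji = exp(-dGij(x))` holds for every x, capped or not.
#' Detachment `k31` equals `kAdp0` for positive post-stroke extension and is
#' strain-accelerated (Arrhenius with distance delta) for `x + d <= 0`,
#' capped at `capK31`. `k13` is 0.
#'
#' @param x strain, nm (vectorized); NaN rejected
#' @param params a \linkS4class{RateParams}
#' @param kappaXb crossbridge stiffness, pN/nm
#' @return data.frame with columns k12, k21, k23, k32, k31, k13 (1/s)
#' @examples
#' transitionRates(0, rateParams())   # k12 = 134, k21 = 134/exp(3)
#' @export
transitionRates <- function(x, params = rateParams(), kappaXb = 1.3) {
  if (any(!is.finite(x))) stop("strain x must be finite")
  as.data.frame(cxx_rates(as.numeric(x), ratesList(params, kappaXb)))
}

checkDt <- function(params) {
  rates <- c(kBind = params@kBind, kAdp0 = params@kAdp0,
             capK23 = params@capK23, capK32 = params@capK32,
             capK31 = params@capK31)
  prod <- rates * params@dt
  if (any(prod >= 0.05)) {
    worst <- names(prod)[which.max(prod)]
    stop(sprintf(
      "dt too large: %s * dt = %.3g >= 0.05 violates the first-order Monte Carlo probability bound",
      worst, max(prod)))
  }
  if (params@k13 != 0)
    stop("nonzero k13 is not supported by the Monte Carlo engine")
}

runEngine <- function(lattice, rates, duration, seed, recordDt, snapshotDt,
                      snapshotStart, rigid, tol, maxit, logEvents) {
  checkDt(rates)
  if (duration <= 0) stop("duration must be > 0")
  cxx_run_sim(latticeToList(lattice),
              ratesList(rates, lattice@elastic@kappaXb),
              duration, as.integer(seed), recordDt, snapshotDt, snapshotStart,
              rigid, tol, as.integer(maxit), logEvents)
}

resultToTrace <- function(res, lattice, rates, seed, duration) {
  lat <- lattice
  lat@actinZ <- res$actinZ
  lat@myosinZ <- res$myosinZ
  lat@attachments <- data.frame(head = res$attHead, thin = res$attThin,
                                monomer = res$attMonomer, state = res$attState)
  ev <- as.data.frame(res$events)
  new("SimulationTrace", times = res$times, thinForce = res$thinForce,
      thickForce = res$thickForce, nState2 = res$nState2,
      nState3 = res$nState3, xbForceSum = res$xbForceSum,
      xbCount = res$xbCount, snapshotTimes = as.numeric(res$snapshotTimes),
      snapshots = as.list(res$snapshots), events = ev, lattice = lat,
      rates = rates, seed = as.integer(seed), duration = duration)
}

#' Advance the lattice by a fixed number of Monte Carlo steps
#'
#' Each head is tested independently per step with probability
#' `1 - exp(-k dt)` per available transition; detached heads choose one
#' candidate site per step with probability proportional to
#' `k12(x_site) dt`. Events are applied atomically and the mechanical
#' equilibrium is re-solved only on steps where at least one event occurred.
#' Identical (lattice, rates, seed) give bit-identical event logs.
#'
#' @param lattice a \linkS4class{HalfSarcomereLattice}
#' @param rates a \linkS4class{RateParams} (its `dt` slot is the step)
#' @param nSteps number of steps
#' @param seed RNG seed
#' @param rigid if TRUE filaments are rigid: no mechanics re-solve
#' @param tol,maxit equilibrium solver controls
#' @return list with the updated `lattice` and the `events` data.frame
#'   (step, head, from, to, thin, monomer)
#' @export
mcUpdate <- function(lattice, rates = rateParams(), nSteps = 1L, seed = 1L,
                     rigid = FALSE, tol = 1e-3, maxit = 2000) {
  duration <- nSteps * rates@dt
  res <- runEngine(lattice, rates, duration, seed, recordDt = duration,
                   snapshotDt = 0, snapshotStart = 0, rigid = rigid,
                   tol = tol, maxit = maxit, logEvents = TRUE)
  tr <- resultToTrace(res, lattice, rates, seed, duration)
  list(lattice = tr@lattice, events = tr@events)
}

#' Run an isometric contraction
#'
#' Fixed-step Monte Carlo at time step `rates@dt` with both ends of the half
#' sarcomere held (isometric): thin filaments fixed at the Z-disc, thick
#' filament anchors fixed at the M-band. Records per-filament boundary
#' forces, bound-head counts by state and total crossbridge force at
#' `recordDt` cadence, and monomer-position snapshots from `snapshotStart`
#' onward at `snapshotDt` cadence.
#'
#' @param lattice a \linkS4class{HalfSarcomereLattice}
#' @param rates a \linkS4class{RateParams}
#' @param duration simulated time, s
#' @param seed RNG seed; identical seeds give identical traces
#' @param recordDt force record cadence, s
#' @param snapshotDt snapshot cadence, s (0 disables snapshots)
#' @param snapshotStart time of the first snapshot, s (default half the run)
#' @param rigid if TRUE skip mechanics (rigid filaments)
#' @param tol,maxit equilibrium solver controls
#' @param logEvents keep the full event log (set FALSE for long runs)
#' @return a \linkS4class{SimulationTrace}
#' @export
runIsometric <- function(lattice, rates = rateParams(), duration = 0.5,
                         seed = 1L, recordDt = 1e-3, snapshotDt = 0.01,
                         snapshotStart = duration / 2, rigid = FALSE,
                         tol = 1e-3, maxit = 2000, logEvents = TRUE) {
  res <- runEngine(lattice, rates, duration, seed, recordDt, snapshotDt,
                   snapshotStart, rigid, tol, maxit, logEvents)
  resultToTrace(res, lattice, rates, seed, duration)
}

#' Plateau (steady-state) onset time of a trace
#'
#' The plateau is declared at the first record time from which the windowed
#' mean of the total force drifts by less than `driftTol` (relative) over a
#' `window`-long interval.
#'
#' @param trace a \linkS4class{SimulationTrace}
#' @param window drift-test window, s (default 0.05)
#' @param driftTol relative drift tolerance (default 0.01)
#' @return plateau onset time in s (NA if never reached)
#' @export
plateauStart <- function(trace, window = 0.05, driftTol = 0.01) {
  tt <- trace@times
  f <- rowSums(trace@thinForce)
  if (length(tt) < 3 || max(tt) < 2 * window) return(NA_real_)
  half <- window / 2
  wmean <- vapply(tt, function(t0)
    mean(f[tt >= t0 - half & tt <= t0 + half]), numeric(1))
  ok <- rep(FALSE, length(tt))
  for (i in seq_along(tt)) {
    j <- which(tt >= tt[i] + window)[1]
    if (is.na(j)) { ok[i] <- NA; next }
    ok[i] <- abs(wmean[j] - wmean[i]) <= driftTol * max(abs(wmean[j]), 1e-12)
  }
  i <- which(ok)[1]
  if (is.na(i) || !length(i)) NA_real_ else tt[i]
}

#' Fraction of heads in the attached states
#'
#' Time-averaged fraction of heads in states 2 or 3 over the last `window`
#' seconds of the trace, together with its distribution across thick
#' filaments.
#'
#' @param trace a \linkS4class{SimulationTrace}
#' @param window averaging window counted back from the end of the run, s
#' @return list with `fraction` (scalar in `[0, 1]`) and `perFilament`
#'   (mean bound fraction per thick filament)
#' @export
boundFraction <- function(trace, window = 0.1) {
  tt <- trace@times
  if (window > max(tt)) stop("window exceeds the trace duration")
  sel <- tt >= max(tt) - window
  g <- trace@lattice@geometry
  headsPerThick <- g@nCrowns * g@headsPerCrown
  bound <- trace@nState2[sel, , drop = FALSE] +
    trace@nState3[sel, , drop = FALSE]
  perFil <- colMeans(bound) / headsPerThick
  list(fraction = mean(bound) / headsPerThick, perFilament = perFil)
}
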