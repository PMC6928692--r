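---
title: "Estimating actin filament forces from meridional X-ray reflections"
author: "sarcoXray"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating actin filament forces from meridional X-ray reflections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sarcoXray)
```

## The problem

During isometric contraction, myosin heads bind actin at random positions
and each bound crossbridge injects a small force into the thin filament.
Because actin filaments are extensible, the cumulative tension stretches the
inter-monomer spacing: the spacing rises stepwise from the filament tip
toward the Z-disc and is largest (and spatially constant) in the I-band,
where no heads bind. Small-angle X-ray diffraction sees these spacings
directly: the first-order actin meridional reflection near 2.73 nm reports
the average monomer spacing, and the width of the second-order reflection
near 1.365 nm reports how *nonuniform* the spacings are, along and between
filaments. The package implements the full forward-and-inverse chain:

1. a spatially explicit Monte Carlo simulation of a half sarcomere with
   extensible filaments and strain-dependent three-state crossbridge
   kinetics (`buildHalfSarcomere()`, `runIsometric()`);
2. a meridional diffraction calculator for arbitrary, nonuniformly spaced
   monomer positions (`meridionalIntensity()`, `convolveBeam()`);
3. peak metrology (centroid of the top half, FWHM) and the estimation
   pipeline that converts a relaxed/contracted reflection pair into the mean
   and distribution of per-filament forces and the whole-muscle tension
   (`peakTopHalfCentroid()`, `estimateFromProfiles()`).

## The mechanical model

The half sarcomere spans `z = 0` (Z-disc) to `z = SL/2` (M-band). Each thin
filament is a chain of 364 monomer nodes at a relaxed spacing
`s0 = 2.73 nm` (length 993.7 nm), anchored at the Z-disc. Each thick
filament hangs from a fixed M-band anchor: a bare zone, then 50 crowns every
14.3 nm, three heads per crown (150 per half filament). At a sarcomere
length of 2.3 um, direct construction places the crown region at
[360, 1060.7] nm, so the crowns overlap the thin filament over
[360, 993.7] nm (634 nm) and the I-band side non-overlap region is 360 nm.
Filaments are linearly elastic with moduli `Ka = 0.65e5 pN` (65 pN/nm per
1 um of actin, Kojima's direct measurement) and `Km = 1.32e5 pN`; a segment
of length L has stiffness modulus/L. Crossbridges are linear springs of
stiffness `kappa = 1.3 pN/nm` whose rest position shifts by the power
stroke `d = 10.5 nm` in the post-stroke state.

After every binding, stroke or detachment event the network is brought to
quasi-static equilibrium. Under isometric boundary conditions the elastic
configuration is piecewise constant between events, so the solver runs
event-driven rather than per time step -- this is what makes desk-scale runs
feasible. The solver alternates exact tridiagonal (Thomas) solves of each
filament chain with the other family held fixed; the coupled system is
symmetric positive definite under the stated constraints, so the iteration
converges, and it stops when the net force on every free node is below a
tolerance (default `1e-6` pN for one-shot solves; values much below `1e-8`
pN are not representable because nodal forces are differences of ~1e7 pN
spring terms). Inside Monte Carlo runs the solver tracks conservative
per-filament residual bounds and revisits only the elastic neighbourhood of
each event; the run-time default tolerance is `1e-3` pN, at which the true
residual stays near `1e-4` pN and position errors are below `1e-7` nm --
far smaller than any strain that affects a rate or an observable.
A dense single-matrix solve implemented independently in the test suite
agrees with it to 1e-10.

## The crossbridge cycle

Three states: detached (1), weakly attached / pre-stroke (2), post-stroke
(3). The strain coordinate `x` is the axial offset between the head's crown
anchor and its actin site; a head that strokes at `x = 0` pulls its site
toward the M-band with force `kappa * d`. Energies (kBT units):

* `G1 = 0`
* `G2(x) = dG_bind + kappa x^2 / 2kBT`, `dG_bind = -3` (binding equilibrium
  constant `exp(3) ~ 20`)
* `G3(x) = dG_bind + dG_stroke + kappa (x+d)^2 / 2kBT`, `dG_stroke = -15`

Rates: Gaussian-weighted binding `k12 = k_bind exp(-kappa x^2/2kBT)` with
`k_bind = 134 /s` at reference activation (titratable -- activation level is
represented entirely by this rate); a sigmoidal stroke rate
`k23 = cap23 / (1 + exp(dG23(x)))`; Arrhenius ADP-release/detachment
`k31 = k_adp0 exp(-(kappa delta (x+d) + kappa delta^2/2)/kBT)` for negative
post-stroke extension and `k_adp0 = 70 /s` otherwise, with the second
power stroke `delta = 1 nm`; `k13 = 0`. Exponential rates are capped
(`k23 <= 1000`, `k32 <= 100`, `k31 <= 1e4` 1/s); whenever a cap engages,
the paired rate is recomputed from the cap so that detailed balance
`kij/kji = exp(-dGij(x))` holds at every strain. These explicit forms are
the package's single model-form choice point: the published parameter set
constrains them (equilibrium constants, caps, stroke distances) but does not
print the full expressions, so `transitionRates()` is where any alternative
would be swapped in. As specified, the `k31` law has a small downward step
(factor `exp(-kappa delta^2 / 2kBT) ~ 0.85`) at `x + d = 0`; it is kept
verbatim.

The Monte Carlo uses fixed time steps of `dt = 1 us`; each head is tested
independently per step with probability `1 - exp(-k dt)` per available
transition, and detached heads pick one candidate site per step with
probability proportional to `k12(x_site) dt`. A precondition
`max-rate x dt < 0.05` bounds the first-order discretization error.
Internally the engine samples the per-transition geometric waiting times
between events, which is *exactly* equivalent to the per-step Bernoulli
scheme (rates are constant between events, and the geometric distribution
is memoryless) while skipping the empty steps. The RNG is a seeded
`mt19937_64`; identical seeds give bit-identical event logs.

## Lattice wiring choices

The published geometry states three myosin neighbours per actin filament
and 2:1 stoichiometry but no azimuthal binding rule, so the package adopts
a deterministic one: each thick filament has six neighbouring thin
filaments in a periodic (toroidal) arrangement, and head j of crown c
serves direction `2j + (c mod 2)`, cycling with crown index. Every thin
filament then faces exactly 75 heads (25 from each of three thick
filaments), which removes lattice edge effects that would otherwise
dominate at the 20-filament scale used here. Candidate binding sites are
limited to `|x| <= 8 nm`; at `kappa = 1.3 pN/nm` and `kBT = 3.96 pN nm`
the Gaussian binding weight at 8 nm is below 1e-3 of its peak, so the
truncation is negligible. Because thick filaments are axially in register,
facing heads from different thick filaments compete for the same target
monomers; this contention is physical and the occupancy rule (one head per
monomer) resolves it. Titin is available as an optional linear spring
between the thick filament tip and the Z-disc and defaults to zero
stiffness, since no titin stiffness is printed in the source parameter set.

## Diffraction

On the meridian (R = 0) every atom of a helical filament contributes with
the same azimuthal phase (only the zero-order Bessel term survives), so the
axial positions of the monomer centres determine the profile completely and
the full helical-transform machinery is unnecessary. For each filament,
`A(Z) = sum_j f(Z) exp(2 pi i Z z_j)` and the ensemble profile is the
incoherent sum of `|A|^2` over filaments -- no axial register between
filaments is assumed, and a coherent mode is deliberately not offered.
Scatterers are points by default; a uniform-sphere form factor with a
configurable subunit diameter is available. Uniform filaments reproduce the
finite-lattice closed form `|sin(N pi Z h)/sin(pi Z h)|^2` to 1e-8, which
the test suite uses as an oracle. Beam smearing is a unit-area Gaussian
convolution; edge contributions are renormalized per source point so the
integrated intensity is conserved exactly.

## Metrology and the estimation pipeline

Peak positions use the centroid of the top half: the intensity-weighted
mean of Z over points at or above half maximum, weighted by the excess over
half maximum. On noiseless uniform-helix profiles the spacing error is
below 1e-5 relative, comfortably inside the 0.05% accuracy budget of the
original plate data. Backgrounds are removed with a linear chord through
the window endpoints (exact for constant and sloped baselines) or an
optional polynomial fitted to the window margins; a window whose margins
still carry a large curved residual is rejected as cutting into the peak
core.

The estimation steps are: (i) mean spacings of the relaxed and contracted
states from the first-order centroid and their difference `Del H`;
(ii) conversion of the mean strain to the I-band plateau strain through the
mean-to-plateau ratio g; (iii) mean per-filament force `Ka x plateau
strain`; (iv) optional titration of `k_bind` until the simulated plateau
force matches, yielding the matched ensemble; (v) the force histogram from
that ensemble and the muscle tension via the filament areal density
(`occupancy x 1e6 / ((2/sqrt(3)) d10^2)` thick filaments per um^2 at the
slack-length d10 of 37 nm, twice that for actin: ~506 and ~1012, so 297 pN
per filament is ~300 kPa).

One subtlety deserves emphasis. The centroid of the first-order peak of a
*nonuniformly* strained ensemble is not the plain real-space mean spacing:
the uniformly strained I-band plateau diffracts coherently and pulls the
centroid toward the plateau spacing (a ~7% effect at 300 pN). The default
estimator therefore calibrates the centroid-to-plateau mapping by running
the same metrology on a forward-modelled ensemble of stepwise strained
filaments at the estimated operating force (`calibratedGRatio()`, two
fixed-point passes), and after titration it recalibrates against the
matched simulation itself. The purely geometric mapping
`g = (L_I + L_ov/2)/L_thin = 0.68` (linear tension decay) and the
real-space profile ratio are both available as alternatives (`gSource`);
the real-space route reproduces the published spacing-to-force table rows
within 3%.

## The synthetic experiment generator

`syntheticExperiment()` stands in for the unavailable plate data: it draws
per-filament I-band forces from a normal distribution truncated at zero,
spreads each filament's force over 54 stepwise loads (the expected bound
crossbridge count per thin filament at full activation) placed uniformly at
random in the overlap region, diffracts relaxed and contracted ensembles
over the first two orders, convolves with a Gaussian beam and applies
multiplicative intensity noise. Defaults: 250 filaments (metrology is
converged well below this), beam FWHM `3e-4 1/nm`, noise SD `5e-4`
relative (the 0.05%-scale accuracy of the original data). The beam width is
not printed in the source; `3e-4 1/nm` is narrow relative to the intrinsic
first-order width (9e-4), which keeps the observed qualitative feature that
the second-order reflection is relatively broader than the first -- a beam
much wider than ~1e-3 would itself dominate the first-order width and
invert that ordering. What the generator does *not* emulate: myosin-based
meridional reflections (e.g. the 2.86 nm peak neighbouring the first actin
order), activation-related thin-filament twisting, detector geometry, or
radial integration bands. Passing the closed-loop tests therefore
demonstrates internal consistency of the estimation chain, not robustness
to every artefact of real plates.

## Numerical and statistical choices

* Time step `1e-6 s`; plateau detection requires the windowed mean force to
  drift < 1% over 50 ms; plateau statistics use the last 0.2 s of a run.
* Force heterogeneity (`forceStatistics()`) pools *instantaneous*
  per-filament Z-disc forces over plateau records: the published histograms
  describe filament-to-filament spread at an instant, and time-averaging
  would shrink it roughly with the square root of the number of correlation
  times in the window.
* The ensemble spacing SD (`ensembleSpacingStats()`) is reported relative
  to the *maximum* spacing change in the ensemble (maximum over filaments
  and positions). The alternative reading -- relative to the ensemble-mean
  plateau change -- would contradict the published filament-force SD/mean
  ratios of 0.12-0.16, so the maximum-based reading is used and stated.
* Steady-state checks run 20 thick filaments (3000 heads, 40 thin
  filaments) for 0.5 s and three seeds; the published simulations used 500
  thick filaments, so filament-count-sensitive quantities carry ~5x larger
  sampling error here. The 20/0.5 s/3-seed scale keeps every stochastic
  observable's seed-to-seed spread well inside the stated tolerances.
* Binding-rate titration bisects on a log scale against the seed-averaged
  plateau force (default tolerance 3%); it can run on a reduced lattice
  because the periodic wiring makes per-filament statistics nearly
  independent of the lattice size.

## Known limitations

* The exact strain-dependent rate expressions of the source platform are
  not published; the forms here satisfy every printed constraint but are
  not guaranteed identical. At the reference `k_bind = 134 /s` this model
  develops ~205 pN per thin filament rather than ~297 pN; the estimation
  procedure is insensitive to this because activation is matched by
  titration, exactly as the source procedure adjusts `k_bind` per
  experiment, but the bound-head mixture (and hence the mean force per
  crossbridge, ~4.8 pN at the matched point vs ~5.5 reported) differs
  toward the edge of the stated tolerance.
* Calcium regulation, two-headed myosin, ATP/ADP/Pi dependence, filament
  bending/torsion, radial lattice mechanics and multi-sarcomere chains are
  out of scope.
* Only the meridional axis is computed; 2D patterns, equatorials and layer
  lines are not.

## A small worked example

```{r example, eval = FALSE}
geo <- sarcomereGeometry()
lat <- buildHalfSarcomere(geo, elasticParams(), nThick = 6)
tr <- runIsometric(lat, rateParams(), duration = 0.25, seed = 1,
                   snapshotDt = 0.025, snapshotStart = 0.15)
boundFraction(tr, window = 0.1)$fraction      # ~0.69
pos <- do.call(cbind, tr@snapshots)
p1 <- meridionalIntensity(pos, orderGrid(1))
peakTopHalfCentroid(p1, peakOrderWindow(1), 1)  # spacing ~2.732 nm

xp <- syntheticExperiment(meanForce = 300, sdForce = 40, seed = 1)
estimateFromProfiles(xp$relaxed, xp$contracted)
```
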