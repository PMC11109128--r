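---
title: "From broadband light to retinal ganglion neuron spikes: the optorgn model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From broadband light to retinal ganglion neuron spikes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

optorgn simulates the complete chain from a light source's spectrum to the
spike train of a channelrhodopsin-expressing retinal ganglion neuron (RGN).
This vignette describes the model, its assumptions, the numerical choices,
and the limits of what the simulations can show.

## The light model

A light source is a `light_spectrum`: spectral irradiance on a uniform
wavelength grid, by default 380–700 nm at 1 nm (covering the 390–650 nm
range over which opsin activation spectra have been characterized, with
margin; at 1 nm the trapezoidal quadrature error is far below parameter
uncertainty).  Five parametric kinds are built in:

* `led` — rectangular band, default 20 nm full width, at a chosen centre.
  The discrete top-hat carries half-height edge samples so that its
  trapezoidal integral equals the nominal band exactly.
* `white` — spectrally flat ("pure white", the idealized broadband
  reference).
* `rgb` — three Gaussians at 458/521/628 nm, 20 nm FWHM, with adjustable
  relative amplitudes.
* `lamp` — a halogen-lamp-like Gaussian peaking at 600 nm with 150 nm FWHM.
  Only the peak position and broadband character of such lamps are
  specified anywhere; the Gaussian width is this package's choice.
* `sunlight` — a fixed, synthetic 18-point approximation of the terrestrial
  (AM1.5-like) visible spectrum, unit peak at 550 nm, spline-interpolated.
  Real solar spectra carry Fraunhofer/atmospheric structure that this
  smooth table deliberately omits; the exact solar table used in the
  original study was never published, so sunlight-driven results carry a
  few-percent shape uncertainty that white/LED results do not.

### What "irradiance" means for a broadband source

For a narrowband LED, "irradiance E" is unambiguous: the band integral.
For broadband sources two conventions exist, and they differ by large
factors:

* `integrated` — the spectral integral equals E (`scale_to_irradiance()`).
* `band` (default, `set_irradiance()`) — the unit-peak spectral shape is
  scaled so its *peak spectral density* is E/20 nm, i.e. the density of a
  20 nm reference LED carrying E.  Equal-irradiance comparisons between
  sources are then equal-peak-density comparisons of the normalized
  spectra, and the two conventions coincide for the LED itself.

All bundled protocols use the band convention.  It is the convention under
which the package reproduces the published reference photocurrents
(a flat-white 0.1 µW/mm² pulse gives a 79.4 pA ChRmine peak, four times
the LED value at equal stated irradiance) and the published photon-flux
equivalents of broadband thresholds; under the integrated convention a
flat white source at the same nominal irradiance delivers roughly nine
times fewer action-weighted photons and none of those comparisons holds.

### Effective photon flux

The only way light enters the kinetics is the scalar effective photon flux

$$\phi = \int \varepsilon(\lambda)\, I(\lambda)\, \frac{\lambda}{hc}\, d\lambda,$$

with the action spectrum \(\varepsilon(\lambda)\) fitted as a sum of up to
three Gaussians per opsin (amplitudes, centres, widths shipped in the
parameter table).  Two fitting conventions needed care: the Gaussian
exponent is implemented with the standard negative sign (a positive sign
diverges and cannot produce the bell-shaped activation spectra), and
negative fitted amplitudes (rsChRmine, CatCh, PsCatCh2.0) are kept but the
summed \(\varepsilon\) is floored at zero — negative lobes are artifacts of
unconstrained fitting outside the measured range.  A consequence of
\(\phi\)-mediation worth knowing: two spectrally different stimuli with
equal \(\phi\) produce bitwise-identical model responses (this is a tested
invariant).

## The photocycle

Each opsin follows a four-state cycle: dark ground state C1, a
high-conductance open state O1, a longer-lived low-conductance open state
O2 (conductance ratio \(\gamma\)), and a desensitized closed state C2.
Light drives C1→O1 and C2→O2 with Hill-type saturating rates
\(k\,\phi^p/(\phi^p+\phi_m^p)\); O1↔O2 interconversion has dark and
light-driven components; O2→C2 and C2→C1 relax thermally.  The
desensitized-state balance is implemented as
\(\dot C_2 = G_{d2} O_2 - (G_{a2}+G_r) C_2\), the only form for which the
four derivatives sum to zero; occupancy conservation then holds to the
solver tolerance (asserted ≤ 1e−8 along every trace).

Voltage-clamp photocurrent is \(I = g\,(O_1+\gamma O_2)(V_h - E)\) with the
whole-cell conductance and reversal from the parameter table.  The holding
potential is −70 mV throughout; it is not stated in the source tables but
it is the value at which the model reproduces the published 20.8 pA
(LED) / 79.4 pA (white) ChRmine reference peaks, and it is the
conventional clamp for such characterizations.

Derived metrics follow the standard definitions: peak magnitude and its
time; plateau as the mean magnitude over the final 5% of the pulse (the
plateau estimator is otherwise unspecified; 5% is long enough to average
solver ripple and short enough to stay inside the adapted regime);
turn-off time `t_off` to 1/e of the light-off current, by interpolation;
adaptation ratio = plateau/peak (the ratio is stated both ways in the
source's figure caption and text; plateau/peak is the form that decreases
with irradiance and pulse width, which is the documented behavior).
`EPD50` brackets the saturated peak current with a decade sweep (saturation
declared when a further decade adds <1%) and bisects on log-irradiance to
1% for the half-saturation point; with the Hill exponent p = 0.8 the
approach to saturation is slow, hence the wide default sweep.

## The retinal ganglion neuron

The membrane model is the Fohlmeister–Miller RGN soma: Na, delayed-
rectifier K, A-type K, Ca, Ca-gated K and leak currents on 1 µF/cm², with
first-order voltage-gated kinetics, a Nernstian Ca reversal computed from
instantaneous intracellular Ca (T = 295 K, external Ca 1.8 mM), Ca removal
with a 50 ms time constant toward the 1e−4 mM residual, and
\(g_{KCa}\) rising with the square of Ca relative to its 1e−3 mM
dissociation constant.  The Ca influx coefficient 3/(2Fr) is used as the
printed composite 1.5e−5 (the cell radius r is never given separately).
Rate expressions with removable singularities are evaluated by their
analytic limits.

Two entries required a decision beyond transcription:

* The Ca-gated K current reverses at \(E_K\).  The source prints
  \(E_{Ca}\), but a K⁺ current reversing near +125 mV would be
  depolarizing, contradicting the channel's identity and the
  Fohlmeister–Miller model this neuron derives from.  (Tested: using the
  printed reversal shifts thresholds by only ~20%, so the choice is not
  results-critical.)
* The A-type K channel's printed gating row is internally corrupted: its
  activation α is negative over the physiological range as printed, and
  the printed inactivation pair opens with depolarization.  The package
  uses the Fohlmeister–Miller forms for this channel (the other nine
  printed entries match that model exactly).  Running the printed row
  verbatim (with only the sign fix its α needs to be a rate) yields a
  nearly inexcitable cell, so it cannot be what produced the published
  simulations either.

The opsin enters as a conductance density — whole-cell conductance divided
by the 1000 µm² reference membrane area — with the sign that makes
illumination depolarizing.  Every protocol starts from a dark-equilibrated
state: the autonomous system is integrated for 2000 ms from −65 mV (gates
at steady state, Ca at 1e−4 mM, photocycle fully dark-adapted), and the
endpoint — a stable rest near −61 mV that drifts < 0.1 mV over a further
2 s — seeds the run.  In darkness the photocycle stays exactly at C1 = 1,
so the equilibrium is opsin-independent and cached.

Spikes are upward 0 mV crossings with a 2 ms dead time, localized by linear
interpolation on the 0.02 ms output grid; the detector agrees with an
independent prominence-based peak finder on simulated traces.

## Numerics

Both right-hand sides are compiled (C, via deSolve's compiled-code
interface) with reference R implementations exported for inspection and
cross-checked against the compiled path in the tests.  Integration uses
lsoda with rtol 1e−8 / atol 1e−10 — the rate constants span five orders of
magnitude, so a stiff adaptive method is required — and restarts at every
stimulus edge so that flux discontinuities never cross a solver step.
Output is sampled at 0.02 ms for spike-timing work, coarser for
voltage-clamp metrics.  Everything is deterministic; repeated runs are
bitwise identical, and rerunning an experiment config reproduces its CSV
byte for byte.

Threshold searches (MIT, MIT100, minimum pulse width) do a decade pre-scan
followed by log-space bisection to 2% relative tolerance (thresholds are
meaningful to two significant figures), returning the upper bracket end so
the bracketing property holds: the returned value satisfies the criterion
and 0.9× it does not.  The 1:1 frequency limit searches irradiance per
frequency — first the lowest irradiance giving a spike on every 0.2 ms
pulse, then a short ladder of multiples probed for exactly one spike per
pulse — capped at the long-exposure retinal safety bound 0.77 mW/mm²
(a cap an order of magnitude lower leaves the fast low-sensitivity opsins
with no attainable 1:1 regime at any frequency).

## Problem sizes

Default analyses use 1 s pulses for rate/threshold work, 10-pulse trains
for fidelity, 5 s pulses for firing adaptation, a 10–150 Hz grid in 10 Hz
steps for the frequency limit, and quarter-decade irradiance grids for
rate plateaus.  These match the published protocols; all run in seconds to
a couple of minutes on one core thanks to the compiled right-hand sides.

## What reproduces, and what does not

With the band irradiance convention the package reproduces, without any
fitted or adjusted parameter:

* the reference photocurrents (white 79.4 pA, LED ~20.7 pA vs published
  20.8) and the fourfold white:LED ratio;
* every published ordering and ratio we tested: white < sunlight < LED
  thresholds, EPD50 lowest for white, white:LED MIT100 ratio (~5.3 vs
  published ~5.7), minimum-width ratio (~4.4 vs 4.0), hsChRmine needing
  2–3× ChRmine's irradiance, adaptation strongest for white, latency
  decreasing with irradiance and source-independent at saturation;
* the published statement that broadband firing begins at ~5e−6 mW/mm²
  (our white MIT: 5.7 nW/mm²).

Absolute RGN threshold values, however, sit a systematic ~2.2–2.7× above
the published ones (and the published abstract quotes a white MIT of
1.2 nW/mm², 4.8× below ours and inconsistent with the ~5e−6 mW/mm² figure
in the same paper's results text).  Equivalently, the published neuron
fires with ~0.25 µA/cm² of sustained opsin current where this
reconstruction needs ~0.8 µA/cm².  We verified the gap is not attributable
to the irradiance convention, the spike criterion, initialization, the
K(Ca) reversal choice, or any single viable reading of the printed A-type
K row; it appears to reflect an unprinted difference in the original
neuron implementation.  No parameter here was tuned to close it: all
constants are the printed ones, and the discrepancy is reported as
measured.

## Limitations

Single-compartment soma only (dendritic membrane would lower thresholds
further); no temperature or pH dependence of photocycle rates; no
stochastic channel gating (responses are noiseless, so "spike probability"
is deterministic per pulse); no eye-optics or photoreceptor-layer
modelling; colorimetric lux↔irradiance conversions are out of scope.  The
synthetic sunlight/lamp shapes capture peak position and bandwidth, not
fine spectral structure, so sunlight/lamp/RGB results should be read with
correspondingly more tolerance than LED/white ones.
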