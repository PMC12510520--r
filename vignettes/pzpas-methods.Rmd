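---
title: "Models and design choices in pzpas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in pzpas}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pzpas)
```

`pzpas` models a mid-infrared photoacoustic glucose sensor end to end: the
optics of layered skin, the acoustics that let a piezoelectric (PZT)
detector ride a standing-wave resonance, the synthesis of photoacoustic
spectra, a generator of realistic oral glucose tolerance test (OGTT)
datasets, and the discrimination pipeline that turns spectra into a
hyperglycaemia call. This vignette explains each model, its assumptions,
the tunable parameters and the choices made where the design was genuinely
open.

## Layered optics

Skin is reduced to two optical layers. The **stratum corneum** (the dead
outer layer, ~10–20 µm) attenuates the incoming light; the **interstitial
fluid** beneath it is the optically thick absorber that generates the
photoacoustic signal. In the 930–1200 cm⁻¹ band, water dominates
absorption, so each layer's effective absorption coefficient is

$$\mu_a(\nu) = w\,\mu_{a,\mathrm{water}}
  + \sum_k a_k \exp\!\left\{-\frac{(\nu - c_k)^2}{2\sigma_k^2}\right\},$$

with water fraction $w$, $\mu_{a,\mathrm{water}} = 817\ \mathrm{cm^{-1}}$,
and Gaussian bands (centre $c_k$, width $\sigma_k$, amplitude $a_k$, all in
cm⁻¹). The Gaussian profile is a modelling choice — any unimodal shape with
a local maximum at the centre would serve; Gaussian is the simplest.
Absorbance is **decadic** (Bel): $A = \mu_a t / \ln 10$. The $\ln 10$
conversion matters — it is what places the 10-µm/10 %-water and
20-µm/30 %-water stratum corneum bounds at 0.04 and 0.21 Bel, and it pairs
with the transmitted fraction $10^{-A}$.

Penetration depth is defined as $1/\mu_a$ and quoted in µm
($10^4/\mu_a$ for $\mu_a$ in cm⁻¹). For the wettest stratum corneum
($w = 0.3$) this gives 40.8 µm, the nominal ~40 µm operating depth. An
alternative reading — inverting the 0.21 Bel upper absorbance bound over
20 µm — gives 41.4 µm; both round to 40, and the reciprocal definition is
adopted because it is parameter-free. There is no scattering or radiative
transfer in the model: at these wavelengths absorption dominates, and the
package's argument is purely absorptive.

## Quarter-wave acoustics

A layer of thickness $t$ with sound speed $v$ supports thickness-direction
standing waves when $t = (2m+1)\lambda/4$, i.e. at

$$f_m = \frac{(2m+1)\,v}{4t}, \qquad m = 0, 1, 2, \ldots$$

For a 2-mm layer at $v = 1389\ \mathrm{m\,s^{-1}}$ the $m=1$ mode sits at
520.9 kHz; for 4 mm, $m=2$ gives 434.1 kHz. The package treats these
formula values as ground truth. (Measured peaks can drift when compression
changes the local sound speed — e.g. the $m=3$ mode of a 4-mm gel computes
to 607.7 kHz rather than an observed ~637 kHz — which is why
`estimateThickness()` exposes the inverse problem instead of hard-coding a
correction.)

The frequency response is a sum of Lorentzians sharing one quality factor
$Q$: $L_m(f) = 1/(1 + (2Q(f-f_m)/f_m)^2)$, scaled as
$\mathrm{baseline}\times(1 + \mathrm{gain}\sum_m L_m)$. No line-shape model
is dictated by the physics beyond "a damped resonator", so the minimal
single-$Q$ Lorentzian family is used. The default `resonance_gain = 3`
makes the on/off-resonance amplitude ratio 4, matching the enhancement
observed for a 2-mm gel; it is transducer- and coupling-specific and fully
configurable. Lateral (non-thickness) resonances are supported only as
user-supplied extra mode frequencies — there is no lateral geometry model.

Peak detection uses topographic prominence: a local maximum is reported
when its prominence exceeds `prominence_fraction` (default 0.1) of the
sweep's amplitude range. For $Q \ge 20$ and modes separated by more than a
few half-widths, this recovers the analytic $f_m$ to within one grid step
(a property the test suite checks across $Q$ and thickness).

Acoustic impedance mismatches are summarised by the scalar pressure
reflection coefficient $r = (Z_2 - Z_1)/(Z_2 + Z_1)$, used as an
upper-bound interface diagnostic only; there is no multilayer
transfer-matrix acoustics.

## Photoacoustic synthesis

For absorbers thicker than a few tens of micrometres, stronger absorption
confines the deposited heat to a thinner slab, so the heated volume — and
the thermoelastic amplitude — shrinks as $1/\mu_a$:

$$S(\nu) = c\;\frac{10^{-A_{\mathrm{top}}(\nu)}}{\mu_{a,\mathrm{bulk}}(\nu)}.$$

Two consequences drive everything downstream: absorption **peaks appear as
dips** in the spectrum, and a protein-banded cover layer (collagen-like,
bands at 1030/1080 cm⁻¹) superimposes its own dips on the glucose dips
(990/1110 cm⁻¹) of the bulk. The inverse law is taken as exactly
reciprocal — the underlying argument (heated volume ∝ 1/µₐ) is
qualitative, and no additive offset is identifiable from it. Top-layer
attenuation is applied once, on the way in: the return trip is acoustic,
not optical. Laser irradiance bookkeeping is the average power over the
1/e² spot area, $P/(\pi (d/2)^2)$ — 12 mW over a 1-mm spot gives
1.5 W cm⁻²; peak Gaussian irradiance would give roughly twice that and
does not reproduce the stated operating point.

## The synthetic OGTT generator

No public spectral dataset exists for this instrument class, so
`generateDataset()` is a first-class, tested module that emulates the
measurement campaign: a fasting subject drinks a glucose load; fingerstick
references are taken every 5 min for 2 h before and after; each record's
spectrum is synthesized from a two-layer skin sample whose glucose-band
amplitudes scale linearly with that record's glucose.

**Glucose curve.** Baseline 90 mg/dL; after ingestion
$g(t) = g_0 + \Delta g\,(t/t_p)^k e^{k(1 - t/t_p)}$ with $k = t_p/\tau$.
This gamma-like shape peaks exactly at $t_p$ (default 45 min, default
excursion $\Delta g = 70$ mg/dL, so the curve crosses the 140 mg/dL
threshold for a nontrivial stretch) and decays with time constant $\tau$
(default 40 min); for $\tau = t_p$ it reduces to the familiar
$(t/t_p)e^{1-t/t_p}$ form. The exponent generalisation exists solely to
give the decay time an independent role. Fingerstick noise is 2 mg/dL.
Records cycle through the curve day by day (49 records/day at the
defaults), with a per-day additive baseline drift standing in for
interday variation; labels apply the 140 mg/dL rule to the
trailing-3-point-averaged references (the smoothing is applied to the
glucose time series, not to spectra — a flagged ambiguity resolved this
way because the references are the noisier, clinically meaningful series).

**Effect size.** The glucose→band-amplitude coefficient (0.06 cm⁻¹ per
mg/dL) was set analytically so a 90→180 mg/dL excursion moves the
1110 cm⁻¹ dip by about 5 % of the spectrum's dynamic range — a small,
honest effect that keeps the classification problem nontrivial. No molar
absorptivity is available to pin this physically.

**Acquisition modes and noise.** Repositioning the probe between
measurements changes the illuminated spot and the acoustic coupling;
tissue inhomogeneity then alters the observed *band structure*, not just
the overall gain. The generator therefore distinguishes multiplicative
gain jitter (removed later by min–max scaling) from per-band amplitude
jitter (which survives preprocessing and genuinely degrades the model).
Defaults — additive noise 0.002 a.u. on a ~1 a.u. signal, gain jitter
1 %/5 %, band-amplitude jitter 2 %/10 % for fixed/repositioned — were
calibrated once so the generator reproduces the instrument's documented
behaviour: fixed-mode fivefold accuracy around 0.9 and a consistent
several-point drop under repositioning, mirroring the reported 85.3 % vs
77.3 % ordering. A subject-specific band-position shift (off by default)
provides a qualitative intersubject-variability knob.

What the generator does **not** emulate: the physiological blood↔ISF lag,
hydration/temperature covariates, drift within a measurement, and real
instrument line shapes. Passing tests demonstrate the pipeline's
correctness and its qualitative response to acquisition noise — not
clinical performance on human data.

## Preprocessing

The chain is fixed in order: laser-power normalisation (pointwise
quotient), min–max scaling to [0, 1] with extrema computed on the closed
window 970–1162 cm⁻¹, then restriction of the features to the closed
target window 1022–1148 cm⁻¹ (64 features on the 2 cm⁻¹ grid). Window
endpoints are inclusive by convention here, documented for bit-exactness.
Because the target window is contained in the scaling window, features are
guaranteed to lie in [0, 1]. A spectrum constant on the scaling window
raises an error rather than silently producing zeros — a flat spectrum
means a dead channel, and surfacing it beats imputing it.

## PLS-DA, Q² and validation

The classifier is a from-scratch univariate-response NIPALS PLS: per
component $w \propto X^\top y$ (unit norm), $t = Xw$,
$p = X^\top t/t^\top t$, $q = y^\top t/t^\top t$, deflate both $X$ and
$y$; the regression vector is $b = W(P^\top W)^{-1}q$ on centred data. At
full rank it reproduces ordinary least squares, and its predictions match
an independent PLS implementation — both are standing tests, not
assumptions. Degenerate deflation ($\|t\| \to 0$) stops extraction early
with a warning; requesting more components than the rank of centred $X$
is an error.

Numerical conventions, each deliberate:

- **Posterior** = the PLS prediction of the 0/1 response clipped to
  [0, 1]; ties at the 0.5 threshold go to class 1 (documented, arbitrary).
- **Glucose exactly 140 mg/dL** is class 0 (the rule is "above" the
  threshold).
- **Q²** uses the training-fold mean in TSS (strict out-of-sample
  convention): $Q^2 = 1 - \sum_i (y_i - \hat y_{-i})^2 / \sum_i (y_i -
  \bar y_{-i})^2$. Ties in the component count go to the smaller count.
- **Posterior→glucose** is the linear map onto 95–185 mg/dL. The midpoint
  0.5 then lands exactly on 140 mg/dL — an internal-consistency argument
  for the linear choice, which is a reconstruction rather than a published
  formula.
- **Fivefold CV** is stratified and seeded; fold-averaged and pooled
  accuracies are both reported since the convention is ambiguous.
- **Clarke zones** follow the original piecewise-linear definition; the
  if/else cascade makes assignment a total function on (0, 600]², verified
  on a 1-mg/dL lattice in the tests.

**Null calibration.** The chance-level check (random labels → accuracy
near 0.5, max Q² < 0.3) is run at 50/50 class balance. With the OGTT-shaped
label distribution (~25 % hyperglycaemic), the majority rate — what "chance"
means there — is ~0.75, so a balance-free band around 0.5 would be
unsatisfiable by construction; class balance is an exposed property of the
generator, not of the classifier under test.

## Problem sizes

The test suite and examples use the campaign-scale defaults throughout:
datasets of 80 records (two simulated days), 64 spectral features,
fivefold CV, component counts screened over 1–5, 20-seed sweeps for the
stochastic orderings and 50 random-label draws for the null — sizes at
which every property is stable under reseeding while the full suite runs
in well under a minute per file.

## Known limitations

- The inverse-proportionality law is asserted, not derived from a thermal
  PDE; thin-sample behaviour ($S \propto \mu_a t$) is available but unused
  by the generator.
- Acoustics is 1-D: no lateral modes, no transfer-matrix multilayers, no
  transducer electrical model.
- The generator's linear glucose→amplitude map and Gaussian bands are
  phenomenological; absolute concentrations are not identifiable, which is
  why the pipeline targets threshold discrimination, not regression.
- Intersubject variability is a single band-shift knob, not a population
  model.
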