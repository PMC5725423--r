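---
title: "Orientation selectivity through electrical synapses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Orientation selectivity through electrical synapses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinOS)
```

## The scientific problem

OFF orientation-selective (OS) retinal ganglion cells respond to dark
oriented stimuli: they fire at a low baseline in darkness, are completely
suppressed at light onset, and fire preferentially for gratings drifting
along one orientation. Unusually, their tuning is not built from oriented
chemical inhibition. Voltage-clamp dissection shows a small, flat-IV
(electrical, gap-junction) input that is orientation tuned — dipping below
baseline (net inward) in the preferred orientation — alongside a roughly
ten-fold larger chloride-mediated inhibition that is essentially untuned.
`retinOS` packages the quantitative machinery needed to analyse such
recordings and to test, in a model, whether the gap-junction input alone can
account for the spiking tuning: tuning statistics, morphometrics, IV-curve
analysis, a conductance-based leaky integrate-and-fire (LIF) model, and the
current-shuffling bootstrap. Because no raw recordings are deposited
anywhere, a synthetic-data module generates every input with the statistical
structure the recordings are described to have; all claims the tests make
are claims about that synthetic world.

## Tuning statistics

The selectivity index is the standard circular-variance vector sum: for
responses $R(\theta)$ at direction angles $\theta$,

$$\mathrm{OSI} = \frac{\left|\sum_\theta R(\theta)\,e^{2i\theta}\right|}
{\sum_\theta R(\theta)},$$

with the angle doubling dropped for the direction index (DSI). The preferred
angle is the complex phase over the order (mod 180° for orientation, 360°
for direction). `vector_sum_index()` refuses negative responses — inward
currents must be converted to magnitudes by the caller — and flags preferred
angles as unreliable below an index of 0.02 rather than omitting them.
Angles are degrees, counter-clockwise, 0° = the horizontal (nasal-temporal)
axis; orientations are stored mod 180. Cells are OFF OS when baseline
< 50 Hz and peak light-offset rate < 120 Hz (both strict; the 135 Hz display
boundary is available via an argument), and hOS/vOS by whether the preferred
orientation falls in [45°, 135°) (vOS) or not, the 45° boundary going to vOS
by the half-open convention.

`hodges_ajne_test()` implements the exact tail probability
$P(M \le m) = 2^{1-n}(n-2m)\binom{n}{m}$ for $m < n/3$ and Ajne's
large-sample form otherwise. `dip_statistic()` computes Hartigan's dip
directly from its definition — the smallest sup-norm distance between the
empirical CDF and any unimodal CDF — by bisecting over the band half-width
and checking, per candidate mode, whether a convex function fits the band to
the left and a concave one to the right (an atom is allowed at the mode; for
a mode inside a gap the junction point constrains both halves). This choice
avoids interpolation tables, is exact at small n, and is validated against
closed forms: two equal atoms give 1/4, an evenly spaced sample 1/(2n), a
point mass 0. `dip_test()` maps orientations to [0, 1) and simulates the
uniform null with a fixed seed.

## Morphometrics

Dendritic fields are summarized by a polygon outline resampled to 1000
perimeter points at uniform arc length. The default outline is the convex
hull; a radial angular-sweep outline (`alpha_outline`) is provided for
concave fields because no alpha-shape library is available in this
environment. Area and centroid come from the shoelace first-moment formulas;
the asymmetry vector runs from the soma to the centre of mass (a
ventrally-displaced vertical-type field has angle 270° in the package's
retinal convention). The dendritic orientation index (DOI) is the
orientation-doubled vector sum over centroid-to-perimeter vectors,
magnitude-weighted by default; the unweighted variant is available because
the original description does not state the weighting, and the two differ
little on realistic fields. Analyses are planar; stratification depth is out
of scope.

## Voltage-clamp analysis

Peak currents are signed extrema in stated windows (0–200 ms for the fast
inhibition-dominated onset component, 500–1000 ms for the sustained
gap-junction component). The IV line $I = g(V - E)$ is fitted by least
squares over all holdings (robust to noise; bracketing interpolation adds
nothing here), and a source is classified electrical when $|g|$ falls below
0.1 nS — an order of magnitude below the chemical slopes in the synthetic
regime — in which case the reversal potential is reported undefined.
Inhibition is isolated by subtracting the record at the chloride reversal
from the record at the cation reversal, and converted to a conductance by
dividing by the driving force. Spikes are removed from current-clamp records
with a centred 25 ms sliding average (250 samples at 10 kHz, shrinking at
the edges): a 2 ms action potential is attenuated more than ten-fold while
the 2 Hz grating oscillation loses only ~0.4% of its F1 (the sinc factor).

Electrochemical conventions: the Nernst potential at 305 K with 105 mM
external and 12 mM internal chloride (10 TEA-Cl + 2 QX-314, assumed chloride
salts) is −57.0 mV. Reported potentials are commanded values *plus* the
−8.58 mV liquid junction potential, so a −60 mV command reads −68.58 mV; the
correction direction is a package convention since only the magnitude is
stated by the source methods.

## The synthetic world

`gen_grating_currents()` emulates cycle-averaged grating responses with one
sinusoidal cycle at the 2 Hz grating frequency, half-wave biased: the
outward (light-phase) lobe has fixed amplitude at every angle (80 pA for the
gap-junction input, 757 pA for inhibition) and the inward (dark-phase) lobe
carries the orientation tuning. The real per-angle waveforms are nowhere
published numerically; this shape is a stand-in with the described
qualitative features, no more.

The tuning profile is constructed so the vector-sum index of the per-angle
inward-peak magnitudes equals the requested `osi_gj` *exactly* on the actual
angle grid. Below 0.3 the profile is the classic cosine
$(1 + m\cos 2\Delta\theta)/(1+m)$ (index = m/2 on a uniform grid); at and
above 0.3 it is the raised-cosine power $((1+\cos 2\Delta\theta)/2)^p$,
which is exactly zero at the null orientation so null cycles are everywhere
outward. The two requirements — index round-trip down to arbitrarily small
values and strictly outward null cycles — are mutually exclusive on a
12-direction grid (any profile with silent null directions has index at
least 0.2), which is why the family switches; 0.3 is the threshold at which
the outward-null property is required.

One free amplitude is not constrained by any published number: the inward
excursion depth at the preferred orientation. Its default, 120 pA, was
chosen once so that the default LIF cell fires at ~100 Hz during the
preferred dark phase and shows a model OSI near the recorded population
(~0.45); it is a calibration of the synthetic world to the paper-scale
behaviour, not a fitted quantity. Noise is opt-in (`noise_sd_pA = 0` by
default) so the stated examples are exact.

Light-step spike trains are inhomogeneous Poisson (thinning): baseline rate
before the step, zero during it, exponential recovery toward
baseline × (1 + overshoot) afterwards. IV families apply one Gaussian draw
per holding to the evoked amplitude, so the measured IV point is exactly
$g(V - E) + \varepsilon$; per-sample noise would bias windowed peaks toward
extreme excursions. Spot-size profiles are a difference of saturating
exponentials for inhibition (centre 80 µm, surround 500 µm, weight 0.8) and
a single saturating exponential (300 µm) for the gap-junction input — the
published description is qualitative, so these are illustrative shapes with
the right argmax structure.

## The integrate-and-fire model

$$\tau\frac{dV}{dt} = V_{\mathrm{rest}} - V(t) - R\,I_{\mathrm{ext}}(t),
\qquad
I_{\mathrm{ext}} = I_{\mathrm{gj}}(t) + (V - V_{\mathrm{rev,inh}})\,
g_{\mathrm{inh}}(t).$$

Outward current is positive and hyperpolarizes, so the outward gap-junction
lobe at light onset suppresses firing, as recorded. Spiking is
threshold/reset with the membrane time constant swapped to
$\tau_{\mathrm{refractory}}$ for a fixed 3 ms after each spike ("temporarily
increased" is all the source states; a fixed-duration swap is the simplest
faithful reading). Integration is forward Euler at 0.1 ms, in C++; the
subthreshold step response matches the exponential solution to within 0.2%
at dt = τ/100 and constant-drive inter-spike intervals match the closed form
(including the refractory segment) to within 2·dt.

Defaults: τ = 15 ms, R = 500 MΩ, V_rest = −60, V_th = −45, V_reset = −65,
τ_refractory = 45 ms, V_rev,inh = −67 mV. None of these are published for
these cells. R deserves a note: 100 MΩ with τ = 15 ms would imply a 150 pF
cell — far too large for these small ganglion cells — and would render the
tens-of-pA gap-junction currents invisible to a 15 mV threshold gap, leaving
the model silent everywhere. 500 MΩ (30 pF) is the physiologically sensible
scale at which the measured currents drive realistic firing.

## The shuffling bootstrap

Per draw, the per-angle cycle waveforms of one input type are randomly
permuted across grating angles (`shuffle_inh`, `shuffle_gj`, or both,
independently), the sweep is re-simulated, and the model OSI recorded;
`intact` is a single deterministic evaluation. "Bootstrapped 10,000 times"
is read as sampling permutations with replacement — the only reading
consistent with random permutation between angles. One master seed spawns
per-condition substreams so conditions are individually reproducible.

Because one angle's simulated spike count depends only on the waveform pair
assigned to it, the package precomputes the n × n spike-count matrix and
evaluates each draw by lookup — an exact shortcut that makes 10,000 draws
essentially free.

A structural fact worth understanding: under this design the shuffled
per-angle counts are *exactly* a permutation of the intact counts, so the
mean per-draw OSI under shuffling is a combinatorial functional of the
intact tuning curve, bounded below by roughly 0.38 × the intact OSI for
cosine-like curves (and by ~0.12 for any curve silent at the null
directions). Shuffling the gap-junction input therefore reduces the model
OSI several-fold (e.g. 0.44 → 0.17 in the default world) but cannot push
the *mean of per-draw OSIs* toward zero while the intact OSI stays large.
The OSI of the *draw-averaged* tuning curve, by contrast, does collapse to
~0.01, since averaging over permutations flattens the curve.
`bootstrap_osi()` reports both quantities; which one a given summary of
"average OSI under shuffling" refers to matters, and the package makes the
distinction explicit.

## What a green test establishes — and what it does not

The synthetic world reproduces the described *structure*: amplitudes, sign
conventions, tuning depths, OFF-step firing profiles, flat-vs-reversing IVs,
surround suppression, arbor asymmetries calibrated to the reported
145.5 µm / 50.1 µm centre-of-mass vectors. It does not emulate waveform
irregularity, cross-angle correlations, trial-to-trial variability of real
cycle averages, electrode artefacts, or any spatial receptive-field
structure (no grating convolution model). Model results are therefore
statements about the mechanism — inward gap-junction lobes are sufficient,
and their angular arrangement necessary, for the model's orientation
tuning — not re-measurements of any recorded value.

## Numerical choices and degenerate inputs

* Exact-zero response sums raise errors rather than returning NaN indices;
  fully silent sweeps report OSI 0 with an undefined preferred angle.
* `tuning_profile()` solves its exponent by `uniroot` to 1e-12 on the
  actual angle grid, so generator-metric round trips are exact to test
  tolerance by construction, for any grid on which the target is reachable
  (coarse grids cannot reach all indices; the error message says so).
* The dip bisection runs 45 halvings (≈3e-14 resolution); Monte-Carlo
  p-values use the (1 + exceedances)/(n_null + 1) estimator.
* Polygon resampling requires a non-degenerate perimeter; zero-area
  polygons and all-centroid outlines raise errors. Radial jagged noise
  keeps synthetic outlines simple by construction; if noise would drive the
  radius non-positive the generator halves it and warns.
* Seeds: every generator takes an explicit integer seed and restores the
  global RNG state (`withr::with_seed`); the pipeline derives per-cell,
  per-stage seeds from one master seed, making the 20-cell demo
  byte-reproducible.

## Known limitations

Config files are JSON only (no YAML parser exists in the target
environment). The shuffling analysis offers no inferential statistics beyond
means, SDs and deltas — the pairwise tests a report would add are standard
and deliberately out of scope. The LIF model is a point neuron: no
bidirectional coupling with the presynaptic amacrine cell, no dendritic
structure, no channel noise — so it cannot speak to where in the arbor the
electrical synapses act, only to what their currents suffice to produce.
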