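---
title: "How retinal waves build a concentric orientation map: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How retinal waves build a concentric orientation map: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scwavemap)
```

## The model in one paragraph

Before eye opening, the mouse retina generates spontaneous stage III waves of
activity in which OFF retinal ganglion cells (RGCs) fire about one second
after the ON cells, and the waves tend to propagate away from a localized
source of asymmetric inhibition.  `scwavemap` models a 40 x 40 lattice of
ON/OFF RGC pairs connected retinotopically to a 40 x 40 lattice of superior
colliculus (SC) neurons, refines the synaptic weights with Hebbian learning
under subtractive normalization while waves sweep the retina, and asks what
receptive fields (RFs) and what orientation-preference map (OPM) emerge.  Two
wave features carry all the structure: the OFF delay segregates each SC
neuron's ON and OFF subfields (creating orientation tuning), and the spatial
statistics of wave directions arrange the preferred orientations into a
concentric map whose singularity sits near the centre of vision.

## Wave generation

Each epoch simulates one wave.  An initiation pixel is drawn uniformly; a
source of asymmetric inhibition is drawn from an isotropic Gaussian of spread
`sigma_ai_um` centred on the nose position (the centre of vision, 250 um from
the anterior edge at the medial-lateral midline); the wave heading points
from the source to the initiation site, rounded to the nearest of the 8
lattice directions.  Propagation is stochastic: an active pixel attempts to
activate each Moore neighbour with probability derived from a truncated
Gaussian over the 8 neighbour angles, centred on the heading and with its
spread solved numerically (`optimize_sigma_prop`) so that the polar bias
index of the distribution equals the target bias `b = 0.35`.  A pixel
activates when at least `n_theta = 1` attempts succeed and its own refractory
interval (60 frames = 30 s) has elapsed; each activation lasts one frame,
and the epoch ends when no pixel is active.

Two readings of the probability scaling were examined.  Treating the scaling
constant `q = 2.4` as an exponent (`rho = p^(1/q)`) nearly flattens the
anisotropy of the neighbour probabilities (their bias drops to about 0.17)
and produces fans that saturate almost the whole lattice, whose flow field is
radial about the grid centre regardless of the heading statistics — the
map singularity then never tracks the inhibition source.  Treating it as a
scale (`rho = min(q p, 1)`, the default `rho_rule = "scale"`) preserves the
bias `b` exactly in the propagation probabilities and yields compact,
direction-following waves; only then do smaller inhibition spreads pull the
flow singularity towards the nose, which is the behaviour the model exists
to study.  Both rules are available in `wave_params()`.

With the refractory interval (60 frames) comparable to the grid traversal
time, a rare epoch re-enters previously recovered territory and spirals.
`propagate_wave()` treats an epoch exceeding 400 frames as an error by
default; `simulate_waves()` instead truncates such epochs at the cap and
counts them in the `n_truncated` attribute, so ensemble generation is total.

## RGC activity and noise

An activation drives a boxcar response kernel: firing rate `r` for
`t_wave_s = 1` s (two 0.5 s frames), delayed by `tau_on_s = 0` for the ON
channel and `tau_off_s = 1` s for the OFF channel.  The OFF movie is
therefore a frame-shifted copy of the ON movie — including the noise term,
because both channels share a single kernel.  Three noise modes are
implemented, all scaled by `gamma`:

* `"background"` (default): a Gaussian white-noise trace per pixel added to
  every frame of both channels, the OFF channel receiving the same trace
  delayed.  Rates are not clipped; the noise is zero-mean, so its variance
  in silent pixels is exactly `gamma^2`.
* `"background_clipped"`: as above with rates clipped at zero.  Clipping
  rectifies the noise into a positive offset whose spurious pairwise
  correlations are of the same order as the wave signal; the trained map is
  then markedly less noise-robust, which is why this is not the default.
* `"kernel"`: noise drawn only within active response kernels (the literal
  kernel equation), shared between the channels.

The shared (copied) noise trace matters: ON/OFF-independent noise injects
uncorrelated jitter directly into the difference `w_ON - w_OFF` that carries
all RF structure, and the map then loses its noise tolerance at 10-20%
noise.  With the copied trace the common-mode noise cancels in the
difference and the trained map's noise tolerance roughly triples: at the
problem sizes used here the map-mean LHI stays within 10% of its noiseless
value up to the 30% noise level and the map-mean gOSI up to the 20% level
(it sits at the 10% boundary at 30%), before both collapse steeply towards
the chance floor over the 40-60% levels.

## Plasticity

Weights from every in-arbor ON and OFF RGC (arbor radius 175 um, i.e. a
350 um integration-site diameter, 37 RGCs per polarity for an interior
neuron) start at `w0 = 0.1`.  Time is binned into trials — by default one
trial per epoch, since epochs are independent and the trial length is
otherwise a free parameter — and each trial applies the correlation-driven
update

\[
\Delta w_P(x,\alpha) = \eta\Big[\textstyle\sum_{\beta,P'} w_{P'}(x,\beta)\,
C_{P,P'}(\alpha,\beta) - \frac{\sum w\,C\,w}{2\sum_\gamma R(x,\gamma)}\Big],
\]

with \(C\) the trial-averaged products of presynaptic rates, followed by the
constraint that zeroes negative weights and shrinks positive ones
proportionally, conserving each neuron's signed total exactly.  The
subtractive term as defined does not itself conserve the total for arbitrary
weights: totals drift upward until the weighted mean weight approaches one.
The literal dynamics are the default; `conserve_total = TRUE` rescales each
neuron's total to its initial value after the constraint for users who want
strict homeostasis.  A neuron whose negative mass reaches its positive mass
has no nonnegative configuration with the same total and is zeroed with a
warning (this arises only for adversarial inputs, not in the model's own
dynamics).  The learning rate `eta = 0.01` is chosen so single-epoch deltas
are about 1% of `w0`; it is exposed in `learning_params()` and reported by
the experiment configs.  Optional multiplicative noise on each delta
(`plasticity_noise_sd`) and per-synapse update dropout (`update_dropout_p`)
model imperfect plasticity; both default to off.

The trial loop is compiled (Rcpp) using the algebraically equivalent
postsynaptic-trace form of the update; a test verifies the compiled path
against the literal R composition (`trial_correlations` +
`hebbian_update` + `constrain_weights`) to 1e-12.

## Receptive fields and map analysis

Each RGC's visual-field RF is a difference of Gaussians (centre spread 17
visual-field pixels, surround 3x wider with weight 1/5, 0.6 deg per pixel;
"width" is read as the Gaussian sigma), positive for ON and negative for
OFF.  An SC neuron's RF is the weight-weighted sum of its presynaptic RFs,
rendered on a +-60 pixel crop around the neuron's retinotopic position
(block matrix products over a cached kernel stack; the crop contains > 3.5
centre sigmas, and since the OFF kernel is the negated ON kernel the field
depends only on `w_ON - w_OFF`).

Orientation statistics come from the RF's Fourier amplitude spectrum, padded
to 128 x 128 and restricted to the inscribed Nyquist disc so every
orientation covers the same frequency range.  The preferred orientation is
the frequency-weighted double-angle resultant; the frequency-vector angle is
rotated by 90 degrees so that the reported angle is the stimulus (stripe)
orientation — a neuron with ON/OFF lobes displaced along an axis prefers
gratings orthogonal to that axis, which is what its tuning curve and the
orthogonality between preferences and wave flow require.  The tuning curve
samples the centred spectrum along the frequency ray of each of 8
orientations (bilinear interpolation, DC excluded); a wedge-binned sum was
rejected because almost all spectral mass of these smooth RFs lies within a
few frequency pixels of DC, where wedge pixel counts are badly unbalanced.
gOSI is the double-angle resultant of the tuning curve; tuning strength is
its maximum.

ON/OFF segregation is quantified both on the weights and on the rendered
subfields; the local homogeneity index (LHI) uses a 100 um Gaussian
neighbourhood and is normalised by the local weight mass so a uniform map
scores exactly 1 (the unnormalised Riemann sum is available with
`normalize = FALSE`).  The wave-flow field sums frame-to-frame displacements
of the activity centre of mass in 3 x 3 windows, skipping frame pairs with an
empty window and never crossing epochs; the map singularity is the argmin of
the flow magnitude after a 2-pixel Gaussian smoothing, with ties resolved by
the centroid of the tied set.

## The experiments

* `run_single_neuron_sweep()`: OFF delay (0-3.5 s) by heading-bias sweep for
  the central neuron, waves sampled from a discrete von Mises ensemble over
  the 8 headings (concentration solved so the polar bias index matches the
  target) and initiated 15 pixels from the neuron against the heading.
  Rasters are independent of the OFF delay and are shared across the delay
  column of each (bias, seed) cell.
* `run_map_regimes()`: (A) rate-matched i.i.d. activations with
  per-activation random ON/OFF order, (B) uniform waves (2000 um inhibition
  spread) with per-wave OFF delay drawn from {-2, ..., +2} s, (C) uniform
  waves with the 1 s OFF delay, (D) biased waves (50 um spread) with the 1 s
  delay.  Regime B preserves more map smoothness than a fully random regime
  because orientation is invariant to an ON/OFF sign flip; the orderings
  C > A and C > B in LHI still hold.
* `run_ai_spread_sweep()`: the 13 inhibition spreads from 5 to 3000 um;
  heading bias falls monotonically with spread and the singularity-to-nose
  distance falls with bias.
* `run_noise_sweep()`: noise fractions 0-100% with `r + gamma = 1`, each
  level trained on the same wave sets across levels (a paired design with a
  fixed seed set) and averaged over seed replicates.

## Problem sizes, determinism, and what the tests do not show

Full-scale development involves roughly 57,600 stage III waves (about five
days at eight waves per minute).  The package's default experiment sizes are
2,000 waves for map experiments and 400 (200 in the shipped acceptance
sweep, 5 seeds) for single-neuron experiments — sizes at which every
qualitative result above is stable and a full noise sweep completes in
minutes on one CPU; the wave count is configurable up to the full-scale
setting.  All randomness flows from a single integer seed through
`derive_seed()`; runs are bit-reproducible, and the compiled core uses its
own deterministic generator seeded from R.

The synthetic waves emulate lattice geometry, direction statistics, the
ON/OFF temporal order, and refractoriness of stage III waves.  They do not
emulate biophysics (no starburst-amacrine mechanism — the inhibition source
is sampled, not simulated), retinotopic imprecision, RGC type diversity,
eye-specific competition, or spherical visual-field geometry; the retina, SC
and visual field are related by the identity map plus a scale factor.
Passing tests therefore show that the two wave features are *sufficient* in
this idealised setting, not that they are the mechanism in vivo.

Array archives are deliberately plain text: per-neuron map summaries export
to fixed-schema CSV (`write_map_csv`), configurations and manifests to YAML.
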