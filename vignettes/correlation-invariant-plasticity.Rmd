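---
title: "Correlation-invariant synaptic plasticity: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation-invariant synaptic plasticity: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model family

A rate neuron `y = (w'x)_+` receives `N` inputs through weights `w`.
Classical Hebbian learning with nonlinear LTP, `dw ~ x y^(p-1)`, aligns
`w` with directions of large variance: second-order input correlations
dominate and sparse (super-Gaussian) latent features are lost. The rule
family implemented here adds *linear* Hebbian LTD gated by a homeostatic
factor:

    dw = eta * ( x y^(p-1) - h_y * x y ),      h_y = <y^r>

For any `p > 2` and `r > p - 2` this is a stable stochastic ascent on the
*normalized* sparsity objective `< (y / sigma_y)^p >` with
`sigma_y = sqrt(<y^2>)`. Because the objective only depends on the
normalized output, it is invariant to any invertible linear transformation
of the input: whitening, channel-wise rescaling, or mixing. The LTD term
is exactly the "anti-PCA" correction: at the homeostatic equilibrium it
cancels the sensitivity of the LTP term to the input covariance, in both
the radial (norm) and tangential (selectivity) directions.

Special cases and controls provided by `rule_config()`:

* `corr_invariant` — `p = 3, r = 2`: quadratic LTP, `h_y = <y^2>`
  (a rectified-linear BCM rule).
* `kurtosis_bcm` — `p = 4, r = 3`: cubic LTP, `h_y = <y^3>`.
* `oja_heterosyn` — `dw = eta (x y^2 - w y^2)`: same nonlinear LTP but
  *heterosynaptic* (weight-proportional) LTD. Stable, but not
  correlation-invariant: it converges to high-variance directions.
* `oja_linear` — the linear Oja rule (leading principal component).
* `norm_constrained` — nonlinear Hebbian LTP with explicit weight
  normalization, the classical sparse-coding baseline.

Two analytic consequences are used as test oracles: with the *balancing*
factor `h* = <y^p>/<y^2>` the radial drift `<w' dw>` vanishes exactly
(indifferent stability), and with the running `h_y = <y^r>` the converged
norm satisfies `|w| = (<x_w^p> / (<x_w^r> <x_w^2>))^(1/(r-p+2))` where
`x_w` is the rectified input projection on the converged direction.

## Input generators and what they emulate

All experiments run on synthetic inputs; nothing is downloaded.

* **Grouped rate inputs** (`gen_selectivity_dataset()`): a sparse ON/OFF
  group (ON duration 100 ms, exponential inter-stimulus intervals with
  mean 1 s, unit ON amplitude), an Ornstein-Uhlenbeck "network" group
  (sd 1.2, 200 ms), and white-noise channels (sd 2.2), 20 channels per
  group, 1 sample = 1 ms, all channels mean-subtracted. The sparse group
  carries the *smallest* variance but the only non-Gaussian structure.
  The per-channel noise on the signal-carrying groups is not specified in
  the reference setting; 0.1 is used.
* **Amplitude / noise subgroup datasets** (`gen_subgroup_dataset()`): the
  sparse channels split into three subgroups (7/7/6). In the amplitude
  variant the common-component sds are 1.5/1.0/0.7 with noise scaled
  proportionally (equal per-channel SNR); in the noise variant the signal
  sd is 1.0 everywhere and the noise sds are 1.5/1.0/0.7. Two Gaussian
  distractor groups are appended. Here the subgroup amplitudes are
  *standard deviations* of the common component — the variance-following
  control rule can then express its weight-proportional-to-amplitude
  behaviour, which would be impossible if the sparse subgroups were
  variance-starved.
* **Circular population code** (`gen_population_dataset()`): a latent on
  the circle `[0,1)` driving 100 evenly spaced Gaussian tuning curves
  (width 0.05, additive noise 0.01). The latent is a Gaussian random walk
  smoothed with a 100 ms exponential filter and wrapped modulo 1; the
  walk increment sd (0.01, a free parameter of the model description) was
  chosen once so that the latent's occupancy histogram is close to
  uniform within a few times `1e5` samples while the motion stays slow
  relative to the tuning width. Heterogeneous populations multiply each
  input's width, amplitude and noise by independent log-normal factors
  (log-sd 0.2). Wrapped Gaussians are truncated at three periods
  (error < 1e-8 for widths <= 0.2).
* **Correlated image patches** (`gen_image_patches()`): a Gaussian field
  with `1/f` amplitude spectrum (strong neighbour-pixel correlation) plus
  a Poisson number (mean 1.5) of oriented line segments per patch (sparse
  higher-order structure). The generator has unit *expected* pixel
  variance but individual patches keep their contrast fluctuations —
  deliberately, since patch-to-patch contrast variation is what gives
  untuned spiking neurons the response kurtosis that sustains triplet LTP
  early in development; per-patch normalisation (which the generator does
  *not* do) would remove it. Patches are mean-subtracted and split into
  rectified ON/OFF Poisson rates (100 Hz per unit amplitude, saturating
  at 500 Hz). These patches emulate the second-order spatial correlations
  and sparse oriented structure of natural scenes, not their full
  statistics: there is no scale mixture, no occlusion geometry, and the
  segment process is isotropic. Passing tests therefore demonstrate the
  mechanisms, not performance on real images.

## Training protocol

Mini-batches of 100 samples are drawn i.i.d. with replacement (temporal
order is deliberately destroyed; no online mode), the homeostatic EMA is
updated before each weight step with an effective window of
`tau_h = 200` *samples* (so the per-batch coefficient is
`batch_size / tau_h`), and the update is applied through Adam
(lr 0.003, standard moment defaults). Two deliberate choices deserve
emphasis:

* **Initialisation.** Weights start at `N(0, 1/N)` so the initial output
  activity is O(1) and the weight norm starts *below* the rule's
  equilibrium. From there learning is LTP-led and selects the sparse
  direction within a few thousand steps. Unit-variance initialisation
  (available via `init_sd = 1`) puts the norm far above equilibrium; the
  LTD-dominated shrinking transient then buries the weight mass in
  near-null noise directions and escaping the resulting Gaussian plateau
  takes two orders of magnitude more optimizer steps than any desk-scale
  budget.
* **Converged weights.** Adam maintains a stationary per-coordinate
  exploration noise of order lr. Where weight values are compared against
  analytic predictions or decoders, `tail_averaged_w()` (mean over the
  last half of the recorded trajectory) is used as the estimator of the
  converged solution.

Convergence is declared by a fixed sample budget, not a tolerance. Desk
budgets used by the packaged experiments: `2e5` samples for the
selectivity experiment, `1.5e6` for the subgroup decoding experiments
(where the comparison against the OLS decoder is tight), `3e5` for the
population network, `2e4` patches (2000 s) for the spiking network.

## Population network

Sixteen output neurons with feedforward plasticity (correlation-invariant
or heterosynaptic, plus weight decay 0.001) and all-to-all recurrent
inhibition. Per sample the recurrent dynamics `y <- (W x + W_rec y)_+`
run for 10 iterations from zero. The inhibitory rule is covariance-like
with target `theta = 1`, rate 0.03 and decay 1.0, clipped to non-positive
weights with zero diagonal; the decay acts multiplicatively *toward zero*
(`-eta_rec * lambda_rec * w`) — the only reading under which the rule is
stable for inhibitory (negative) weights. Feedforward and inhibitory
updates are applied concurrently per mini-batch; the recurrent iteration
is the plain fixed-point map (no damping was needed at these parameters).

Evaluation freezes the trained state and bins the network's responses
over the latent into 64 bins. Tuning width is full width at half maximum
with the curve minimum as baseline and linear interpolation between bins,
circularly. Linear Fisher information uses central-difference slopes and
per-bin response covariances augmented by the slope outer product times
the within-bin latent variance, with a global diagonal floor of 5% of the
mean response variance. The augmentation makes the estimator consistent
with its own resolution — it cannot report more information than the
bin-discretised latent carries (`12 n_bins^2`, about `4.9e4` at 64 bins)
— and the global floor prevents divergent contributions from neurons that
are silent (zero sampled variance) inside a bin while their cross-bin
slope is nonzero. This is one defensible choice among several; linear FI
magnitudes should be compared only between runs using the same estimator.

## Spiking network

ON/OFF Poisson inputs drive leaky integrate-and-fire neurons
(rest/reset -65 mV, threshold -50 mV, membrane 15 ms, dt 1 ms) through
non-negative weights; a tonic negative current tracking each channel's
firing-rate estimate (200 s EMA) cancels the mean input drive.
Excitatory synapses follow minimal triplet STDP with linear LTD:
potentiation at postsynaptic spikes proportional to the postsynaptic
trace times the presynaptic trace, depression at presynaptic spikes
proportional to the slower postsynaptic trace and to the homeostatic
factor `h_y = <y>^2` (squared 200 s rate estimate), plus weight decay;
all traces are unitless (jump 1 per spike, 30 ms). The heterosynaptic
variant replaces linear LTD by weight-proportional depression
`w * h_y`. Weights are clipped to `[0, w_max]`; the upper bound is
required because triplet LTP alone is unstable.

The published constants (`eta = 1e-4`, `tau_h = 200` s, decay 0.05/s)
are the `triplet_params()` defaults and are sized for developmental runs
of order `1e5` seconds. The packaged desk-scale experiment compresses
time: `eta_plus = eta_minus = 5e-4`, `tau_h = 10` s, decay 0.005/s, and
an LTD scale constant (0.01 for linear LTD, 0.1 for the heterosynaptic
variant — the constant that bridges `h_y`'s rate-squared units into the
update) calibrated so that output rates settle in the 5-20 Hz band over a
2000 s run. The rate estimate initialises at 2 Hz: starting it high makes
the quadratic homeostatic penalty crush the weights into the absorbing
silent state before the slow homeostat can relax. Receptive fields are
read out as ON-minus-OFF weight maps; localization is the maximal energy
fraction in a `(patch/4)^2` window.

## Degenerate inputs and numerical guards

Rectifier output at exactly zero contributes to neither LTP nor LTD.
Zero-length batches are valid for the generators (metadata only). The
trainers abort with a diagnostic when any weight magnitude exceeds `1e6`
(the signature of `r <= p - 2` misuse or an oversized learning rate).
Whitening refuses rank-deficient covariances unless a pseudo-inverse is
requested, and reports the rank. The FWHM of a flat curve is an error,
and a curve above its half level everywhere reports width 1.

## Known limitations

* The correlation-invariance property is asymptotic in the learning rate;
  at lr 0.003 the converged direction carries Adam noise of a few percent,
  which is why the invariance check compares output time series rather
  than raw weight vectors.
* The control (heterosynaptic) population network reproduces the
  qualitative width ordering but measures ~0.13 rather than 0.17 mean
  FWHM at these parameters, and the width-weight correlation of the
  invariant rule on heterogeneous inputs is stronger (more negative) than
  the reference value; both depend on the unstated activity scale
  relative to the inhibitory target.
* Linear Fisher information at these noise levels is resolution-limited;
  its absolute scale is an estimator property, and the small
  control-versus-invariant ordering difference is not reproduced reliably.
* The spiking results are demonstrated at a reduced scale (8 neurons,
  8x8 patches); full-size runs are supported by the same code but not by
  the packaged experiment budgets.
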