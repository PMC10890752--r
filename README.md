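# corrinv

Simulation and analysis tools for **correlation-invariant synaptic
plasticity**: Hebbian learning rules in which nonlinear long-term
potentiation (LTP) is balanced by *linear* Hebbian long-term depression
(LTD) through a homeostatic metaplasticity factor.

## The scientific problem

Cortical neurons are thought to develop their receptive fields by aligning
synaptic weights with sparse latent features of their input. Plain
nonlinear Hebbian learning cannot do this in realistic conditions: input
channels have diverse amplitudes, noise levels and second-order
correlations, and variance-driven plasticity locks onto the largest
covariance direction (a PCA-like outcome) instead of the sparse feature.
The rule family implemented here,

    dw = eta * ( x y^(p-1)  -  h_y * x y ),        h_y = <y^r>,

for a rectified linear neuron `y = (w'x)_+`, with `p > 2` and
`r > p - 2`, performs stochastic ascent on the *normalized* sparsity
objective `<(y/sigma_y)^p>`. The normalization makes the objective — and
hence the learned feature — invariant to any invertible linear
transformation of the input. The linear-in-`y` LTD term is the essential
ingredient: at the homeostatic equilibrium it cancels exactly the LTP
term's sensitivity to the input covariance. Heterosynaptic
(weight-proportional) LTD, as in the Oja rule, stabilises learning but
does not confer this invariance, and is included as the control.

The package provides, for this rule family and its controls:

* seeded generators for grouped sparse/Gaussian rate inputs, circular
  tuning-curve populations and spatially correlated synthetic image
  patches (`gen_selectivity_dataset()`, `gen_subgroup_dataset()`,
  `gen_population_dataset()`, `gen_image_patches()`);
* single-neuron training with Adam/SGD (`train_neuron()`);
* a recurrently inhibited 16-neuron population-coding network with
  concurrent inhibitory plasticity (`train_population()`);
* a spiking leaky integrate-and-fire network with triplet STDP (linear or
  heterosynaptic LTD) and an input-mean-cancellation current
  (`run_development()`, C++ core);
* analysis metrics: ZCA whitening, output SNR against the optimal linear
  decoder, tuning-curve estimation, FWHM, linear Fisher information,
  width-weight correlation, receptive-field localization;
* figure-level experiment drivers (`run_experiment()`).

## Worked example

A single neuron on the three-group benchmark: 20 channels sharing a weak
sparse ON/OFF signal, 20 sharing a stronger Gaussian Ornstein-Uhlenbeck
"network" signal, 20 of large-amplitude white noise.

```r
library(corrinv)

batch <- gen_selectivity_dataset(2e5, seed = 1)
fit <- train_neuron(batch, rule_config("corr_invariant"),
                    train_config(n_samples = 2e5, seed = 1))
round(group_projection(fit$final_state$w, batch), 3)
#>  sparse network   noise
#>   0.962  -0.015  -0.004
```

The correlation-invariant rule puts 96% of the (normalized) weight vector
on the sparse group's signal direction even though that group has the
*smallest* variance; `rule_config("oja_heterosyn")` on the same data
converges to the network group instead (projection ~1.0 there). The
converged weight norm is itself predicted by the input statistics:

```r
w <- fit$final_state$w
sqrt(sum(w^2))                                        # 2.79
predicted_weight_norm(w / sqrt(sum(w^2)), batch$data) # 3.05
```

Population and spiking experiments run the same way through the driver:

```r
run_experiment("population", scale = "desk", seeds = 1:3)
run_experiment("spiking_rf", scale = "desk", seeds = 1)
```

An equivalent shell entry point is installed at
`inst/scripts/corrinv-run.R`.

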