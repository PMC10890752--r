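#' Leaky integrate-and-fire neuron parameters
#'
#' @param v_rest resting potential, mV (default -65).
#' @param v_threshold spike threshold, mV (default -50).
#' @param v_reset post-spike reset, mV (default -65).
#' @param tau_mem membrane time constant, ms (default 15).
#' @param dt integration step, ms (default 1; must satisfy
#'   `dt <= tau_mem / 5`).
#' @return an object of class `"lif_params"`.
#' @export
lif_params <- function(v_rest = -65, v_threshold = -50, v_reset = -65,
                       tau_mem = 15, dt = 1) {
  stopifnot(v_reset <= v_rest, v_rest < v_threshold, dt > 0)
  if (dt > tau_mem / 5) stop("dt too coarse: require dt <= tau_mem / 5")
  structure(list(v_rest = v_rest, v_threshold = v_threshold,
                 v_reset = v_reset, tau_mem = tau_mem, dt = dt),
            class = "lif_params")
}

#' Triplet STDP parameters
#'
#' LTP requires one presynaptic and two postsynaptic spikes (through the
#' traces `xbar_plus` and `ybar_plus`); LTD is linear in pre- and
#' postsynaptic activity (`x(t) * ybar_minus`) and scaled by the
#' homeostatic factor `h_y = <y>^2` (squared EMA of the output rate in Hz).
#' The `heterosyn_ltd` variant replaces linear LTD by weight-proportional
#' depression `w * h_y`.
#'
#' @param eta_plus LTP amplitude per triplet event (default 1e-4).
#' @param eta_minus LTD amplitude (default 1e-4).
#' @param lambda_decay weight decay per second (default 0.05).
#' @param trace_tau time constant of the spike traces, ms (default 30).
#' @param tau_h homeostatic rate-estimate time constant, s (default 200).
#' @param variant `"linear_ltd"` or `"heterosyn_ltd"`.
#' @param ltd_scale dimensionless multiplier on the LTD term (default 1).
#'   Spike traces are rate estimates in Hz (an exponential filter of the
#'   spike train with gain `1/trace_tau`), which makes the printed
#'   `eta_plus`, `eta_minus` and `lambda_decay` mutually commensurate
#'   without extra unit constants.
#' @param w_max upper bound on excitatory weights (default 2).
#' @return an object of class `"triplet_params"`.
#' @export
triplet_params <- function(eta_plus = 1e-4, eta_minus = 1e-4,
                           lambda_decay = 0.05, trace_tau = 30, tau_h = 200,
                           variant = c("linear_ltd", "heterosyn_ltd"),
                           ltd_scale = 1, w_max = 2) {
  variant <- match.arg(variant)
  stopifnot(trace_tau > 0, tau_h > 0, w_max > 0)
  structure(list(eta_plus = eta_plus, eta_minus = eta_minus,
                 lambda_decay = lambda_decay, trace_tau = trace_tau,
                 tau_h = tau_h, variant = variant, ltd_scale = ltd_scale,
                 w_max = w_max),
            class = "triplet_params")
}

#' One leaky integrate-and-fire step
#'
#' `v <- v + dt/tau_mem * (v_rest - v) + input`; neurons at or above
#' threshold emit a spike and reset.
#'
#' @param v membrane potentials (mV).
#' @param input_current input per neuron for this step (mV).
#' @param params a [lif_params()].
#' @return list with updated `v` and logical `spike`.
#' @export
lif_step <- function(v, input_current, params) {
  v <- v + params$dt / params$tau_mem * (params$v_rest - v) + input_current
  if (any(!is.finite(v))) stop("non-finite membrane potential")
  spike <- v >= params$v_threshold
  v[spike] <- params$v_reset
  list(v = v, spike = spike)
}

#' Poisson spike raster
#'
#' Independent Bernoulli(`rate * dt`) spikes per channel and step.
#'
#' @param rates vector of rates in Hz (>= 0).
#' @param duration_ms raster duration.
#' @param dt step in ms (default 1).
#' @param seed integer seed.
#' @return logical matrix, steps x channels.
#' @export
poisson_encode <- function(rates, duration_ms, dt = 1, seed = 1) {
  stopifnot(all(rates >= 0))
  p <- rates * dt / 1000
  if (any(p > 1)) stop("rate * dt exceeds 1 spike per step; decrease dt")
  steps <- round(duration_ms / dt)
  local_seed(seed, {
    matrix(runif(steps * length(rates)) < rep(p, each = steps),
           steps, length(rates))
  })
}

#' One triplet-STDP weight update step
#'
#' Reference (single-step) implementation of the excitatory update used in
#' the development loop: per step,
#' `dW = eta_plus * y * ybar_plus * xbar_plus'
#'       - eta_minus * ltd_scale * h_y * ybar_minus * x'
#'       - lambda * W * dt_s`,
#' with spikes as 0/1 indicators, traces as rate estimates in Hz, and
#' weights clipped to `[0, w_max]`. For `heterosyn_ltd` the LTD term is
#' `eta_minus * ltd_scale * h_y * W * dt_s`.
#'
#' @param W `M x C` excitatory weight matrix.
#' @param pre_spikes 0/1 vector of presynaptic spikes (length `C`).
#' @param post_spikes 0/1 vector of postsynaptic spikes (length `M`).
#' @param traces list with `xbar_plus` (length `C`), `ybar_plus`,
#'   `ybar_minus` (length `M`, all in Hz) evaluated just before the
#'   current post spikes, and `h_y` (length `M`, Hz^2).
#' @param params a [triplet_params()].
#' @param dt step in ms.
#' @return the updated weight matrix.
#' @export
triplet_update <- function(W, pre_spikes, post_spikes, traces, params, dt = 1) {
  dts <- dt / 1000
  ltp <- params$eta_plus * (post_spikes * traces$ybar_plus) %o% traces$xbar_plus
  ltd <- if (params$variant == "linear_ltd") {
    params$eta_minus * params$ltd_scale *
      (traces$h_y * traces$ybar_minus) %o% pre_spikes
  } else {
    params$eta_minus * params$ltd_scale * traces$h_y * W * dts
  }
  W <- W + ltp - ltd - params$lambda_decay * W * dts
  pmin(pmax(W, 0), params$w_max)
}

#' One inhibitory STDP step
#'
#' Symmetric covariance rule with decay on the non-positive recurrent
#' weights: potentiation of inhibition (more negative weight) when pre- or
#' postsynaptic activity exceeds the target `theta`, relaxation toward
#' zero otherwise.
#'
#' @param W_inh `M x M` non-positive inhibitory weight matrix (entry
#'   `[i, j]`: synapse from neuron `j` to neuron `i`).
#' @param pre_spikes,post_spikes 0/1 spike vectors (length `M`).
#' @param traces list with `xbar` (presynaptic trace) and `ybar`
#'   (postsynaptic trace), both length `M`, in Hz.
#' @param eta learning rate (default 0.001).
#' @param theta target activity (default 0.003).
#' @param lambda decay per second (default 3).
#' @param dt step in ms.
#' @return the updated inhibitory weight matrix (non-positive, zero
#'   diagonal).
#' @export
inhibitory_stdp_update <- function(W_inh, pre_spikes, post_spikes, traces,
                                   eta = 0.001, theta = 0.003, lambda = 3,
                                   dt = 1) {
  dts <- dt / 1000
  drive <- (post_spikes - theta * dts) %o% traces$xbar +
    (traces$ybar - theta) %o% pre_spikes
  W_inh <- W_inh - eta * drive - lambda * W_inh * dts
  W_inh <- pmin(W_inh, 0)
  diag(W_inh) <- 0
  W_inh
}

#' Spiking receptive-field development
#'
#' Runs the full development loop: each patch is presented for
#' `sample_duration_ms`, encoded as ON/OFF Poisson spikes, integrated by
#' leaky integrate-and-fire output neurons with an input-mean-cancellation
#' current (a negative current tracking each channel's firing-rate
#' estimate, time constant 200 s), while excitatory weights follow triplet
#' STDP and, optionally, recurrent inhibitory weights follow the
#' inhibitory STDP rule. The inner loop is implemented in C++.
#'
#' @param patches output of [gen_image_patches()].
#' @param n_neurons number of output neurons (default 64).
#' @param triplet a [triplet_params()].
#' @param lif a [lif_params()].
#' @param lateral_inhibition enable recurrent inhibitory plasticity.
#' @param seed integer seed.
#' @param w_init_max excitatory weights initialised uniform on
#'   `[0, w_init_max]` (default 1; with the default patch rate scale this
#'   yields initial output rates of a few Hz).
#' @param init_rate_hz initial value of the output-rate estimate feeding
#'   the homeostatic factor (default 2 Hz). Starting the estimate low lets
#'   triplet LTP differentiate channels before homeostatic LTD reaches
#'   full strength, mirroring the low-activity initialisation of the rate
#'   trainers; a high initial estimate triggers an LTD-dominated collapse
#'   that the slow (200 s) homeostat cannot correct.
#' @param inhib_eta,inhib_theta,inhib_lambda inhibitory rule constants.
#' @param record_rate_every record the population mean rate every this many
#'   patches (0 disables).
#' @return list of class `"spiknet_result"`: `W_exc`, `W_inh`, `rates`
#'   (per-neuron rate estimates, Hz), `rf_maps` (list of ON-minus-OFF
#'   square maps), `rate_trace`, and the parameter objects.
#' @export
run_development <- function(patches, n_neurons = 64,
                            triplet = triplet_params(),
                            lif = lif_params(),
                            lateral_inhibition = FALSE, seed = 1,
                            w_init_max = 1, init_rate_hz = 2,
                            inhib_eta = 0.001, inhib_theta = 0.003,
                            inhib_lambda = 3, record_rate_every = 100) {
  s <- patches$spec$patch_size
  C <- 2L * s * s
  rates <- cbind(patches$on, patches$off)  # n_patches x C, Hz
  if (max(rates) * lif$dt / 1000 > 1) {
    stop("rate * dt exceeds 1; decrease rate_scale or dt")
  }
  res <- local_seed(seed, {
    run_development_cpp(rates, as.integer(n_neurons),
                        as.integer(round(patches$spec$sample_duration_ms / lif$dt)),
                        lif$dt, lif$v_rest, lif$v_threshold, lif$v_reset,
                        lif$tau_mem,
                        triplet$eta_plus, triplet$eta_minus,
                        triplet$lambda_decay, triplet$trace_tau,
                        triplet$tau_h, triplet$ltd_scale,
                        triplet$variant == "heterosyn_ltd", triplet$w_max,
                        lateral_inhibition, inhib_eta, inhib_theta,
                        inhib_lambda, w_init_max, init_rate_hz,
                        as.integer(record_rate_every))
  })
  n_pix <- s * s
  rf_maps <- lapply(seq_len(n_neurons), function(m) {
    matrix(res$W_exc[m, 1:n_pix] - res$W_exc[m, (n_pix + 1):C], s, s)
  })
  structure(list(W_exc = res$W_exc, W_inh = res$W_inh, rates = res$rates,
                 rf_maps = rf_maps, rate_trace = res$rate_trace,
                 ltp_trace = res$ltp_trace, ltd_trace = res$ltd_trace,
                 triplet = triplet, lif = lif,
                 lateral_inhibition = lateral_inhibition),
            class = "spiknet_result")
}
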