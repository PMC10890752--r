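#' Specification of one input group
#'
#' Describes a group of input channels that share a single latent component
#' (a sparse ON/OFF signal or an Ornstein-Uhlenbeck process) or carry pure
#' white noise. Channels within a group receive the common component with
#' equal loading plus independent Gaussian noise.
#'
#' @param name label for the group.
#' @param n_inputs number of channels (>= 1).
#' @param process one of `"sparse_on_off"`, `"ou"`, `"white_noise"`.
#' @param signal_sd standard deviation of the common component
#'   (dimensionless activity units); ignored for `"white_noise"`.
#' @param noise_sd per-channel independent Gaussian noise sd.
#' @param timescale_ms process time constant: the mean inter-stimulus
#'   interval for `"sparse_on_off"`, the relaxation time for `"ou"`.
#'   One sample corresponds to 1 ms.
#' @param on_duration_ms duration of each ON state for `"sparse_on_off"`.
#' @return an object of class `"group_spec"`.
#' @export
group_spec <- function(name, n_inputs, process = c("sparse_on_off", "ou", "white_noise"),
                       signal_sd = 1, noise_sd = 0.1, timescale_ms = 1000,
                       on_duration_ms = 100) {
  process <- match.arg(process)
  stopifnot(n_inputs >= 1, signal_sd >= 0, noise_sd >= 0)
  if (process != "white_noise" && timescale_ms <= 0) {
    stop("timescale_ms must be positive")
  }
  structure(list(name = name, n_inputs = as.integer(n_inputs), process = process,
                 signal_sd = signal_sd, noise_sd = noise_sd,
                 timescale_ms = timescale_ms, on_duration_ms = on_duration_ms),
            class = "group_spec")
}

# ---- elementary processes ---------------------------------------------------

#' Sparse ON/OFF input group
#'
#' All channels share one binary latent signal with ON states of fixed
#' duration and exponentially distributed inter-stimulus intervals; the ON
#' amplitude is `spec$signal_sd` (the sparse signal's amplitude parameter;
#' with duty cycle `q` the centred component has sd
#' `signal_sd * sqrt(q (1 - q))`). Independent Gaussian noise is added per
#' channel and channels are mean-subtracted.
#'
#' @param n_samples number of 1-ms samples.
#' @param spec a [group_spec()] with `process = "sparse_on_off"`.
#' @param seed integer seed.
#' @return list with `data` (`n_samples x n_inputs`, zero-mean columns) and
#'   `latent` (the centred common component).
#' @export
gen_sparse_on_off <- function(n_samples, spec, seed) {
  stopifnot(n_samples >= 1)
  if (spec$timescale_ms <= 0) stop("timescale_ms must be positive")
  on_dur <- spec$on_duration_ms
  q <- on_dur / (on_dur + spec$timescale_ms)  # duty cycle of the renewal process
  amp <- spec$signal_sd                       # deterministic ON amplitude
  local_seed(seed, {
    state <- numeric(n_samples)
    t <- 1 + if (runif(1) < q) 0 else round(rexp(1, rate = 1 / spec$timescale_ms))
    while (t <= n_samples) {
      on_end <- min(t + on_dur - 1, n_samples)
      state[t:on_end] <- 1
      t <- on_end + 1 + round(rexp(1, rate = 1 / spec$timescale_ms))
    }
    common <- amp * state
    noise <- matrix(rnorm(n_samples * spec$n_inputs, sd = spec$noise_sd),
                    n_samples, spec$n_inputs)
    data <- common + noise
    data <- sweep(data, 2, colMeans(data))
    list(data = data, latent = common - mean(common))
  })
}

#' Ornstein-Uhlenbeck input group
#'
#' One stationary OU realisation (relaxation time `spec$timescale_ms`,
#' stationary sd `spec$signal_sd`) broadcast to all channels, plus
#' independent Gaussian noise; channels are mean-subtracted.
#'
#' @inheritParams gen_sparse_on_off
#' @return list with `data` and `latent` as in [gen_sparse_on_off()].
#' @export
gen_ou <- function(n_samples, spec, seed) {
  stopifnot(n_samples >= 1, spec$timescale_ms > 0)
  rho <- exp(-1 / spec$timescale_ms)
  sig <- spec$signal_sd
  local_seed(seed, {
    eps <- rnorm(n_samples, sd = sig * sqrt(1 - rho^2))
    common <- numeric(n_samples)
    common[1] <- rnorm(1, sd = sig)
    if (n_samples > 1) {
      for (t in 2:n_samples) common[t] <- rho * common[t - 1] + eps[t]
    }
    noise <- matrix(rnorm(n_samples * spec$n_inputs, sd = spec$noise_sd),
                    n_samples, spec$n_inputs)
    data <- common + noise
    data <- sweep(data, 2, colMeans(data))
    list(data = data, latent = common - mean(common))
  })
}

gen_white_noise <- function(n_samples, spec, seed) {
  local_seed(seed, {
    data <- matrix(rnorm(n_samples * spec$n_inputs, sd = spec$noise_sd),
                   n_samples, spec$n_inputs)
    data <- sweep(data, 2, colMeans(data))
    list(data = data, latent = rep(0, n_samples))
  })
}

# ---- input batches ----------------------------------------------------------

new_input_batch <- function(data, groups, latent, seed, mixed = FALSE,
                            tuning = NULL) {
  structure(list(data = data, groups = groups, latent = latent, seed = seed,
                 mixed = mixed, tuning = tuning),
            class = "input_batch")
}

#' @export
print.input_batch <- function(x, ...) {
  cat(sprintf("<input_batch> %d samples x %d channels, %d group(s)%s\n",
              nrow(x$data), ncol(x$data), length(x$groups),
              if (isTRUE(x$mixed)) ", linearly mixed" else ""))
  for (g in x$groups) {
    cat(sprintf("  %-12s %3d channels  process=%s signal_sd=%.3g noise_sd=%.3g\n",
                g$spec$name, g$spec$n_inputs, g$spec$process,
                g$spec$signal_sd, g$spec$noise_sd))
  }
  invisible(x)
}

# assemble groups generated independently (sub-seeds derived from `seed`)
assemble_groups <- function(n_samples, specs, seed, latent_from = 1L) {
  blocks <- vector("list", length(specs))
  latent <- NULL
  offset <- 0L
  groups <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    gen <- switch(sp$process,
                  sparse_on_off = gen_sparse_on_off,
                  ou = gen_ou,
                  white_noise = gen_white_noise)
    res <- gen(n_samples, sp, seed = (seed * 131L + i) %% .Machine$integer.max)
    blocks[[i]] <- res$data
    if (i == latent_from) latent <- res$latent
    groups[[i]] <- list(spec = sp, channels = offset + seq_len(sp$n_inputs))
    offset <- offset + sp$n_inputs
  }
  new_input_batch(do.call(cbind, blocks), groups, latent, seed)
}

#' Three-group selectivity dataset
#'
#' The single-neuron benchmark input: a sparse ON/OFF group (common
#' component sd 1.0), a "network" group sharing a Gaussian
#' Ornstein-Uhlenbeck component (sd 1.2, time constant 200 ms), and a group
#' of independent white noise (sd 2.2), 20 channels each. The sparse latent
#' has the lowest amplitude yet is the only non-Gaussian component, so a
#' correlation-invariant learner should select it while variance-driven
#' learners select the network group.
#'
#' @param n_samples number of samples (1 sample = 1 ms).
#' @param seed integer seed.
#' @param n_per_group channels per group (default 20).
#' @return an `input_batch`; `latent` is the centred sparse signal.
#' @export
gen_selectivity_dataset <- function(n_samples, seed, n_per_group = 20) {
  specs <- list(
    group_spec("sparse", n_per_group, "sparse_on_off", signal_sd = 1.0,
               noise_sd = 0.1, timescale_ms = 1000),
    group_spec("network", n_per_group, "ou", signal_sd = 1.2,
               noise_sd = 0.1, timescale_ms = 200),
    group_spec("noise", n_per_group, "white_noise", signal_sd = 0,
               noise_sd = 2.2))
  assemble_groups(n_samples, specs, seed, latent_from = 1L)
}

#' Subdivided sparse-signal dataset (amplitude or noise heterogeneity)
#'
#' The sparse input group is split into three subgroups. In the
#' `"amplitude"` variant the subgroups carry the common sparse signal at
#' amplitudes 1.5, 1.0 and 0.7 with noise scaled proportionally (equal
#' per-channel signal-to-noise ratios). In the `"noise"` variant the signal
#' amplitude is fixed at 1.0 while the noise sds are 1.5, 1.0 and 0.7.
#' Two Gaussian distractor groups (an OU "network" group and white noise)
#' are appended as in [gen_selectivity_dataset()].
#'
#' Subgroup signal amplitudes are standard deviations of the common
#' component (unlike the unit-amplitude convention of
#' [gen_selectivity_dataset()]): here the subgroups must dominate the input
#' variance so that both the correlation-invariant rule and the
#' heterosynaptic-LTD control attach to them, differing only in how they
#' weight the subgroups.
#'
#' @param variant `"amplitude"` or `"noise"`.
#' @param n_samples number of samples; 0 returns an empty batch with valid
#'   metadata.
#' @param seed integer seed.
#' @param subgroup_sizes channel counts of the three sparse subgroups.
#' @param base_snr_noise noise sd per unit signal sd in the
#'   `"amplitude"` variant (default 1, matching the noise variant's middle
#'   subgroup).
#' @return an `input_batch`; `latent` is the centred common sparse signal.
#' @export
gen_subgroup_dataset <- function(variant = c("amplitude", "noise"), n_samples,
                                 seed, subgroup_sizes = c(7L, 7L, 6L),
                                 base_snr_noise = 1) {
  variant <- match.arg(variant)
  sig <- if (variant == "amplitude") c(1.5, 1.0, 0.7) else c(1.0, 1.0, 1.0)
  noi <- if (variant == "amplitude") base_snr_noise * sig else c(1.5, 1.0, 0.7)
  if (n_samples == 0) {
    specs <- make_subgroup_specs(subgroup_sizes, sig, noi)
    groups <- list()
    offset <- 0L
    for (sp in specs) {
      groups[[length(groups) + 1L]] <- list(spec = sp,
                                            channels = offset + seq_len(sp$n_inputs))
      offset <- offset + sp$n_inputs
    }
    return(new_input_batch(matrix(0, 0, offset), groups, numeric(0), seed))
  }
  # shared sparse latent across the three subgroups: generate once, add
  # per-subgroup scaled copies and noise
  lat_spec <- group_spec("latent", 1, "sparse_on_off", signal_sd = 1,
                         noise_sd = 0, timescale_ms = 1000)
  lat <- gen_sparse_on_off(n_samples, lat_spec, seed)$latent
  lat <- lat / sd(lat)  # subgroup signal_sd is the common-component sd here
  specs <- make_subgroup_specs(subgroup_sizes, sig, noi)
  blocks <- vector("list", length(specs))
  groups <- vector("list", length(specs))
  offset <- 0L
  local_seed(seed + 7L, {
    for (i in seq_along(specs)) {
      sp <- specs[[i]]
      if (sp$process == "sparse_on_off") {
        data <- sp$signal_sd * lat +
          matrix(rnorm(n_samples * sp$n_inputs, sd = sp$noise_sd),
                 n_samples, sp$n_inputs)
        data <- sweep(data, 2, colMeans(data))
      } else {
        gen <- if (sp$process == "ou") gen_ou else gen_white_noise
        data <- gen(n_samples, sp, seed = (seed * 131L + i) %% .Machine$integer.max)$data
      }
      blocks[[i]] <- data
      groups[[i]] <- list(spec = sp, channels = offset + seq_len(sp$n_inputs))
      offset <- offset + sp$n_inputs
    }
  })
  new_input_batch(do.call(cbind, blocks), groups, lat, seed)
}

make_subgroup_specs <- function(sizes, sig, noi) {
  c(lapply(1:3, function(i) {
    group_spec(paste0("sparse", i), sizes[i], "sparse_on_off",
               signal_sd = sig[i], noise_sd = noi[i], timescale_ms = 1000)
  }),
  list(group_spec("network", 20, "ou", signal_sd = 1.2, noise_sd = 0.1,
                  timescale_ms = 200),
       group_spec("noise", 20, "white_noise", signal_sd = 0, noise_sd = 2.2)))
}

# ---- population-coding inputs ----------------------------------------------

#' Specification of a circular tuning-curve input population
#'
#' @param n_inputs number of input neurons (default 100).
#' @param tuning_sd Gaussian tuning width on the circular domain `[0,1)`
#'   (default 0.05).
#' @param noise_sd additive independent Gaussian noise (default 0.01).
#' @param latent_timescale_ms exponential smoothing constant of the latent
#'   random walk (default 100).
#' @param heterogeneity_sd log-sd of the log-normal multipliers applied
#'   per input to width, amplitude and noise (0 = homogeneous).
#' @param walk_increment_sd per-step sd of the latent random walk before
#'   smoothing (default 0.01, chosen so the latent mixes over the circle
#'   within a few times 1e4 samples while moving slowly relative to the
#'   tuning width).
#' @return an object of class `"tuning_population_spec"`.
#' @export
tuning_population_spec <- function(n_inputs = 100, tuning_sd = 0.05,
                                   noise_sd = 0.01, latent_timescale_ms = 100,
                                   heterogeneity_sd = 0,
                                   walk_increment_sd = 0.01) {
  stopifnot(n_inputs >= 2, tuning_sd > 0, noise_sd >= 0,
            latent_timescale_ms > 0, heterogeneity_sd >= 0)
  structure(list(n_inputs = as.integer(n_inputs), tuning_sd = tuning_sd,
                 noise_sd = noise_sd, latent_timescale_ms = latent_timescale_ms,
                 heterogeneity_sd = heterogeneity_sd,
                 walk_increment_sd = walk_increment_sd),
            class = "tuning_population_spec")
}

#' Smoothed circular random-walk latent
#'
#' A Gaussian random walk smoothed by an exponential filter and wrapped to
#' the circular domain `[0, 1)`.
#'
#' @param n_samples number of samples.
#' @param timescale_ms smoothing time constant.
#' @param increment_sd per-step walk increment sd.
#' @param seed integer seed.
#' @return numeric vector of latent values in `[0, 1)`.
#' @export
gen_latent_walk <- function(n_samples, timescale_ms = 100, increment_sd = 0.01,
                            seed = 1) {
  local_seed(seed, {
    walk <- cumsum(rnorm(n_samples, sd = increment_sd))
    theta <- numeric(n_samples)
    a <- 1 / timescale_ms
    theta[1] <- walk[1]
    if (n_samples > 1) {
      for (t in 2:n_samples) theta[t] <- theta[t - 1] + a * (walk[t] - theta[t - 1])
    }
    theta %% 1
  })
}

# circular Gaussian bump, wrapped over 3 periods (error < 1e-8 for sd <= 0.2)
gauss_circ <- function(theta, center, sd) {
  d <- theta - center
  exp(-(d - round(d))^2 / (2 * sd^2)) +
    exp(-(d - round(d) - 1)^2 / (2 * sd^2)) +
    exp(-(d - round(d) + 1)^2 / (2 * sd^2))
}

#' Population-coding input dataset
#'
#' A circular latent variable (smoothed random walk on `[0,1)`) is encoded
#' by `n_inputs` evenly spaced Gaussian tuning curves with additive
#' independent noise; channels are mean-subtracted. With
#' `heterogeneity_sd > 0`, per-input log-normal multipliers jitter the
#' tuning width, amplitude and noise level.
#'
#' @param spec a [tuning_population_spec()].
#' @param n_samples number of samples.
#' @param seed integer seed.
#' @return an `input_batch` whose `latent` is the circular latent and whose
#'   `tuning` field records per-input centres, widths, amplitudes and noise
#'   sds.
#' @export
gen_population_dataset <- function(spec, n_samples, seed) {
  stopifnot(inherits(spec, "tuning_population_spec"))
  n <- spec$n_inputs
  theta <- gen_latent_walk(n_samples, spec$latent_timescale_ms,
                           spec$walk_increment_sd, seed)
  centers <- (seq_len(n) - 1) / n
  local_seed(seed + 1L, {
    if (spec$heterogeneity_sd > 0) {
      widths <- spec$tuning_sd * rlnorm(n, 0, spec$heterogeneity_sd)
      amps <- rlnorm(n, 0, spec$heterogeneity_sd)
      noise_sds <- spec$noise_sd * rlnorm(n, 0, spec$heterogeneity_sd)
    } else {
      widths <- rep(spec$tuning_sd, n)
      amps <- rep(1, n)
      noise_sds <- rep(spec$noise_sd, n)
    }
    data <- matrix(0, n_samples, n)
    for (i in seq_len(n)) {
      data[, i] <- amps[i] * gauss_circ(theta, centers[i], widths[i]) +
        rnorm(n_samples, sd = noise_sds[i])
    }
    data <- sweep(data, 2, colMeans(data))
    grp <- list(list(spec = group_spec("tuning", n, "white_noise",
                                       signal_sd = 1, noise_sd = spec$noise_sd),
                     channels = seq_len(n)))
    new_input_batch(data, grp, theta, seed,
                    tuning = list(centers = centers, widths = widths,
                                  amps = amps, noise_sds = noise_sds,
                                  spec = spec))
  })
}

# ---- synthetic image patches -----------------------------------------------

#' Specification of the synthetic correlated-image patch generator
#'
#' @param patch_size pixels per side (default 16; must be >= 4).
#' @param spectral_exponent exponent of the `1/f^a` amplitude spectrum of
#'   the Gaussian background field (default 1, i.e. a `1/f^2` power
#'   spectrum).
#' @param edge_density expected number of oriented line segments per patch
#'   (default 1.5); segments carry the sparse higher-order structure.
#' @param rate_scale Hz of Poisson drive per unit pixel amplitude
#'   (default 100, giving mean ON/OFF channel rates near 40 Hz).
#' @param rate_cap saturation rate in Hz (default 500): pixel amplitudes
#'   in the tails of the distribution saturate the Poisson drive, as
#'   retinal firing rates do.
#' @param sample_duration_ms presentation time per patch (default 100).
#' @return an object of class `"patch_spec"`.
#' @export
patch_spec <- function(patch_size = 16, spectral_exponent = 1,
                       edge_density = 1.5, rate_scale = 100,
                       sample_duration_ms = 100, rate_cap = 500) {
  if (patch_size < 4) stop("patch_size must be >= 4")
  structure(list(patch_size = as.integer(patch_size),
                 spectral_exponent = spectral_exponent,
                 edge_density = edge_density, rate_scale = rate_scale,
                 sample_duration_ms = sample_duration_ms,
                 rate_cap = rate_cap),
            class = "patch_spec")
}

# one spatially low-pass Gaussian field, patch_size x patch_size, scaled so
# the expected per-pixel variance is 1 (patches keep their individual
# contrast fluctuations)
pink_field <- function(s, exponent) {
  fx <- c(0:(floor(s / 2)), -((ceiling(s / 2) - 1):1)) / s
  f2 <- outer(fx^2, fx^2, "+")
  amp <- 1 / (sqrt(f2)^(2 * exponent) + (1 / s)^(2 * exponent))
  amp <- amp / sqrt(sum(amp^2) / s^4)
  z <- matrix(complex(real = rnorm(s * s), imaginary = rnorm(s * s)), s, s)
  Re(fft(z * amp, inverse = TRUE)) / (s * s)
}

add_segment <- function(img, s) {
  x0 <- runif(1, 1, s); y0 <- runif(1, 1, s)
  ang <- runif(1, 0, pi)
  len <- runif(1, s / 4, s * 0.75)
  amp <- sample(c(-1, 1), 1) * runif(1, 1.5, 3)
  tt <- seq(-len / 2, len / 2, by = 0.5)
  xs <- round(x0 + tt * cos(ang)); ys <- round(y0 + tt * sin(ang))
  keep <- xs >= 1 & xs <= s & ys >= 1 & ys <= s
  img[cbind(xs[keep], ys[keep])] <- img[cbind(xs[keep], ys[keep])] + amp
  img
}

#' Synthetic correlated image patches with ON/OFF Poisson rates
#'
#' Generates grayscale patches as a `1/f`-amplitude Gaussian field (strong
#' positive neighbour-pixel correlation) plus a Poisson number of oriented
#' line segments (sparse higher-order structure). The generator is
#' normalised to unit expected pixel variance; individual patches keep
#' their contrast fluctuations (as natural scenes do). Each patch is
#' mean-subtracted, then split into rectified ON and OFF rate channels.
#'
#' @param spec a [patch_spec()].
#' @param n_patches number of patches.
#' @param seed integer seed.
#' @return list with `patches` (`n x s x s` array), `on` and `off`
#'   (`n x s^2` non-negative rate matrices in Hz) and `spec`.
#' @export
gen_image_patches <- function(spec, n_patches, seed) {
  stopifnot(inherits(spec, "patch_spec"), n_patches >= 1)
  s <- spec$patch_size
  local_seed(seed, {
    patches <- array(0, c(n_patches, s, s))
    for (k in seq_len(n_patches)) {
      img <- pink_field(s, spec$spectral_exponent)
      n_seg <- rpois(1, spec$edge_density)
      if (n_seg > 0) for (j in seq_len(n_seg)) img <- add_segment(img, s)
      img <- img - mean(img)
      patches[k, , ] <- img
    }
    flat <- matrix(patches, n_patches, s * s)
    list(patches = patches,
         on = pmin(spec$rate_scale * pmax(flat, 0), spec$rate_cap),
         off = pmin(spec$rate_scale * pmax(-flat, 0), spec$rate_cap),
         spec = spec)
  })
}

# ---- linear mixing ----------------------------------------------------------

#' Apply an invertible linear transformation to an input batch
#'
#' Replaces each sample `x` by `L x`. The latent is unchanged; group
#' metadata are kept but the batch is marked as mixed (group projections
#' are no longer defined).
#'
#' @param batch an `input_batch`.
#' @param L an invertible `N x N` matrix.
#' @return the transformed `input_batch`.
#' @export
apply_linear_mixing <- function(batch, L) {
  stopifnot(inherits(batch, "input_batch"))
  N <- ncol(batch$data)
  if (!is.matrix(L) || nrow(L) != N || ncol(L) != N) {
    stop("L must be a square matrix matching the channel count")
  }
  if (rcond(L) < 1e-12) stop("L is singular or ill-conditioned")
  out <- batch
  out$data <- batch$data %*% t(L)
  out$mixed <- TRUE
  out
}
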