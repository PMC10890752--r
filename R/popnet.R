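#' Configuration of the recurrently inhibited population network
#'
#' Feedforward weights from `N` tuned inputs to `n_outputs` rate neurons
#' follow a rate-based plasticity rule with weight decay; all-to-all
#' recurrent inhibitory weights follow a covariance-like inhibitory rule
#' with decay, clipped to non-positive values.
#'
#' @param n_outputs number of output neurons (default 16).
#' @param rec_steps recurrent fixed-point iterations per sample
#'   (default 10).
#' @param eta_rec inhibitory learning rate (default 0.03).
#' @param theta_rec inhibitory target rate (default 1.0).
#' @param lambda_rec inhibitory weight decay (default 1.0).
#' @param lambda_ff feedforward weight decay (default 0.001).
#' @param rule a [rule_config()] for the feedforward plasticity
#'   (default correlation-invariant, `p = 3, r = 2`).
#' @return an object of class `"popnet_config"`.
#' @export
popnet_config <- function(n_outputs = 16, rec_steps = 10, eta_rec = 0.03,
                          theta_rec = 1.0, lambda_rec = 1.0,
                          lambda_ff = 0.001,
                          rule = rule_config("corr_invariant")) {
  stopifnot(n_outputs >= 1, rec_steps >= 1, eta_rec >= 0, lambda_rec >= 0,
            lambda_ff >= 0)
  structure(list(n_outputs = as.integer(n_outputs),
                 rec_steps = as.integer(rec_steps), eta_rec = eta_rec,
                 theta_rec = theta_rec, lambda_rec = lambda_rec,
                 lambda_ff = lambda_ff, rule = rule),
            class = "popnet_config")
}

new_population_state <- function(W, W_rec, h) {
  structure(list(W = W, W_rec = W_rec, h = h), class = "population_state")
}

#' Recurrent network response
#'
#' Iterates `y <- (W x + W_rec y)_+` from `y = 0` for `rec_steps`
#' iterations and returns the final activity.
#'
#' @param x input vector of length `N`, or an `N x K` matrix of samples in
#'   columns.
#' @param state a `population_state` (fields `W`, `W_rec`).
#' @param rec_steps number of iterations (default 10).
#' @return activity vector of length `M`, or an `M x K` matrix.
#' @export
recurrent_forward <- function(x, state, rec_steps = 10) {
  stopifnot(rec_steps >= 1)
  ff <- state$W %*% (if (is.matrix(x)) x else matrix(x, ncol = 1))
  y <- matrix(0, nrow(ff), ncol(ff))
  for (i in seq_len(rec_steps)) {
    y <- pmax(ff + state$W_rec %*% y, 0)
  }
  if (any(!is.finite(y))) stop("non-finite activities in recurrent dynamics")
  if (is.matrix(x)) y else drop(y)
}

#' Inhibitory recurrent plasticity update
#'
#' Covariance-like rule with multiplicative decay,
#' `dw_ij = -eta_rec * y_i (y_j - theta) - eta_rec * lambda_rec * w_ij`,
#' applied to off-diagonal entries (batch-averaged when `y` is a matrix),
#' then clipped to non-positive values with a zero diagonal. The decay term
#' relaxes weights toward zero; correlated supra-threshold activity drives
#' them negative, with clamped-activity equilibrium
#' `w_ij = -y_i (y_j - theta) / lambda_rec`.
#'
#' @param state a `population_state`.
#' @param y activity vector of length `M` or an `M x K` batch matrix.
#' @param cfg a [popnet_config()].
#' @return the updated recurrent weight matrix `W_rec`.
#' @export
inhibitory_update <- function(state, y, cfg) {
  ym <- if (is.matrix(y)) y else matrix(y, ncol = 1)
  K <- ncol(ym)
  cov_term <- ym %*% t(ym - cfg$theta_rec) / K
  W_rec <- state$W_rec - cfg$eta_rec * cov_term -
    cfg$eta_rec * cfg$lambda_rec * state$W_rec
  W_rec <- pmin(W_rec, 0)
  diag(W_rec) <- 0
  W_rec
}

#' Train the population-coding network
#'
#' Per mini-batch: settle the recurrent dynamics, apply the feedforward
#' plasticity rule per output neuron (with decay `lambda_ff`) through the
#' optimizer, apply the inhibitory update, and update each neuron's
#' homeostatic estimate. Feedforward and recurrent plasticity run
#' concurrently.
#'
#' @param batch an `input_batch` from [gen_population_dataset()].
#' @param cfg a [popnet_config()].
#' @param train a [train_config()]; its `seed` controls initialisation and
#'   batch sampling.
#' @return a list of class `"popnet_result"` with `state`
#'   (`population_state`), and `diagnostics` (per-snapshot mean `|W|` row
#'   norm, mean `h`, mean recurrent weight).
#' @export
train_population <- function(batch, cfg, train = train_config(n_samples = 3e5)) {
  stopifnot(inherits(batch, "input_batch"), inherits(cfg, "popnet_config"))
  X <- batch$data                       # n x N, samples in rows
  N <- ncol(X)
  M <- cfg$n_outputs
  rule <- cfg$rule
  n_steps <- max(1L, floor(train$n_samples / train$batch_size))
  local_seed(train$seed, {
    W <- matrix(rnorm(M * N, sd = 1 / sqrt(N)), M, N)
    W_rec <- matrix(0, M, M)
    state <- new_population_state(W, W_rec, h = rep(0, M))
    y0 <- recurrent_forward(t(X[sample.int(nrow(X), min(1000L, nrow(X))), ,
                                drop = FALSE]), state, cfg$rec_steps)
    state$h <- rowMeans(y0^rule$r)
    opt <- adam_init(M * N)
    snap <- max(1L, floor(n_steps / 100))
    diagnostics <- list(step = integer(0), w_norm = numeric(0),
                        h_mean = numeric(0), rec_mean = numeric(0))
    for (step in seq_len(n_steps)) {
      idx <- sample.int(nrow(X), train$batch_size, replace = TRUE)
      Xb <- t(X[idx, , drop = FALSE])   # N x K
      Y <- recurrent_forward(Xb, state, cfg$rec_steps)  # M x K
      K <- ncol(Y)
      # homeostatic update first (faster timescale than the weights);
      # tau_h is a window in samples, one batch consumes K of them
      tau_b <- max(1, rule$tau_h / K)
      state$h <- state$h * (1 - 1 / tau_b) + rowMeans(Y^rule$r) / tau_b
      G <- switch(rule$variant,
        corr_invariant = ,
        kurtosis_bcm = (Y^(rule$p - 1) - state$h * Y) %*% t(Xb) / K,
        oja_heterosyn = (Y^2) %*% t(Xb) / K - rowMeans(Y^2) * state$W,
        stop("unsupported feedforward variant for the population network"))
      G <- G - cfg$lambda_ff * state$W
      if (train$optimizer == "adam") {
        opt <- adam_step(opt, as.vector(G), train$lr)
        state$W <- state$W + matrix(opt$delta, M, N)
      } else {
        state$W <- state$W + rule$eta * G
      }
      state$W_rec <- inhibitory_update(state, Y, cfg)
      if (max(abs(state$W)) > 1e6) stop("weight divergence in population network")
      if (step %% snap == 0) {
        diagnostics$step <- c(diagnostics$step, step)
        diagnostics$w_norm <- c(diagnostics$w_norm,
                                mean(sqrt(rowSums(state$W^2))))
        diagnostics$h_mean <- c(diagnostics$h_mean, mean(state$h))
        diagnostics$rec_mean <- c(diagnostics$rec_mean, mean(state$W_rec))
      }
    }
    structure(list(state = state, diagnostics = diagnostics, config = cfg,
                   train = train),
              class = "popnet_result")
  })
}

#' Evaluate population responses over a dataset
#'
#' Runs the (frozen) trained network over all samples in chunks and
#' returns the activity matrix, for tuning-curve estimation.
#'
#' @param state a `population_state`.
#' @param batch an `input_batch`.
#' @param rec_steps recurrent iterations (default 10).
#' @param chunk chunk size in samples.
#' @return `n_samples x M` activity matrix.
#' @export
population_responses <- function(state, batch, rec_steps = 10, chunk = 20000L) {
  n <- nrow(batch$data)
  M <- nrow(state$W)
  Y <- matrix(0, n, M)
  i <- 1L
  while (i <= n) {
    j <- min(i + chunk - 1L, n)
    Y[i:j, ] <- t(recurrent_forward(t(batch$data[i:j, , drop = FALSE]),
                                    state, rec_steps))
    i <- j + 1L
  }
  Y
}
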