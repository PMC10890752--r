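#' Training configuration for stochastic-optimization runs
#'
#' @param n_samples total number of sample presentations (default 1e6).
#' @param batch_size mini-batch size (default 100).
#' @param optimizer `"adam"` or `"sgd"`.
#' @param lr learning rate of the optimizer (default 0.003).
#' @param init_sd sd of the Gaussian weight initialisation. The default
#'   `NULL` scales the init as `1/sqrt(N)` so the initial output activity
#'   is of order one and the weight norm starts below its plasticity
#'   equilibrium; from there nonlinear LTP amplifies sparse directions
#'   directly instead of first dissolving the initial weight mass through
#'   an LTD-dominated transient.
#' @param seed integer seed controlling initialisation and batch sampling.
#' @param record_every trajectory snapshot stride in optimizer steps
#'   (default 50).
#' @return an object of class `"train_config"`.
#' @export
train_config <- function(n_samples = 1e6, batch_size = 100,
                         optimizer = c("adam", "sgd"), lr = 0.003,
                         init_sd = NULL, seed = 1, record_every = 50) {
  optimizer <- match.arg(optimizer)
  stopifnot(n_samples >= batch_size, batch_size >= 1, lr >= 0)
  structure(list(n_samples = n_samples, batch_size = as.integer(batch_size),
                 optimizer = optimizer, lr = lr, init_sd = init_sd,
                 seed = as.integer(seed), record_every = as.integer(record_every)),
            class = "train_config")
}

# Adam optimizer state and step (standard published defaults for the moment
# decays and epsilon)
adam_init <- function(dim) {
  list(m = rep(0, dim), v = rep(0, dim), t = 0L,
       beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

adam_step <- function(opt, grad, lr) {
  opt$t <- opt$t + 1L
  opt$m <- opt$beta1 * opt$m + (1 - opt$beta1) * grad
  opt$v <- opt$beta2 * opt$v + (1 - opt$beta2) * grad^2
  mhat <- opt$m / (1 - opt$beta1^opt$t)
  vhat <- opt$v / (1 - opt$beta2^opt$t)
  opt$delta <- lr * mhat / (sqrt(vhat) + opt$eps)
  opt
}

#' Train a single rate neuron
#'
#' Draws mini-batches i.i.d. with replacement from the rows of
#' `batch$data`, updates the homeostatic estimate before each weight
#' update, and applies the optimizer to the plasticity update as an ascent
#' direction. Deterministic given the seed in `cfg`.
#'
#' @param batch an `input_batch`.
#' @param rule a [rule_config()].
#' @param cfg a [train_config()].
#' @return a list of class `"train_result"` with `final_state`
#'   ([neuron_state()]), `w_trajectory` (snapshots x N), `h_trajectory`,
#'   and `group_projections` (snapshot x group matrix, `NULL` for mixed
#'   batches).
#' @export
train_neuron <- function(batch, rule, cfg) {
  stopifnot(inherits(batch, "input_batch"))
  X <- batch$data
  N <- ncol(X)
  n_steps <- max(1L, floor(cfg$n_samples / cfg$batch_size))
  init_sd <- cfg$init_sd %||% (1 / sqrt(N))
  local_seed(cfg$seed, {
    w <- rnorm(N, sd = init_sd)
    if (rule$variant == "norm_constrained") w <- w / sqrt(sum(w^2))
    rectified <- rule$variant != "oja_linear"
    state <- neuron_state(w, h_y = mean(forward(w, X[sample.int(nrow(X),
                            min(1000L, nrow(X))), , drop = FALSE],
                            rectified = rectified)^rule$r))
    opt <- adam_init(N)
    rule_h <- rule
    rule_h$tau_h <- max(1, rule$tau_h / cfg$batch_size)
    n_rec <- floor((n_steps - 1) / cfg$record_every) + 1L
    w_traj <- matrix(NA_real_, n_rec, N)
    h_traj <- numeric(n_rec)
    ri <- 0L
    for (step in seq_len(n_steps)) {
      idx <- sample.int(nrow(X), cfg$batch_size, replace = TRUE)
      xb <- X[idx, , drop = FALSE]
      y <- forward(state$w, xb, rectified = rectified)
      # tau_h is a window in samples; one batch consumes batch_size samples
      state <- update_h(state, y, rule_h)
      g <- delta_w(state, xb, rule)
      if (cfg$optimizer == "adam") {
        opt <- adam_step(opt, g, cfg$lr)
        state$w <- state$w + opt$delta
      } else {
        state$w <- state$w + g
      }
      if (rule$variant == "norm_constrained") {
        state$w <- state$w / sqrt(sum(state$w^2))
      }
      if (max(abs(state$w)) > 1e6) {
        stop("weight divergence: |w| exceeded 1e6 (check that r > p - 2)")
      }
      state$step <- step
      if ((step - 1) %% cfg$record_every == 0) {
        ri <- ri + 1L
        w_traj[ri, ] <- state$w
        h_traj[ri] <- state$h_y
      }
    }
    proj <- NULL
    if (!isTRUE(batch$mixed) && length(batch$groups)) {
      proj <- t(apply(w_traj, 1, group_projection, batch = batch))
      colnames(proj) <- vapply(batch$groups, function(g) g$spec$name, "")
    }
    structure(list(final_state = state, w_trajectory = w_traj,
                   h_trajectory = h_traj, group_projections = proj,
                   rule = rule, config = cfg),
              class = "train_result")
  })
}

#' Normalized projections of a weight vector on group signal directions
#'
#' For each input group, the inner product between `w` and the unit vector
#' of the group's common-signal loading (equal loading across the group's
#' channels), normalised by `|w|`. These are the coordinates used to
#' visualise learning trajectories in the selectivity experiment.
#'
#' @param w weight vector.
#' @param batch an unmixed `input_batch` with group metadata.
#' @return named numeric vector, one value per group.
#' @export
group_projection <- function(w, batch) {
  stopifnot(inherits(batch, "input_batch"))
  if (isTRUE(batch$mixed)) {
    stop("group projections are undefined for linearly mixed batches")
  }
  nw <- sqrt(sum(w^2))
  out <- vapply(batch$groups, function(g) {
    u <- rep(1 / sqrt(length(g$channels)), length(g$channels))
    sum(w[g$channels] * u) / nw
  }, 0)
  names(out) <- vapply(batch$groups, function(g) g$spec$name, "")
  out
}

#' Tail-averaged converged weights
#'
#' Average of the recorded weight snapshots over the final fraction of
#' training (Polyak-style averaging). Adam keeps a small exploration
#' noise on every coordinate at stationarity; averaging the tail of the
#' trajectory removes it and is the package's estimator of the converged
#' weight vector.
#'
#' @param result a `train_result` from [train_neuron()].
#' @param frac final fraction of snapshots to average (default 0.5).
#' @return numeric weight vector.
#' @export
tail_averaged_w <- function(result, frac = 0.5) {
  W <- result$w_trajectory
  k <- nrow(W)
  colMeans(W[max(1L, floor((1 - frac) * k)):k, , drop = FALSE])
}
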