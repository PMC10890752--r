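#' Configuration of a rate-based plasticity rule
#'
#' The central rule family combines nonlinear Hebbian LTP (`x * y^(p-1)`)
#' with linear Hebbian LTD (`- h_y * x * y`), where the homeostatic factor
#' `h_y` tracks `<y^r>`. For any `p > 2` and `r > p - 2` the rule is stable
#' and converges to features invariant to second-order input correlations.
#' Comparison variants: `kurtosis_bcm` (`p = 4, r = 3`), the Oja rule
#' (`oja_linear`), its nonlinear-LTP heterosynaptic-LTD counterpart
#' (`oja_heterosyn`), and a norm-constrained nonlinear Hebbian baseline
#' (`norm_constrained`).
#'
#' @param variant one of `"corr_invariant"`, `"kurtosis_bcm"`,
#'   `"oja_linear"`, `"oja_heterosyn"`, `"norm_constrained"`.
#' @param p LTP exponent (activity power is `p - 1`); must exceed 2 for the
#'   correlation-invariant family.
#' @param r homeostatic exponent, `h_y = <y^r>`; must exceed `p - 2`.
#' @param eta learning rate (default 0.003).
#' @param tau_h homeostatic averaging window in samples (default 200).
#' @param weight_decay decay coefficient `lambda` (default 0).
#' @param balancing_h if `TRUE`, use the balancing factor
#'   `h* = <y^p>/<y^2>` computed on each batch instead of the running
#'   average (leaves the weight norm indifferent).
#' @return an object of class `"rule_config"`.
#' @export
rule_config <- function(variant = c("corr_invariant", "kurtosis_bcm",
                                    "oja_linear", "oja_heterosyn",
                                    "norm_constrained"),
                        p = NULL, r = NULL, eta = 0.003, tau_h = 200,
                        weight_decay = 0, balancing_h = FALSE) {
  variant <- match.arg(variant)
  if (is.null(p)) p <- switch(variant, corr_invariant = 3, kurtosis_bcm = 4, 3)
  if (is.null(r)) r <- switch(variant, corr_invariant = 2, kurtosis_bcm = 3, 2)
  if (variant %in% c("corr_invariant", "kurtosis_bcm")) {
    if (p <= 2) stop("the correlation-invariant family requires p > 2")
    if (r <= p - 2) stop("stability requires r > p - 2")
  }
  stopifnot(eta > 0, tau_h >= 1, weight_decay >= 0)
  structure(list(variant = variant, p = p, r = r, eta = eta, tau_h = tau_h,
                 weight_decay = weight_decay, balancing_h = balancing_h),
            class = "rule_config")
}

#' State of a single rate neuron
#'
#' @param w weight vector (unconstrained sign).
#' @param h_y homeostatic scalar, the running estimate of `<y^r>`.
#' @param step update counter.
#' @return an object of class `"neuron_state"`.
#' @export
neuron_state <- function(w, h_y = 0, step = 0L) {
  structure(list(w = as.numeric(w), h_y = h_y, step = as.integer(step)),
            class = "neuron_state")
}

#' Neuron activation
#'
#' Rectified linear response `y = (w' x)_+` per sample. For the
#' `oja_linear` variant the response is purely linear (`rectified = FALSE`).
#'
#' @param w weight vector of length `N`.
#' @param x an input vector of length `N` or a batch matrix
#'   (`K x N`, samples in rows).
#' @param rectified apply the positive-part rectifier (default `TRUE`).
#' @return activity `y`, scalar or length-`K` vector.
#' @export
forward <- function(w, x, rectified = TRUE) {
  if (is.matrix(x)) {
    if (ncol(x) != length(w)) stop("dimension mismatch between w and x")
    y <- drop(x %*% w)
  } else {
    if (length(x) != length(w)) stop("dimension mismatch between w and x")
    y <- sum(w * x)
  }
  if (rectified) pmax(y, 0) else y
}

#' Batch-averaged weight update
#'
#' Computes the plasticity update for one mini-batch. For the
#' correlation-invariant family the update is
#' `eta * mean(x * y^(p-1) - h_y * x * y) - eta * lambda * w`;
#' variants substitute heterosynaptic LTD (`- w * y^2`), the linear Oja
#' rule, or plain nonlinear Hebbian LTP (the caller renormalises for
#' `norm_constrained`).
#'
#' @param state a [neuron_state()] whose `h_y` is current for this batch
#'   (ignored in `balancing_h` mode, where `h*` is computed on the batch).
#' @param x_batch `K x N` input matrix.
#' @param cfg a [rule_config()].
#' @return the weight update vector (length `N`), already scaled by `eta`.
#' @export
delta_w <- function(state, x_batch, cfg) {
  if (!is.matrix(x_batch)) x_batch <- matrix(x_batch, nrow = 1)
  if (anyNA(x_batch)) stop("NaN/NA in input batch")
  w <- state$w
  K <- nrow(x_batch)
  rectified <- cfg$variant != "oja_linear"
  y <- forward(w, x_batch, rectified = rectified)
  h <- if (isTRUE(cfg$balancing_h)) balancing_h_star(w, x_batch, cfg$p) else state$h_y
  upd <- switch(cfg$variant,
    corr_invariant = ,
    kurtosis_bcm = drop(crossprod(x_batch, y^(cfg$p - 1) - h * y)) / K,
    oja_heterosyn = drop(crossprod(x_batch, y^2)) / K - w * mean(y^2),
    oja_linear = drop(crossprod(x_batch, y)) / K - w * mean(y^2),
    norm_constrained = drop(crossprod(x_batch, y^2)) / K,
    stop("unknown rule variant"))
  dw <- cfg$eta * upd - cfg$eta * cfg$weight_decay * w
  if (any(!is.finite(dw))) stop("non-finite weight update (divergence?)")
  dw
}

#' Update the homeostatic estimate
#'
#' Exponential moving average of `y^r` with window `tau_h`:
#' `h <- h * (1 - 1/tau_h) + mean(y^r) / tau_h`.
#'
#' @param state a [neuron_state()].
#' @param y_batch activity values of the current batch.
#' @param cfg a [rule_config()].
#' @return the updated `neuron_state`.
#' @export
update_h <- function(state, y_batch, cfg) {
  state$h_y <- state$h_y * (1 - 1 / cfg$tau_h) + mean(y_batch^cfg$r) / cfg$tau_h
  state
}

#' Balancing homeostatic factor
#'
#' The value `h* = <y^p> / <y^2>` at which the expected update has no
#' component along the weight vector (`<w' dw> = 0`), leaving the norm at
#' an indifferent equilibrium. For `p = 3` this is `<y^3>/<y^2>`.
#'
#' @param w weight vector.
#' @param x_batch `K x N` input matrix.
#' @param p LTP exponent.
#' @return scalar `h*`.
#' @export
balancing_h_star <- function(w, x_batch, p = 3) {
  if (!is.matrix(x_batch)) x_batch <- matrix(x_batch, nrow = 1)
  y <- forward(w, x_batch)
  m2 <- mean(y^2)
  if (m2 <= 0) stop("balancing factor undefined: batch has no activity")
  mean(y^p) / m2
}

#' Predicted converged weight norm
#'
#' For the stable rule family with `h_y = <y^r>`, the norm at convergence
#' depends only on the rectified input projection onto the converged
#' direction, `x_w = (u' x)_+` for a unit vector `u`:
#' `|w| = (<x_w^p> / (<x_w^r> <x_w^2>))^(1/(r - p + 2))`.
#' For `p = 3, r = 2` this reduces to `<x_w^3> / <x_w^2>^2`.
#'
#' @param w_direction unit-norm direction vector.
#' @param x_batch `K x N` input matrix used to estimate the moments.
#' @param p LTP exponent.
#' @param r homeostatic exponent.
#' @return predicted weight norm (scalar).
#' @export
predicted_weight_norm <- function(w_direction, x_batch, p = 3, r = 2) {
  if (abs(sum(w_direction^2) - 1) > 1e-6) {
    stop("w_direction must have unit norm")
  }
  if (r - p + 2 == 0) stop("exponent 1/(r - p + 2) undefined")
  xw <- forward(w_direction, x_batch)
  m2 <- mean(xw^2)
  if (m2 <= 0) stop("no activity in the supplied direction")
  (mean(xw^p) / (mean(xw^r) * m2))^(1 / (r - p + 2))
}
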