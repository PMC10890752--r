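#' Whitening matrix from a data sample
#'
#' Symmetric (ZCA) whitening: with eigendecomposition
#' `<x x'> = R D R'`, returns `M = R D^(-1/2) R'` so that the transformed
#' sample `M x` has identity second-moment matrix.
#'
#' @param X `n x N` data matrix (assumed zero-mean columns).
#' @param pseudo_inverse if `TRUE`, rank-deficient directions are dropped
#'   (pseudo-inverse square root) and the rank is reported as an attribute.
#' @param tol relative eigenvalue tolerance for rank decisions.
#' @return the `N x N` whitening matrix (symmetric positive semi-definite).
#' @export
whitening_matrix <- function(X, pseudo_inverse = FALSE, tol = 1e-10) {
  C <- crossprod(X) / nrow(X)
  e <- eigen(C, symmetric = TRUE)
  pos <- e$values > tol * max(e$values)
  if (!all(pos) && !pseudo_inverse) {
    stop("covariance is rank deficient; set pseudo_inverse = TRUE")
  }
  inv_sqrt <- ifelse(pos, 1 / sqrt(pmax(e$values, 0)), 0)
  M <- e$vectors %*% (inv_sqrt * t(e$vectors))
  attr(M, "rank") <- sum(pos)
  M
}

#' Output signal-to-noise ratio relative to a latent signal
#'
#' Regresses `y` on the latent (ordinary least squares with intercept) and
#' returns the ratio of explained to residual variance. A perfect
#' reconstruction yields `Inf`.
#'
#' @param y output activity vector.
#' @param latent latent signal, vector or matrix with one column per
#'   latent component.
#' @return scalar SNR (possibly `Inf`).
#' @export
output_snr <- function(y, latent) {
  L <- if (is.matrix(latent)) latent else matrix(latent, ncol = 1)
  stopifnot(length(y) == nrow(L))
  if (var(y) == 0) return(0)
  fit <- lm.fit(cbind(1, L), y)
  v_res <- var(fit$residuals)
  v_fit <- var(y - fit$residuals)
  if (v_res < 1e-14 * v_fit) return(Inf)
  v_fit / v_res
}

#' Optimal linear decoder of a latent signal
#'
#' Ordinary least squares of the latent on the input channels; the decoded
#' output's SNR is the oracle against which learned decoders are compared.
#'
#' @param X `n x N` input matrix.
#' @param latent latent signal vector.
#' @param ridge ridge fallback penalty used if the design is numerically
#'   singular (default 1e-8 times the mean channel variance).
#' @return list with `weights` (length `N`), `intercept`, `decoded` and
#'   `snr`.
#' @export
optimal_linear_decoder <- function(X, latent, ridge = 1e-8) {
  stopifnot(nrow(X) == length(latent))
  Xc <- sweep(X, 2, colMeans(X))
  lc <- latent - mean(latent)
  G <- crossprod(Xc) / nrow(Xc)
  b <- drop(crossprod(Xc, lc)) / nrow(Xc)
  w <- tryCatch(solve(G, b), error = function(e) {
    warning("singular design; using ridge fallback")
    solve(G + ridge * mean(diag(G)) * diag(ncol(G)), b)
  })
  decoded <- drop(Xc %*% w)
  list(weights = w, intercept = mean(latent), decoded = decoded,
       snr = output_snr(decoded, latent))
}

#' Binned tuning curves over a circular latent
#'
#' @param Y `n x M` response matrix (neurons in columns).
#' @param theta circular latent values in `[0, 1)`.
#' @param n_bins number of bins (>= 16, default 64).
#' @param min_count minimum samples required in every bin (default 50).
#' @return an object of class `"tuning_curve_set"`: `theta_grid` (bin
#'   centres), `mean_response` and `response_sd` (`M x n_bins`),
#'   `n_per_bin`, and `bin_index` (per-sample bin assignment).
#' @export
estimate_tuning <- function(Y, theta, n_bins = 64, min_count = 50) {
  if (!is.matrix(Y)) Y <- matrix(Y, ncol = 1)
  stopifnot(n_bins >= 16, nrow(Y) == length(theta))
  bin <- pmin(floor(theta %% 1 * n_bins) + 1L, n_bins)
  counts <- tabulate(bin, n_bins)
  if (any(counts < min_count)) {
    stop(sprintf("bin occupancy too low (min %d < %d); use more samples",
                 min(counts), min_count))
  }
  M <- ncol(Y)
  mu <- matrix(0, M, n_bins)
  sdv <- matrix(0, M, n_bins)
  for (b in seq_len(n_bins)) {
    yb <- Y[bin == b, , drop = FALSE]
    mu[, b] <- colMeans(yb)
    sdv[, b] <- apply(yb, 2, sd)
  }
  structure(list(theta_grid = (seq_len(n_bins) - 0.5) / n_bins,
                 mean_response = mu, response_sd = sdv, n_per_bin = counts,
                 bin_index = bin),
            class = "tuning_curve_set")
}

#' Full width at half maximum of a circular tuning curve
#'
#' Baseline is the curve minimum; the half level is halfway between
#' baseline and maximum. The width is the circular distance between the
#' two half-level crossings bracketing the global peak, linearly
#' interpolated between bins.
#'
#' @param curve response values over the circular grid.
#' @param theta_grid bin centres in `[0, 1)` (defaults to an even grid).
#' @return width as a fraction of the circular domain.
#' @export
fwhm <- function(curve, theta_grid = NULL) {
  n <- length(curve)
  if (is.null(theta_grid)) theta_grid <- (seq_len(n) - 0.5) / n
  lo <- min(curve); hi <- max(curve)
  if (hi - lo <= 0) stop("flat curve: FWHM undefined")
  half <- lo + (hi - lo) / 2
  pk <- which.max(curve)
  above <- curve >= half
  # walk left from the peak to the first below-half bin (circularly)
  step_left <- function(i) if (i == 1) n else i - 1
  step_right <- function(i) if (i == n) 1 else i + 1
  i <- pk; nl <- 0
  while (above[step_left(i)] && nl < n) { i <- step_left(i); nl <- nl + 1 }
  j <- pk; nr <- 0
  while (above[step_right(j)] && nr < n) { j <- step_right(j); nr <- nr + 1 }
  if (nl + nr + 1 >= n) return(1)  # whole circle above half level
  # interpolate between bin i (above) and its left neighbour (below)
  il <- step_left(i)
  fl <- (curve[i] - half) / (curve[i] - curve[il])
  jr <- step_right(j)
  fr <- (curve[j] - half) / (curve[j] - curve[jr])
  dt <- 1 / n
  width <- (nl + nr + 1) * dt - dt + fl * dt + fr * dt
  min(width, 1)
}

#' Linear Fisher information of a tuning-curve set
#'
#' `J(theta) = f'(theta)' Sigma(theta)^-1 f'(theta)` with tuning-curve
#' slopes from circular central differences of the binned means and
#' `Sigma` the per-bin response covariance across samples
#' (diagonal-regularised). Returns the mean over bins.
#'
#' @param tuning a `tuning_curve_set` from [estimate_tuning()].
#' @param Y the response matrix used to build `tuning` (needed for per-bin
#'   covariances); if `NULL`, a diagonal covariance from `response_sd` is
#'   used.
#' @param reg diagonal regularisation as a fraction of the population-mean
#'   response variance (default 0.05). The floor is global (not per bin)
#'   so that neurons that are silent within a bin, and therefore have zero
#'   sampled variance there while their cross-bin slope is nonzero, do not
#'   contribute divergent information.
#' @return mean linear Fisher information (per unit latent squared). The
#'   estimate is resolution-limited: per-bin covariances include the
#'   response variability caused by latent motion within a bin, so the
#'   estimate cannot exceed roughly `12 n_bins^2`, the information in the
#'   bin-discretised latent itself.
#' @export
fisher_information <- function(tuning, Y = NULL, reg = 0.05) {
  stopifnot(inherits(tuning, "tuning_curve_set"))
  mu <- tuning$mean_response
  n_bins <- ncol(mu)
  if (n_bins < 32) stop("need >= 32 bins for slope estimation")
  dtheta <- 1 / n_bins
  left <- c(n_bins, seq_len(n_bins - 1))
  right <- c(2:n_bins, 1)
  floor_var <- reg * mean(tuning$response_sd^2)
  J <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    fp <- (mu[, right[b]] - mu[, left[b]]) / (2 * dtheta)
    if (!is.null(Y)) {
      yb <- Y[tuning$bin_index == b, , drop = FALSE]
      # augment by the slope outer product times the within-bin latent
      # variance: makes the estimate consistent with the bin resolution
      # (J cannot exceed 12 * n_bins^2, the information in the
      # discretised latent itself) despite rectification kinks that the
      # sampled covariance does not register for partially silent neurons
      S <- stats::cov(yb) + tcrossprod(fp) * dtheta^2 / 12
    } else {
      S <- diag(tuning$response_sd[, b]^2, nrow = nrow(mu))
    }
    S <- S + floor_var * diag(nrow(S))
    J[b] <- drop(crossprod(fp, solve(S, fp)))
  }
  mean(J)
}

#' Correlation between input tuning widths and synaptic weight magnitudes
#'
#' Pearson correlation between each input's tuning width and its mean
#' absolute feedforward weight across output neurons.
#'
#' @param W `M x N` feedforward weight matrix.
#' @param input_widths per-input tuning widths (length `N`).
#' @return scalar Pearson correlation.
#' @export
weight_width_correlation <- function(W, input_widths) {
  stopifnot(ncol(W) == length(input_widths))
  if (sd(input_widths) == 0) stop("degenerate: all input widths are equal")
  cor(input_widths, colMeans(abs(W)))
}

#' Receptive-field localization index
#'
#' Maximum over positions of the fraction of total squared amplitude
#' contained in a `k x k` window (`k = patch_size / 4` by default); 1 for
#' a perfectly localized field, `k^2 / patch_size^2` for a uniform one.
#'
#' @param rf_map square matrix, e.g. the ON-minus-OFF weight map.
#' @param k window side (default `nrow(rf_map) / 4`, at least 1).
#' @return scalar in `(0, 1]`.
#' @export
rf_localization_index <- function(rf_map, k = NULL) {
  stopifnot(is.matrix(rf_map), nrow(rf_map) == ncol(rf_map))
  s <- nrow(rf_map)
  if (is.null(k)) k <- max(1L, floor(s / 4))
  e <- rf_map^2
  tot <- sum(e)
  if (tot == 0) stop("all-zero receptive field map")
  # summed-area table for O(1) window sums
  cs <- apply(apply(e, 2, cumsum), 1, cumsum)  # cs[j, i] = sum e[1:i, 1:j]
  win_sum <- function(i, j) {  # window rows i..i+k-1, cols j..j+k-1
    a <- cs[j + k - 1, i + k - 1]
    b <- if (j > 1) cs[j - 1, i + k - 1] else 0
    d <- if (i > 1) cs[j + k - 1, i - 1] else 0
    c0 <- if (i > 1 && j > 1) cs[j - 1, i - 1] else 0
    a - b - d + c0
  }
  best <- 0
  for (i in seq_len(s - k + 1)) {
    for (j in seq_len(s - k + 1)) {
      best <- max(best, win_sum(i, j))
    }
  }
  best / tot
}
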