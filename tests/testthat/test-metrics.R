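test_that("whitening matrix decorrelates to the identity", {
  set.seed(61)
  Z <- matrix(rnorm(5e4), 5e3, 10)
  expect_equal(whitening_matrix(Z), diag(10), tolerance = 0.1,
               ignore_attr = TRUE)
  # diagonal covariance: closed form
  X2 <- cbind(rnorm(2e4, sd = 2), rnorm(2e4, sd = 1))
  X2 <- sweep(X2, 2, colMeans(X2))
  M2 <- whitening_matrix(X2)
  expect_equal(M2, diag(c(0.5, 1)), tolerance = 0.05, ignore_attr = TRUE)
  # random correlated data: M X has identity second moment
  A <- matrix(rnorm(100), 10, 10)
  X <- Z %*% t(A)
  M <- whitening_matrix(X)
  expect_equal(M, t(M), ignore_attr = TRUE)    # symmetric
  expect_true(all(eigen(M, symmetric = TRUE, only.values = TRUE)$values > 0))
  Xw <- X %*% t(M)
  expect_equal(crossprod(Xw) / nrow(Xw), diag(10), tolerance = 1e-8)
  # rank-deficient input
  Xr <- cbind(Z[, 1], Z[, 1], Z[, 2])
  expect_error(whitening_matrix(Xr), "rank")
  Mr <- whitening_matrix(Xr, pseudo_inverse = TRUE)
  expect_equal(attr(Mr, "rank"), 2L)
})

test_that("output SNR is the explained-to-residual variance ratio", {
  set.seed(62)
  lat <- rnorm(2e4)
  expect_equal(output_snr(lat, lat), Inf)
  expect_equal(output_snr(lat + rnorm(2e4), lat), 1, tolerance = 0.05)
  expect_lt(output_snr(rnorm(2e4), lat), 0.01)
  expect_equal(output_snr(rep(1, 100), rnorm(100)), 0)
})

test_that("optimal linear decoder recovers symmetric designs and SNR ordering", {
  set.seed(63)
  lat <- rnorm(3e4)
  d1 <- optimal_linear_decoder(matrix(lat, ncol = 1), lat)
  expect_equal(unname(d1$weights), 1, tolerance = 1e-8)
  expect_equal(d1$snr, Inf)
  # two channels, equal signal and independent equal noise: equal weights
  X <- cbind(lat + rnorm(3e4), lat + rnorm(3e4))
  d2 <- optimal_linear_decoder(X, lat)
  expect_equal(unname(d2$weights[1] / d2$weights[2]), 1, tolerance = 0.02)
  # noise dataset: decoder weights ordered by per-channel SNR
  b <- gen_subgroup_dataset("noise", 1e5, seed = 63)
  d3 <- optimal_linear_decoder(b$data, b$latent)
  mw <- vapply(b$groups[1:3], function(g) mean(d3$weights[g$channels]), 0)
  expect_true(all(diff(mw) > 0))   # noise sds decrease across subgroups
})

test_that("tuning estimation equals brute-force groupby averaging", {
  set.seed(64)
  theta <- runif(2e4)
  Y <- cbind(exp(-(theta - 0.5)^2 / (2 * 0.05^2)), rnorm(2e4))
  tun <- estimate_tuning(Y, theta, n_bins = 32, min_count = 20)
  bin <- pmin(floor(theta * 32) + 1, 32)
  for (b in c(1, 16, 32)) {
    expect_equal(tun$mean_response[, b], colMeans(Y[bin == b, ]))
  }
  # deterministic tuning recovered within bin discretisation
  peak_bin <- which.max(tun$mean_response[1, ])
  expect_lt(abs(tun$theta_grid[peak_bin] - 0.5), 1 / 32)
  # flat response for pure noise
  expect_lt(diff(range(tun$mean_response[2, ])), 6 / sqrt(2e4 / 32))
  expect_error(estimate_tuning(Y, theta, n_bins = 32, min_count = 1e5),
               "occupancy")
})

test_that("FWHM matches closed forms and is affine invariant", {
  grid <- (seq_len(256) - 0.5) / 256
  curve <- exp(-(pmin(abs(grid - 0.5), 1 - abs(grid - 0.5)))^2 / (2 * 0.05^2))
  w <- fwhm(curve, grid)
  expect_equal(w, 2 * sqrt(2 * log(2)) * 0.05, tolerance = 0.005)
  # triangular peak of half-width h has FWHM exactly h (linear
  # interpolation is exact when the apex sits on a sample point)
  tri <- pmax(0, 1 - abs(grid - grid[128]) / 0.1)
  expect_equal(fwhm(tri, grid), 0.1, tolerance = 1e-10)
  # invariant to positive affine rescaling
  expect_equal(fwhm(5 * curve + 2, grid), w)
  expect_error(fwhm(rep(1, 64)), "flat")
  # peak wrapping across the origin is handled circularly
  curve2 <- exp(-(pmin(abs(grid - 0.01), 1 - abs(grid - 0.01)))^2 / (2 * 0.05^2))
  expect_equal(fwhm(curve2, grid), w, tolerance = 0.01)
})

test_that("Fisher information matches the single-neuron closed form and scalings", {
  n_bins <- 64
  grid <- (seq_len(n_bins) - 0.5) / n_bins
  mu <- matrix(exp(-(pmin(abs(grid - 0.5), 1 - abs(grid - 0.5)))^2 /
                     (2 * 0.08^2)), 1, n_bins)
  sdm <- matrix(0.3, 1, n_bins)
  tun <- structure(list(theta_grid = grid, mean_response = mu,
                        response_sd = sdm, n_per_bin = rep(100, n_bins),
                        bin_index = NULL),
                   class = "tuning_curve_set")
  J <- fisher_information(tun, Y = NULL, reg = 0)
  # closed form with central differences on the same grid
  left <- c(n_bins, 1:(n_bins - 1)); right <- c(2:n_bins, 1)
  fp <- (mu[1, right] - mu[1, left]) / (2 / n_bins)
  expect_equal(J, mean(fp^2 / 0.3^2), tolerance = 1e-10)
  # doubling the noise sd divides FI by 4
  tun2 <- tun; tun2$response_sd <- 2 * sdm
  expect_equal(fisher_information(tun2, Y = NULL, reg = 0), J / 4)
  # two identical independent neurons double the information
  tun3 <- tun
  tun3$mean_response <- rbind(mu, mu)
  tun3$response_sd <- rbind(sdm, sdm)
  expect_equal(fisher_information(tun3, Y = NULL, reg = 0), 2 * J)
})

test_that("width-weight correlation has the right edge cases and null", {
  W <- matrix(rnorm(32), 4, 8)
  expect_error(weight_width_correlation(W, rep(0.05, 8)), "degenerate")
  widths <- seq(0.02, 0.09, length.out = 8)
  W2 <- matrix(rep(0.5 - 2 * widths, each = 4), 4, 8)  # positive, decreasing
  expect_equal(weight_width_correlation(W2, widths), -1)
  # null distribution: random weights give small |rho| on most seeds
  hits <- vapply(1:10, function(s) {
    set.seed(100 + s)
    Wn <- matrix(rnorm(16 * 100), 16, 100)
    abs(weight_width_correlation(Wn, runif(100, 0.02, 0.1))) < 0.2
  }, TRUE)
  expect_gte(sum(hits), 8)
})

test_that("localization index equals the exhaustive window scan", {
  m <- matrix(0, 16, 16); m[5, 7] <- 2
  expect_equal(rf_localization_index(m), 1)
  expect_equal(rf_localization_index(matrix(1, 16, 16)), 16 / 256)
  set.seed(66)
  r <- matrix(rnorm(64), 8, 8)
  k <- 2
  brute <- max(vapply(1:7, function(i) {
    max(vapply(1:7, function(j) sum(r[i:(i + 1), j:(j + 1)]^2), 0))
  }, 0))
  expect_equal(rf_localization_index(r, k = 2), brute / sum(r^2))
  expect_error(rf_localization_index(matrix(0, 8, 8)), "zero")
})
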