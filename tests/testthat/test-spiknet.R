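test_that("LIF integration has the right fixed points and threshold semantics", {
  p <- lif_params()
  r <- lif_step(rep(p$v_rest, 3), rep(0, 3), p)
  expect_equal(r$v, rep(p$v_rest, 3))
  expect_false(any(r$spike))
  # constant subthreshold drive: v_inf = v_rest + I * tau_mem / dt
  I <- 0.8
  v <- p$v_rest
  for (i in 1:500) v <- lif_step(v, I, p)$v
  expect_equal(v, p$v_rest + I * p$tau_mem / p$dt, tolerance = 1e-6)
  # threshold is inclusive (>=) and resets: input exactly cancelling the
  # leak keeps v pinned at -50, which must fire
  leak_at_thr <- p$dt / p$tau_mem * (p$v_threshold - p$v_rest)
  r3 <- lif_step(p$v_threshold, leak_at_thr, p)
  expect_true(r3$spike)
  expect_equal(r3$v, p$v_reset)
  expect_error(lif_params(tau_mem = 3, dt = 1), "dt")
})

test_that("Poisson encoding has the right mean and is seed-deterministic", {
  expect_equal(sum(poisson_encode(0, 1000, seed = 1)), 0)
  counts <- colSums(poisson_encode(rep(50, 2e4), 100, dt = 1, seed = 2))
  expect_equal(mean(counts), 5, tolerance = 0.05)
  expect_identical(poisson_encode(c(10, 20), 500, seed = 3),
                   poisson_encode(c(10, 20), 500, seed = 3))
  expect_false(identical(poisson_encode(c(10, 20), 500, seed = 3),
                         poisson_encode(c(10, 20), 500, seed = 4)))
  expect_error(poisson_encode(2000, 100, dt = 1), "dt")
})

test_that("triplet update follows the two-spike event algebra", {
  params <- triplet_params(eta_plus = 0.01, eta_minus = 0.01,
                           lambda_decay = 0, ltd_scale = 1)
  W <- matrix(0.5, 1, 2)
  fresh <- list(xbar_plus = c(0, 0), ybar_plus = 0, ybar_minus = 0, h_y = 100)
  # pre spike with no postsynaptic trace: nothing happens
  W1 <- triplet_update(W, c(1, 0), 0, fresh, params)
  expect_equal(W1, W)
  # post spike 10 ms later: pre trace decayed, but ybar_plus still 0 -> no LTP;
  # LTD needs a pre spike at the post time -> no change either
  tr <- list(xbar_plus = c(exp(-10 / 30), 0), ybar_plus = 0, ybar_minus = 0,
             h_y = 100)
  W2 <- triplet_update(W1, c(0, 0), 1, tr, params)
  expect_equal(W2, W1)
  # second post spike with a standing post trace -> LTP on the traced channel
  tr2 <- list(xbar_plus = c(0.7, 0), ybar_plus = 0.9, ybar_minus = 0.9,
              h_y = 100)
  W3 <- triplet_update(W2, c(0, 0), 1, tr2, params)
  expect_equal(W3[1, 1], W2[1, 1] + 0.01 * 0.9 * 0.7)
  expect_equal(W3[1, 2], W2[1, 2])
  # pre spike against a standing LTD trace -> depression scaled by h_y
  tr3 <- list(xbar_plus = c(0.7, 0), ybar_plus = 0.9, ybar_minus = 0.9,
              h_y = 1)
  W4 <- triplet_update(W3, c(1, 0), 0, tr3, params)
  expect_equal(W4[1, 1], W3[1, 1] - 0.01 * 1 * 1 * 0.9)
  # weight decay alone, spikes absent
  pd <- triplet_params(eta_plus = 0, eta_minus = 0, lambda_decay = 0.05)
  Wd <- matrix(1, 1, 2)
  for (i in 1:1000) Wd <- triplet_update(Wd, c(0, 0), 0, fresh, pd)
  expect_equal(Wd[1, 1], (1 - 0.05 / 1000)^1000, tolerance = 1e-9)
})

test_that("triplet drift in a Poisson regime matches the rate-based reduction", {
  # independent pre/post Poisson trains, frozen h; expected drift per second:
  # LTP eta+ nu_y^2 nu_x tau^2 - LTD eta- h nu_x nu_y tau  (unitless traces)
  set.seed(42)
  nu_x <- 40; nu_y <- 20; tau <- 0.03
  h <- 1
  params <- triplet_params(eta_plus = 1e-3, eta_minus = 1e-3,
                           lambda_decay = 0, ltd_scale = 1, w_max = 1e6)
  n_steps <- 4e5
  dec <- exp(-1 / 30)
  W <- matrix(50, 1, 1)    # large start so depression cannot clip at zero
  xb <- 0; yb_p <- 0; yb_m <- 0
  for (t in seq_len(n_steps)) {
    sx <- runif(1) < nu_x / 1000
    sy <- runif(1) < nu_y / 1000
    xb <- xb * dec + sx
    W <- triplet_update(W, sx, sy,
                        list(xbar_plus = xb, ybar_plus = yb_p,
                             ybar_minus = yb_m, h_y = h),
                        params)
    yb_p <- yb_p * dec + sy
    yb_m <- yb_m * dec + sy
  }
  drift <- (W[1, 1] - 50) / (n_steps / 1000)    # per second
  expected <- 1e-3 * nu_y^2 * nu_x * tau^2 - 1e-3 * h * nu_x * nu_y * tau
  expect_equal(drift, expected, tolerance = 0.2)
})

test_that("inhibitory STDP decays when silent and potentiates with activity", {
  W <- matrix(c(0, -1, -0.4, 0), 2, 2)
  tr0 <- list(xbar = c(0, 0), ybar = c(0, 0))
  W1 <- inhibitory_stdp_update(W, c(0, 0), c(0, 0), tr0)
  expect_equal(W1, W * (1 - 3 / 1000))
  expect_equal(diag(W1), c(0, 0))
  # post spike while the presynaptic trace is high: more inhibition
  tr <- list(xbar = c(0, 2), ybar = c(0, 0))
  W2 <- inhibitory_stdp_update(W, c(0, 0), c(1, 0), tr)
  expect_lt(W2[1, 2], W[1, 2] * (1 - 3 / 1000))
  expect_true(all(W2 <= 0))
})

test_that("spiking development is seed-deterministic and clamps weights", {
  p <- gen_image_patches(patch_spec(patch_size = 8), 300, seed = 51)
  tp <- triplet_params(variant = "linear_ltd", eta_plus = 5e-4,
                       eta_minus = 5e-4, ltd_scale = 0.01, tau_h = 10,
                       lambda_decay = 0.005, w_max = 3)
  d1 <- run_development(p, n_neurons = 4, triplet = tp, seed = 51,
                        record_rate_every = 0)
  d2 <- run_development(p, n_neurons = 4, triplet = tp, seed = 51,
                        record_rate_every = 0)
  expect_identical(d1$W_exc, d2$W_exc)
  expect_true(all(d1$W_exc >= 0 & d1$W_exc <= 3))
  expect_equal(length(d1$rf_maps), 4)
  expect_equal(dim(d1$rf_maps[[1]]), c(8, 8))
  # plasticity off, decay only: weights stay within the init envelope
  tp0 <- triplet_params(eta_plus = 0, eta_minus = 0, lambda_decay = 0.05)
  d3 <- run_development(p, n_neurons = 4, triplet = tp0, seed = 51,
                        record_rate_every = 0)
  expect_true(all(d3$W_exc <= 1))
  expect_lt(mean(d3$W_exc), 0.5)   # 30 s of decay at 0.05/s
})
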