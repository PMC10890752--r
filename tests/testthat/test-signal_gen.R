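test_that("sparse ON/OFF generator has the renewal-process duty cycle", {
  spec <- group_spec("s", 3, "sparse_on_off", signal_sd = 1, noise_sd = 0,
                     timescale_ms = 1000)
  # duty cycle = on / (on + mean ISI) = 100 / 1100; averaged over seeds to
  # beat the ~90-event-per-trace sampling error
  on_frac <- mean(vapply(11:14, function(sd) {
    mean(gen_sparse_on_off(2e5, spec, seed = sd)$latent > 0)
  }, 0))
  expect_lt(abs(on_frac - 100 / 1100), 0.01)
  res <- gen_sparse_on_off(1e5, spec, seed = 11)
  # all channels share the common latent exactly (no noise here)
  expect_equal(res$data[, 1], res$data[, 2])
  expect_equal(max(abs(colMeans(res$data))), 0, tolerance = 1e-12)
})

test_that("zero-amplitude sparse group degenerates to pure noise", {
  spec <- group_spec("s", 4, "sparse_on_off", signal_sd = 0, noise_sd = 0.5)
  res <- gen_sparse_on_off(5e3, spec, seed = 1)
  expect_true(all(res$latent == 0))
  expect_lt(abs(sd(res$data[, 1]) - 0.5), 0.05)
  bad <- group_spec("s", 1, "sparse_on_off")
  bad$timescale_ms <- -5
  expect_error(gen_sparse_on_off(10, bad, 1), "timescale")
})

test_that("OU generator has the right autocorrelation and Gaussian marginals", {
  spec <- group_spec("o", 1, "ou", signal_sd = 1, noise_sd = 0,
                     timescale_ms = 200)
  res <- gen_ou(1e6, spec, seed = 2)
  x <- res$latent
  lag_ac <- cor(x[-(1:200)], x[1:(length(x) - 200)])
  expect_lt(abs(lag_ac - exp(-1)), 0.05)
  kurt <- mean(x^4) / mean(x^2)^2 - 3
  expect_lt(abs(kurt), 0.15)
  expect_lt(abs(sd(x) - 1), 0.05)
})

test_that("selectivity dataset matches its design", {
  b <- gen_selectivity_dataset(1e5, seed = 3)
  expect_equal(ncol(b$data), 60)
  expect_equal(vapply(b$groups, function(g) length(g$channels), 0L),
               c(20L, 20L, 20L))
  expect_lt(max(abs(colMeans(b$data))), 1e-12)
  # sparse group marginals are super-Gaussian, OU group is Gaussian
  kurt <- function(x) mean(x^4) / mean(x^2)^2 - 3
  k_sparse <- kurt(b$data[, 1] )
  k_net <- kurt(b$data[, 21])
  expect_gt(k_sparse, 1)
  expect_lt(abs(k_net), 0.5)
  expect_gt(k_sparse, k_net)
  # noise group per-channel sd
  expect_lt(abs(sd(b$data[, 41]) - 2.2), 0.05)
})

test_that("generators are pure functions of (spec, n, seed)", {
  b1 <- gen_selectivity_dataset(2e4, seed = 9)
  b2 <- gen_selectivity_dataset(2e4, seed = 9)
  expect_identical(b1$data, b2$data)
  b3 <- gen_selectivity_dataset(2e4, seed = 10)
  expect_false(identical(b1$data, b3$data))
})

test_that("subgroup datasets realise equal SNR or equal amplitude", {
  amp <- gen_subgroup_dataset("amplitude", 1e5, seed = 4)
  # SNR = signal_sd / noise_sd identical across the three sparse subgroups
  snrs <- vapply(amp$groups[1:3],
                 function(g) g$spec$signal_sd / g$spec$noise_sd, 0)
  expect_lt(diff(range(snrs)) / mean(snrs), 0.02)
  # realised common-component loading scales with the nominal amplitude
  u <- vapply(1:3, function(i) {
    ch <- amp$groups[[i]]$channels[1]
    coef(lm(amp$data[, ch] ~ amp$latent))[2]
  }, 0)
  expect_equal(unname(u / u[2]), c(1.5, 1, 0.7), tolerance = 0.05)

  noi <- gen_subgroup_dataset("noise", 1e5, seed = 4)
  sig <- vapply(noi$groups[1:3], function(g) g$spec$signal_sd, 0)
  expect_true(all(sig == sig[1]))
  expect_equal(vapply(noi$groups[1:3], function(g) g$spec$noise_sd, 0),
               c(1.5, 1, 0.7))

  empty <- gen_subgroup_dataset("amplitude", 0, seed = 1)
  expect_equal(nrow(empty$data), 0)
  expect_equal(length(empty$groups), 5L)
  expect_error(gen_subgroup_dataset("bogus", 10, 1))
})

test_that("population dataset encodes a mixing circular latent", {
  spec <- tuning_population_spec()
  b <- gen_population_dataset(spec, 5e4, seed = 5)
  expect_equal(ncol(b$data), 100)
  expect_true(all(b$latent >= 0 & b$latent < 1))
  expect_equal(b$tuning$widths, rep(0.05, 100))
  expect_equal(diff(b$tuning$centers), rep(0.01, 99))
  expect_lt(max(abs(colMeans(b$data))), 1e-12)
  # heterogeneity off -> all multipliers exactly one
  expect_equal(b$tuning$amps, rep(1, 100))
  # latent occupancy approximately uniform over a long trajectory
  th <- gen_latent_walk(1e6, 100, 0.01, seed = 6)
  counts <- tabulate(floor(th * 20) + 1, 20)
  expect_lt(max(abs(counts / 5e4 - 1)), 0.2)
  expect_error(gen_population_dataset(tuning_population_spec(n_inputs = 1),
                                      100, 1))
})

test_that("heterogeneous population has strictly positive log-normal jitter", {
  spec <- tuning_population_spec(heterogeneity_sd = 0.2)
  b <- gen_population_dataset(spec, 2e4, seed = 7)
  expect_true(all(b$tuning$widths > 0))
  expect_true(all(b$tuning$amps > 0))
  expect_gt(sd(b$tuning$widths), 0)
  expect_lt(abs(mean(log(b$tuning$widths / 0.05))), 0.1)
})

test_that("image patches are spatially correlated with disjoint ON/OFF split", {
  p <- gen_image_patches(patch_spec(patch_size = 8), 500, seed = 8)
  expect_true(all(p$on * p$off == 0))
  expect_true(all(p$on >= 0) && all(p$off >= 0))
  expect_true(all(p$on <= p$spec$rate_cap))
  cc <- vapply(1:500, function(k) {
    cor(as.vector(p$patches[k, 1:7, ]), as.vector(p$patches[k, 2:8, ]))
  }, 0)
  expect_gt(mean(cc), 0.3)
  expect_lt(max(abs(apply(p$patches, 1, mean))), 1e-12)
  expect_error(patch_spec(patch_size = 3), "patch_size")
})

test_that("linear mixing transforms the covariance as L Cov L'", {
  b <- gen_selectivity_dataset(5e4, seed = 12)
  expect_identical(apply_linear_mixing(b, diag(60))$data, b$data)
  b2 <- apply_linear_mixing(b, 2 * diag(60))
  expect_equal(apply(b2$data, 2, sd), 2 * apply(b$data, 2, sd))
  set.seed(1)
  Q <- qr.Q(qr(matrix(rnorm(3600), 60, 60)))
  bm <- apply_linear_mixing(b, Q)
  expect_true(bm$mixed)
  C <- crossprod(b$data) / nrow(b$data)
  Cm <- crossprod(bm$data) / nrow(bm$data)
  expect_equal(Cm, Q %*% C %*% t(Q), tolerance = 1e-8)
  L_sing <- diag(60); L_sing[1, 1] <- 0
  expect_error(apply_linear_mixing(b, L_sing), "singular")
})
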