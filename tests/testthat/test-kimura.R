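test_that("mass, mean and variance identities hold on a (p, b) subgrid", {
  # the full 10 x 10 grid runs in the acceptance suite
  for (p in c(0.05, 0.35, 0.65, 0.95)) {
    for (b in c(0.05, 0.5, 0.95)) {
      kd <- kimura_distribution(p, b)
      mom <- kimura_moments(kd)
      expect_lt(abs(mom$mass - 1), 1e-6)
      expect_lt(abs(mom$mean - p), 1e-6)
      expect_lt(abs(mom$var - p * (1 - p) * (1 - b)), 1e-6)
    }
  }
})

test_that("no-drift limit degenerates at p; parameter validation", {
  kd <- kimura_distribution(0.4, 0.999999999999)
  expect_true(kd$degenerate)
  expect_equal(kd$mean, 0.4)
  expect_equal(kd$loss_mass + kd$fixation_mass, 0)
  expect_warning(x <- kimura_sample(kd, 10, seed = 1), "degenerate")
  expect_equal(x, rep(0.4, 10))

  # near-degenerate but proper: mass concentrates around p
  kd2 <- kimura_distribution(0.4, 0.999)
  expect_lt(kd2$loss_mass + kd2$fixation_mass, 1e-8)
  expect_equal(kd2$variance, 0.4 * 0.6 * 0.001, tolerance = 1e-4)

  expect_error(kimura_distribution(0, 0.5), "strictly in")
  expect_error(kimura_distribution(0.5, -0.1), "in \\[0, 1\\]")
  expect_error(kimura_distribution(0.5, 0.5, tolerance = 0.1), "tolerance")
})

test_that("mirror symmetry: (p, b) under x -> 1-x equals (1-p, b)", {
  p <- 0.25
  b <- 0.6
  kd <- kimura_distribution(p, b)
  mir <- kimura_distribution(1 - p, b)
  expect_equal(kd$loss_mass, mir$fixation_mass, tolerance = 1e-10)
  expect_equal(kd$fixation_mass, mir$loss_mass, tolerance = 1e-10)
  xs <- c(0.1, 0.3, 0.5, 0.77)
  expect_equal(kd$density(xs), mir$density(1 - xs), tolerance = 1e-9)
})

test_that("Kimura distribution matches the Wright-Fisher oracle", {
  # one config here; the N x b grid runs in the acceptance suite
  N <- 50
  t <- 34                      # (1 - 1/50)^34 ~ 0.50
  b <- (1 - 1 / N)^t
  kd <- kimura_distribution(0.5, b)
  wf <- wf_oracle(0.5, N, t, n_rep = 1e5, seed = 99)
  expect_lt(lattice_tv(kd, wf, N), 0.02)
})

test_that("sampling is deterministic and reproduces the moments", {
  kd <- kimura_distribution(0.3, 0.7)
  x1 <- kimura_sample(kd, 1000, seed = 5)
  x2 <- kimura_sample(kd, 1000, seed = 5)
  expect_identical(x1, x2)
  expect_false(identical(x1, kimura_sample(kd, 1000, seed = 6)))

  x <- kimura_sample(kd, 1e6, seed = 11)
  se_mean <- sd(x) / sqrt(length(x))
  expect_lt(abs(mean(x) - 0.3), 3 * se_mean)
  v <- var(x)
  se_var <- sd((x - mean(x))^2) / sqrt(length(x))
  expect_lt(abs(v - 0.3 * 0.7 * 0.3), 3 * se_var)
  # atoms appear at the boundaries with roughly the right frequency
  expect_equal(mean(x == 0), kd$loss_mass, tolerance = 0.01)
})

test_that("estimate_b recovers the drift parameter and handles edge cases", {
  kd <- kimura_distribution(0.3, 0.7)
  ok <- 0
  for (r in 1:50) {
    h <- kimura_sample(kd, 500, seed = 1000 + r)
    fit <- estimate_b(rep(0.3, 500), h)
    ok <- ok + (abs(fit$b_hat - 0.7) <= 0.05)
  }
  expect_gte(ok, 47)  # 95% criterion at full scale runs in acceptance

  # zero dispersion -> 1-limit flag
  fit <- estimate_b(rep(0.4, 10), rep(0.4, 10))
  expect_true(fit$no_drift)
  expect_lt(fit$b_hat, 1)
  # complete fixation/loss at mean h0 -> b_hat = 0
  h0 <- rep(0.5, 400)
  h <- rep(c(0, 1), 200)
  expect_warning(fit0 <- estimate_b(h0, h), NA)
  expect_equal(fit0$b_hat, 0, tolerance = 1e-12)
  expect_error(estimate_b(0.5, 0.5), "at least 2")
  expect_error(estimate_b(c(0, 0.5), c(0.1, 0.2)), "strictly in")
})

test_that("ks_distance agrees with stats::ks.test", {
  set.seed(3)
  for (r in 1:20) {
    x <- rnorm(sample(5:50, 1))
    y <- rnorm(sample(5:200, 1), mean = runif(1, -1, 1))
    expect_equal(mitodrift:::ks_distance(x, y),
                 unname(suppressWarnings(stats::ks.test(x, y)$statistic)))
  }
})
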