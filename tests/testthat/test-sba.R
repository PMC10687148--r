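test_that("the closed box gives exactly zero fluctuation at lambda = 1", {
  g <- gen_binomial_gas(200, 5, 3, seed = 2)
  fc <- subvolume_fluctuations(g$trajectory, lambda = c(0.3, 1), placements = 8,
                               seed = 1)
  expect_identical(fc$chi[fc$lambda == 1], 0)
  expect_equal(fc$mean_N[fc$lambda == 1], 200)
})

test_that("lambda outside (0, 1] is rejected", {
  g <- gen_binomial_gas(10, 5, 1, seed = 2)
  expect_error(subvolume_fluctuations(g$trajectory, lambda = c(0, 0.5)),
               "lambda")
  expect_error(subvolume_fluctuations(g$trajectory, lambda = 1.2), "lambda")
})

test_that("binomial gas follows chi = 1 - lambda^3 at every grid point", {
  g <- gen_binomial_gas(2000, 10, 60, seed = 7)
  fc <- subvolume_fluctuations(g$trajectory, placements = 64, seed = 3)
  open_l <- fc$lambda < 1
  dev <- abs(fc$chi[open_l] - (1 - fc$lambda[open_l]^3)) / fc$stderr[open_l]
  expect_lt(max(dev), 3)
})

test_that("co-located particles give the two-point count law chi = N(1 - p)", {
  N <- 100
  pt <- matrix(rep(c(2.2, 3.3, 4.4), each = N), ncol = 3)
  traj <- trajectory(list(frame(pt, 10)))
  lam <- 0.5
  fc <- subvolume_fluctuations(traj, lambda = lam, placements = 20000,
                               seed = 5, n_blocks = 2)
  # counts are either 0 or N, so chi = N(1 - p_hat) exactly, with p_hat the
  # observed coverage fraction; p_hat must sit inside its binomial band
  p_hat <- 1 - fc$chi / N
  p <- lam^3
  expect_lt(abs(p_hat - p), 4 * sqrt(p * (1 - p) / 20000))
})

test_that("a noiseless finite-size-model curve is recovered exactly", {
  lambda <- seq(0.05, 0.95, length.out = 20)
  chi_inf <- 0.05
  intercept <- 0.002
  chi <- chi_inf * (1 - lambda^3) + intercept / lambda
  curve <- structure(
    data.frame(lambda = lambda, chi = chi, stderr = 0, mean_N = 1000),
    class = c("fluct_curve", "data.frame"), V0 = 1000, rho = 5,
    placements = 1, seed = 1)
  fit <- suppressWarnings(sba_fit(curve, window = c(0.05, 0.30), temperature = 300))
  expect_equal(fit$chi_inf, chi_inf, tolerance = 1e-12)
  expect_equal(fit$intercept, intercept, tolerance = 1e-12)
  # window robustness: any sub-window returns the same parameters
  fit2 <- suppressWarnings(sba_fit(curve, window = c(0.05, 0.15), temperature = 300))
  expect_equal(fit2$chi_inf, chi_inf, tolerance = 1e-10)
  # full-curve prediction reproduces the generating curve
  expect_equal(fit$prediction$chi, chi, tolerance = 1e-10)
})

test_that("degenerate fits error or flag instead of failing silently", {
  lambda <- c(0.1, 0.2)
  curve <- structure(
    data.frame(lambda = lambda, chi = 1, stderr = 0, mean_N = 100),
    class = c("fluct_curve", "data.frame"), V0 = 1000, rho = 5,
    placements = 1, seed = 1)
  expect_error(sba_fit(curve), "at least 3")
  lambda <- seq(0.05, 0.28, length.out = 6)
  # y = lambda * chi = 0.3 - lambda: a genuinely negative slope
  curve <- structure(
    data.frame(lambda = lambda, chi = (0.3 - lambda) / lambda, stderr = 0,
               mean_N = 100),
    class = c("fluct_curve", "data.frame"), V0 = 1000, rho = 5,
    placements = 1, seed = 1)
  expect_warning(fit <- sba_fit(curve), "negative slope")
  expect_true(fit$flagged)
})

test_that("low-occupancy lambda points are excluded with a message", {
  g <- gen_binomial_gas(300, 10, 5, seed = 6)
  fc <- subvolume_fluctuations(g$trajectory, placements = 32, seed = 1)
  expect_message(try(sba_fit(fc), silent = TRUE), "excluded")
})

test_that("binomial-gas SBA fit recovers chi_inf = 1 with zero intercept", {
  g <- gen_binomial_gas(3000, 10, 60, seed = 14)
  lam <- c(seq(0.05, 0.30, by = 0.0125), seq(0.35, 1, by = 0.05))
  fc <- subvolume_fluctuations(g$trajectory, lambda = lam, placements = 128,
                               seed = 4)
  fit <- suppressMessages(sba_fit(fc, temperature = 300))
  expect_gt(fit$chi_inf, 0.95)
  expect_lt(fit$chi_inf, 1.05)
  expect_lt(abs(fit$intercept), 0.01)
})

test_that("identical seeds give bit-identical fluctuation curves", {
  g <- gen_binomial_gas(400, 6, 5, seed = 3)
  f1 <- subvolume_fluctuations(g$trajectory, placements = 16, seed = 99)
  f2 <- subvolume_fluctuations(g$trajectory, placements = 16, seed = 99)
  expect_identical(f1$chi, f2$chi)
  f3 <- subvolume_fluctuations(g$trajectory, placements = 16, seed = 100)
  expect_false(identical(f3$chi, f1$chi))
})

test_that("volume-fluctuation estimator matches closed forms", {
  expect_equal(kappa_from_volume_fluctuations(rep(1000, 50), 300)$kappa_Pa, 0)
  V1 <- 1010; V2 <- 990
  kB <- 1.380649e-23
  k <- kappa_from_volume_fluctuations(rep(c(V1, V2), 50), 300)
  closed <- (V1 - V2)^2 / (2 * kB * 300 * (V1 + V2)) * 1e-27
  expect_equal(k$kappa_Pa, closed, tolerance = 1e-12)
  expect_error(kappa_from_volume_fluctuations(1000, 300), "2 volume samples")
})

test_that("Gaussian volume series recovers the planted compressibility", {
  vs <- gen_volume_series(2200, 25, 1e5, seed = 21, temperature = 300)
  k <- kappa_from_volume_fluctuations(vs$volumes, 300)
  expect_lt(abs(k$kappa_Pa - vs$spec$truth$kappa_Pa) / vs$spec$truth$kappa_Pa,
            0.05)
})

test_that("fit-window halving moves chi_inf by less than its standard error", {
  g <- gen_binomial_gas(4000, 10, 50, seed = 13)
  lam <- c(seq(0.05, 0.30, by = 0.01), seq(0.35, 1, by = 0.05))
  fc <- subvolume_fluctuations(g$trajectory, lambda = lam, placements = 96,
                               seed = 5)
  full <- suppressMessages(sba_fit(fc, window = c(0.05, 0.30)))
  half <- suppressMessages(sba_fit(fc, window = c(0.05, 0.18)))
  se <- sqrt(full$chi_inf_se^2 + half$chi_inf_se^2)
  expect_lt(abs(full$chi_inf - half$chi_inf), 3 * se)
})
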