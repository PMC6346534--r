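test_that("squared-exponential kernel matches its closed form", {
  h <- list(signal_sd = 1, noise_sd = 0.1, lengthscale = 2)
  expect_equal(se_kernel(3, 3, h)[1, 1], 1)
  expect_equal(se_kernel(0, 2 * sqrt(2), h)[1, 1], exp(-1))
  h2 <- list(signal_sd = 1.7, noise_sd = 0.1, lengthscale = 0.8)
  tt <- c(0, 0.3, 1.1, 2.5)
  K <- se_kernel(tt, tt, h2)
  expect_equal(K, t(K))
  expect_equal(diag(K), rep(1.7^2, 4))
})

test_that("log marginal likelihood matches scalar and dense oracles", {
  # D = 1, x = 0, total variance 1: standard normal log-density at 0
  h <- list(signal_sd = sqrt(0.5), noise_sd = sqrt(0.5), lengthscale = 1)
  expect_equal(gp_log_marginal_likelihood(0, 0, h), -0.5 * log(2 * pi),
               tolerance = 1e-7)
  # D = 1, x = a: univariate normal log-pdf
  a <- 1.7; v <- 0.3^2 + 0.9^2
  h2 <- list(signal_sd = 0.3, noise_sd = 0.9, lengthscale = 5)
  expect_equal(gp_log_marginal_likelihood(a, 2, h2),
               -a^2 / (2 * v) - 0.5 * log(v) - 0.5 * log(2 * pi),
               tolerance = 1e-6)
  # random instances vs naive dense evaluation
  set.seed(31)
  for (i in 1:10) {
    D <- sample(3:10, 1)
    tt <- sort(runif(D, 0, 10))
    y <- rnorm(D)
    h3 <- list(signal_sd = runif(1, 0.5, 2), noise_sd = runif(1, 0.05, 1),
               lengthscale = runif(1, 0.5, 5))
    expect_equal(gp_log_marginal_likelihood(y, tt, h3),
                 as.numeric(dense_gp_loglik(y, tt, h3)), tolerance = 1e-8)
  }
})

test_that("log marginal likelihood is invariant to permuting observations", {
  set.seed(7)
  tt <- sort(runif(8, 0, 10)); y <- rnorm(8)
  h <- list(signal_sd = 1, noise_sd = 0.3, lengthscale = 2)
  base <- gp_log_marginal_likelihood(y, tt, h)
  for (i in 1:5) {
    p <- sample(8)
    expect_equal(gp_log_marginal_likelihood(y[p], tt[p], h), base,
                 tolerance = 1e-9)
  }
})

test_that("posterior mean and covariance match a dense oracle", {
  set.seed(11)
  for (i in 1:5) {
    D <- sample(2:10, 1)
    tt <- sort(runif(D, 0, 10)); y <- rnorm(D)
    h <- list(signal_sd = 1.2, noise_sd = 0.2, lengthscale = 1.5)
    fit <- structure(list(hyper = h, train_times = tt,
                          train_values = y - mean(y), train_mean = mean(y)),
                     class = "gp_fit")
    ts <- seq(-1, 11, length.out = 7)
    po <- gp_posterior(fit, ts)
    Ky <- se_kernel(tt, tt, h) + diag(h$noise_sd^2 + 1e-8 * h$signal_sd^2, D)
    Ks <- se_kernel(ts, tt, h)
    mean_ref <- Ks %*% solve(Ky) %*% (y - mean(y)) + mean(y)
    cov_ref <- se_kernel(ts, ts, h) - Ks %*% solve(Ky) %*% t(Ks)
    expect_equal(po$mean, as.numeric(mean_ref), tolerance = 1e-8)
    expect_equal(po$cov, cov_ref, tolerance = 1e-8)
    expect_true(all(diag(po$cov) > -1e-8))
  }
})

test_that("noiseless GP interpolates and reverts to the prior far away", {
  tt <- seq(0, 10, length.out = 6)
  y <- sin(tt) + 2
  h <- list(signal_sd = 1, noise_sd = 1e-6, lengthscale = 2)
  fit <- structure(list(hyper = h, train_times = tt,
                        train_values = y - mean(y), train_mean = mean(y)),
                   class = "gp_fit")
  po <- gp_posterior(fit, tt)
  expect_lt(max(abs(po$mean - y)), 1e-6)
  far <- gp_posterior(fit, 1e3)
  expect_equal(far$mean, mean(y), tolerance = 1e-6)
  expect_equal(far$cov[1, 1], h$signal_sd^2, tolerance = 1e-6)
})

test_that("analytic posterior derivative agrees with finite differences", {
  set.seed(13)
  n_ok <- 0L
  for (i in 1:20) {
    D <- sample(5:12, 1)
    tt <- sort(runif(D, 0, 10))
    y <- sin(tt) + 0.05 * rnorm(D)
    fit <- fit_gp(y, tt, restarts = 3, seed = i)
    ts <- seq(1, 9, length.out = 5)
    ana <- gp_posterior_derivative(fit, ts)
    eps <- 1e-6 * fit$hyper$lengthscale
    fd <- (gp_posterior(fit, ts + eps)$mean -
             gp_posterior(fit, ts - eps)$mean) / (2 * eps)
    # relative to the derivative scale of the fit (pointwise relative error
    # is ill-defined where the derivative crosses zero, and a fit that has
    # explained the data as noise has derivative zero everywhere)
    rel <- abs(ana - fd) / max(abs(fd), 1e-6)
    n_ok <- n_ok + all(rel < 1e-4)
  }
  expect_identical(n_ok, 20L)
})

test_that("derivative vanishes at a coincident single training point", {
  h <- list(signal_sd = 1, noise_sd = 0.1, lengthscale = 1)
  fit <- structure(list(hyper = h, train_times = 2, train_values = 0.7,
                        train_mean = 0), class = "gp_fit")
  expect_equal(gp_posterior_derivative(fit, 2), 0)
})

test_that("GP fitted to linear data recovers the slope in its derivative", {
  tt <- seq(0, 10, length.out = 21)
  y <- 1.5 + 0.4 * tt
  fit <- fit_gp(y, tt, restarts = 2, seed = 1, fixed_lengthscale = 20)
  d <- gp_posterior_derivative(fit, seq(2, 8, length.out = 5))
  expect_true(all(abs(d - 0.4) / 0.4 < 0.01))
})

test_that("fit_gp is deterministic, improves on its starts, and recovers
           known hyperparameters", {
  tt <- seq(0, 20, length.out = 41)
  set.seed(3)
  h_true <- list(signal_sd = 1, noise_sd = 0.1, lengthscale = exp(1))
  K <- se_kernel(tt, tt, h_true) + diag(h_true$noise_sd^2, 41)
  rel_err <- vapply(1:20, function(s) {
    set.seed(100 + s)
    y <- as.numeric(t(chol(K)) %*% rnorm(41))
    f <- fit_gp(y, tt, restarts = 4, seed = s)
    abs(log(f$hyper$lengthscale) - log(h_true$lengthscale)) /
      abs(log(h_true$lengthscale))
  }, numeric(1))
  expect_lt(median(rel_err), 0.3)
  set.seed(200); y <- as.numeric(t(chol(K)) %*% rnorm(41))
  f1 <- fit_gp(y, tt, restarts = 4, seed = 9)
  f2 <- fit_gp(y, tt, restarts = 4, seed = 9)
  expect_identical(f1$hyper, f2$hyper)
  expect_gte(f1$log_marginal_likelihood, max(f1$start_values) - 1e-8)
  expect_error(fit_gp(1:2, 1:2, seed = 1), "at least 3")
})

test_that("numeric forward difference matches its definition", {
  expect_equal(numeric_derivative(function(t) t^2, 1, delta = 1e-4),
               2 + 1e-4)
  expect_equal(numeric_derivative(function(t) rep(3, length(t)), c(1, 2)),
               c(0, 0))
  # close to the analytic GP derivative on a smooth fit
  tt <- seq(0, 10, length.out = 21)
  y <- sin(tt)
  fit <- fit_gp(y, tt, restarts = 3, seed = 2)
  ts <- seq(2, 8, length.out = 5)
  nd <- numeric_derivative(function(t) gp_posterior(fit, t)$mean, ts)
  ad <- gp_posterior_derivative(fit, ts)
  expect_equal(nd, ad, tolerance = 1e-3)
})

test_that("multi-output likelihood and posterior match dense Kronecker oracles", {
  set.seed(17)
  N <- 2; D <- 4
  tt <- c(0, 1, 2.5, 4)
  Y <- matrix(rnorm(D * N), D, N)
  L <- matrix(c(1.2, 0.5, 0, 0.8), 2, 2); L[1, 2] <- 0
  B <- L %*% t(L); sn <- 0.3; l <- 1.5
  nll <- grnmatch:::mogp_nll(Y, tt, L, sn, l)
  K <- exp(-outer(tt, tt, "-")^2 / (2 * l^2))
  Sig <- kronecker(B, K) + diag(sn^2, N * D)
  y <- as.vector(Y)
  dense <- 0.5 * t(y) %*% solve(Sig) %*% y +
    0.5 * as.numeric(determinant(Sig)$modulus) + N * D / 2 * log(2 * pi)
  expect_equal(nll, as.numeric(dense), tolerance = 1e-8)
  # joint covariance over stacked outputs has dimension (N*D)^2
  expect_identical(dim(Sig), c(8L, 8L))
  # posterior mean via the eigen identity vs dense solve
  fit <- structure(list(coreg_matrix = B, noise_sd = sn, lengthscale = l,
                        train_times = tt, train_Y = Y,
                        train_means = c(0, 0)), class = "mogp_fit")
  ts <- c(0.5, 3)
  pm <- predict(fit, ts)
  Ks <- exp(-outer(ts, tt, "-")^2 / (2 * l^2))
  cross <- cbind(B[, 1] %x% t(rep(1, 1)), B[, 2]) # per-gene blocks below
  dense_mean <- sapply(1:N, function(n) {
    Kcross <- do.call(cbind, lapply(1:N, function(m) B[n, m] * Ks))
    as.numeric(Kcross %*% solve(Sig) %*% y)
  })
  expect_equal(pm, dense_mean, tolerance = 1e-8)
})

test_that("identity coregionalisation decouples into single-output posteriors", {
  tt <- seq(0, 10, length.out = 8)
  Y <- rbind(sin(tt), cos(tt))
  fit <- structure(list(coreg_matrix = diag(2), noise_sd = 0.1,
                        lengthscale = 2, train_times = tt, train_Y = t(Y),
                        train_means = c(0, 0)), class = "mogp_fit")
  ts <- seq(0, 10, length.out = 11)
  pm <- predict(fit, ts)
  h <- list(signal_sd = 1, noise_sd = 0.1, lengthscale = 2)
  for (g in 1:2) {
    single <- structure(list(hyper = h, train_times = tt,
                             train_values = Y[g, ], train_mean = 0),
                        class = "gp_fit")
    expect_equal(pm[, g], gp_posterior(single, ts)$mean, tolerance = 1e-6)
  }
})

test_that("duplicated outputs yield a near-perfect coregionalisation correlation", {
  tt <- seq(0, 10, length.out = 15)
  set.seed(5)
  y <- sin(tt) + 0.01 * rnorm(15)
  fit <- fit_multioutput_gp(rbind(y, y), tt, restarts = 2, seed = 1)
  B <- fit$coreg_matrix
  expect_gte(B[1, 2] / sqrt(B[1, 1] * B[2, 2]), 0.95)
})

test_that("multi-output fit is deterministic given the seed", {
  tt <- seq(0, 10, length.out = 9)
  set.seed(8)
  Y <- rbind(sin(tt), cos(tt), sin(2 * tt)) + 0.05 * matrix(rnorm(27), 3)
  f1 <- fit_multioutput_gp(Y, tt, restarts = 2, seed = 4)
  f2 <- fit_multioutput_gp(Y, tt, restarts = 2, seed = 4)
  expect_identical(f1$coreg_matrix, f2$coreg_matrix)
  expect_identical(f1$lengthscale, f2$lengthscale)
})

test_that("smooth_dataset honours shape contracts and recovers decay dynamics", {
  spec <- decay_spec(s = 0, gamma = 0.2, x0 = 2)
  tt <- seq(0, 15, length.out = 16)
  d <- simulate_deterministic(spec, tt)
  sm <- smooth_dataset(d, "single_output", n_pred = 21, restarts = 3, seed = 1)
  expect_identical(length(sm$pred_times), 21L)
  expect_identical(dim(sm$values), c(1L, 21L))
  expect_identical(dim(sm$derivatives), c(1L, 21L))
  # derivatives of a pure-decay gene satisfy dx/dt = -gamma x
  interior <- 4:18
  rel <- abs(sm$derivatives[1, interior] + 0.2 * sm$values[1, interior]) /
    pmax(0.2 * sm$values[1, interior], 1e-8)
  expect_lt(max(rel), 0.05)
})

test_that("smoothed trajectories round-trip through CSV", {
  spec <- mutual_repression_spec()
  d <- simulate_deterministic(spec, seq(0, 20, length.out = 11))
  sm <- smooth_dataset(d, "single_output", n_pred = 11, restarts = 2, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_smoothed_csv(sm, path)
  back <- read_smoothed_csv(path)
  expect_equal(back$pred_times, sm$pred_times)
  expect_equal(unname(back$values), unname(sm$values), tolerance = 1e-12)
  expect_equal(unname(back$derivatives), unname(sm$derivatives),
               tolerance = 1e-12)
})
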