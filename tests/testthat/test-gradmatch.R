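# Shared noise-free smoothed data from the 2-gene activation motif.
motif_smoothed <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- two_gene_motif()
      d <- simulate_deterministic(spec, seq(0, 30, length.out = 21))
      cache <<- smooth_dataset(d, "single_output", n_pred = 21,
                               restarts = 4, seed = 1)
    }
    cache
  }
})

test_that("l2_distance matches a naive loop oracle and its trivial cases", {
  set.seed(23)
  tt <- seq(0, 10, length.out = 9)
  vals <- rbind(runif(9, 0.5, 2), runif(9, 0.5, 2))
  deriv <- rbind(rnorm(9, sd = 0.2), rnorm(9, sd = 0.2))
  sm <- manual_smoothed(tt, vals, deriv)
  m <- candidate_model(2, 1L, "activation")
  p <- c(s = 0.1, beta = 1.2, gamma = 0.4, k1 = 1.1, h1 = 2.3)
  got <- l2_distance(m, p, sm)
  loop <- 0
  for (i in 1:9) {
    f <- p[["s"]] + p[["beta"]] *
      hill_term(vals[1, i], p[["k1"]], p[["h1"]], "activation") -
      p[["gamma"]] * vals[2, i]
    loop <- loop + (f - deriv[2, i])^2
  }
  expect_equal(got, loop, tolerance = 1e-10)
  expect_gte(got, 0)
  # rhs equal to the derivative everywhere -> zero
  sm0 <- manual_smoothed(tt, vals,
                         rbind(deriv[1, ],
                               0.1 + 1.2 * hill_term(vals[1, ], 1.1, 2.3,
                                                     "activation") -
                                 0.4 * vals[2, ]))
  expect_equal(l2_distance(m, p, sm0), 0, tolerance = 1e-20)
  # constant offset c at all S points -> S * c^2
  smc <- manual_smoothed(tt, vals, sm0$derivatives - 0.3)
  expect_equal(l2_distance(m, p, smc), 9 * 0.3^2, tolerance = 1e-10)
  expect_error(l2_distance(candidate_model(3, 1L, "activation"), p, sm),
               "cover")
})

test_that("free-parameter counts follow the prior regime by construction", {
  sm <- motif_smoothed()
  without <- parameter_prior("without_prior")
  with <- parameter_prior("with_prior", true_spec = two_gene_motif())
  for (np in 0:1) {
    m <- candidate_model(2, if (np) 1L else integer(),
                         if (np) "activation" else character())
    f_wo <- fit_candidate(m, sm, without, restarts = 2, seed = 1)
    expect_identical(f_wo$n_free_params, as.integer(3 + 2 * np))
    f_wi <- fit_candidate(m, sm, with, restarts = 2, seed = 1)
    expect_identical(f_wi$n_free_params, as.integer(1 + 2 * np))
    expect_equal(f_wi$params[["s"]], 0.05)
    expect_equal(f_wi$params[["gamma"]], 0.3)
  }
})

test_that("gradient matching recovers decay kinetics from noise-free data", {
  spec <- decay_spec(s = 0.3, gamma = 0.25, x0 = 2.5)
  # 2-gene system so enumeration applies; gene 2 is an independent decay
  kin <- list(gene_kinetics(0.3, 0, 0.25), gene_kinetics(0.1, 0, 0.4))
  spec2 <- ode_model_spec(kin, c(2.5, 1.5))
  d <- simulate_deterministic(spec2, seq(0, 20, length.out = 21))
  sm <- smooth_dataset(d, "single_output", n_pred = 21, restarts = 4,
                       seed = 2)
  f <- fit_candidate(candidate_model(1, integer(), character()), sm,
                     parameter_prior("without_prior"), restarts = 3,
                     seed = 2)
  expect_lt(abs(f$params[["gamma"]] - 0.25) / 0.25, 0.10)
  expect_lt(abs(f$params[["s"]] - 0.3) / 0.3, 0.20)
})

test_that("the true-parent candidate beats the empty model on the motif", {
  sm <- motif_smoothed()
  prior <- parameter_prior("without_prior")
  for (s in 1:5) {
    f_true <- fit_candidate(candidate_model(2, 1L, "activation"), sm,
                            prior, restarts = 3, seed = s)
    f_empty <- fit_candidate(candidate_model(2, integer(), character()),
                             sm, prior, restarts = 3, seed = s)
    expect_lt(f_true$l2_distance, f_empty$l2_distance)
  }
})

test_that("the correctly typed model beats the mistyped one on the motif", {
  sm <- motif_smoothed()
  prior <- parameter_prior("without_prior")
  wins <- vapply(1:5, function(s) {
    f_a <- fit_candidate(candidate_model(2, 1L, "activation"), sm, prior,
                         restarts = 3, seed = s)
    f_r <- fit_candidate(candidate_model(2, 1L, "repression"), sm, prior,
                         restarts = 3, seed = s)
    f_a$l2_distance < f_r$l2_distance
  }, logical(1))
  expect_gte(sum(wins), 3)
})

test_that("fit_candidate improves on every initialisation and is seeded", {
  sm <- motif_smoothed()
  prior <- parameter_prior("without_prior")
  m <- candidate_model(2, 1L, "repression")
  f <- fit_candidate(m, sm, prior, restarts = 4, seed = 3)
  expect_true(all(f$l2_distance <= f$start_distances + 1e-12))
  f2 <- fit_candidate(m, sm, prior, restarts = 4, seed = 3)
  expect_identical(f$params, f2$params)
})

test_that("candidate sweeps preserve order, purity and order-invariance", {
  sm <- motif_smoothed()
  prior <- parameter_prior("without_prior")
  cand <- enumerate_candidate_models(2, 2, NULL, typed = TRUE)[[2]]
  expect_length(cand, 3L)  # {}, {1a}, {1r}
  fits <- fit_all_candidates(2L, cand, sm, prior, restarts = 2, seed = 4)
  expect_length(fits, 3L)
  # duplicated candidates give identical results
  fits2 <- fit_all_candidates(2L, c(cand, cand[2]), sm, prior,
                              restarts = 2, seed = 4)
  expect_identical(fits2[[4]]$params, fits2[[2]]$params)
  # shuffling leaves the (model, distance) set unchanged
  perm <- c(3L, 1L, 2L)
  fits3 <- fit_all_candidates(2L, cand[perm], sm, prior, restarts = 2,
                              seed = 4)
  key <- function(fs) sort(vapply(fs, function(f)
    paste(grnmatch:::candidate_key(f$model), signif(f$l2_distance, 12)),
    character(1)))
  expect_identical(key(fits), key(fits3))
  expect_error(fit_all_candidates(1L, cand, sm, prior), "share")
})

test_that("with N=5 and M=2 each child has 33 typed and 11 untyped candidates", {
  expect_length(enumerate_candidate_models(5, 2, 2, typed = TRUE)[[3]], 33L)
  expect_length(enumerate_candidate_models(5, 1, 2, typed = FALSE)[[3]], 11L)
  expect_length(enumerate_candidate_models(5, 1, 3, typed = FALSE)[[3]], 15L)
})

test_that("non-parametric fits match a dense likelihood oracle and are seeded", {
  set.seed(29)
  tt <- seq(0, 10, length.out = 5)
  vals <- rbind(runif(5, 0.5, 2), runif(5, 0.5, 2))
  deriv <- rbind(rnorm(5, sd = 0.3), rnorm(5, sd = 0.3))
  sm <- manual_smoothed(tt, vals, deriv)
  m <- candidate_model(2, 1L, NULL, includes_self = TRUE)
  f <- fit_nonparametric(m, sm, restarts = 3, seed = 5)
  expect_identical(f$n_hyperparams, 4L)  # 2 ARD lengthscales + 2 sds
  # recompute the marginal likelihood densely at the returned hypers
  X <- scale(t(vals[c(2, 1), ]))
  y <- deriv[2, ] - mean(deriv[2, ])
  ls <- f$hyper[1:2]; sf <- f$hyper[["signal_sd"]]; sn <- f$hyper[["noise_sd"]]
  d2 <- outer(X[, 1], X[, 1], "-")^2 / ls[1]^2 +
    outer(X[, 2], X[, 2], "-")^2 / ls[2]^2
  Ky <- sf^2 * exp(-d2 / 2) + diag(sn^2 + 1e-8 * sf^2, 5)
  dense <- -0.5 * t(y) %*% solve(Ky) %*% y -
    0.5 * as.numeric(determinant(Ky)$modulus) - 5 / 2 * log(2 * pi)
  expect_equal(f$max_log_likelihood, as.numeric(dense), tolerance = 1e-8)
  f2 <- fit_nonparametric(m, sm, restarts = 3, seed = 5)
  expect_identical(f$hyper, f2$hyper)
  expect_error(fit_nonparametric(candidate_model(2, 1L, "activation"), sm),
               "untyped")
})

test_that("the true parent raises the non-parametric likelihood on the motif", {
  spec <- two_gene_motif()
  d <- simulate_deterministic(spec, seq(0, 30, length.out = 21))
  wins <- vapply(1:5, function(s) {
    sm <- smooth_dataset(d, "single_output", n_pred = 21, restarts = 3,
                         seed = s)
    f_true <- fit_nonparametric(
      candidate_model(2, 1L, NULL, includes_self = TRUE), sm,
      restarts = 3, seed = s)
    f_self <- fit_nonparametric(
      candidate_model(2, integer(), NULL, includes_self = TRUE), sm,
      restarts = 3, seed = s)
    f_true$max_log_likelihood > f_self$max_log_likelihood
  }, logical(1))
  expect_gte(sum(wins), 3)
})

test_that("degenerate constant inputs pin their lengthscale at the bound", {
  tt <- seq(0, 10, length.out = 8)
  vals <- rbind(rep(1.5, 8), runif(8, 0.5, 2))
  deriv <- rbind(rep(0, 8), rnorm(8, sd = 0.2))
  sm <- manual_smoothed(tt, vals, deriv)
  m <- candidate_model(2, 1L, NULL, includes_self = TRUE)
  f <- fit_nonparametric(m, sm, restarts = 2, seed = 1)
  expect_equal(unname(f$hyper[["l_1"]]), 1e3)
})

test_that("non-parametric sweeps record failures without aborting", {
  sm <- motif_smoothed()
  cand <- enumerate_candidate_models(2, 1, NULL, typed = FALSE)[[2]]
  fits <- fit_all_nonparametric(2L, cand, sm, restarts = 2, seed = 6)
  expect_length(fits, length(cand))
  expect_true(all(vapply(fits, function(f)
    is.finite(f$max_log_likelihood), logical(1))))
})

test_that("fit records serialise to JSON lines", {
  sm <- motif_smoothed()
  prior <- parameter_prior("without_prior")
  cand <- enumerate_candidate_models(2, 2, NULL, typed = TRUE)[[2]]
  fits <- fit_all_candidates(2L, cand, sm, prior, restarts = 2, seed = 1)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_fits_jsonl(fits, path)
  lines <- readLines(path)
  expect_length(lines, 3L)
  rec <- jsonlite::fromJSON(lines[2])
  expect_identical(rec$child, 2L)
  expect_identical(rec$G, 5L)
  expect_true(is.finite(rec$l2_distance))
})
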