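#' Squared-exponential kernel
#'
#' `k(t, t') = sigma_f^2 * exp(-(t - t')^2 / (2 l^2))`.
#'
#' @param t,t2 Time vectors; the result is the `length(t) x length(t2)`
#'   cross-covariance matrix.
#' @param hyper List with elements `signal_sd` (`sigma_f`), `noise_sd`
#'   (`sigma_n`, unused here) and `lengthscale` (`l`), all > 0.
#' @return Covariance matrix.
#' @export
se_kernel <- function(t, t2, hyper) {
  stopifnot(hyper$signal_sd > 0, hyper$lengthscale > 0)
  d <- outer(t, t2, "-")
  hyper$signal_sd^2 * exp(-d^2 / (2 * hyper$lengthscale^2))
}

gp_hyper <- function(signal_sd, noise_sd, lengthscale) {
  stopifnot(signal_sd > 0, noise_sd > 0, lengthscale > 0)
  list(signal_sd = signal_sd, noise_sd = noise_sd, lengthscale = lengthscale)
}

# Cholesky of K + sigma_n^2 I with relative jitter 1e-8 * sigma_f^2.
gp_chol <- function(times, hyper) {
  D <- length(times)
  K <- se_kernel(times, times, hyper)
  Ky <- K + diag(hyper$noise_sd^2 + 1e-8 * hyper$signal_sd^2, D)
  L <- tryCatch(chol(Ky), error = function(e)
    stop("covariance matrix not positive definite (sigma_f=",
         signif(hyper$signal_sd, 3), ", l=", signif(hyper$lengthscale, 3), ")"))
  L
}

#' GP log marginal likelihood
#'
#' `-x' (K + sigma_n^2 I)^{-1} x / 2 - log|K + sigma_n^2 I| / 2 -
#' (D/2) log(2 pi)`, evaluated through a Cholesky factorisation.
#'
#' @param values Observation vector (assumed zero-mean; callers centre).
#' @param times Matching time vector.
#' @param hyper Hyperparameter list as in [se_kernel()].
#' @return Scalar log marginal likelihood.
#' @export
gp_log_marginal_likelihood <- function(values, times, hyper) {
  stopifnot(length(values) == length(times), length(values) >= 1L)
  L <- gp_chol(times, hyper)
  a <- backsolve(L, backsolve(L, values, transpose = TRUE))
  -0.5 * sum(values * a) - sum(log(diag(L))) -
    length(values) / 2 * log(2 * pi)
}

#' Fit a single-output GP by marginal-likelihood maximisation
#'
#' Centres the data, then maximises the log marginal likelihood over
#' log-hyperparameters with bounded L-BFGS-B. Because the likelihood is
#' multi-modal in the lengthscale (noise-dominated versus smooth basins),
#' the search is staged: the likelihood is first profiled over a
#' data-informed grid of candidate lengthscales (plus seeded random draws,
#' `restarts` starts in total) with only the standard deviations
#' optimised, and the best profiled candidates are then polished with all
#' hyperparameters free. Bounds: lengthscale in \[1e-2, 1e3\] time units,
#' both standard deviations in \[1e-4, 1e2\] times the data standard
#' deviation.
#'
#' @param values Observation vector (length D >= 3 unless the lengthscale
#'   is fixed).
#' @param times Matching times.
#' @param restarts Number of multi-start initialisations (>= 1).
#' @param seed Integer seed making the fit deterministic.
#' @param fixed_lengthscale If non-`NULL`, hold the lengthscale at this
#'   value and optimise only the two standard deviations.
#' @return A `gp_fit` object: `hyper`, `train_times`, `train_values`
#'   (centred), `train_mean`, `log_marginal_likelihood`, and
#'   `start_values` (profiled log marginal likelihood of each stage-1
#'   candidate, best first).
#' @export
fit_gp <- function(values, times, restarts = 5L, seed = 1L,
                   fixed_lengthscale = NULL) {
  stopifnot(length(values) == length(times))
  D <- length(values)
  if (D < 3L && is.null(fixed_lengthscale))
    stop("need at least 3 observations for a free-lengthscale fit")
  mu <- mean(values)
  y <- values - mu
  s <- sd(values); if (!is.finite(s) || s == 0) s <- 1
  span <- diff(range(times)); if (span == 0) span <- 1
  lb_sd <- log(1e-4 * s); ub_sd <- log(1e2 * s)
  lb_l <- log(1e-2); ub_l <- log(1e3)
  free_l <- is.null(fixed_lengthscale)

  unpack <- function(p) {
    gp_hyper(signal_sd = exp(p[1L]), noise_sd = exp(p[2L]),
             lengthscale = if (free_l) exp(p[3L]) else fixed_lengthscale)
  }
  nll <- function(p) {
    h <- unpack(p)
    v <- tryCatch(-gp_log_marginal_likelihood(y, times, h),
                  error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }
  lower <- c(lb_sd, lb_sd, if (free_l) lb_l)
  upper <- c(ub_sd, ub_sd, if (free_l) ub_l)

  set.seed(as.integer(seed))
  # Two-stage search. The marginal likelihood is multi-modal in the
  # lengthscale (a noise-dominated basin competes with smooth basins), so
  # stage 1 profiles it: on a data-informed grid of candidate
  # lengthscales, only the two standard deviations are optimised.
  # Stage 2 polishes the best profiled candidates with l free.
  spacing <- span / max(D - 1L, 1L)
  l_grid <- if (free_l)
    unique(pmin(pmax(c(span / 3, span / 10, 2 * spacing, 5 * spacing,
                       exp(runif(max(restarts - 4L, 0L), lb_l, ub_l))),
                     1e-2), 1e3))
  else fixed_lengthscale
  sd_inits <- list(c(log(s), log(0.1 * s)), c(log(s), log(1e-3 * s)))

  profile_fit <- function(l) {
    res <- NULL
    for (si in sd_inits) {
      f <- tryCatch(
        optim(si, function(p) nll(c(p, if (free_l) log(l))),
              method = "L-BFGS-B", lower = lower[1:2], upper = upper[1:2],
              control = list(maxit = 100)),
        error = function(e) NULL)
      if (!is.null(f) && (is.null(res) || f$value < res$value)) res <- f
    }
    res
  }
  stage1 <- lapply(l_grid, profile_fit)
  keep <- !vapply(stage1, is.null, logical(1))
  stage1 <- stage1[keep]; l_grid <- l_grid[keep]
  if (length(stage1) == 0L) stop("all GP optimisation restarts failed")
  ord <- order(vapply(stage1, `[[`, numeric(1), "value"))
  start_values <- -vapply(stage1, `[[`, numeric(1), "value")[ord]

  best <- NULL
  if (!free_l) {
    b1 <- stage1[[ord[1L]]]
    best <- list(par = b1$par, value = b1$value)
  } else {
    for (i in ord[seq_len(min(3L, length(ord)))]) {
      init <- c(stage1[[i]]$par, log(l_grid[i]))
      fit <- tryCatch(
        optim(init, nll, method = "L-BFGS-B", lower = lower, upper = upper,
              control = list(maxit = 200)),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$value < best$value) best <- fit
    }
    if (is.null(best)) {
      i <- ord[1L]
      best <- list(par = c(stage1[[i]]$par, log(l_grid[i])),
                   value = stage1[[i]]$value)
    }
  }
  hyper <- unpack(best$par)
  structure(list(hyper = hyper, train_times = times, train_values = y,
                 train_mean = mu,
                 log_marginal_likelihood = -best$value,
                 start_values = start_values),
            class = "gp_fit")
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf(
    "GP fit: D=%d, sigma_f=%.4g, sigma_n=%.4g, l=%.4g, logML=%.4f\n",
    length(x$train_times), x$hyper$signal_sd, x$hyper$noise_sd,
    x$hyper$lengthscale, x$log_marginal_likelihood))
  invisible(x)
}

#' GP posterior mean and covariance
#'
#' Posterior over function values at `pred_times` given the training data:
#' mean `K_* (K + sigma_n^2 I)^{-1} x` (offset restored), covariance
#' `K_** - K_* (K + sigma_n^2 I)^{-1} K_*'`.
#'
#' @param fit A `gp_fit`.
#' @param pred_times Prediction time vector.
#' @return List with `mean` (vector) and `cov` (matrix).
#' @export
gp_posterior <- function(fit, pred_times) {
  L <- gp_chol(fit$train_times, fit$hyper)
  Ks <- se_kernel(pred_times, fit$train_times, fit$hyper)   # S x D
  Kss <- se_kernel(pred_times, pred_times, fit$hyper)
  a <- backsolve(L, backsolve(L, fit$train_values, transpose = TRUE))
  V <- backsolve(L, t(Ks), transpose = TRUE)                # D x S
  list(mean = as.numeric(Ks %*% a) + fit$train_mean,
       cov = Kss - crossprod(V))
}

#' GP posterior derivative
#'
#' The derivative of a GP is again a GP; the posterior mean derivative at
#' `pred_times` is `L_* (K + sigma_n^2 I)^{-1} x` with
#' `[L_*]_{ij} = ((t_i - t*_j) / l^2) [K_*]_{ij}` (training index i,
#' prediction index j). The centring offset has zero derivative.
#'
#' @inheritParams gp_posterior
#' @return Vector of posterior mean derivatives, one per prediction time.
#' @export
gp_posterior_derivative <- function(fit, pred_times) {
  Lc <- gp_chol(fit$train_times, fit$hyper)
  a <- backsolve(Lc, backsolve(Lc, fit$train_values, transpose = TRUE))
  Kst <- se_kernel(fit$train_times, pred_times, fit$hyper)  # D x S
  Lst <- outer(fit$train_times, pred_times, "-") /
    fit$hyper$lengthscale^2 * Kst
  as.numeric(crossprod(Lst, a))
}

#' @export
predict.gp_fit <- function(object, pred_times, derivative = FALSE, ...) {
  if (derivative) gp_posterior_derivative(object, pred_times)
  else gp_posterior(object, pred_times)$mean
}

#' Forward-difference numeric derivative
#'
#' `(x(t + delta) - x(t)) / delta` for a black-box prediction function;
#' used for multi-output GP means, whose analytic derivatives are
#' cumbersome. The default step `delta = 1e-4` trades approximation
#' accuracy against noise sensitivity.
#'
#' @param predict_fn Function mapping a time vector to predicted values
#'   (vector, or matrix with one row per time).
#' @param pred_times Times at which to differentiate.
#' @param delta Step size (> 0).
#' @return Derivatives in the same shape as `predict_fn`'s output.
#' @export
numeric_derivative <- function(predict_fn, pred_times, delta = 1e-4) {
  stopifnot(delta > 0)
  (predict_fn(pred_times + delta) - predict_fn(pred_times)) / delta
}
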