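# Intrinsic-coregionalisation multi-output GP: covariance B %x% k(t, t')
# with a full-rank PSD coregionalisation matrix B (signal variance folded
# into its diagonal), one shared lengthscale and one shared noise variance.
# Likelihood and solves use the Kronecker eigen-decomposition
#   (B %x% K + s2 I)^{-1} = (V %x% U) diag(1 / (mu_n lambda_d + s2)) (V %x% U)'
# so each evaluation costs one D x D and one N x N eigendecomposition.

mogp_nll_parts <- function(Y, times, Lmat, sigma_n, lengthscale) {
  # Y: D x N centred observations; Lmat: lower-triangular factor of B
  D <- nrow(Y); N <- ncol(Y)
  B <- Lmat %*% t(Lmat)
  K <- exp(-outer(times, times, "-")^2 / (2 * lengthscale^2))
  eK <- eigen(K, symmetric = TRUE)
  eB <- eigen(B, symmetric = TRUE)
  lam <- pmax(eK$values, 0); mu <- pmax(eB$values, 0)
  denom <- outer(lam, mu) + sigma_n^2        # D x N
  denom <- pmax(denom, 1e-12)
  Yt <- crossprod(eK$vectors, Y) %*% eB$vectors
  At <- Yt / denom
  list(quad = sum(Yt * At), logdet = sum(log(denom)),
       Amat = eK$vectors %*% At %*% t(eB$vectors), B = B)
}

mogp_nll <- function(Y, times, Lmat, sigma_n, lengthscale) {
  p <- mogp_nll_parts(Y, times, Lmat, sigma_n, lengthscale)
  0.5 * p$quad + 0.5 * p$logdet + length(Y) / 2 * log(2 * pi)
}

vec_to_L <- function(v, N) {
  L <- matrix(0, N, N)
  diag(L) <- exp(v[seq_len(N)])
  if (N > 1L) L[lower.tri(L)] <- v[N + seq_len(N * (N - 1) / 2)]
  L
}

#' Fit a coregionalised multi-output GP
#'
#' Jointly fits all genes with covariance `B %x% k(t, t')` over the `N * D`
#' stacked observations, maximising the marginal likelihood over the
#' Cholesky-parameterised positive-semidefinite coregionalisation matrix
#' `B`, a single shared lengthscale and a shared noise standard deviation.
#' The per-output signal variance is absorbed into `B`'s diagonal.
#'
#' @param values Matrix, genes in rows, time points in columns (`N x D`).
#' @param times Observation times (length D).
#' @param restarts Number of seeded initialisations.
#' @param seed Integer seed.
#' @param fixed_lengthscale Optional fixed lengthscale (time units).
#' @return A `mogp_fit` object: `coreg_matrix` (B), `noise_sd`,
#'   `lengthscale`, centred training data, per-gene offsets, and the
#'   maximised `log_marginal_likelihood`.
#' @export
fit_multioutput_gp <- function(values, times, restarts = 3L, seed = 1L,
                               fixed_lengthscale = NULL) {
  values <- as.matrix(values)
  N <- nrow(values); D <- ncol(values)
  stopifnot(N >= 2L, D == length(times))
  mu <- rowMeans(values)
  Y <- t(values - mu)                       # D x N, centred
  s <- mean(apply(values, 1, sd)); if (!is.finite(s) || s == 0) s <- 1
  span <- diff(range(times)); if (span == 0) span <- 1
  free_l <- is.null(fixed_lengthscale)
  n_off <- N * (N - 1) / 2

  unpack <- function(p) {
    list(L = vec_to_L(p[seq_len(N + n_off)], N),
         sigma_n = exp(p[N + n_off + 1L]),
         l = if (free_l) exp(p[N + n_off + 2L]) else fixed_lengthscale)
  }
  nll <- function(p) {
    u <- unpack(p)
    v <- tryCatch(mogp_nll(Y, times, u$L, u$sigma_n, u$l),
                  error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }
  lower <- c(rep(log(1e-4 * s), N), rep(-50, n_off), log(1e-4 * s),
             if (free_l) log(1e-2))
  upper <- c(rep(log(1e2 * s), N), rep(50, n_off), log(1e2 * s),
             if (free_l) log(1e3))

  # deterministic ladder over plausible lengthscales; at each, B is
  # initialised at its noise-free profile estimate Y' K^{-1} Y / D
  spacing <- span / max(D - 1L, 1L)
  l_ladder <- if (free_l) c(span / 4, span / 10, 2 * spacing)
              else fixed_lengthscale
  profile_init <- function(l) {
    K <- exp(-outer(times, times, "-")^2 / (2 * l^2)) + diag(1e-6, D)
    Bh <- crossprod(Y, solve(K, Y)) / D + diag(1e-6 * s^2, N)
    L0 <- t(chol(Bh))
    c(log(pmax(diag(L0), 1e-8)), L0[lower.tri(L0)], log(0.01 * s),
      if (free_l) log(l))
  }
  set.seed(as.integer(seed))
  inits <- lapply(seq_len(restarts), function(r) {
    if (r <= length(l_ladder)) profile_init(l_ladder[r])
    else profile_init(exp(runif(1, log(spacing / 2), log(2 * span)))) +
      rnorm(N + n_off + 1L + free_l, sd = 0.3)
  })
  inits <- lapply(inits, function(p) pmin(pmax(p, lower), upper))
  best <- NULL
  for (init in inits) {
    fit <- tryCatch(
      optim(init, nll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all multi-output GP restarts failed")
  u <- unpack(best$par)
  structure(list(coreg_matrix = u$L %*% t(u$L), noise_sd = u$sigma_n,
                 lengthscale = u$l, train_times = times, train_Y = Y,
                 train_means = mu, gene_names = rownames(values),
                 log_marginal_likelihood = -best$value),
            class = "mogp_fit")
}

#' @export
print.mogp_fit <- function(x, ...) {
  cat(sprintf(
    "Coregionalised GP fit: N=%d outputs, D=%d, l=%.4g, sigma_n=%.4g, logML=%.4f\n",
    ncol(x$train_Y), nrow(x$train_Y), x$lengthscale, x$noise_sd,
    x$log_marginal_likelihood))
  invisible(x)
}

# Posterior mean of a multi-output GP at pred_times; optionally with an
# explicit B / hyper override (used by tests to check the B = I identity).
mogp_posterior_mean <- function(fit, pred_times) {
  p <- mogp_nll_parts(fit$train_Y, fit$train_times,
                      t(chol(fit$coreg_matrix + diag(1e-10, ncol(fit$train_Y)))),
                      fit$noise_sd, fit$lengthscale)
  Ks <- exp(-outer(pred_times, fit$train_times, "-")^2 /
              (2 * fit$lengthscale^2))          # S x D
  M <- Ks %*% p$Amat %*% p$B                    # S x N
  sweep(M, 2L, fit$train_means, "+")
}

#' @export
predict.mogp_fit <- function(object, pred_times, derivative = FALSE,
                             delta = 1e-4, ...) {
  if (!derivative) return(mogp_posterior_mean(object, pred_times))
  numeric_derivative(function(tt) mogp_posterior_mean(object, tt),
                     pred_times, delta = delta)
}
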