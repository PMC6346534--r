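# Non-parametric gradient matching: the child gene's smoothed derivative is
# modelled as a GP function of the smoothed expression levels of its
# candidate parents plus (always) itself. The kernel is an ARD squared
# exponential over the input genes, so the marginal likelihood can prune
# irrelevant parents; the number of hyperparameters G is
# (n_parents + 1) ARD lengthscales + signal sd + noise sd.

ard_kernel <- function(X1, X2, signal_sd, lengthscales) {
  # X1: n1 x Q, X2: n2 x Q standardised inputs
  d2 <- matrix(0, nrow(X1), nrow(X2))
  for (q in seq_len(ncol(X1)))
    d2 <- d2 + outer(X1[, q], X2[, q], "-")^2 / lengthscales[q]^2
  signal_sd^2 * exp(-d2 / 2)
}

ard_log_marginal_likelihood <- function(y, X, signal_sd, noise_sd,
                                        lengthscales) {
  S <- length(y)
  K <- ard_kernel(X, X, signal_sd, lengthscales)
  Ky <- K + diag(noise_sd^2 + 1e-8 * signal_sd^2, S)
  L <- chol(Ky)
  a <- backsolve(L, backsolve(L, y, transpose = TRUE))
  -0.5 * sum(y * a) - sum(log(diag(L))) - S / 2 * log(2 * pi)
}

#' Fit a non-parametric (GP-on-parents) candidate model
#'
#' GP regression of the child gene's smoothed derivative on the smoothed
#' expression levels of the candidate's parents and of the child itself
#' (the self-input stands in for first-order degradation and is always
#' included; it does not count against the parent limit). Inputs are
#' standardised per dimension, targets centred. The ARD
#' squared-exponential hyperparameters (one lengthscale per input gene
#' plus signal and noise standard deviations) are optimised by bounded
#' multi-start maximum marginal likelihood. Constant input columns are
#' dropped to zero with their lengthscale pinned at the upper bound.
#'
#' @param model An untyped [candidate_model()] (`includes_self = TRUE`).
#' @param smoothed A `smoothed_trajectories` covering child and parents.
#' @param restarts Number of multi-starts.
#' @param seed Base seed (hashed with the model, so sweep order is
#'   irrelevant).
#' @return An `np_fit` object: `model`, `hyper` (named vector:
#'   per-input lengthscales, `signal_sd`, `noise_sd`),
#'   `max_log_likelihood`, `n_hyperparams`.
#' @export
fit_nonparametric <- function(model, smoothed, restarts = 5L, seed = 1L) {
  if (!is.null(model$itypes))
    stop("non-parametric fits use untyped candidate models")
  inputs <- c(model$child, model$parents)  # self always first
  if (any(inputs > nrow(smoothed$values)))
    stop("smoothed data does not cover all model genes")
  Q <- length(inputs)
  X <- t(smoothed$values[inputs, , drop = FALSE])   # S x Q
  y <- smoothed$derivatives[model$child, ]
  S <- length(y)

  # standardise inputs; constant columns become all-zero (pinned below)
  csd <- apply(X, 2, sd)
  degenerate <- !is.finite(csd) | csd < 1e-12
  csd[degenerate] <- 1
  X <- scale(X, center = TRUE, scale = csd)
  X[, degenerate] <- 0
  ymu <- mean(y); yc <- y - ymu
  ys <- sd(yc); if (!is.finite(ys) || ys == 0) ys <- 1

  lb_l <- log(1e-2); ub_l <- log(1e3)
  lb_s <- log(1e-4 * ys); ub_s <- log(1e2 * ys)
  lower <- c(rep(lb_l, Q), lb_s, lb_s)
  upper <- c(rep(ub_l, Q), ub_s, ub_s)

  nll <- function(p) {
    ls <- exp(p[seq_len(Q)])
    ls[degenerate] <- exp(ub_l)
    v <- tryCatch(
      -ard_log_marginal_likelihood(yc, X, exp(p[Q + 1L]), exp(p[Q + 2L]), ls),
      error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }

  set.seed(candidate_seed(seed, model))
  best <- NULL
  for (r in seq_len(restarts)) {
    init <- if (r == 1L) c(rep(log(1), Q), log(ys), log(0.1 * ys))
            else runif(Q + 2L, lower, upper)
    init <- pmin(pmax(init, lower), upper)
    fit <- tryCatch(
      optim(init, nll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all non-parametric GP restarts failed")
  ls <- exp(best$par[seq_len(Q)])
  ls[degenerate] <- exp(ub_l)
  hyper <- c(setNames(ls, paste0("l_", c("self", model$parents))),
             signal_sd = exp(best$par[Q + 1L]),
             noise_sd = exp(best$par[Q + 2L]))
  structure(list(model = model, hyper = hyper,
                 max_log_likelihood = -best$value,
                 n_hyperparams = Q + 2L),
            class = "np_fit")
}

#' @export
print.np_fit <- function(x, ...) {
  cat(format(x$model), " logL=", signif(x$max_log_likelihood, 6),
      " G=", x$n_hyperparams, "\n", sep = "")
  invisible(x)
}

#' Fit all non-parametric candidates of one child gene
#'
#' Runs [fit_nonparametric()] over an untyped candidate list; per-candidate
#' failures are recorded with `max_log_likelihood = -Inf` and the sweep
#' continues. For `N = 5`, `M = 2` there are 11 candidates per child
#' (55 in total).
#'
#' @param child Child gene id (consistency check).
#' @param candidates List of untyped [candidate_model()]s.
#' @param smoothed,restarts,seed As in [fit_nonparametric()].
#' @return List of `np_fit` objects, in input order.
#' @export
fit_all_nonparametric <- function(child, candidates, smoothed,
                                  restarts = 5L, seed = 1L) {
  if (!all(vapply(candidates, function(m) m$child, integer(1)) == child))
    stop("all candidates must share the child gene")
  lapply(candidates, function(m)
    tryCatch(fit_nonparametric(m, smoothed, restarts, seed),
             error = function(e)
               structure(list(model = m, hyper = NULL,
                              max_log_likelihood = -Inf,
                              n_hyperparams = length(m$parents) + 3L),
                         class = "np_fit")))
}
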