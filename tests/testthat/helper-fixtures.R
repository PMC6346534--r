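# Small fixtures shared across test files; everything is generated in code.

# Two-gene activation motif: gene 1 relaxes autonomously, gene 2 is
# activated by gene 1. Rich early dynamics on t in [0, 30].
two_gene_motif <- function() {
  kin <- list(
    gene_kinetics(0.2, 0, 0.15),
    gene_kinetics(0.05, 1, 0.3, parents = 1L, itypes = "activation"))
  ode_model_spec(kin, c(1.5, 0.1))
}

# Mutual repression toy used for integrator cross-checks.
mutual_repression_spec <- function() {
  kin <- list(
    gene_kinetics(0.1, 1, 0.4, parents = 2L, itypes = "repression"),
    gene_kinetics(0.1, 1, 0.4, parents = 1L, itypes = "repression"))
  ode_model_spec(kin, c(1.2, 0.2))
}

# Isolated decay gene (no regulation): closed-form x(t) = x0 exp(-g t) + ...
decay_spec <- function(s = 0, gamma = 0.25, x0 = 2) {
  ode_model_spec(list(gene_kinetics(s, 0, gamma)), x0)
}

# Smoothed trajectories built directly from known functions (bypassing GP
# fitting) so gradient-matching internals can be tested in isolation.
manual_smoothed <- function(times, values, derivatives) {
  structure(list(pred_times = times, values = values,
                 derivatives = derivatives, source = "manual",
                 gene_names = rownames(values), fits = NULL),
            class = "smoothed_trajectories")
}

# Fixed-step RK4 integrator: independent oracle for deSolve-based runs.
rk4_trajectory <- function(spec, times, n_sub = 40L) {
  x <- spec$initial_state
  out <- matrix(0, length(x), length(times))
  out[, 1L] <- x
  for (i in seq_len(length(times) - 1L)) {
    h <- (times[i + 1L] - times[i]) / n_sub
    for (s in seq_len(n_sub)) {
      k1 <- ode_rhs(x, spec)
      k2 <- ode_rhs(pmax(x + h / 2 * k1, 0), spec)
      k3 <- ode_rhs(pmax(x + h / 2 * k2, 0), spec)
      k4 <- ode_rhs(pmax(x + h * k3, 0), spec)
      x <- pmax(x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4), 0)
    }
    out[, i + 1L] <- x
  }
  out
}

# Dense-matrix GP log marginal likelihood (naive oracle for the
# factorised implementation).
dense_gp_loglik <- function(y, times, hyper) {
  K <- se_kernel(times, times, hyper)
  Ky <- K + diag(hyper$noise_sd^2 + 1e-8 * hyper$signal_sd^2,
                 length(times))
  -0.5 * t(y) %*% solve(Ky) %*% y -
    0.5 * as.numeric(determinant(Ky)$modulus) -
    length(y) / 2 * log(2 * pi)
}
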