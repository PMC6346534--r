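#' Hill regulation term
#'
#' Saturating Hill kinetics for a single regulator: activation
#' `x^h / (k^h + x^h)`, repression `k^h / (k^h + x^h)`. Both lie in
#' \[0, 1\] and equal 1/2 at `x = k`.
#'
#' @param x Regulator concentration (>= 0); vectorised.
#' @param threshold Hill threshold `k` (> 0).
#' @param coeff Hill coefficient `h` (>= 1).
#' @param itype `"activation"` or `"repression"`.
#' @return Regulation strength in \[0, 1\].
#' @export
#' @examples
#' hill_term(2, 1, 2, "activation")  # 4/5
hill_term <- function(x, threshold, coeff, itype) {
  if (any(x < 0)) stop("negative concentration in hill_term")
  if (threshold <= 0) stop("threshold must be > 0")
  if (coeff < 1) stop("hill coefficient must be >= 1")
  itype <- match.arg(itype, INTERACTION_TYPES)
  xh <- (x / threshold)^coeff  # scaled form avoids overflow for large x
  if (itype == "activation") xh / (1 + xh) else 1 / (1 + xh)
}

#' Per-gene kinetic parameters
#'
#' Kinetics of one gene under the model
#' `dx/dt = s + beta * f(parents) - gamma * x`, where `f` is the arithmetic
#' mean of per-parent Hill terms (so `f` stays in \[0, 1\] regardless of
#' in-degree and `beta` keeps its meaning as regulation strength).
#'
#' @param basal_rate Basal transcription rate `s` (>= 0).
#' @param sensitivity Regulation strength `beta` (>= 0).
#' @param decay_rate First-order decay rate `gamma` (> 0).
#' @param parents Integer vector of parent gene ids (possibly empty).
#' @param itypes Per-parent interaction types.
#' @param hill_thresholds,hill_coefficients Per-parent Hill parameters
#'   (`k > 0`, `h >= 1`); recycled to the number of parents.
#' @return A `gene_kinetics` object.
#' @export
gene_kinetics <- function(basal_rate, sensitivity, decay_rate,
                          parents = integer(), itypes = character(),
                          hill_thresholds = 1, hill_coefficients = 2) {
  np <- length(parents)
  stopifnot(basal_rate >= 0, sensitivity >= 0, decay_rate > 0,
            length(itypes) == np)
  hill_thresholds <- rep_len(hill_thresholds, np)
  hill_coefficients <- rep_len(hill_coefficients, np)
  if (np) stopifnot(all(hill_thresholds > 0), all(hill_coefficients >= 1),
                    all(itypes %in% INTERACTION_TYPES))
  structure(list(basal_rate = basal_rate, sensitivity = sensitivity,
                 decay_rate = decay_rate, parents = as.integer(parents),
                 itypes = as.character(itypes),
                 hill_thresholds = hill_thresholds,
                 hill_coefficients = hill_coefficients),
            class = "gene_kinetics")
}

#' Full ODE model specification
#'
#' @param kinetics List with one [gene_kinetics()] per gene.
#' @param initial_state Non-negative initial concentration vector, one per
#'   gene.
#' @param gene_names Optional labels.
#' @return An `ode_model_spec` object.
#' @export
ode_model_spec <- function(kinetics, initial_state, gene_names = NULL) {
  n <- length(kinetics)
  stopifnot(n >= 1, length(initial_state) == n, all(initial_state >= 0))
  for (k in kinetics) {
    stopifnot(inherits(k, "gene_kinetics"))
    if (length(k$parents) && any(k$parents < 1L | k$parents > n))
      stop("parent id outside gene range")
  }
  if (is.null(gene_names)) gene_names <- paste0("G", seq_len(n))
  structure(list(kinetics = kinetics, initial_state = as.numeric(initial_state),
                 gene_names = gene_names, n_genes = n),
            class = "ode_model_spec")
}

# Ground truth implied by an ODE spec (edges = parent lists with types).
spec_truth <- function(spec) {
  if (spec$n_genes < 2L) return(NULL)  # single-gene toys have no network
  p <- integer(); ch <- integer(); ty <- character()
  for (n in seq_len(spec$n_genes)) {
    k <- spec$kinetics[[n]]
    p <- c(p, k$parents); ch <- c(ch, rep(n, length(k$parents)))
    ty <- c(ty, k$itypes)
  }
  ground_truth_network(spec$n_genes, p, ch, ty, gene_names = spec$gene_names)
}

#' ODE right-hand side
#'
#' Evaluates `dx_n/dt = s_n + beta_n * f_n(x_parents) - gamma_n * x_n` for
#' every gene, with `f_n` the mean of per-parent Hill terms (0 for genes
#' without parents, so the `beta` term drops out).
#'
#' @param state Concentration vector, one entry per gene.
#' @param spec An [ode_model_spec()].
#' @return Rate-of-change vector.
#' @export
ode_rhs <- function(state, spec) {
  if (length(state) != spec$n_genes) stop("state length != number of genes")
  vapply(seq_len(spec$n_genes), function(n) {
    k <- spec$kinetics[[n]]
    f <- 0
    if (length(k$parents)) {
      terms <- vapply(seq_along(k$parents), function(j) {
        hill_term(state[k$parents[j]], k$hill_thresholds[j],
                  k$hill_coefficients[j], k$itypes[j])
      }, numeric(1))
      f <- mean(terms)
    }
    k$basal_rate + k$sensitivity * f - k$decay_rate * state[n]
  }, numeric(1))
}

#' Construct an expression dataset
#'
#' Container for a genes-by-time expression matrix with its time grid,
#' optional ground truth and provenance.
#'
#' @param times Strictly increasing vector of observation times (length D).
#' @param values Numeric matrix, genes in rows, time points in columns.
#' @param gene_names Optional row labels.
#' @param truth Optional [ground_truth_network()].
#' @param provenance `"deterministic"` or `"stochastic"`.
#' @param seed Seed used for stochastic simulation (or `NA`).
#' @return An `expression_dataset` object.
#' @export
expression_dataset <- function(times, values, gene_names = NULL, truth = NULL,
                               provenance = "deterministic", seed = NA) {
  times <- as.numeric(times)
  values <- as.matrix(values)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (ncol(values) != length(times)) stop("values must have one column per time")
  if (!all(is.finite(values))) stop("values must be finite")
  if (is.null(gene_names)) gene_names <- rownames(values)
  if (is.null(gene_names)) gene_names <- paste0("G", seq_len(nrow(values)))
  rownames(values) <- gene_names
  structure(list(times = times, values = values, gene_names = gene_names,
                 truth = truth, provenance = provenance, seed = seed),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("Expression dataset: %d genes x %d time points (%s), t in [%g, %g]\n",
              nrow(x$values), length(x$times), x$provenance,
              min(x$times), max(x$times)))
  if (!is.null(x$truth))
    cat("  ground truth attached:", nrow(x$truth$edges), "edges\n")
  invisible(x)
}

#' Simulate deterministic expression time courses
#'
#' Integrates the Hill-kinetics ODE system numerically (`deSolve::ode`,
#' `lsoda`, relative tolerance 1e-10) and samples it at the requested times.
#'
#' @param spec An [ode_model_spec()].
#' @param times Strictly increasing times; the first is the initial time.
#' @return An [expression_dataset()] with the spec's implied ground truth
#'   attached.
#' @export
simulate_deterministic <- function(spec, times) {
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  fn <- function(t, y, parms) list(ode_rhs(pmax(y, 0), spec))
  sol <- deSolve::ode(y = spec$initial_state, times = times, func = fn,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-10)
  if (attr(sol, "istate")[1L] < 0)
    stop("ODE integration failed (istate ", attr(sol, "istate")[1L], ")")
  vals <- t(unname(sol[, -1, drop = FALSE]))
  vals <- pmax(vals, 0)  # clip tiny negative round-off
  expression_dataset(times, vals, gene_names = spec$gene_names,
                     truth = spec_truth(spec), provenance = "deterministic")
}

#' Simulate stochastic expression time courses
#'
#' Euler-Maruyama integration of
#' `dX = f(X) dt + process_noise_sd * sqrt(X) dW` (reflected at zero;
#' square-root multiplicative noise mimics demographic process noise),
#' followed by i.i.d. Gaussian observation noise truncated at zero. The
#' integration step is 1/2000 of the time span.
#'
#' @inheritParams simulate_deterministic
#' @param process_noise_sd Intensity of the process noise (>= 0).
#' @param obs_noise_sd Standard deviation of the observation noise (>= 0).
#' @param seed Integer seed; the run is fully reproducible from it.
#' @return An [expression_dataset()] with provenance `"stochastic"`.
#' @export
simulate_stochastic <- function(spec, times, process_noise_sd = 0.05,
                                obs_noise_sd = 0.05, seed = 1L) {
  times <- as.numeric(times)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  stopifnot(process_noise_sd >= 0, obs_noise_sd >= 0)
  set.seed(as.integer(seed))
  n_steps <- 2000L
  t0 <- times[1L]; t1 <- times[length(times)]
  dt <- (t1 - t0) / n_steps
  grid <- t0 + dt * (0:n_steps)
  n <- spec$n_genes
  x <- spec$initial_state
  path <- matrix(0, nrow = n, ncol = n_steps + 1L)
  path[, 1L] <- x
  sq_dt <- sqrt(dt)
  for (s in seq_len(n_steps)) {
    drift <- ode_rhs(x, spec)
    x <- x + drift * dt +
      process_noise_sd * sqrt(pmax(x, 0)) * sq_dt * rnorm(n)
    if (!all(is.finite(x))) stop("SDE integration diverged")
    x <- abs(x)  # reflecting boundary at 0
    path[, s + 1L] <- x
  }
  idx <- vapply(times, function(tt) which.min(abs(grid - tt)), integer(1))
  vals <- path[, idx, drop = FALSE]
  vals <- vals + matrix(rnorm(length(vals), sd = obs_noise_sd),
                        nrow = n)
  vals <- pmax(vals, 0)
  expression_dataset(times, vals, gene_names = spec$gene_names,
                     truth = spec_truth(spec), provenance = "stochastic",
                     seed = as.integer(seed))
}

#' Benchmark network specifications
#'
#' Built-in benchmark systems:
#' \describe{
#'   \item{`non_oscillatory_5`}{Five genes, eight typed interactions
#'     arranged like a synthetic yeast switch network (two interlocked
#'     feedback loops). Deterministic trajectories relax to a steady
#'     state.}
#'   \item{`oscillatory_5`}{The same network with one activation edge
#'     removed (seven interactions) and sharper Hill coefficients
#'     (h = 4), so a delayed negative feedback loop dominates and the
#'     trajectories oscillate (every gene shows two or more local maxima
#'     over the default horizon).}
#'   \item{`stochastic_10`}{Ten genes, ten typed interactions drawn
#'     reproducibly from `seed` (no self-loops, in-degree at most 2),
#'     intended for stochastic simulation of a DREAM-style in silico
#'     network.}
#' }
#' Default kinetics: `s = 0.05`, `beta = 1`, `gamma = 0.3`, `k = 1`,
#' `h = 2` for every gene.
#'
#' @param variant One of `"non_oscillatory_5"`, `"oscillatory_5"`,
#'   `"stochastic_10"`.
#' @param seed Integer seed (used only by `stochastic_10`).
#' @return A list with elements `spec` ([ode_model_spec()]) and `truth`
#'   ([ground_truth_network()]).
#' @export
make_benchmark_spec <- function(variant = c("non_oscillatory_5",
                                            "oscillatory_5",
                                            "stochastic_10"),
                                seed = 1L) {
  variant <- match.arg(variant)
  s <- 0.05; beta <- 1.0; gamma <- 0.3; k <- 1.0; h <- 2
  if (variant %in% c("non_oscillatory_5", "oscillatory_5")) {
    # Cascade CBF1-like(1) -> GAL4-like(2) -> SWI5-like(3) with SWI5
    # feeding back through GAL80-like(4) (repressor) and ASH1-like(5).
    edges <- data.frame(
      parent = c(3L, 5L, 1L, 2L, 4L, 3L, 3L, 4L),
      child  = c(1L, 1L, 2L, 3L, 3L, 4L, 5L, 2L),
      type   = c("activation", "repression", "activation", "activation",
                 "repression", "activation", "activation", "repression"),
      stringsAsFactors = FALSE)
    hcoef <- rep(h, 8)
    if (variant == "oscillatory_5") {
      # Dropping SWI5 -> CBF1 removes the short positive loop 3->1->2->3,
      # leaving the delayed negative loop 3->5-|1->2->3 dominant; with
      # sharper Hill kinetics (h = 4 throughout) the system shows
      # sustained oscillations over t in [0, 100].
      edges <- edges[-1L, ]  # 7 interactions remain
      hcoef <- rep(4, nrow(edges))
    } else hcoef <- hcoef[seq_len(nrow(edges))]
    kin <- lapply(seq_len(5L), function(g) {
      sel <- edges$child == g
      gene_kinetics(s, beta, gamma,
                    parents = edges$parent[sel], itypes = edges$type[sel],
                    hill_thresholds = rep(k, sum(sel)),
                    hill_coefficients = hcoef[sel])
    })
    x0 <- c(1.0, 0.2, 0.1, 0.3, 0.6)
    spec <- ode_model_spec(kin, x0)
  } else {
    set.seed(as.integer(seed))
    n <- 10L
    # 10 unique directed edges, no self-loops, in-degree capped at 2
    picked <- data.frame(parent = integer(), child = integer())
    indeg <- integer(n)
    while (nrow(picked) < 10L) {
      p <- sample.int(n, 1L); ch <- sample.int(n, 1L)
      if (p == ch || indeg[ch] >= 2L) next
      if (any(picked$parent == p & picked$child == ch)) next
      picked <- rbind(picked, data.frame(parent = p, child = ch))
      indeg[ch] <- indeg[ch] + 1L
    }
    picked$type <- sample(INTERACTION_TYPES, 10L, replace = TRUE)
    thr <- runif(10L, 0.5, 1.5)  # varied thresholds diversify dynamics
    kin <- lapply(seq_len(n), function(g) {
      sel <- picked$child == g
      gene_kinetics(s, beta, gamma,
                    parents = picked$parent[sel], itypes = picked$type[sel],
                    hill_thresholds = thr[sel], hill_coefficients = h)
    })
    x0 <- runif(n, 0.1, 1.0)
    spec <- ode_model_spec(kin, x0)
  }
  list(spec = spec, truth = spec_truth(spec))
}

#' Default observation grid for a benchmark variant
#'
#' Evenly spaced grids on \[0, 100\]: 21 or 41 points for the five-gene
#' variants, 20 points for the ten-gene stochastic variant.
#'
#' @param variant Benchmark variant name.
#' @param n_points Number of time points (`NULL` for the variant default).
#' @return Numeric time vector.
#' @export
default_time_grid <- function(variant, n_points = NULL) {
  if (is.null(n_points))
    n_points <- if (variant == "stochastic_10") 20L else 21L
  seq(0, 100, length.out = n_points)
}

#' Read / write expression CSV
#'
#' Plain CSV with a `time` column first and one column per gene; values
#' round-trip at 12 significant digits.
#'
#' @param data An [expression_dataset()].
#' @param path File path.
#' @return `read_expression_csv()` returns an [expression_dataset()];
#'   `write_expression_csv()` invisibly returns `path`.
#' @export
write_expression_csv <- function(data, path) {
  df <- data.frame(time = signif(data$times, 12))
  for (g in seq_len(nrow(data$values)))
    df[[data$gene_names[g]]] <- signif(data$values[g, ], 12)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_expression_csv
#' @export
read_expression_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  if (names(df)[1L] != "time") stop("expression CSV must start with a time column")
  vals <- t(as.matrix(df[, -1, drop = FALSE]))
  expression_dataset(df$time, vals, gene_names = rownames(vals))
}
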