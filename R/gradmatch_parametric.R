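#' Parameter prior for parametric gradient matching
#'
#' Two regimes for ODE parameter optimisation:
#' \describe{
#'   \item{`with_prior`}{basal transcription (`s`) and decay (`gamma`)
#'     rates are known (fixed at the supplied true values) and the
#'     remaining parameters are box-constrained to
#'     `[0.5 * true, 2 * true]` around the generating values.}
#'   \item{`without_prior`}{nothing is known; wide scale-aware default
#'     boxes are used: `s, beta` in \[0, 10\], `gamma` in \[1e-3, 10\],
#'     Hill threshold `k` in \[1e-2, 1e2 * max(data)\], Hill coefficient
#'     `h` in \[1, 4\].}
#' }
#'
#' @param mode `"with_prior"` or `"without_prior"`.
#' @param true_spec The generating [ode_model_spec()]; required for
#'   `with_prior` (source of the fixed rates and tight boxes).
#' @return A `parameter_prior` object.
#' @export
parameter_prior <- function(mode = c("without_prior", "with_prior"),
                            true_spec = NULL) {
  mode <- match.arg(mode)
  if (mode == "with_prior" && is.null(true_spec))
    stop("with_prior requires the generating model spec")
  structure(list(mode = mode, true_spec = true_spec),
            class = "parameter_prior")
}

# Parameter layout for a candidate model: always (s, beta, gamma) then
# (k_j, h_j) per parent. With prior, s and gamma are fixed (not free).
gm_param_layout <- function(model, prior, data_max = 10) {
  np <- length(model$parents)
  names_free <- c("s", "beta", "gamma",
                  if (np) paste0(rep(c("k", "h"), np),
                                 rep(seq_len(np), each = 2)))
  if (prior$mode == "without_prior") {
    lower <- c(0, 0, 1e-3, rep(c(1e-2, 1), np))
    upper <- c(10, 10, 10, rep(c(1e2 * max(data_max, 1e-2), 4), np))
    fixed <- setNames(numeric(0), character(0))
  } else {
    tk <- prior$true_spec$kinetics[[model$child]]
    fixed <- c(s = tk$basal_rate, gamma = tk$decay_rate)
    tb <- tk$sensitivity
    # per-parent true Hill parameters where the parent is a true one;
    # generic defaults (k = 1, h = 2) anchor the box otherwise
    tks <- thy <- numeric(np)
    for (j in seq_len(np)) {
      hit <- match(model$parents[j], tk$parents)
      tks[j] <- if (!is.na(hit)) tk$hill_thresholds[hit] else 1
      thy[j] <- if (!is.na(hit)) tk$hill_coefficients[hit] else 2
    }
    truth <- c(max(tb, 1e-3), as.numeric(rbind(tks, thy)))
    lower <- 0.5 * truth
    upper <- 2.0 * truth
    if (np) {  # Hill coefficients sit at positions 3, 5, ...; keep h in [1, 4]
      hpos <- 1 + 2 * seq_len(np)
      lower[hpos] <- pmax(lower[hpos], 1)
      upper[hpos] <- pmin(upper[hpos], 4)
    }
    names_free <- setdiff(names_free, names(fixed))
  }
  list(names = names_free, lower = lower, upper = upper, fixed = fixed,
       n_free = length(names_free))
}

# Evaluate the candidate right-hand side f(xhat, alpha) at all S points.
# smoothed values: genes x S matrix; params named per gm_param_layout.
gm_rhs <- function(model, params, fixed, values) {
  s <- if ("s" %in% names(fixed)) fixed[["s"]] else params[["s"]]
  gamma <- if ("gamma" %in% names(fixed)) fixed[["gamma"]] else params[["gamma"]]
  beta <- params[["beta"]]
  np <- length(model$parents)
  f <- 0
  if (np) {
    terms <- matrix(0, np, ncol(values))
    for (j in seq_len(np))
      terms[j, ] <- hill_term(values[model$parents[j], ],
                              params[[paste0("k", j)]],
                              params[[paste0("h", j)]], model$itypes[j])
    f <- colMeans(terms)
  }
  s + beta * f - gamma * values[model$child, ]
}

#' L2 gradient-matching distance
#'
#' Squared distance between a candidate model's right-hand side evaluated
#' on the smoothed trajectories and the GP-derived derivative of the child
#' gene, summed over all S prediction points:
#' `sum_i (f(xhat(t_i), alpha) - dxhat_n/dt(t_i))^2`.
#'
#' @param model A typed [candidate_model()].
#' @param params Named parameter vector (see [fit_candidate()] for the
#'   layout: `s`, `beta`, `gamma`, then `k<j>`, `h<j>` per parent; fixed
#'   entries may be supplied through `fixed`).
#' @param smoothed A `smoothed_trajectories` covering child and parents.
#' @param fixed Named vector of fixed parameters (default none).
#' @return Non-negative scalar distance.
#' @export
l2_distance <- function(model, params, smoothed, fixed = numeric()) {
  need <- c(model$child, model$parents)
  if (any(need > nrow(smoothed$values)))
    stop("smoothed data does not cover all model genes")
  rhs <- gm_rhs(model, as.list(params), fixed, smoothed$values)
  sum((rhs - smoothed$derivatives[model$child, ])^2)
}

#' Fit one candidate model by gradient matching
#'
#' Minimises the [l2_distance()] over the candidate's free ODE parameters.
#' The objective is linear in `(s, beta, gamma)` given the per-parent Hill
#' parameters, so the optimisation is separable: the Hill parameters are
#' searched with bounded L-BFGS-B from `restarts` seeded log-uniform
#' starts, the linear block is solved by least squares at every step
#' (clipped into its box), and the best point is polished jointly within
#' all bounds. The free-parameter count `G` is `3 + 2 * n_parents` without
#' prior and `1 + 2 * n_parents` with prior (`s` and `gamma` fixed).
#'
#' @param model A typed [candidate_model()].
#' @param smoothed A `smoothed_trajectories`.
#' @param prior A [parameter_prior()].
#' @param restarts Number of multi-starts.
#' @param seed Base seed; the effective seed also hashes the model so
#'   results do not depend on sweep order.
#' @return A `gm_fit` object: `model`, `params` (all parameters, fixed
#'   ones included), `l2_distance`, `n_free_params`, `start_distances`.
#' @export
fit_candidate <- function(model, smoothed, prior, restarts = 5L, seed = 1L) {
  lay <- gm_param_layout(model, prior, data_max = max(smoothed$values))
  nfree <- lay$n_free
  np <- length(model$parents)
  target <- smoothed$derivatives[model$child, ]
  xchild <- smoothed$values[model$child, ]
  obj <- function(p) {
    v <- tryCatch(
      l2_distance(model, setNames(as.list(p), lay$names), smoothed,
                  fixed = lay$fixed),
      error = function(e) Inf)
    if (!is.finite(v)) 1e10 else v
  }

  # The objective is linear in (s, beta, gamma) given the per-parent Hill
  # parameters, so the search is separable (variable projection): optimise
  # the 2*np Hill parameters with the linear block solved by least squares
  # (clipped into its box), then polish all free parameters jointly.
  lin_names <- intersect(c("s", "beta", "gamma"), lay$names)
  hill_idx <- which(!(lay$names %in% lin_names))
  lin_idx <- match(lin_names, lay$names)
  hill_mean <- function(ph) {
    # ph: (k_1, h_1, ..., k_np, h_np)
    terms <- vapply(seq_len(np), function(j)
      hill_term(smoothed$values[model$parents[j], ],
                ph[2L * j - 1L], ph[2L * j], model$itypes[j]),
      numeric(length(target)))
    if (np == 1L) as.numeric(terms) else rowMeans(terms)
  }
  solve_linear <- function(ph) {
    g <- if (np) hill_mean(ph) else rep(0, length(target))
    # columns of the design matrix for the free linear parameters
    cols <- list(s = rep(1, length(target)), beta = g, gamma = -xchild)
    X <- do.call(cbind, cols[lin_names])
    off <- rep(0, length(target))
    if ("s" %in% names(lay$fixed)) off <- off + lay$fixed[["s"]]
    if ("gamma" %in% names(lay$fixed))
      off <- off - lay$fixed[["gamma"]] * xchild
    beta_hat <- tryCatch(qr.solve(X, target - off), error = function(e)
      rep(0, length(lin_names)))
    pmin(pmax(beta_hat, lay$lower[lin_idx]), lay$upper[lin_idx])
  }
  assemble <- function(ph, bl) {
    p <- numeric(nfree)
    p[lin_idx] <- bl
    if (np) p[hill_idx] <- ph
    p
  }
  vp_obj <- function(ph) obj(assemble(ph, solve_linear(ph)))

  set.seed(candidate_seed(seed, model))
  lo <- lay$lower; hi <- lay$upper
  start_d <- numeric(restarts)
  best_p <- NULL; best_v <- Inf
  for (r in seq_len(restarts)) {
    if (np) {
      ph0 <- exp(runif(2L * np, log(lo[hill_idx]), log(hi[hill_idx])))
      start_d[r] <- vp_obj(ph0)
      fit <- tryCatch(
        optim(ph0, vp_obj, method = "L-BFGS-B",
              lower = lo[hill_idx], upper = hi[hill_idx],
              control = list(maxit = 200)),
        error = function(e) NULL)
      ph <- if (is.null(fit)) ph0 else fit$par
    } else {
      ph <- numeric(0)
      start_d[r] <- vp_obj(ph)
    }
    p_full <- assemble(ph, solve_linear(ph))
    # joint polish respects the boxes the projection may have clipped into
    pol <- tryCatch(
      optim(p_full, obj, method = "L-BFGS-B", lower = lo, upper = hi,
            control = list(maxit = 200)),
      error = function(e) list(par = p_full, value = obj(p_full)))
    if (pol$value < best_v) { best_v <- pol$value; best_p <- pol$par }
    if (np == 0L) { start_d <- start_d[1L]; break }  # linear-only problem
  }
  if (is.null(best_p))
    return(structure(list(model = model, params = NULL, l2_distance = Inf,
                          n_free_params = nfree, start_distances = start_d),
                     class = "gm_fit"))
  params <- c(setNames(best_p, lay$names), lay$fixed)
  structure(list(model = model, params = params, l2_distance = best_v,
                 n_free_params = nfree, start_distances = start_d),
            class = "gm_fit")
}

#' @export
print.gm_fit <- function(x, ...) {
  cat(format(x$model), " dist=", signif(x$l2_distance, 5),
      " G=", x$n_free_params, "\n", sep = "")
  invisible(x)
}

#' Fit all candidate models of one child gene
#'
#' Runs [fit_candidate()] over a candidate list (all sharing the child);
#' per-candidate failures are recorded as infinite distance and never abort
#' the sweep. Because seeds hash the candidate, the result set is invariant
#' to the list order.
#'
#' @param child Child gene id (consistency check).
#' @param candidates List of typed [candidate_model()]s for that child.
#' @param smoothed,prior,restarts,seed As in [fit_candidate()].
#' @return List of `gm_fit` objects, in input order.
#' @export
fit_all_candidates <- function(child, candidates, smoothed, prior,
                               restarts = 5L, seed = 1L) {
  if (!all(vapply(candidates, function(m) m$child, integer(1)) == child))
    stop("all candidates must share the child gene")
  lapply(candidates, function(m)
    tryCatch(fit_candidate(m, smoothed, prior, restarts, seed),
             error = function(e)
               structure(list(model = m, params = NULL, l2_distance = Inf,
                              n_free_params = NA_integer_,
                              start_distances = numeric()),
                         class = "gm_fit")))
}

#' Serialise gradient-matching fits to JSON lines
#'
#' One JSON object per fit: child, parents, itypes, params, the L2
#' distance (or log-likelihood for non-parametric fits) and `G`.
#'
#' @param fits List of `gm_fit` or `np_fit` objects.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_fits_jsonl <- function(fits, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (f in fits) {
    rec <- candidate_to_list(f$model)
    if (inherits(f, "gm_fit")) {
      rec$params <- as.list(f$params)
      rec$l2_distance <- f$l2_distance
    } else {
      rec$hyper <- as.list(f$hyper)
      rec$max_log_likelihood <- f$max_log_likelihood
    }
    rec$G <- if (inherits(f, "gm_fit")) f$n_free_params else f$n_hyperparams
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, null = "null"),
               con)
  }
  invisible(path)
}
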