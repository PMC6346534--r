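#' Infer a gene regulatory network by gradient matching
#'
#' The package's central fitting function. Runs the two-step pipeline on a
#' time-course expression dataset: (1) GP smoothing of every gene's
#' trajectory with analytic (or finite-difference) derivatives; (2)
#' exhaustive per-child candidate-model fitting by gradient matching —
#' parametric Hill-kinetics ODEs (`ode_with_prior` / `ode_without_prior`)
#' or non-parametric GP-on-parents regression (`gp_only`); (3) BIC scoring
#' and Schwarz-weight model averaging into per-edge confidence weights for
#' each requested inference aim.
#'
#' Only the parametric methods can assign interaction types, so the
#' `typed` aim is unavailable for `gp_only`.
#'
#' @param data An [expression_dataset()].
#' @param method `"gp_only"`, `"ode_with_prior"` or `"ode_without_prior"`.
#' @param interpolation GP smoothing mode, `"single_output"` or
#'   `"multi_output"`.
#' @param n_pred Number of prediction points S for the smoothed grid.
#' @param max_parents In-degree cap M during enumeration.
#' @param restarts Optimiser multi-starts for every fit.
#' @param seed Integer seed; the whole run is deterministic given it.
#' @param fixed_lengthscale Optional fixed GP lengthscale.
#' @param true_spec Generating [ode_model_spec()]; required for
#'   `ode_with_prior`.
#' @param aims Character vector of aims to tabulate (defaults to all aims
#'   the method supports).
#' @param smoothed Optional precomputed `smoothed_trajectories` (skips
#'   step 1; `interpolation`/`n_pred` are then ignored).
#' @return An object of class `grn_fit`; see [print.grn_fit()],
#'   [summary.grn_fit()], [coef.grn_fit()], [plot.grn_fit()].
#' @export
#' @examples
#' \donttest{
#' bench <- make_benchmark_spec("non_oscillatory_5")
#' data <- simulate_deterministic(bench$spec, default_time_grid("non_oscillatory_5"))
#' fit <- grn_gradmatch(data, method = "gp_only", n_pred = 21,
#'                      restarts = 2, seed = 1)
#' summary(fit, truth = bench$truth)
#' }
grn_gradmatch <- function(data,
                          method = c("gp_only", "ode_with_prior",
                                     "ode_without_prior"),
                          interpolation = c("single_output", "multi_output"),
                          n_pred = 41L, max_parents = 2L, restarts = 5L,
                          seed = 1L, fixed_lengthscale = NULL,
                          true_spec = NULL, aims = NULL, smoothed = NULL) {
  method <- match.arg(method)
  interpolation <- match.arg(interpolation)
  N <- nrow(data$values)
  parametric <- method != "gp_only"
  if (is.null(aims))
    aims <- if (parametric) c("typed", "directed", "undirected")
            else c("directed", "undirected")
  if (!parametric && "typed" %in% aims)
    stop("the gp_only method cannot infer interaction types (no typed aim)")
  if (method == "ode_with_prior" && is.null(true_spec))
    stop("ode_with_prior requires the generating model spec (true_spec)")

  if (is.null(smoothed))
    smoothed <- smooth_dataset(data, mode = interpolation, n_pred = n_pred,
                               restarts = restarts, seed = seed,
                               fixed_lengthscale = fixed_lengthscale)
  S <- length(smoothed$pred_times)

  cand <- enumerate_candidate_models(N, n_types = if (parametric) 2L else 1L,
                                     max_parents = max_parents,
                                     typed = parametric)
  prior <- if (parametric)
    parameter_prior(if (method == "ode_with_prior") "with_prior"
                    else "without_prior", true_spec = true_spec)
  scored <- lapply(seq_len(N), function(child) {
    fits <- if (parametric)
      fit_all_candidates(child, cand[[child]], smoothed, prior,
                         restarts = restarts, seed = seed)
    else
      fit_all_nonparametric(child, cand[[child]], smoothed,
                            restarts = restarts, seed = seed)
    score_model_set(fits, S)
  })

  tables <- lapply(setNames(aims, aims), function(a)
    edge_weights(scored, aim = a, n_genes = N))

  structure(list(method = method, interpolation = smoothed$source,
                 n_pred = S, max_parents = max_parents, restarts = restarts,
                 seed = seed, fixed_lengthscale = fixed_lengthscale,
                 gene_names = data$gene_names, n_genes = N,
                 smoothed = smoothed, scored = scored,
                 edge_weights = tables, truth = data$truth,
                 call = match.call()),
            class = "grn_fit")
}

#' @describeIn grn_gradmatch Compact description of a fitted network.
#' @param x,object A `grn_fit`.
#' @param ... Unused.
#' @export
print.grn_fit <- function(x, ...) {
  cat("Gradient-matching GRN fit\n")
  cat("  method:", x$method, "| interpolation:", x$interpolation,
      "| S =", x$n_pred, "| M =", x$max_parents, "\n")
  cat("  genes:", x$n_genes, "| candidate models:",
      sum(vapply(x$scored, function(s) length(s$models), integer(1))), "\n")
  cat("  aims tabulated:", paste(names(x$edge_weights), collapse = ", "),
      "\n")
  invisible(x)
}

#' @describeIn grn_gradmatch Top-ranked edges and, when a ground truth is
#'   available, per-aim AUPR against it.
#' @param truth Optional [ground_truth_network()] (defaults to the truth
#'   attached to the training dataset).
#' @param n_top Number of top edges to display.
#' @export
summary.grn_fit <- function(object, truth = object$truth, n_top = 10L, ...) {
  perf <- NULL
  if (!is.null(truth)) {
    perf <- do.call(rbind, lapply(names(object$edge_weights), function(a) {
      ev <- evaluate_weights(object$edge_weights[[a]], truth)
      data.frame(aim = a, aupr = ev$aupr, baseline = ev$baseline)
    }))
  }
  first <- names(object$edge_weights)[1L]
  tab <- as.data.frame(object$edge_weights[[first]])
  top <- utils::head(tab[order(-tab$weight), ], n_top)
  out <- list(fit = object, performance = perf, top_edges = top,
              top_aim = first)
  class(out) <- "summary.grn_fit"
  out
}

#' @export
print.summary.grn_fit <- function(x, ...) {
  print(x$fit)
  cat("\nTop edges (aim: ", x$top_aim, "):\n", sep = "")
  print(x$top_edges, row.names = FALSE)
  if (!is.null(x$performance)) {
    cat("\nPerformance against ground truth:\n")
    print(x$performance, row.names = FALSE)
  }
  invisible(x)
}

#' @describeIn grn_gradmatch Edge-weight table for one aim (the fitted
#'   "coefficients" of the network model).
#' @param aim Which aim's table to return (default: the first tabulated).
#' @export
coef.grn_fit <- function(object, aim = names(object$edge_weights)[1L], ...) {
  if (!aim %in% names(object$edge_weights))
    stop("aim not tabulated in this fit: ", aim)
  object$edge_weights[[aim]]
}

#' @describeIn grn_gradmatch Precision-recall curve against a ground truth
#'   (requires one), for a chosen aim.
#' @export
plot.grn_fit <- function(x, aim = names(x$edge_weights)[1L],
                         truth = x$truth, ...) {
  if (is.null(truth))
    stop("plotting the PR curve needs a ground-truth network")
  ev <- evaluate_weights(x$edge_weights[[aim]], truth)
  plot(ev$curve, sub = paste("aim:", aim), ...)
  invisible(x)
}
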