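#' Experiment configuration for the benchmark pipeline
#'
#' Bundles one setting combination of the benchmark grid: inference
#' method, dataset variant, interpolation mode, grid size, in-degree cap,
#' optional fixed lengthscale, and repeat/seed bookkeeping.
#'
#' @param inference_method `"gp_only"`, `"ode_with_prior"` or
#'   `"ode_without_prior"`.
#' @param dataset_variant `"non_oscillatory_5"`, `"oscillatory_5"` or
#'   `"stochastic_10"`.
#' @param interpolation `"single_output"` or `"multi_output"`.
#' @param n_points Number of time points (observation and prediction
#'   grids); 21 or 41 for the five-gene variants, 20 for `stochastic_10`.
#' @param max_parents In-degree cap M (2 or 3).
#' @param fixed_lengthscale `NULL` (free) or a fixed GP lengthscale;
#'   intended for the stochastic variant (a warning is issued otherwise).
#' @param n_repeats Number of independent repeats averaged (default 5).
#' @param base_seed Base seed; repeat r uses `base_seed + r`.
#' @param restarts Optimiser multi-starts per fit.
#' @param process_noise_sd,obs_noise_sd Noise intensities for the
#'   stochastic variant.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(inference_method = "gp_only",
                              dataset_variant = "non_oscillatory_5",
                              interpolation = "single_output",
                              n_points = NULL, max_parents = 2L,
                              fixed_lengthscale = NULL, n_repeats = 5L,
                              base_seed = 1L, restarts = 3L,
                              process_noise_sd = 0.05, obs_noise_sd = 0.05) {
  inference_method <- match.arg(inference_method,
                                c("gp_only", "ode_with_prior",
                                  "ode_without_prior"))
  dataset_variant <- match.arg(dataset_variant,
                               c("non_oscillatory_5", "oscillatory_5",
                                 "stochastic_10"))
  interpolation <- match.arg(interpolation,
                             c("single_output", "multi_output"))
  if (is.null(n_points))
    n_points <- if (dataset_variant == "stochastic_10") 20L else 21L
  if (!is.null(fixed_lengthscale) && dataset_variant != "stochastic_10")
    warning("a fixed GP lengthscale is intended for the stochastic variant")
  structure(list(inference_method = inference_method,
                 dataset_variant = dataset_variant,
                 interpolation = interpolation,
                 n_points = as.integer(n_points),
                 max_parents = as.integer(max_parents),
                 fixed_lengthscale = fixed_lengthscale,
                 n_repeats = as.integer(n_repeats),
                 base_seed = as.integer(base_seed),
                 restarts = as.integer(restarts),
                 process_noise_sd = process_noise_sd,
                 obs_noise_sd = obs_noise_sd),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML or JSON
#'
#' Field names mirror [experiment_config()] arguments.
#'
#' @param path YAML (or JSON) file.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  lst <- yaml::read_yaml(path)
  do.call(experiment_config, lst)
}

config_aims <- function(config) {
  if (config$inference_method == "gp_only") c("directed", "undirected")
  else c("typed", "directed", "undirected")
}

#' Run one benchmark experiment
#'
#' Simulates the configured dataset, runs the configured inference method
#' and computes the AUPR for every applicable aim, over `n_repeats`
#' repeats. Deterministic variants are simulated once and shared across
#' repeats (repeats reseed the optimisers); the stochastic variant is
#' re-simulated with fresh noise per repeat.
#'
#' @param config An [experiment_config()].
#' @return A `benchmark_result`: `config`, `per_aim_aupr` (means),
#'   `per_repeat` (aims x repeats matrix), `baselines`, `errors`
#'   (per-repeat failure messages, normally empty).
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  aims <- config_aims(config)
  bench <- make_benchmark_spec(config$dataset_variant,
                               seed = config$base_seed)
  times <- default_time_grid(config$dataset_variant, config$n_points)
  stochastic <- config$dataset_variant == "stochastic_10"
  det_data <- if (!stochastic) simulate_deterministic(bench$spec, times)

  per_repeat <- matrix(NA_real_, length(aims), config$n_repeats,
                       dimnames = list(aims, NULL))
  errors <- character()
  for (r in seq_len(config$n_repeats)) {
    seed_r <- config$base_seed + r
    res <- tryCatch({
      data <- if (stochastic)
        simulate_stochastic(bench$spec, times,
                            process_noise_sd = config$process_noise_sd,
                            obs_noise_sd = config$obs_noise_sd,
                            seed = seed_r)
      else det_data
      fit <- grn_gradmatch(data, method = config$inference_method,
                           interpolation = config$interpolation,
                           n_pred = config$n_points,
                           max_parents = config$max_parents,
                           restarts = config$restarts, seed = seed_r,
                           fixed_lengthscale = config$fixed_lengthscale,
                           true_spec = if (config$inference_method ==
                                           "ode_with_prior") bench$spec,
                           aims = aims)
      vapply(aims, function(a)
        evaluate_weights(fit$edge_weights[[a]], bench$truth)$aupr,
        numeric(1))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors <- c(errors, sprintf("repeat %d: %s", r, conditionMessage(res)))
    } else per_repeat[, r] <- res
  }
  baselines <- vapply(aims, function(a) {
    te <- ground_truth_edges(bench$truth, a)
    random_baseline(te, edge_domain(bench$truth$n_genes, a))
  }, numeric(1))
  structure(list(config = config,
                 per_aim_aupr = rowMeans(per_repeat, na.rm = TRUE),
                 per_repeat = per_repeat, baselines = baselines,
                 errors = errors),
            class = "benchmark_result")
}

#' @export
print.benchmark_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Benchmark: %s on %s (%s GP, S=%d, M=%d, %d repeats)\n",
              cfg$inference_method, cfg$dataset_variant, cfg$interpolation,
              cfg$n_points, cfg$max_parents, cfg$n_repeats))
  for (a in names(x$per_aim_aupr))
    cat(sprintf("  %-10s mean AUPR %.4f (baseline %.4f)\n", a,
                x$per_aim_aupr[a], x$baselines[a]))
  if (length(x$errors)) cat("  partial:", length(x$errors), "failed repeats\n")
  invisible(x)
}

#' Run a grid of benchmark experiments
#'
#' @param configs Non-empty list of [experiment_config()]s.
#' @return A `benchmark_grid`: list of `benchmark_result`s with a tidy
#'   results table attached (one row per config x repeat x aim), suitable
#'   for marginal summaries over any single setting.
#' @export
run_grid <- function(configs) {
  if (length(configs) == 0L) stop("empty experiment grid")
  results <- lapply(configs, function(cfg)
    tryCatch(run_experiment(cfg), error = function(e) e))
  ok <- !vapply(results, inherits, logical(1), "error")
  tidy <- do.call(rbind, lapply(which(ok), function(i)
    tidy_benchmark(results[[i]], config_id = i)))
  structure(list(results = results, table = tidy), class = "benchmark_grid")
}

# One row per repeat x aim for a single benchmark result.
tidy_benchmark <- function(result, config_id = 1L) {
  cfg <- result$config
  grid <- expand.grid(aim = rownames(result$per_repeat),
                      repeat_id = seq_len(ncol(result$per_repeat)),
                      stringsAsFactors = FALSE)
  data.frame(config_id = config_id,
             inference_method = cfg$inference_method,
             dataset_variant = cfg$dataset_variant,
             interpolation = cfg$interpolation,
             n_points = cfg$n_points, max_parents = cfg$max_parents,
             fixed_lengthscale = if (is.null(cfg$fixed_lengthscale)) NA_real_
                                 else cfg$fixed_lengthscale,
             aim = grid$aim, repeat_id = grid$repeat_id,
             aupr = result$per_repeat[cbind(match(grid$aim,
                                                  rownames(result$per_repeat)),
                                            grid$repeat_id)],
             baseline = result$baselines[grid$aim],
             row.names = NULL)
}

#' Marginal AUPR summary of a benchmark grid
#'
#' Groups the tidy results table by one setting column and reports the
#' mean AUPR per group and aim (the tabular analogue of an asymmetric
#' violin decomposition).
#'
#' @param grid A `benchmark_grid` from [run_grid()].
#' @param by Name of a setting column (e.g. `"interpolation"`,
#'   `"n_points"`, `"max_parents"`).
#' @return Data frame with columns `by`-value, `aim`, `mean_aupr`, `n`.
#' @export
marginal_summary <- function(grid, by) {
  tab <- grid$table
  if (!by %in% names(tab)) stop("unknown setting column: ", by)
  agg <- aggregate(tab$aupr, by = list(group = tab[[by]], aim = tab$aim),
                   FUN = mean)
  n <- aggregate(tab$aupr, by = list(group = tab[[by]], aim = tab$aim),
                 FUN = length)
  data.frame(setting = by, value = agg$group, aim = agg$aim,
             mean_aupr = agg$x, n = n$x)
}

#' Persist benchmark grid results
#'
#' Writes the tidy per-repeat table as TSV and a per-config summary
#' (mean AUPR and baseline per aim) as JSON.
#'
#' @param grid A `benchmark_grid`.
#' @param tsv_path,json_path Output files (`NULL` to skip either).
#' @return Invisibly, the tidy table.
#' @export
write_benchmark_results <- function(grid, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    write.table(grid$table, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(json_path)) {
    summ <- lapply(grid$results, function(r) {
      if (inherits(r, "error")) return(list(error = conditionMessage(r)))
      c(as.list(unclass(r$config)[c("inference_method", "dataset_variant",
                                    "interpolation", "n_points",
                                    "max_parents", "n_repeats")]),
        list(mean_aupr = as.list(r$per_aim_aupr),
             baseline = as.list(r$baselines)))
    })
    jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  }
  invisible(grid$table)
}
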