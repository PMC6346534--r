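#' Smooth an expression dataset and extract derivatives
#'
#' First step of gradient matching: fit a GP per gene (`single_output`) or
#' one coregionalised GP over all genes (`multi_output`), then evaluate the
#' posterior mean and its derivative on an evenly spaced prediction grid
#' spanning the observation window. Single-output derivatives are analytic
#' (the derivative of a GP is a GP); multi-output derivatives use a forward
#' difference with step `1e-4`.
#'
#' @param data An [expression_dataset()].
#' @param mode `"single_output"` or `"multi_output"`.
#' @param n_pred Number of prediction points S (21 and 41 are the
#'   benchmark defaults).
#' @param restarts,seed Passed to the GP fitters.
#' @param fixed_lengthscale Optional fixed GP lengthscale (time units).
#' @return A `smoothed_trajectories` object: `pred_times` (length S),
#'   `values` and `derivatives` (genes x S matrices), `source` mode,
#'   `gene_names`, and the underlying fit(s).
#' @export
smooth_dataset <- function(data, mode = c("single_output", "multi_output"),
                           n_pred = 41L, restarts = 5L, seed = 1L,
                           fixed_lengthscale = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_pred >= 2L)
  pred_times <- seq(min(data$times), max(data$times), length.out = n_pred)
  N <- nrow(data$values)
  if (mode == "single_output") {
    fits <- lapply(seq_len(N), function(g)
      fit_gp(data$values[g, ], data$times, restarts = restarts,
             seed = as.integer(seed) + 1000L * g,
             fixed_lengthscale = fixed_lengthscale))
    vals <- t(vapply(fits, function(f) gp_posterior(f, pred_times)$mean,
                     numeric(n_pred)))
    deriv <- t(vapply(fits, function(f) gp_posterior_derivative(f, pred_times),
                      numeric(n_pred)))
  } else {
    fits <- fit_multioutput_gp(data$values, data$times, restarts = restarts,
                               seed = seed,
                               fixed_lengthscale = fixed_lengthscale)
    vals <- t(predict(fits, pred_times))
    deriv <- t(predict(fits, pred_times, derivative = TRUE))
  }
  rownames(vals) <- rownames(deriv) <- data$gene_names
  structure(list(pred_times = pred_times, values = vals, derivatives = deriv,
                 source = mode, gene_names = data$gene_names, fits = fits),
            class = "smoothed_trajectories")
}

#' @export
print.smoothed_trajectories <- function(x, ...) {
  cat(sprintf("Smoothed trajectories: %d genes at %d points (%s GP)\n",
              nrow(x$values), length(x$pred_times), x$source))
  invisible(x)
}

#' @export
plot.smoothed_trajectories <- function(x, data = NULL, ...) {
  N <- nrow(x$values)
  matplot(x$pred_times, t(x$values), type = "l", lty = 1,
          xlab = "time", ylab = "expression",
          main = paste0("GP-smoothed trajectories (", x$source, ")"), ...)
  if (!is.null(data))
    matpoints(data$times, t(data$values), pch = 1)
  invisible(x)
}

#' Read / write smoothed trajectories CSV
#'
#' Columns: `time`, then one value column and one derivative column per
#' gene (`<gene>` and `d<gene>`).
#'
#' @param smoothed A `smoothed_trajectories` object.
#' @param path File path.
#' @return `read_smoothed_csv()` returns a `smoothed_trajectories` (without
#'   the fit objects); `write_smoothed_csv()` invisibly returns `path`.
#' @export
write_smoothed_csv <- function(smoothed, path) {
  df <- data.frame(time = smoothed$pred_times)
  for (g in seq_along(smoothed$gene_names)) {
    df[[smoothed$gene_names[g]]] <- smoothed$values[g, ]
    df[[paste0("d", smoothed$gene_names[g])]] <- smoothed$derivatives[g, ]
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_smoothed_csv
#' @export
read_smoothed_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  nm <- names(df)
  genes <- nm[-1][!startsWith(nm[-1], "d")]
  vals <- t(as.matrix(df[genes]))
  deriv <- t(as.matrix(df[paste0("d", genes)]))
  rownames(vals) <- rownames(deriv) <- genes
  structure(list(pred_times = df$time, values = vals, derivatives = deriv,
                 source = "file", gene_names = genes, fits = NULL),
            class = "smoothed_trajectories")
}
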