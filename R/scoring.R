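#' BIC for a parametric gradient-matching fit
#'
#' `BIC = ln(S) * G + S * ln(dist / S)` with `S` the number of matched
#' points, `G` the number of free parameters and `dist` the L2
#' gradient-matching distance. A distance of exactly zero (perfect fit on
#' noise-free data) is floored at `1e-300` so such models dominate the
#' weighting without producing `-Inf`.
#'
#' @param S Number of prediction points (>= 1).
#' @param G Number of free parameters (>= 0).
#' @param dist Non-negative L2 distance.
#' @return Scalar BIC (lower is better).
#' @export
bic_parametric <- function(S, G, dist) {
  stopifnot(S >= 1, G >= 0, dist >= 0)
  if (!is.finite(dist)) return(Inf)
  dist <- max(dist, 1e-300)
  log(S) * G + S * log(dist / S)
}

#' BIC for a non-parametric gradient-matching fit
#'
#' `BIC = ln(S) * G - 2 * loglik` with `loglik` the maximised GP marginal
#' likelihood and `G` the number of optimised hyperparameters.
#'
#' @param S Number of prediction points (>= 1).
#' @param G Number of hyperparameters.
#' @param loglik Maximised log marginal likelihood.
#' @return Scalar BIC (lower is better).
#' @export
bic_nonparametric <- function(S, G, loglik) {
  stopifnot(S >= 1, G >= 0)
  if (!is.finite(loglik)) return(Inf)
  log(S) * G - 2 * loglik
}

#' Schwarz weights from a vector of BIC values
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = BIC_i - min(BIC)`; the min-shift makes the computation
#' stable and the weights invariant to adding any constant to all BICs.
#' Infinite BICs (failed fits) receive weight zero.
#'
#' @param bics Numeric vector with at least one finite entry.
#' @return Weight vector summing to one.
#' @export
schwarz_weights <- function(bics) {
  if (!any(is.finite(bics))) stop("no finite BIC values to weight")
  delta <- bics - min(bics[is.finite(bics)])
  w <- ifelse(is.finite(delta), exp(-delta / 2), 0)
  w / sum(w)
}

#' Score a child gene's fitted candidate models
#'
#' Converts a list of fits (`gm_fit` or `np_fit`, all for the same child)
#' into BIC values and normalised Schwarz weights.
#'
#' @param fits List of fits for one child.
#' @param S Number of prediction points used in the fits.
#' @return A `scored_model_set`: `child`, `models`, `bic`, `weight`.
#' @export
score_model_set <- function(fits, S) {
  stopifnot(length(fits) >= 1L)
  child <- fits[[1L]]$model$child
  bic <- vapply(fits, function(f) {
    if (inherits(f, "gm_fit")) bic_parametric(S, f$n_free_params, f$l2_distance)
    else bic_nonparametric(S, f$n_hyperparams, f$max_log_likelihood)
  }, numeric(1))
  structure(list(child = child,
                 models = lapply(fits, `[[`, "model"),
                 bic = bic,
                 weight = schwarz_weights(bic)),
            class = "scored_model_set")
}

#' @export
print.scored_model_set <- function(x, ...) {
  cat("Scored model set for child", x$child, ":", length(x$models),
      "models\n")
  ord <- order(x$bic)[seq_len(min(3L, length(x$bic)))]
  for (i in ord)
    cat("  ", format(x$models[[i]]), " BIC=", signif(x$bic[i], 6),
        " w=", signif(x$weight[i], 4), "\n", sep = "")
  invisible(x)
}

# Full candidate edge domain for an aim over N genes (self-loops excluded).
edge_domain <- function(n_genes, aim) {
  pairs <- expand.grid(parent = seq_len(n_genes), child = seq_len(n_genes))
  pairs <- pairs[pairs$parent != pairs$child, ]
  if (aim == "typed") {
    out <- rbind(cbind(pairs, type = INTERACTION_TYPES[1L]),
                 cbind(pairs, type = INTERACTION_TYPES[2L]))
  } else if (aim == "directed") {
    out <- cbind(pairs, type = "*")
  } else {
    und <- pairs[pairs$parent < pairs$child, ]
    out <- cbind(und, type = "*")
  }
  out <- out[order(out$parent, out$child, out$type), ]
  rownames(out) <- NULL
  out
}

#' Per-edge confidence weights by Schwarz-weight model averaging
#'
#' For every candidate edge, sums the Schwarz weights of all of the child's
#' models that contain the edge. Aims:
#' \describe{
#'   \item{typed}{edge identity is (parent, child, type); requires typed
#'     model sets.}
#'   \item{directed}{types marginalised: the typed weights of the two
#'     interaction types are summed (untyped model sets contribute
#'     directly).}
#'   \item{undirected}{the two directed weights `w_{a->b}`, `w_{b->a}` are
#'     combined by noisy-OR, `1 - (1 - w_ab)(1 - w_ba)`, since they come
#'     from different children's (non-exclusive) model averages.}
#' }
#' Self-interactions never appear in the tables.
#'
#' @param scored List of `scored_model_set`, one per child gene.
#' @param aim `"typed"`, `"directed"` or `"undirected"`.
#' @param n_genes Number of genes (default: number of sets).
#' @return An `edge_weight_table`: data frame `parent, child, type, weight`
#'   covering the full candidate domain of the aim, with attribute `aim`.
#' @export
edge_weights <- function(scored, aim = c("directed", "typed", "undirected"),
                         n_genes = length(scored)) {
  aim <- match.arg(aim)
  if (length(scored) == 0L) stop("no scored model sets supplied")
  for (s in scored) if (length(s$models) == 0L)
    stop("child ", s$child, " has no scored models")
  typed_sets <- all(vapply(scored, function(s)
    !is.null(s$models[[1L]]$itypes), logical(1)))
  if (aim == "typed" && !typed_sets)
    stop("typed edge weights require typed candidate models")

  # directed weights (parent -> child), summing over types if present
  dir_w <- matrix(0, n_genes, n_genes)  # [parent, child]
  typ_w <- array(0, c(n_genes, n_genes, 2L),
                 dimnames = list(NULL, NULL, INTERACTION_TYPES))
  for (s in scored) {
    for (i in seq_along(s$models)) {
      m <- s$models[[i]]; w <- s$weight[i]
      for (j in seq_along(m$parents)) {
        p <- m$parents[j]
        if (p == m$child) next
        dir_w[p, m$child] <- dir_w[p, m$child] + w
        if (!is.null(m$itypes))
          typ_w[p, m$child, m$itypes[j]] <- typ_w[p, m$child, m$itypes[j]] + w
      }
    }
  }

  dom <- edge_domain(n_genes, aim)
  dom$weight <- vapply(seq_len(nrow(dom)), function(r) {
    p <- dom$parent[r]; ch <- dom$child[r]
    switch(aim,
      typed = typ_w[p, ch, dom$type[r]],
      directed = dir_w[p, ch],
      undirected = 1 - (1 - dir_w[p, ch]) * (1 - dir_w[ch, p]))
  }, numeric(1))
  dom$weight <- pmin(pmax(dom$weight, 0), 1)  # guard round-off
  structure(dom, aim = aim, class = c("edge_weight_table", "data.frame"))
}

#' Read / write edge-weight TSV
#'
#' Columns `parent  child  type  weight`; `type` is `*` for untyped aims
#' and the child column is the larger gene id for undirected aims.
#'
#' @param weights An `edge_weight_table`.
#' @param path File path.
#' @param aim Aim recorded on read.
#' @return `read_edge_weights_tsv()` returns an `edge_weight_table`;
#'   `write_edge_weights_tsv()` invisibly returns `path`.
#' @export
write_edge_weights_tsv <- function(weights, path) {
  write.table(as.data.frame(weights), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_weights_tsv
#' @export
read_edge_weights_tsv <- function(path, aim = "directed") {
  df <- read.delim(path, stringsAsFactors = FALSE)
  structure(df, aim = aim, class = c("edge_weight_table", "data.frame"))
}

#' @export
print.edge_weight_table <- function(x, ...) {
  cat("Edge weights (aim: ", attr(x, "aim"), "), ", nrow(x),
      " candidate edges\n", sep = "")
  top <- as.data.frame(x)[order(-x$weight), ]
  print(utils::head(top, 10L), row.names = FALSE)
  invisible(x)
}
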