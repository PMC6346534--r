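#' Ground-truth edge set for an inference aim
#'
#' Projects a typed ground-truth network onto one of the three inference
#' aims: `typed` keeps (parent, child, type); `directed` drops types;
#' `undirected` collapses direction (duplicates merged, smaller gene id
#' first).
#'
#' @param truth A [ground_truth_network()].
#' @param aim `"typed"`, `"directed"` or `"undirected"`.
#' @return Data frame `parent, child, type` of unique true edges.
#' @export
ground_truth_edges <- function(truth, aim = c("directed", "typed",
                                              "undirected")) {
  aim <- match.arg(aim)
  e <- truth$edges
  if (aim == "typed") {
    if (any(e$type == "unknown"))
      stop("typed evaluation requires a typed ground truth")
    out <- e
  } else if (aim == "directed") {
    out <- data.frame(parent = e$parent, child = e$child, type = "*")
  } else {
    p <- pmin(e$parent, e$child); ch <- pmax(e$parent, e$child)
    out <- unique(data.frame(parent = p, child = ch, type = "*"))
  }
  rownames(out) <- NULL
  out
}

edge_key <- function(df) paste(df$parent, df$child, df$type, sep = "/")

#' Precision-recall curve of an edge ranking
#'
#' Sorts candidate edges by weight (descending), treats equal-weight edges
#' as one tied group, and records precision and recall at each group
#' boundary.
#'
#' @param weights An [edge_weights()] table (the candidate domain).
#' @param truth_edges Data frame of true edges (from
#'   [ground_truth_edges()]), a subset of the candidate domain.
#' @return A `pr_curve` object: `thresholds` (distinct weights,
#'   descending), `precision`, `recall`, `prevalence`, `n_true`,
#'   `n_candidates`.
#' @export
pr_curve <- function(weights, truth_edges) {
  if (nrow(truth_edges) == 0L) stop("empty ground truth")
  keys <- edge_key(weights)
  tkeys <- edge_key(truth_edges)
  if (!all(tkeys %in% keys))
    stop("some true edges are outside the candidate edge domain")
  is_true <- keys %in% tkeys
  ord <- order(-weights$weight)
  w <- weights$weight[ord]; y <- is_true[ord]
  grp <- cumsum(!duplicated(w))           # tied-group index per edge
  n_in_grp <- tabulate(grp)
  tp_in_grp <- vapply(seq_len(max(grp)), function(g) sum(y[grp == g]),
                      numeric(1))
  tp <- cumsum(tp_in_grp)
  n_cum <- cumsum(n_in_grp)
  n_true <- sum(is_true)
  structure(list(thresholds = w[!duplicated(w)],
                 precision = tp / n_cum,
                 recall = tp / n_true,
                 prevalence = n_true / length(keys),
                 n_true = n_true, n_candidates = length(keys)),
            class = "pr_curve")
}

#' @export
print.pr_curve <- function(x, ...) {
  cat(sprintf(
    "PR curve: %d thresholds, %d true / %d candidate edges (prevalence %.3f), AUPR %.4f\n",
    length(x$thresholds), x$n_true, x$n_candidates, x$prevalence, aupr(x)))
  invisible(x)
}

#' @export
plot.pr_curve <- function(x, ...) {
  plot(c(0, x$recall), c(1, x$precision), type = "s", xlim = c(0, 1),
       ylim = c(0, 1), xlab = "Recall", ylab = "Precision",
       main = sprintf("AUPR = %.3f", aupr(x)), ...)
  abline(h = x$prevalence, lty = 2)
  invisible(x)
}

#' Area under the precision-recall curve
#'
#' Step-wise average precision over tied threshold groups:
#' `sum_k (R_k - R_{k-1}) * P_k`. A perfect ranking scores 1; an all-tied
#' ranking scores the prevalence.
#'
#' @param curve A [pr_curve()].
#' @return Scalar in \[0, 1\].
#' @export
aupr <- function(curve) {
  r <- c(0, curve$recall)
  sum(diff(r) * curve$precision)
}

#' Random-ranking AUPR baseline
#'
#' Expected average precision of a uniformly random edge ranking: the
#' prevalence `|truth| / |candidates|`.
#'
#' @param truth_edges True-edge data frame.
#' @param candidate_domain Candidate-edge data frame (or an
#'   [edge_weights()] table).
#' @return Scalar baseline AUPR.
#' @export
random_baseline <- function(truth_edges, candidate_domain) {
  if (nrow(candidate_domain) == 0L) stop("empty candidate domain")
  nrow(truth_edges) / nrow(candidate_domain)
}

#' Evaluate an edge-weight table against a ground truth
#'
#' Convenience wrapper: builds the true edge set for the table's aim,
#' computes the PR curve, its AUPR and the random baseline.
#'
#' @param weights An [edge_weights()] table.
#' @param truth A [ground_truth_network()].
#' @return List: `aim`, `aupr`, `baseline`, `curve`.
#' @export
evaluate_weights <- function(weights, truth) {
  aim <- attr(weights, "aim")
  te <- ground_truth_edges(truth, aim)
  curve <- pr_curve(weights, te)
  list(aim = aim, aupr = aupr(curve),
       baseline = random_baseline(te, weights), curve = curve)
}
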