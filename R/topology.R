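#' @importFrom stats optim rnorm runif sd setNames approx median aggregate
#' @importFrom utils read.csv read.delim write.csv write.table combn head
#' @importFrom graphics plot abline matplot matpoints
NULL

# The two regulatory interaction types (F = 2 when types are modelled).
INTERACTION_TYPES <- c("activation", "repression")

#' Interaction types
#'
#' The regulatory interaction types supported by the Hill-kinetics model:
#' `"activation"` and `"repression"`. When candidate models are typed, each
#' parent carries one of these, giving `F = 2` alternatives per edge.
#'
#' @return Character vector of the two interaction types, in canonical
#'   (enumeration) order: activation before repression.
#' @export
interaction_types <- function() INTERACTION_TYPES

#' Construct a ground-truth regulatory network
#'
#' A ground-truth network is a set of typed directed edges over `n_genes`
#' genes. It is the reference against which inferred edge rankings are
#' scored.
#'
#' @param n_genes Number of genes `N` (nodes), at least 2.
#' @param parent,child Integer vectors of equal length giving the edges
#'   (1-based gene indices, parent regulates child).
#' @param type Character vector of per-edge interaction types
#'   (`"activation"`, `"repression"`, or `"unknown"` for untyped truths).
#' @param gene_names Optional character vector of gene labels.
#' @return An object of class `grn_truth`: a list with `n_genes`,
#'   `gene_names`, and an `edges` data frame (`parent`, `child`, `type`).
#' @export
ground_truth_network <- function(n_genes, parent = integer(), child = integer(),
                                 type = character(), gene_names = NULL) {
  n_genes <- as.integer(n_genes)
  if (n_genes < 2L) stop("a network needs at least 2 genes")
  parent <- as.integer(parent); child <- as.integer(child)
  if (length(parent) != length(child))
    stop("parent and child must have equal length")
  if (length(type) == 0L) type <- rep("unknown", length(parent))
  type <- as.character(type)
  if (length(type) != length(parent)) stop("one type per edge required")
  bad <- !(type %in% c(INTERACTION_TYPES, "unknown"))
  if (any(bad)) stop("unknown interaction type: ", type[bad][1L])
  if (any(parent < 1L | parent > n_genes | child < 1L | child > n_genes))
    stop("edge endpoints must lie in 1..n_genes")
  if (anyDuplicated(paste(parent, child)))
    stop("duplicate (parent, child) pairs are not allowed")
  if (is.null(gene_names)) gene_names <- paste0("G", seq_len(n_genes))
  structure(list(
    n_genes = n_genes,
    gene_names = gene_names,
    edges = data.frame(parent = parent, child = child, type = type,
                       stringsAsFactors = FALSE)
  ), class = "grn_truth")
}

#' @export
print.grn_truth <- function(x, ...) {
  cat("Ground-truth network:", x$n_genes, "genes,", nrow(x$edges), "edges\n")
  if (nrow(x$edges)) {
    sym <- ifelse(x$edges$type == "repression", "-|",
                  ifelse(x$edges$type == "activation", "->", "--"))
    cat(paste0("  ", x$gene_names[x$edges$parent], " ", sym, " ",
               x$gene_names[x$edges$child], collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Construct a candidate model
#'
#' A candidate model for the decoupled system: one child gene together with
#' a parent set of at most `M` genes and, for parametric (typed) models, one
#' interaction type per parent. Non-parametric models always include a
#' self-interaction input; the flag does not count against the parent limit
#' and does not change the size of the candidate space.
#'
#' @param child Child gene id (1-based integer).
#' @param parents Integer vector of parent gene ids (sorted, no child for
#'   parametric models).
#' @param itypes Character vector of per-parent types, or `NULL` for untyped
#'   models.
#' @param includes_self Logical; whether the model carries a self-input
#'   (always `TRUE` for non-parametric models).
#' @return An object of class `candidate_model`.
#' @export
candidate_model <- function(child, parents = integer(), itypes = NULL,
                            includes_self = FALSE) {
  child <- as.integer(child)
  parents <- as.integer(parents)
  if (!is.null(itypes)) {
    itypes <- as.character(itypes)
    if (length(itypes) != length(parents)) stop("one itype per parent required")
    if (!all(itypes %in% INTERACTION_TYPES)) stop("invalid interaction type")
    if (child %in% parents) stop("typed models may not include the child as parent")
  }
  if (anyDuplicated(parents)) stop("duplicate parents")
  structure(list(child = child, parents = parents, itypes = itypes,
                 includes_self = isTRUE(includes_self)),
            class = "candidate_model")
}

#' @export
format.candidate_model <- function(x, ...) {
  if (length(x$parents) == 0L) p <- "(none)"
  else if (is.null(x$itypes)) p <- paste(x$parents, collapse = ",")
  else p <- paste0(x$parents, substr(x$itypes, 1, 1), collapse = ",")
  paste0("child ", x$child, " <- {", p, "}",
         if (x$includes_self) " +self" else "")
}

#' @export
print.candidate_model <- function(x, ...) {
  cat(format(x), "\n"); invisible(x)
}

check_enum_args <- function(n_genes, n_types, max_parents) {
  n_genes <- as.integer(n_genes)
  n_types <- as.integer(n_types)
  if (is.na(n_genes) || n_genes < 2L) stop("n_genes must be >= 2")
  if (is.na(n_types) || !(n_types %in% c(1L, 2L)))
    stop("n_types must be 1 (untyped) or 2 (activation/repression)")
  if (is.null(max_parents)) max_parents <- n_genes - 1L
  max_parents <- as.integer(max_parents)
  if (is.na(max_parents) || max_parents < 0L || max_parents > n_genes - 1L)
    stop("max_parents must lie in 0..n_genes-1 (or NULL for n_genes-1)")
  list(n_genes = n_genes, n_types = n_types, max_parents = max_parents)
}

#' Count candidate models for the decoupled system
#'
#' Closed-form size of the candidate-model space when gradient matching is
#' performed per gene: `N * sum_{i=0}^{M} choose(N-1, i) * F^i`, where `N`
#' is the number of genes, `F` the number of interaction types and `M` the
#' maximum in-degree. The empty parent set (i = 0) is included.
#'
#' @param n_genes Number of genes `N` (>= 2).
#' @param n_types Number of interaction types `F`, 1 (untyped) or 2.
#' @param max_parents Maximum number of parents `M` per gene, or `NULL`
#'   for no cap (`M = N - 1`).
#' @return Total number of candidate models across all child genes, as a
#'   double (counts can exceed `.Machine$integer.max`).
#' @seealso [enumerate_candidate_models()], [count_fully_coupled()]
#' @export
#' @examples
#' count_candidate_models(5, 2, NULL)  # 405
#' count_candidate_models(5, 2, 2)     # 165
#' count_candidate_models(5, 1, 2)     # 55
count_candidate_models <- function(n_genes, n_types, max_parents = NULL) {
  a <- check_enum_args(n_genes, n_types, max_parents)
  i <- 0:a$max_parents
  a$n_genes * sum(choose(a$n_genes - 1, i) * a$n_types^i)
}

#' Count fully coupled models
#'
#' Size of the model space if genes were not decoupled: the per-gene count
#' raised to the `N`-th power. This is the combinatorial explosion the
#' decoupled gradient-matching formulation avoids.
#'
#' @inheritParams count_candidate_models
#' @return Number of fully coupled network models (double).
#' @export
#' @examples
#' count_fully_coupled(5, 2)  # 3486784401, about 3.5e9
count_fully_coupled <- function(n_genes, n_types) {
  a <- check_enum_args(n_genes, n_types, NULL)
  per_gene <- count_candidate_models(n_genes, n_types, NULL) / a$n_genes
  per_gene^a$n_genes
}

#' Enumerate candidate models for the decoupled system
#'
#' For each child gene, generates all parent subsets of size `0..M` over the
#' remaining `N - 1` genes, crossed (when `typed = TRUE`) with all
#' interaction-type assignments. Ordering is deterministic: parent subsets
#' by size then lexicographically by sorted gene-id tuple, type assignments
#' lexicographically with activation before repression.
#'
#' @inheritParams count_candidate_models
#' @param typed If `TRUE`, cross each parent set with all per-parent type
#'   assignments (requires `n_types = 2`); if `FALSE`, untyped models with a
#'   forced self-interaction input (the non-parametric convention).
#' @return A list with one element per child gene, each a list of
#'   [candidate_model()] objects.
#' @export
enumerate_candidate_models <- function(n_genes, n_types, max_parents = NULL,
                                       typed = n_types > 1L) {
  a <- check_enum_args(n_genes, n_types, max_parents)
  if (typed && a$n_types != 2L) stop("typed enumeration requires n_types = 2")
  if (!typed && a$n_types != 1L) stop("untyped enumeration requires n_types = 1")
  lapply(seq_len(a$n_genes), function(child) {
    others <- setdiff(seq_len(a$n_genes), child)
    out <- list()
    for (size in 0:a$max_parents) {
      subsets <- if (size == 0L) list(integer())
        else if (size == length(others)) list(others)  # combn scalar pitfall
        else combn(others, size, simplify = FALSE)
      for (ps in subsets) {
        if (!typed) {
          out[[length(out) + 1L]] <-
            candidate_model(child, ps, NULL, includes_self = TRUE)
        } else if (size == 0L) {
          out[[length(out) + 1L]] <- candidate_model(child, ps, character())
        } else {
          # all F^size type assignments, lexicographic, activation first
          # (expand.grid varies its first factor fastest, so reverse each row
          # to make the first parent the most significant digit)
          grid <- expand.grid(rep(list(INTERACTION_TYPES), size),
                              stringsAsFactors = FALSE)
          for (r in seq_len(nrow(grid)))
            out[[length(out) + 1L]] <-
              candidate_model(child, ps,
                              rev(unlist(grid[r, ], use.names = FALSE)))
        }
      }
    }
    out
  })
}

# Canonical string key for a candidate model (used for seeding and dedup).
candidate_key <- function(model) {
  paste(model$child,
        paste(model$parents, collapse = "."),
        if (is.null(model$itypes)) "u" else
          paste(substr(model$itypes, 1, 1), collapse = ""),
        sep = "|")
}

# Deterministic small-integer seed derived from a base seed and a model,
# independent of the model's position in any list.
candidate_seed <- function(seed, model) {
  key <- utf8ToInt(candidate_key(model))
  h <- 0
  for (k in key) h <- (h * 31 + k) %% 1000003
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Read / write ground-truth network TSV
#'
#' Tab-separated edge list with header `parent  child  type`; `type` is one
#' of `activation`, `repression`, `unknown`. Gene columns may be integer ids
#' or gene names.
#'
#' @param truth A `grn_truth` object.
#' @param path File path.
#' @param n_genes Number of genes (required on read when the file uses
#'   integer ids and isolated genes exist; inferred otherwise).
#' @return `read_truth_tsv()` returns a `grn_truth`; `write_truth_tsv()`
#'   invisibly returns `path`.
#' @export
write_truth_tsv <- function(truth, path) {
  df <- truth$edges
  df$parent <- truth$gene_names[df$parent]
  df$child <- truth$gene_names[df$child]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_tsv
#' @export
read_truth_tsv <- function(path, n_genes = NULL) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("parent", "child", "type") %in% names(df)))
    stop("truth TSV needs header: parent, child, type")
  if (is.character(df$parent)) {
    genes <- unique(c(df$parent, df$child))
    genes <- genes[order(nchar(genes), genes)]  # G2 before G10
    p <- match(df$parent, genes); ch <- match(df$child, genes)
    if (is.null(n_genes)) n_genes <- length(genes)
    ground_truth_network(n_genes, p, ch, df$type, gene_names = genes)
  } else {
    if (is.null(n_genes)) n_genes <- max(df$parent, df$child)
    ground_truth_network(n_genes, df$parent, df$child, df$type)
  }
}

# JSON serialisation of candidate models (one object per model).
candidate_to_list <- function(model) {
  list(child = model$child, parents = model$parents,
       itypes = if (is.null(model$itypes)) NULL else model$itypes,
       includes_self = model$includes_self)
}
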