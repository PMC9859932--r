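#' PC-stable skeleton of a gene regulatory network
#'
#' Constraint-based structure learning: starting from the complete undirected
#' graph over `genes`, the edge between two genes is removed as soon as some
#' conditioning set of size `0 .. max_cond`, drawn from the current neighbors
#' of either endpoint, makes them conditionally independent at level `alpha`.
#' The stable variant freezes the neighbor sets at the start of each level so
#' the result does not depend on the order in which edges are visited; genes
#' are processed in lexicographic order and conditioning sets in sorted
#' combination order, making the output fully deterministic.
#'
#' Only the skeleton is computed — orientation of edges is deliberately
#' discarded, so the result is returned as an unoriented [cascade_set()]
#' containing every gene's singleton cascade plus one pair cascade per
#' surviving edge.
#'
#' @param m an [expr_matrix()] or numeric matrix with gene column names.
#' @param genes genes to include (default: all columns).
#' @param alpha significance level of the conditional-independence tests.
#' @param max_cond largest conditioning-set size.
#' @param test `"fisher_z"` (continuous data) or `"chi2"` (discretized data).
#' @param ... passed to [chi2_ci_test()] (e.g. `bins`, `min_expected`).
#' @return An unoriented [cascade_set()] with attributes `alpha`, `max_cond`,
#'   `test_kind` and `n_tests`.
#' @export
pc_skeleton <- function(m, genes = NULL, alpha = 0.01, max_cond = 3,
                        test = c("fisher_z", "chi2"), ...) {
  test <- match.arg(test)
  m <- as_expr_matrix(m)
  genes <- sort(unique(as.character(genes %||% m$gene_ids)))
  missing <- setdiff(genes, m$gene_ids)
  if (length(missing)) stop_("genes not in matrix: ", paste(missing, collapse = ", "))
  if (!(alpha > 0 && alpha < 1)) stop_("alpha must be in (0, 1)")
  if (max_cond < 0) stop_("max_cond must be >= 0")
  p <- length(genes)
  n <- nrow(m$values)
  if (test == "fisher_z") {
    V <- m$values[, genes, drop = FALSE]
    sds <- apply(V, 2L, stats::sd)
    if (any(sds == 0))
      stop_("zero variance gene(s): ", paste(genes[sds == 0], collapse = ", "))
    C <- stats::cor(V)
    test_fun <- function(i, j, k) fisher_z_from_cor(C, n, i, j, k)$p
  } else {
    test_fun <- function(i, j, k) {
      chi2_ci_test(genes[i], genes[j], genes[k], m, ...)$p_value
    }
  }
  adj <- matrix(p > 1, p, p); diag(adj) <- FALSE
  n_tests <- 0L
  ell <- 0L
  while (ell <= max_cond) {
    frozen <- adj
    if (!any(rowSums(frozen) - 1L >= ell)) break
    for (i in seq_len(p - 1L)) for (j in seq.int(i + 1L, p)) {
      if (!adj[i, j]) next
      cands <- unique(c(cond_sets(which(frozen[i, ]), j, ell),
                        cond_sets(which(frozen[j, ]), i, ell)))
      for (k in cands) {
        n_tests <- n_tests + 1L
        pv <- tryCatch(test_fun(i, j, k), error = function(e)
          stop_("CI test failed for edge ", genes[i], "-", genes[j],
                if (length(k)) paste0(" | {", paste(genes[k], collapse = ","), "}"),
                ": ", conditionMessage(e)))
        if (pv > alpha) { adj[i, j] <- adj[j, i] <- FALSE; break }
      }
    }
    ell <- ell + 1L
  }
  keys <- genes
  hit <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  if (nrow(hit)) keys <- c(keys, paste(genes[hit[, 1L]], genes[hit[, 2L]], sep = "\t"))
  out <- new_cascade_set(keys, genes, oriented = FALSE)
  attr(out, "alpha") <- alpha
  attr(out, "max_cond") <- max_cond
  attr(out, "test_kind") <- test
  attr(out, "n_tests") <- n_tests
  out
}

# size-ell subsets of nbrs \ {excl}, in sorted combination order
cond_sets <- function(nbrs, excl, ell) {
  nbrs <- sort(setdiff(nbrs, excl))
  if (length(nbrs) < ell) return(list())
  if (ell == 0L) return(list(integer(0)))
  lapply(utils::combn(seq_along(nbrs), ell, simplify = FALSE),
         function(ix) nbrs[ix])
}

#' Eigen-cascades of a cell class
#'
#' Learns the network structure shared by the cells of one cell class from the
#' pooled class expression matrix.  Conceptually this approximates the
#' intersection of the member cells' possessed cascades: an edge survives only
#' when the dependence is strong enough across the pooled class to defy the
#' conditional-independence test.
#'
#' @param m an [expr_matrix()]; either already restricted to one class, or
#'   carrying `class_labels` together with the `class` argument.
#' @param genes the vertex genes of the network (default: all).
#' @param class optional class id to select from `m$class_labels`.
#' @param min_cells smallest admissible class size.
#' @inheritParams pc_skeleton
#' @return An unoriented [cascade_set()] (see [pc_skeleton()]).
#' @export
eigen_cascades <- function(m, genes = NULL, class = NULL, alpha = 0.01,
                           max_cond = 3, test = c("fisher_z", "chi2"),
                           min_cells = 30, ...) {
  m <- as_expr_matrix(m)
  id <- class %||% "<all>"
  if (!is.null(class)) {
    if (is.null(m$class_labels)) stop_("matrix carries no class labels")
    m <- subset_cells(m, m$class_labels == class)
  }
  if (nrow(m$values) < min_cells)
    stop_("class '", id, "' has ", nrow(m$values), " cells; floor is ", min_cells)
  genes <- sort(unique(as.character(genes %||% m$gene_ids)))
  if (length(genes) == 1L)
    return(new_cascade_set(genes, genes, oriented = FALSE))
  pc_skeleton(m, genes = genes, alpha = alpha, max_cond = max_cond,
              test = test, ...)
}
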