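#' A cell class with its eigen-cascades
#'
#' A cell class is an equivalence class of cells under an arbitrary partition
#' (a cluster or a supervised label) — deliberately distinct from an empirical
#' cell type.  For comparison purposes it is characterized entirely by its
#' eigen-cascade set.
#'
#' @param class_id,dataset_id identifying strings.
#' @param eigen an unoriented [cascade_set()] (from [eigen_cascades()] or
#'   supplied ground truth).
#' @param cells optional character vector of member cell ids.
#' @return An object of class `"cell_class"`.
#' @export
cell_class <- function(class_id, dataset_id, eigen, cells = character(0)) {
  if (!is_string(class_id) || !is_string(dataset_id))
    stop_("class_id and dataset_id must be non-empty strings")
  stopifnot(inherits(eigen, "cascade_set"))
  structure(list(class_id = class_id, dataset_id = dataset_id,
                 eigen = eigen, cells = as.character(cells)),
            class = "cell_class")
}

#' @export
print.cell_class <- function(x, ...) {
  cat(sprintf("<cell_class> %s @ %s: %d cell(s), %d cascade(s) (%d edge)\n",
              x$class_id, x$dataset_id, length(x$cells),
              length(x$eigen), length(edges(x$eigen))))
  invisible(x)
}

#' Partition of cells into classes
#'
#' @param labels named character vector mapping every cell id to a class id.
#' @param dataset_id identifying string.
#' @return An object of class `"cell_partition"`.
#' @export
cell_partition <- function(labels, dataset_id = "dataset") {
  if (is.null(names(labels)) || anyDuplicated(names(labels)))
    stop_("labels must be uniquely named by cell id")
  if (anyNA(labels)) stop_("every cell must be assigned a class")
  structure(list(dataset_id = dataset_id,
                 labels = stats::setNames(as.character(labels), names(labels))),
            class = "cell_partition")
}

#' Hamming pseudo-metric between network structures
#'
#' The number of cascades present in exactly one of the two sets (the
#' cardinality of the symmetric difference).  This is the single-cell
#' structural distance: symmetric, zero on identical structures, and
#' satisfying the triangle inequality — but two distinct cells may be at
#' distance zero, hence a pseudo-metric.
#'
#' @param a,b [cascade_set()]s over the same universe with the same
#'   orientation flag.
#' @return A non-negative integer.
#' @export
hamming_distance <- function(a, b) {
  stopifnot(inherits(a, "cascade_set"), inherits(b, "cascade_set"))
  check_same_frame(a, b)
  length(union(a$keys, b$keys)) - length(intersect(a$keys, b$keys))
}

#' Asymmetric structural similarity of cell classes
#'
#' `d_star(a, b) = 1 - |a n b| / |a|`, the fraction of the first set's
#' cascades missing from the second.  Zero exactly when every cascade of `a`
#' is contained in `b` — an asymmetric inclusion measure, not a metric: it is
#' the basis of the labeling/estimation annotation modes, where the centered
#' class supplies the denominator.
#'
#' @param a,b [cascade_set()]s over the same universe with the same
#'   orientation flag; `a` must be non-empty.
#' @return A number in `[0, 1]`.
#' @export
d_star <- function(a, b) {
  stopifnot(inherits(a, "cascade_set"), inherits(b, "cascade_set"))
  check_same_frame(a, b)
  if (length(a) == 0L) stop_("undefined denominator: first cascade set is empty")
  1 - length(intersect(a$keys, b$keys)) / length(a$keys)
}

#' Edge-F1 between an estimated and a true skeleton
#'
#' Harmonic mean of edge precision and recall of an estimated network
#' structure against a reference, ignoring the (always shared) singleton
#' cascades.  1 when both edge sets agree, and by convention 1 when both are
#' empty.
#'
#' @param estimate,truth [cascade_set()]s over the same universe.
#' @return A number in `[0, 1]`.
#' @export
edge_f1 <- function(estimate, truth) {
  stopifnot(inherits(estimate, "cascade_set"), inherits(truth, "cascade_set"))
  check_same_frame(estimate, truth)
  e1 <- edges(estimate)$keys
  e2 <- edges(truth)$keys
  if (!length(e1) && !length(e2)) return(1)
  tp <- length(intersect(e1, e2))
  if (tp == 0L) return(0)
  prec <- tp / length(e1)
  rec <- tp / length(e2)
  2 * prec * rec / (prec + rec)
}
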