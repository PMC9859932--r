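#' Factor scores (regression method)
#'
#' Thurstone regression scores on standardized variables:
#' `Z %*% solve(R) %*% L %*% Phi` with the structure matrix of the oblique
#' solution.
#'
#' @param model a `"factor_model"`.
#' @param m an [expr_matrix()] or numeric matrix containing the model's
#'   variables.
#' @return A cells-by-factors numeric matrix.
#' @export
factor_scores <- function(model, m) {
  stopifnot(inherits(model, "factor_model"))
  m <- as_expr_matrix(m)
  missing <- setdiff(model$variables, m$gene_ids)
  if (length(missing)) stop_("variables not in matrix: ", paste(missing, collapse = ", "))
  if (model$n_factors < 1L || !length(model$variables)) stop_("empty factor model")
  Z <- scale(m$values[, model$variables, drop = FALSE])
  S <- model$loadings %*% model$Phi
  W <- solve(model$R, S)
  scores <- Z %*% W
  rownames(scores) <- m$cell_ids
  scores
}

#' k-means model selection by silhouette
#'
#' Runs k-means (with `n_init` restarts) on a score matrix for every `k` in
#' `k_range`, computes the mean and SD of the silhouette coefficient, the
#' entropy of the cluster-size distribution, and the inertia (total
#' within-cluster sum of squares) with successive differences, and picks the
#' `k` maximizing the mean silhouette (smaller `k` wins ties).
#'
#' @param scores numeric matrix (e.g. from [factor_scores()]).
#' @param k_range integer vector of candidate cluster counts.
#' @param seed optional seed (per-k seeds are derived from it).
#' @param n_init number of random restarts per k.
#' @return A `"clustering_report"` with per-k diagnostics, `chosen_k`, and
#'   `labels` (named character vector of cluster assignments at `chosen_k`).
#' @export
kmeans_select <- function(scores, k_range = 2:15, seed = NULL, n_init = 10) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2L) || any(k_range > n - 1L))
    stop_("k_range must lie within [2, n_cells - 1]")
  if (all(apply(scores, 2L, stats::sd) == 0))
    stop_("silhouette undefined: all points identical")
  D <- stats::dist(scores)
  res <- lapply(seq_along(k_range), function(i) {
    k <- k_range[i]
    km <- with_seed(if (!is.null(seed)) derive_seed(seed, k),
                    stats::kmeans(scores, centers = k, nstart = n_init,
                                  iter.max = 100))
    sil <- cluster::silhouette(km$cluster, D)
    widths <- sil[, "sil_width"]
    list(k = k, sil_mean = mean(widths), sil_sd = stats::sd(widths),
         entropy = categorical_entropy(km$cluster),
         inertia = km$tot.withinss, cluster = km$cluster)
  })
  sil_mean <- vapply(res, `[[`, 0, "sil_mean")
  chosen <- which.max(sil_mean)     # first maximum = smallest k on ties
  labels <- as.character(res[[chosen]]$cluster)
  names(labels) <- rownames(scores) %||% sprintf("cell%d", seq_len(n))
  inertia <- vapply(res, `[[`, 0, "inertia")
  structure(list(k_range = k_range,
                 silhouette_mean = sil_mean,
                 silhouette_sd = vapply(res, `[[`, 0, "sil_sd"),
                 entropy = vapply(res, `[[`, 0, "entropy"),
                 inertia = inertia,
                 inertia_diff = c(NA, diff(inertia)),
                 chosen_k = k_range[chosen],
                 labels = labels),
            class = "clustering_report")
}

#' @export
print.clustering_report <- function(x, ...) {
  cat(sprintf("<clustering_report> chosen k = %d (mean silhouette %.3f)\n",
              x$chosen_k, max(x$silhouette_mean)))
  invisible(x)
}

#' Entropy of a categorical label distribution
#'
#' Shannon entropy in nats of the label proportions; zero for a single
#' cluster, `log(k)` for k equally sized clusters.
#'
#' @param labels vector of labels.
#' @return A non-negative number (nats).
#' @export
categorical_entropy <- function(labels) {
  if (!length(labels)) stop_("need at least one observation")
  p <- as.vector(table(labels)) / length(labels)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Agreement between two partitions
#'
#' Adjusted Rand index and adjusted mutual information (expected values
#' adjusted under the permutation model; AMI uses natural logs and the
#' arithmetic-mean normalization).  Both are 1 for identical partitions (up
#' to relabeling) and near 0 for independent ones.
#'
#' @param a,b partitions over the same cells: [cell_partition()] objects or
#'   named label vectors.
#' @return Named numeric vector `c(ari, ami)`.
#' @export
partition_agreement <- function(a, b) {
  la <- partition_labels(a); lb <- partition_labels(b)
  if (!setequal(names(la), names(lb)))
    stop_("partitions cover different cell sets")
  lb <- lb[names(la)]
  ct <- table(la, lb)
  c(ari = adjusted_rand(ct), ami = adjusted_mutual_information(ct))
}

partition_labels <- function(x) {
  if (inherits(x, "cell_partition")) return(x$labels)
  if (is.null(names(x))) names(x) <- sprintf("cell%d", seq_along(x))
  stats::setNames(as.character(x), names(x))
}

adjusted_rand <- function(ct) {
  n <- sum(ct)
  sum_comb <- function(v) sum(choose(v, 2))
  idx <- sum_comb(as.vector(ct))
  ra <- sum_comb(rowSums(ct)); rb <- sum_comb(colSums(ct))
  expected <- ra * rb / choose(n, 2)
  max_idx <- (ra + rb) / 2
  if (max_idx == expected) return(1)
  (idx - expected) / (max_idx - expected)
}

adjusted_mutual_information <- function(ct) {
  n <- sum(ct)
  a <- rowSums(ct); b <- colSums(ct)
  pa <- a / n; pb <- b / n
  hu <- -sum(pa[pa > 0] * log(pa[pa > 0]))
  hv <- -sum(pb[pb > 0] * log(pb[pb > 0]))
  if (hu == 0 && hv == 0) return(1)
  p <- ct / n
  nz <- p > 0
  mi <- sum(p[nz] * log(p[nz] / outer(pa, pb)[nz]))
  emi <- expected_mi(a, b, n)
  denom <- (hu + hv) / 2 - emi
  if (denom == 0) return(0)
  (mi - emi) / denom
}

# expected MI under the hypergeometric (fixed-margin) permutation model
expected_mi <- function(a, b, n) {
  emi <- 0
  lf <- lfactorial
  for (ai in a) for (bj in b) {
    lo <- max(1, ai + bj - n)
    hi <- min(ai, bj)
    if (hi < lo) next
    nij <- lo:hi
    lp <- lf(ai) + lf(bj) + lf(n - ai) + lf(n - bj) - lf(n) -
      lf(nij) - lf(ai - nij) - lf(bj - nij) - lf(n - ai - bj + nij)
    emi <- emi + sum(nij / n * log(n * nij / (ai * bj)) * exp(lp))
  }
  emi
}
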