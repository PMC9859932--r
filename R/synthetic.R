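#' Random ground-truth regulatory network
#'
#' Samples an Erdős–Rényi DAG over a random topological order of the genes:
#' each admissible (order-respecting) gene pair carries an edge with
#' probability `edge_prob`, with a weight drawn uniformly from
#' `[-max, -min] U [min, max]`.  Together with an exogenous Gaussian noise
#' term per gene this defines a linear structural model in which the latent
#' environment acts as independent parents of every gene.
#'
#' @param n_genes number of genes.
#' @param edge_prob edge probability in `[0, 1]`.
#' @param weight_range length-2 positive vector, the magnitude range of edge
#'   weights.
#' @param noise_sd SD of the exogenous noise term.
#' @param seed optional seed; the same seed reproduces the same network.
#' @param genes optional gene names (default `g01, g02, ...`).
#' @return An object of class `"grn_truth"`: `genes` (sorted), weight matrix
#'   `W` (`W[parent, child]`), topological `order`, `noise_sd`.
#' @export
random_dag <- function(n_genes, edge_prob, weight_range = c(0.5, 1.5),
                       noise_sd = 1, seed = NULL, genes = NULL) {
  if (edge_prob < 0 || edge_prob > 1) stop_("edge_prob must be in [0, 1]")
  if (length(weight_range) != 2L || any(weight_range <= 0))
    stop_("weight_range must be two positive magnitudes")
  genes <- as.character(genes %||% sprintf("g%02d", seq_len(n_genes)))
  stopifnot(length(genes) == n_genes)
  check_gene_symbols(genes)
  with_seed(seed, {
    ord <- sample(genes)
    W <- matrix(0, n_genes, n_genes, dimnames = list(genes, genes))
    for (i in seq_len(max(n_genes - 1L, 0L))) for (j in seq.int(i + 1L, n_genes)) {
      if (n_genes < 2L) break
      if (stats::runif(1) < edge_prob) {
        w <- stats::runif(1, weight_range[1L], weight_range[2L]) * sample(c(-1, 1), 1)
        W[ord[i], ord[j]] <- w
      }
    }
    structure(list(genes = sort(genes), W = W, order = ord,
                   noise_sd = noise_sd, edge_prob = edge_prob),
              class = "grn_truth")
  })
}

#' @export
print.grn_truth <- function(x, ...) {
  cat(sprintf("<grn_truth> %d gene(s), %d edge(s)\n",
              length(x$genes), sum(x$W != 0)))
  invisible(x)
}

#' Ground-truth cascade set of a network
#'
#' The cascade representation of the true structure: every gene's singleton
#' plus, per weighted edge, the pair cascade whose dependent gene is the
#' child (oriented) or the unoriented skeleton edge.
#'
#' @param gt a `"grn_truth"`.
#' @param oriented return the directed cascades (`TRUE`) or the skeleton.
#' @return A [cascade_set()].
#' @export
true_cascades <- function(gt, oriented = FALSE) {
  stopifnot(inherits(gt, "grn_truth"))
  idx <- which(gt$W != 0, arr.ind = TRUE)
  parents <- rownames(gt$W)[idx[, 1L]]
  children <- colnames(gt$W)[idx[, 2L]]
  if (oriented) {
    keys <- c(paste(gt$genes, "-", sep = "\t"),
              paste(children, parents, sep = "\t"))
    new_cascade_set(keys, gt$genes, oriented = TRUE)
  } else {
    pair <- ifelse(parents < children,
                   paste(parents, children, sep = "\t"),
                   paste(children, parents, sep = "\t"))
    new_cascade_set(c(gt$genes, pair), gt$genes, oriented = FALSE)
  }
}

#' Sample cells from a ground-truth network
#'
#' Linear-Gaussian structural sampling: in topological order each gene is the
#' weighted sum of its parents plus independent Gaussian noise (the exogenous
#' environment term).  A `"binary"` mode instead draws Bernoulli states with
#' a logistic link on ±1-coded parents, for the discrete test path.
#'
#' @param gt a `"grn_truth"`.
#' @param n_cells number of cells to draw.
#' @param class_id optional class label attached to every cell.
#' @param seed optional seed.
#' @param mode `"gaussian"` or `"binary"`.
#' @return An [expr_matrix()].
#' @export
sample_cells <- function(gt, n_cells, class_id = NULL, seed = NULL,
                         mode = c("gaussian", "binary")) {
  stopifnot(inherits(gt, "grn_truth"))
  mode <- match.arg(mode)
  if (n_cells < 1L) stop_("n_cells must be >= 1")
  genes <- gt$order                       # topological order
  W <- gt$W[genes, genes, drop = FALSE]
  p <- length(genes)
  X <- with_seed(seed, {
    if (mode == "gaussian") {
      E <- matrix(stats::rnorm(n_cells * p, sd = gt$noise_sd), n_cells, p)
      E %*% solve(diag(p) - W)
    } else {
      M <- matrix(0, n_cells, p)
      for (j in seq_len(p)) {
        eta <- if (j > 1L)
          (2 * M[, seq_len(j - 1L), drop = FALSE] - 1) %*% W[seq_len(j - 1L), j]
        else rep(0, n_cells)
        M[, j] <- stats::rbinom(n_cells, 1L, stats::plogis(2 * eta))
      }
      M
    }
  })
  colnames(X) <- genes
  expr_matrix(X[, gt$genes, drop = FALSE],
              cell_ids = sprintf("%s_c%04d", class_id %||% "cell", seq_len(n_cells)),
              class_labels = if (!is.null(class_id)) rep(class_id, n_cells))
}

#' Assemble a labeled multi-class dataset
#'
#' Samples every class from its own ground-truth network over a shared gene
#' universe, concatenates and shuffles the cells, and keeps the truths
#' alongside the data.
#'
#' @param class_specs named list: one entry per class, each a list with
#'   elements `truth` (a `"grn_truth"`) and `n_cells`.
#' @param seed optional seed (per-class seeds are derived from it).
#' @param mode passed to [sample_cells()].
#' @return A list of class `"synthetic_dataset"` with `matrix` (labeled
#'   [expr_matrix()]) and `truths`.
#' @export
make_dataset <- function(class_specs, seed = NULL, mode = "gaussian") {
  ids <- names(class_specs)
  if (is.null(ids) || anyDuplicated(ids) || any(!nzchar(ids)))
    stop_("class_specs must be uniquely named by class id")
  universes <- lapply(class_specs, function(s) s$truth$genes)
  if (length(unique(vapply(universes, paste, "", collapse = ","))) > 1L)
    stop_("all classes must share one gene universe")
  parts <- lapply(seq_along(class_specs), function(i) {
    s <- class_specs[[i]]
    sample_cells(s$truth, s$n_cells, class_id = ids[i],
                 seed = if (!is.null(seed)) derive_seed(seed, i), mode = mode)
  })
  vals <- do.call(rbind, lapply(parts, function(p) p$values))
  labels <- unlist(lapply(parts, function(p) unname(p$class_labels)))
  cells <- unlist(lapply(parts, function(p) p$cell_ids))
  perm <- with_seed(if (!is.null(seed)) derive_seed(seed, 0L),
                    sample(length(cells)))
  m <- expr_matrix(vals[perm, , drop = FALSE], cell_ids = cells[perm],
                   class_labels = labels[perm])
  structure(list(matrix = m, truths = stats::setNames(
    lapply(class_specs, `[[`, "truth"), ids)),
    class = "synthetic_dataset")
}

#' Perturb a ground-truth network by edge edits
#'
#' Applies `n_edits` random single-edge additions or deletions, respecting
#' the original topological order (so the result stays acyclic) and never
#' touching the same gene pair twice (so edits cannot cancel and the skeleton
#' Hamming distance from the original is exactly `n_edits`).
#'
#' @param gt a `"grn_truth"`.
#' @param n_edits number of edge edits (>= 0).
#' @param seed optional seed.
#' @param weight_range magnitude range for added edges.
#' @return A `"grn_truth"`; the edit list is attached as attribute
#'   `"edits"`.
#' @export
perturb_grn <- function(gt, n_edits, seed = NULL, weight_range = c(0.5, 1.5)) {
  stopifnot(inherits(gt, "grn_truth"))
  if (n_edits < 0) stop_("n_edits must be >= 0")
  ord <- gt$order
  with_seed(seed, {
    W <- gt$W
    touched <- character(0)
    edits <- character(0)
    pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "|")
    for (e in seq_len(n_edits)) {
      present <- which(W != 0, arr.ind = TRUE)
      del_cand <- if (nrow(present)) {
        keys <- apply(present, 1L, function(ij)
          pair_key(rownames(W)[ij[1L]], colnames(W)[ij[2L]]))
        present[!keys %in% touched, , drop = FALSE]
      } else present
      add_cand <- NULL
      for (i in seq_len(length(ord) - 1L)) for (j in seq.int(i + 1L, length(ord))) {
        a <- ord[i]; b <- ord[j]
        if (W[a, b] == 0 && W[b, a] == 0 && !pair_key(a, b) %in% touched)
          add_cand <- rbind(add_cand, c(a, b))
      }
      can_del <- !is.null(del_cand) && nrow(del_cand) > 0
      can_add <- !is.null(add_cand) && nrow(add_cand) > 0
      if (!can_del && !can_add)
        stop_("impossible edit budget: no untouched pairs left")
      do_add <- if (can_add && can_del) stats::runif(1) < 0.5 else can_add
      if (do_add) {
        r <- add_cand[sample(nrow(add_cand), 1L), ]
        W[r[1L], r[2L]] <- stats::runif(1, weight_range[1L], weight_range[2L]) *
          sample(c(-1, 1), 1)
        touched <- c(touched, pair_key(r[1L], r[2L]))
        edits <- c(edits, paste0("+", r[1L], "->", r[2L]))
      } else {
        ri <- del_cand[sample(nrow(del_cand), 1L), ]
        a <- rownames(W)[ri[1L]]; b <- colnames(W)[ri[2L]]
        W[ri[1L], ri[2L]] <- 0
        touched <- c(touched, pair_key(a, b))
        edits <- c(edits, paste0("-", a, "->", b))
      }
    }
    out <- gt
    out$W <- W
    attr(out, "edits") <- edits
    out
  })
}

#' Simulate a block factor structure
#'
#' Draws cells from a common-factor model with disjoint variable blocks: each
#' block loads `loading` on its own factor, optional extra genes are pure
#' noise.  Used to exercise the factor-analysis and clustering paths with a
#' known latent structure.
#'
#' @param n_cells number of cells.
#' @param block_sizes integer vector, one entry per factor/block.
#' @param loading common loading of block variables on their factor.
#' @param n_noise number of additional pure-noise genes.
#' @param factor_cor correlation between factors.
#' @param seed optional seed.
#' @return An [expr_matrix()]; the latent factor scores are attached as
#'   attribute `"factors"`.
#' @export
simulate_factor_blocks <- function(n_cells, block_sizes = c(10, 10),
                                   loading = 0.8, n_noise = 0,
                                   factor_cor = 0, seed = NULL) {
  k <- length(block_sizes)
  with_seed(seed, {
    Fm <- matrix(stats::rnorm(n_cells * k), n_cells, k)
    if (k > 1L && factor_cor != 0) {
      Sigma <- matrix(factor_cor, k, k); diag(Sigma) <- 1
      Fm <- Fm %*% chol(Sigma)
    }
    p <- sum(block_sizes)
    L <- matrix(0, p, k)
    stops <- cumsum(block_sizes)
    starts <- c(1L, utils::head(stops, -1L) + 1L)
    for (j in seq_len(k)) L[starts[j]:stops[j], j] <- loading
    X <- Fm %*% t(L) +
      matrix(stats::rnorm(n_cells * p, sd = sqrt(1 - loading^2)), n_cells, p)
    genes <- unlist(lapply(seq_len(k), function(j)
      sprintf("blk%d_g%02d", j, seq_len(block_sizes[j]))))
    if (n_noise > 0) {
      X <- cbind(X, matrix(stats::rnorm(n_cells * n_noise), n_cells, n_noise))
      genes <- c(genes, sprintf("noise_g%02d", seq_len(n_noise)))
    }
    colnames(X) <- genes
    out <- expr_matrix(X)
    attr(out, "factors") <- Fm
    out
  })
}

#' Ensemble of ground-truth networks with distinct skeletons
#'
#' Draws `n` independent random DAGs and, when `distinct = TRUE`, resamples
#' until all pairwise skeletons are distinct and non-nested.  Non-nestedness
#' matters for annotation benchmarks: if one true skeleton is contained in
#' another, the asymmetric similarity of the smaller class to the larger
#' reference is exactly zero and the true assignment is ambiguous by
#' construction.
#'
#' @param n number of networks.
#' @param n_genes,edge_prob,weight_range,noise_sd as in [random_dag()].
#' @param distinct require pairwise distinct, non-nested skeletons.
#' @param seed optional seed.
#' @param max_tries resampling budget.
#' @return A list of `"grn_truth"` objects.
#' @export
random_dag_ensemble <- function(n, n_genes, edge_prob,
                                weight_range = c(0.5, 1.5), noise_sd = 1,
                                distinct = TRUE, seed = NULL, max_tries = 100) {
  for (try in seq_len(max_tries)) {
    gts <- lapply(seq_len(n), function(i)
      random_dag(n_genes, edge_prob, weight_range, noise_sd,
                 seed = if (!is.null(seed)) derive_seed(seed, try * 1000L + i)))
    if (!distinct) return(gts)
    sk <- lapply(gts, function(g) true_cascades(g)$keys)
    ok <- TRUE
    if (n > 1L) for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      if (all(sk[[i]] %in% sk[[j]]) || all(sk[[j]] %in% sk[[i]])) ok <- FALSE
    }
    if (ok) return(gts)
  }
  stop_("could not draw ", n, " non-nested skeletons in ", max_tries, " tries")
}
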