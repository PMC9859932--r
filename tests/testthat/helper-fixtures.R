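# shared fixture builders (all data generated in code)

# random dependency oracle as a logical matrix over `genes`
random_dep_matrix <- function(genes, prob = 0.3) {
  p <- length(genes)
  D <- matrix(stats::runif(p * p) < prob, p, p, dimnames = list(genes, genes))
  diag(D) <- FALSE
  D
}

# random complete possessed-cascade set over up to `max_genes` genes
random_possessed_set <- function(max_genes = 8, prob = 0.3) {
  p <- sample(2:max_genes, 1)
  genes <- sort(sample(letters, p))
  cascades_from_dependency(random_dep_matrix(genes, prob), genes)
}

# small labeled two-class linear-Gaussian dataset
toy_dataset <- function(seed = 1, n_cells = 200, n_genes = 5, edge_prob = 0.4) {
  gts <- random_dag_ensemble(2, n_genes, edge_prob, seed = seed)
  make_dataset(list(A = list(truth = gts[[1]], n_cells = n_cells),
                    B = list(truth = gts[[2]], n_cells = n_cells)),
               seed = seed)
}
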