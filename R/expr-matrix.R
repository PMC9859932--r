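#' Expression matrix container
#'
#' A light cells-by-genes container for (normalized) expression values with
#' optional per-cell class labels (cell classes / clusters) and group labels
#' (finer subclasses, used to keep folds grouped in cross-validation).
#'
#' @param values numeric matrix, cells in rows, genes in columns.
#' @param cell_ids,gene_ids character vectors; default to dimnames.
#' @param class_labels,group_labels optional per-cell character vectors.
#' @return An object of class `"expr_matrix"`.
#' @export
expr_matrix <- function(values, cell_ids = rownames(values),
                        gene_ids = colnames(values),
                        class_labels = NULL, group_labels = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop_("expression values must be numeric")
  if (nrow(values) < 1L) stop_("at least one cell is required")
  if (anyNA(values)) stop_("missing values in expression matrix")
  if (is.null(cell_ids)) cell_ids <- sprintf("cell%d", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- sprintf("g%d", seq_len(ncol(values)))
  cell_ids <- as.character(cell_ids); gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values) || length(gene_ids) != ncol(values))
    stop_("id lengths do not match matrix dimensions")
  if (anyDuplicated(gene_ids)) stop_("gene ids must be unique")
  check_gene_symbols(gene_ids)
  dimnames(values) <- list(cell_ids, gene_ids)
  lbl <- function(x, what) {
    if (is.null(x)) return(NULL)
    x <- as.character(x)
    if (length(x) != nrow(values)) stop_(what, " must have one entry per cell")
    names(x) <- cell_ids
    x
  }
  structure(list(values = values, cell_ids = cell_ids, gene_ids = gene_ids,
                 class_labels = lbl(class_labels, "class_labels"),
                 group_labels = lbl(group_labels, "group_labels")),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d cell(s) x %d gene(s)%s\n",
              nrow(x$values), ncol(x$values),
              if (!is.null(x$class_labels))
                sprintf(", %d class(es)", length(unique(x$class_labels))) else ""))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix
#'
#' @param x an [expr_matrix()].
#' @param cells,genes indices, ids, or logical masks; `NULL` keeps all.
#' @return An [expr_matrix()].
#' @export
subset_cells <- function(x, cells = NULL, genes = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  ci <- if (is.null(cells)) seq_len(nrow(x$values)) else cells
  gi <- if (is.null(genes)) seq_len(ncol(x$values)) else genes
  expr_matrix(x$values[ci, gi, drop = FALSE],
              class_labels = if (!is.null(x$class_labels)) unname(x$class_labels[ci]),
              group_labels = if (!is.null(x$group_labels)) unname(x$group_labels[ci]))
}

as_expr_matrix <- function(m) {
  if (inherits(m, "expr_matrix")) m else expr_matrix(as.matrix(m))
}

# ---------------------------------------------------------------------------

#' Read an expression matrix
#'
#' `dense_tsv` expects genes in rows (first column = gene symbol, header =
#' cell barcodes), the common export convention; values are transposed to the
#' internal cells-by-genes layout.  `mtx` expects a Matrix Market triplet file
#' with `genes.tsv` and `barcodes.tsv` sidecars in the same directory (the
#' droplet-sequencing convention, genes x cells).
#'
#' @param path file path (for `mtx`, the `.mtx` file or its directory).
#' @param format `"dense_tsv"` or `"mtx"`.
#' @param labels optional path to a two-column TSV (cell id, class id) of
#'   per-cell class labels.
#' @return An [expr_matrix()].
#' @export
read_matrix <- function(path, format = c("dense_tsv", "mtx"), labels = NULL) {
  format <- match.arg(format)
  m <- switch(format, dense_tsv = read_dense_tsv(path), mtx = read_mtx(path))
  if (!is.null(labels)) {
    lab <- utils::read.delim(labels, header = FALSE, colClasses = "character")
    if (ncol(lab) < 2L) stop_("label file needs two columns: cell id, class id")
    key <- stats::setNames(lab[[2L]], lab[[1L]])
    missing <- setdiff(m$cell_ids, names(key))
    if (length(missing)) stop_("cells without labels: ", paste(utils::head(missing), collapse = ", "))
    m$class_labels <- stats::setNames(unname(key[m$cell_ids]), m$cell_ids)
  }
  m
}

read_dense_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L) stop_("empty matrix: ", path)
  genes <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    bad <- which(!apply(df[, -1L, drop = FALSE], 1L, function(r) all(!is.na(suppressWarnings(as.numeric(r))))))
    stop_("non-numeric entries at data line(s): ", paste(utils::head(bad + 1L), collapse = ", "))
  }
  if (anyDuplicated(genes)) {
    genes <- make.unique(genes, sep = ".")
    message("duplicate gene symbols disambiguated with suffixes")
  }
  expr_matrix(t(vals), cell_ids = colnames(vals), gene_ids = genes)
}

read_mtx <- function(path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    dirn <- path
  } else {
    mtx <- path
    dirn <- dirname(path)
  }
  if (!file.exists(mtx)) stop_("matrix file not found: ", mtx)
  lines <- readLines(mtx)
  body_idx <- which(!startsWith(lines, "%"))
  if (!length(body_idx)) stop_("empty matrix: ", mtx)
  hdr <- as.numeric(strsplit(trimws(lines[body_idx[1L]]), "\\s+")[[1L]])
  if (length(hdr) != 3L || anyNA(hdr)) stop_("malformed size header at line ", body_idx[1L])
  ng <- hdr[1L]; nc <- hdr[2L]; nnz <- hdr[3L]
  ent_lines <- body_idx[-1L]
  if (length(ent_lines) != nnz)
    stop_("entry count mismatch: header says ", nnz, ", found ", length(ent_lines))
  vals <- matrix(0, nrow = ng, ncol = nc)
  for (li in ent_lines) {
    e <- suppressWarnings(as.numeric(strsplit(trimws(lines[li]), "\\s+")[[1L]]))
    if (length(e) != 3L || anyNA(e))
      stop_("non-numeric or malformed entry at line ", li)
    if (e[1L] < 1 || e[1L] > ng || e[2L] < 1 || e[2L] > nc)
      stop_("index out of range at line ", li)
    vals[e[1L], e[2L]] <- e[3L]
  }
  genes <- utils::read.delim(file.path(dirn, "genes.tsv"), header = FALSE)[[1L]]
  cells <- utils::read.delim(file.path(dirn, "barcodes.tsv"), header = FALSE)[[1L]]
  if (length(genes) != ng || length(cells) != nc)
    stop_("sidecar dimensions do not match the matrix header")
  genes <- as.character(genes)
  if (anyDuplicated(genes)) {
    genes <- make.unique(genes, sep = ".")
    message("duplicate gene symbols disambiguated with suffixes")
  }
  expr_matrix(t(vals), cell_ids = as.character(cells), gene_ids = genes)
}

#' Write an expression matrix as dense TSV (genes in rows)
#'
#' @param m an [expr_matrix()].
#' @param path output path.
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "expr_matrix"))
  df <- data.frame(gene = m$gene_ids, t(m$values), check.names = FALSE)
  colnames(df) <- c("gene", m$cell_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Library-size normalization
#'
#' Scales every cell to one million total counts (RPM) and optionally applies
#' a `log2(x + 1)` (reference convention) or `ln(x + 1)` (query convention)
#' transform.
#'
#' @param m an [expr_matrix()] of raw non-negative counts.
#' @param mode one of `"rpm_log2"`, `"rpm_ln"`, `"rpm"`, `"none"`.
#' @return An [expr_matrix()].
#' @export
normalize_expression <- function(m, mode = c("rpm_log2", "rpm_ln", "rpm", "none")) {
  mode <- match.arg(mode)
  m <- as_expr_matrix(m)
  if (mode == "none") return(m)
  if (any(m$values < 0)) stop_("normalization expects non-negative counts")
  totals <- rowSums(m$values)
  zero <- totals <= 0
  if (any(zero))
    stop_("cell(s) with zero total counts: ",
          paste(utils::head(m$cell_ids[zero]), collapse = ", "))
  v <- m$values / totals * 1e6
  v <- switch(mode, rpm = v, rpm_log2 = log2(v + 1), rpm_ln = log(v + 1))
  m$values <- v
  m
}

#' Mitochondrial-fraction quality control
#'
#' Drops cells whose fraction of counts on mitochondrial genes (matched by
#' symbol prefix) exceeds a ceiling.
#'
#' @param m an [expr_matrix()] of raw counts.
#' @param prefix gene-symbol prefix identifying mitochondrial genes.
#' @param ceiling maximum allowed mitochondrial fraction.
#' @return An [expr_matrix()]; the number of dropped cells is attached as
#'   attribute `"n_dropped"`.
#' @export
qc_mito <- function(m, prefix = "MT-", ceiling = 0.10) {
  m <- as_expr_matrix(m)
  mito <- startsWith(m$gene_ids, prefix)
  if (!any(mito)) {
    warning("no genes match prefix '", prefix, "'; quality control skipped")
    attr(m, "n_dropped") <- 0L
    return(m)
  }
  totals <- rowSums(m$values)
  frac <- ifelse(totals > 0, rowSums(m$values[, mito, drop = FALSE]) / totals, 1)
  keep <- frac <= ceiling
  out <- subset_cells(m, keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}
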