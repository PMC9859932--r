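new_ci_test <- function(x, y, cond, p, stat, kind, extra = list()) {
  structure(c(list(pair = c(x, y), conditioning_set = sort(cond),
                   p_value = p, statistic = stat, test_kind = kind), extra),
            class = "ci_test")
}

#' @export
print.ci_test <- function(x, ...) {
  cat(sprintf("%s CI test: %s _||_ %s%s  stat = %.4g, p = %.4g\n",
              x$test_kind, x$pair[1L], x$pair[2L],
              if (length(x$conditioning_set))
                paste0(" | {", paste(x$conditioning_set, collapse = ","), "}") else "",
              x$statistic, x$p_value))
  invisible(x)
}

#' Fisher-z partial-correlation independence test
#'
#' Tests the null of zero partial correlation between two genes given a
#' conditioning set, for continuous expression values.  The partial
#' correlation is obtained from the inverse of the sub-correlation matrix; the
#' statistic `z = atanh(r) * sqrt(n - |cond| - 3)` is referred to a standard
#' normal (two-sided).
#'
#' @param x,y gene symbols.
#' @param cond character vector of conditioning genes (may be empty).
#' @param m an [expr_matrix()] or numeric matrix with gene column names.
#' @return A `"ci_test"` object with fields `p_value`, `statistic`,
#'   `test_kind`, `pair`, `conditioning_set`.
#' @export
fisher_z_test <- function(x, y, cond = character(0), m) {
  m <- as_expr_matrix(m)
  cond <- setdiff(as.character(cond), c(x, y))
  vars <- c(x, y, cond)
  missing <- setdiff(vars, m$gene_ids)
  if (length(missing)) stop_("genes not in matrix: ", paste(missing, collapse = ", "))
  n <- nrow(m$values)
  if (n <= length(cond) + 3L)
    stop_("need more than |cond| + 3 cells (have ", n, ")")
  V <- m$values[, vars, drop = FALSE]
  if (any(apply(V, 2L, stats::sd) == 0)) stop_("zero variance column among test variables")
  C <- stats::cor(V)
  res <- fisher_z_from_cor(C, n, 1L, 2L, seq_along(cond) + 2L)
  new_ci_test(x, y, cond, res$p, res$z, "fisher_z", list(partial_cor = res$r))
}

# partial correlation of variables i, j given k (indices into C), Fisher-z p
fisher_z_from_cor <- function(C, n, i, j, k) {
  if (length(k) == 0L) {
    r <- C[i, j]
  } else {
    idx <- c(i, j, k)
    S <- C[idx, idx, drop = FALSE]
    P <- tryCatch(solve(S), error = function(e) stop_("collinear conditioning set"))
    r <- -P[1L, 2L] / sqrt(P[1L, 1L] * P[2L, 2L])
  }
  r <- max(min(r, 1 - 1e-12), -1 + 1e-12)
  z <- atanh(r) * sqrt(n - length(k) - 3)
  list(r = r, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Stratified chi-square independence test
#'
#' Tests independence of two (discretized) genes within every stratum of the
#' conditioning genes and pools the Pearson chi-square statistics and degrees
#' of freedom across strata.  Strata where any expected cell count falls below
#' `min_expected` are skipped and counted.
#'
#' @inheritParams fisher_z_test
#' @param bins discretization rule: `"median"` splits continuous columns at
#'   their median; columns with at most 5 distinct values are used as
#'   categories directly.  Alternatively a function mapping a numeric vector
#'   to a discrete vector.
#' @param min_expected expected-count floor below which a stratum is skipped.
#' @return A `"ci_test"` object; `n_strata_skipped` records skipped strata.
#' @export
chi2_ci_test <- function(x, y, cond = character(0), m, bins = "median",
                         min_expected = 5) {
  m <- as_expr_matrix(m)
  cond <- setdiff(as.character(cond), c(x, y))
  vars <- c(x, y, cond)
  missing <- setdiff(vars, m$gene_ids)
  if (length(missing)) stop_("genes not in matrix: ", paste(missing, collapse = ", "))
  D <- apply(m$values[, vars, drop = FALSE], 2L, discretize_column, bins = bins)
  if (!is.matrix(D)) D <- matrix(D, ncol = length(vars), dimnames = list(NULL, vars))
  for (v in vars) if (length(unique(D[, v])) < 2L)
    stop_("discretized variable '", v, "' has fewer than 2 levels")
  strata <- if (length(cond)) interaction(as.data.frame(D[, cond, drop = FALSE]), drop = TRUE)
            else factor(rep(1L, nrow(D)))
  stat <- 0; df <- 0L; skipped <- 0L
  for (s in levels(strata)) {
    sel <- strata == s
    tab <- table(D[sel, 1L], D[sel, 2L])
    tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(tab) < 2L || ncol(tab) < 2L) { skipped <- skipped + 1L; next }
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < min_expected)) { skipped <- skipped + 1L; next }
    stat <- stat + sum((tab - expected)^2 / expected)
    df <- df + (nrow(tab) - 1L) * (ncol(tab) - 1L)
  }
  if (df == 0L) stop_("insufficient counts: all strata skipped")
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  new_ci_test(x, y, cond, p, stat, "chi_square",
              list(df = df, n_strata_skipped = skipped))
}

discretize_column <- function(v, bins) {
  if (is.function(bins)) return(as.character(bins(v)))
  u <- unique(v)
  if (length(u) <= 5L) return(as.character(v))
  as.character(v > stats::median(v))
}
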