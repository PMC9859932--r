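#' Kaiser-Meyer-Olkin sampling adequacy
#'
#' Computes the overall KMO index and the per-variable measure of sampling
#' adequacy (MSA) from the ratio of squared correlations to squared
#' anti-image partial correlations.  Values near 1 indicate variables well
#' explained by the others; variables with low MSA are poor candidates for a
#' common-factor model.
#'
#' @param m an [expr_matrix()] or numeric matrix.
#' @param variables columns to use (default: all).
#' @param ridge if `TRUE`, add a small ridge (1e-8) to the correlation matrix
#'   when it is singular instead of failing.
#' @return A list with `overall` (scalar KMO) and `msa` (named per-variable
#'   vector).  Degenerate inputs with no correlation at all return `NaN` with
#'   a warning.
#' @export
kmo_msa <- function(m, variables = NULL, ridge = FALSE) {
  m <- as_expr_matrix(m)
  variables <- as.character(variables %||% m$gene_ids)
  if (length(variables) < 3L) stop_("need at least 3 variables")
  X <- m$values[, variables, drop = FALSE]
  R <- stats::cor(X)
  S <- tryCatch(solve(R), error = function(e) {
    if (!ridge) stop_("singular correlation matrix")
    solve(R + diag(1e-8, nrow(R)))
  })
  A <- -S / sqrt(outer(diag(S), diag(S)))   # anti-image partial correlations
  diag(A) <- 0
  R0 <- R; diag(R0) <- 0
  r2 <- R0^2; a2 <- A^2
  denom_all <- sum(r2) + sum(a2)
  overall <- if (denom_all == 0) NaN else sum(r2) / denom_all
  denom_v <- colSums(r2) + colSums(a2)
  msa <- ifelse(denom_v == 0, NaN, colSums(r2) / denom_v)
  names(msa) <- variables
  if (anyNA(c(overall, msa)))
    warning("no correlation among variables; sampling adequacy undefined")
  list(overall = overall, msa = msa)
}

#' Horn's parallel analysis
#'
#' Retains the leading eigenvalues of the observed correlation matrix that
#' exceed the chosen percentile of eigenvalues obtained from data with every
#' column independently permuted (which preserves the marginals but destroys
#' all correlation).
#'
#' @param m an [expr_matrix()] or numeric matrix.
#' @param n_perm number of permuted null matrices.
#' @param percentile null quantile compared against, per eigenvalue rank.
#' @param seed optional seed for the permutations.
#' @return Integer count of retained components, with attributes
#'   `"eigenvalues"` and `"thresholds"`.
#' @export
parallel_analysis <- function(m, n_perm = 100, percentile = 0.95, seed = NULL) {
  m <- as_expr_matrix(m)
  if (n_perm < 1L) stop_("n_perm must be >= 1")
  if (percentile <= 0 || percentile > 1) stop_("percentile must be in (0, 1]")
  X <- m$values
  if (ncol(X) < 2L) stop_("need at least 2 variables")
  ev <- eigen(stats::cor(X), symmetric = TRUE, only.values = TRUE)$values
  null_ev <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      P <- apply(X, 2L, sample)
      eigen(stats::cor(P), symmetric = TRUE, only.values = TRUE)$values
    }, numeric(ncol(X)))
  })
  thr <- apply(null_ev, 1L, stats::quantile, probs = percentile, names = FALSE)
  keep <- ev > thr
  n <- if (keep[1L]) which.min(c(keep, FALSE)) - 1L else 0L
  structure(as.integer(n), eigenvalues = ev, thresholds = thr)
}

# --- minimum-residual factor extraction -------------------------------------

# ULS/minres objective: sum of squared trailing eigenvalues of R - diag(psi)
minres_objective <- function(psi, R, k) {
  ev <- eigen(R - diag(psi, nrow(R)), symmetric = TRUE, only.values = TRUE)$values
  sum(ev[-seq_len(k)]^2)
}

fa_minres <- function(R, k) {
  p <- nrow(R)
  if (k >= p) stop_("n_factors must be smaller than the number of variables")
  smc <- tryCatch(1 - 1 / diag(solve(R)), error = function(e) rep(0.5, p))
  start <- pmin(pmax(1 - smc, 0.05), 0.95)
  fit <- stats::optim(start, minres_objective, R = R, k = k, method = "L-BFGS-B",
                      lower = 1e-3, upper = 1, control = list(maxit = 500))
  psi <- fit$par
  ed <- eigen(R - diag(psi, p), symmetric = TRUE)
  ev <- pmax(ed$values[seq_len(k)], 0)
  L <- ed$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(ev), k)
  # sign convention: largest-magnitude loading of each factor positive
  for (j in seq_len(k)) {
    if (L[which.max(abs(L[, j])), j] < 0) L[, j] <- -L[, j]
  }
  dimnames(L) <- list(rownames(R), paste0("F", seq_len(k)))
  list(loadings = L, converged = fit$convergence == 0)
}

# --- quartimin rotation (oblique gradient-projection) -----------------------

quartimin_vgQ <- function(L) {
  L2 <- L^2
  k <- ncol(L)
  N <- matrix(1, k, k) - diag(k)
  X <- L2 %*% N
  list(f = sum(L2 * X) / 4, Gq = L * X)
}

quartimin_rotate <- function(A, maxit = 1000, eps = 1e-6) {
  k <- ncol(A)
  if (k < 2L) return(list(loadings = A, Phi = diag(k), converged = TRUE))
  Tmat <- diag(k)
  al <- 1
  Ti <- solve(Tmat)
  L <- A %*% t(Ti)
  VgQ <- quartimin_vgQ(L)
  f <- VgQ$f
  G <- -t(t(L) %*% VgQ$Gq %*% Ti)
  converged <- FALSE
  for (iter in seq_len(maxit)) {
    Gp <- G - Tmat %*% diag(colSums(Tmat * G), k)
    s <- sqrt(sum(Gp^2))
    if (s < eps) { converged <- TRUE; break }
    al <- 2 * al
    for (i in seq_len(20)) {
      X <- Tmat - al * Gp
      Tt <- X %*% diag(1 / sqrt(colSums(X^2)), k)
      Ti <- solve(Tt)
      L <- A %*% t(Ti)
      VgQt <- quartimin_vgQ(L)
      if (VgQt$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tmat <- Tt
    f <- VgQt$f
    G <- -t(t(L) %*% VgQt$Gq %*% Ti)
  }
  dimnames(L) <- dimnames(A)
  Phi <- t(Tmat) %*% Tmat
  dimnames(Phi) <- list(colnames(A), colnames(A))
  list(loadings = L, Phi = Phi, converged = converged)
}

#' Fit a common-factor model
#'
#' Minimum-residual extraction (unweighted least squares on the off-diagonal
#' of the correlation matrix) followed by an oblique quartimin rotation —
#' latent biological factors are not assumed orthogonal.  Communalities and
#' uniquenesses come from the unrotated solution (rotation leaves them
#' unchanged) and satisfy `communality + uniqueness = 1` on standardized
#' variables.
#'
#' @param m an [expr_matrix()] or numeric matrix.
#' @param variables columns to model (default: all).
#' @param n_factors number of common factors (>= 1).
#' @param rotation `"quartimin"` or `"none"`.
#' @return An object of class `"factor_model"`: rotated `loadings`, factor
#'   correlation `Phi`, `communality`, `uniqueness`, the variable correlation
#'   matrix `R`, and bookkeeping fields.
#' @export
fit_factor_model <- function(m, variables = NULL, n_factors,
                             rotation = c("quartimin", "none")) {
  rotation <- match.arg(rotation)
  m <- as_expr_matrix(m)
  variables <- as.character(variables %||% m$gene_ids)
  if (n_factors < 1L) stop_("n_factors must be >= 1")
  missing <- setdiff(variables, m$gene_ids)
  if (length(missing)) stop_("variables not in matrix: ", paste(missing, collapse = ", "))
  X <- scale(m$values[, variables, drop = FALSE])
  if (any(!is.finite(X))) stop_("zero-variance variable among 'variables'")
  R <- stats::cor(X)
  ext <- fa_minres(R, n_factors)
  communality <- rowSums(ext$loadings^2)
  rot <- if (rotation == "quartimin") quartimin_rotate(ext$loadings)
         else list(loadings = ext$loadings, Phi = diag(n_factors), converged = TRUE)
  structure(list(variables = variables, n_factors = n_factors,
                 loadings = rot$loadings, Phi = rot$Phi,
                 communality = stats::setNames(communality, variables),
                 uniqueness = stats::setNames(1 - communality, variables),
                 unrotated = ext$loadings, R = R, rotation = rotation,
                 converged = ext$converged && rot$converged),
            class = "factor_model")
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("<factor_model> %d variable(s), %d factor(s), %s rotation\n",
              length(x$variables), x$n_factors, x$rotation))
  invisible(x)
}

#' Iterative factor-analysis workflow
#'
#' The feature-selection loop: variables with MSA below `msa_floor` are
#' removed, the number of factors is set by [parallel_analysis()], a
#' quartimin-rotated minimum-residual model is fitted, and the weakest factor
#' (the one whose largest absolute loading is smallest) is eliminated and the
#' model refitted until every remaining factor carries at least one loading
#' of magnitude `loading_floor`.
#'
#' @inheritParams fit_factor_model
#' @param msa_floor variables with MSA below this are dropped (re-checked on
#'   each iteration when `reapply_msa` is `TRUE`).
#' @param loading_floor smallest admissible maximum absolute loading per
#'   factor.
#' @param n_perm,percentile,seed passed to [parallel_analysis()].
#' @param reapply_msa re-apply the MSA filter whenever the model is refitted.
#' @return A `"factor_model"` with extra fields `msa` and `dropped_variables`.
#' @export
iterative_factor_analysis <- function(m, variables = NULL, msa_floor = 0.6,
                                      loading_floor = 0.5, n_perm = 100,
                                      percentile = 0.95, seed = NULL,
                                      reapply_msa = TRUE) {
  m <- as_expr_matrix(m)
  variables <- sort(as.character(variables %||% m$gene_ids))
  dropped <- character(0)
  filter_msa <- function(vars) {
    adequacy <- kmo_msa(m, vars)
    bad <- names(adequacy$msa)[is.na(adequacy$msa) | adequacy$msa < msa_floor]
    list(vars = setdiff(vars, bad), bad = bad, msa = adequacy$msa)
  }
  flt <- filter_msa(variables)
  dropped <- flt$bad; vars <- flt$vars; msa <- flt$msa
  if (length(vars) < 3L)
    stop_("no interpretable factors: fewer than 3 variables pass the MSA floor")
  k <- as.integer(parallel_analysis(subset_cells(m, genes = vars),
                                    n_perm = n_perm, percentile = percentile,
                                    seed = seed))
  if (k < 1L) stop_("no interpretable factors: parallel analysis retained none")
  k <- min(k, length(vars) - 1L)
  repeat {
    model <- fit_factor_model(m, vars, n_factors = k)
    peak <- apply(abs(model$loadings), 2L, max)
    if (all(peak >= loading_floor)) break
    k <- k - 1L
    if (k < 1L) stop_("no interpretable factors: all factors fell below the loading floor")
    if (reapply_msa) {
      flt <- filter_msa(vars)
      dropped <- union(dropped, flt$bad); vars <- flt$vars; msa <- flt$msa
      if (length(vars) < 3L)
        stop_("no interpretable factors: fewer than 3 variables pass the MSA floor")
    }
  }
  model$msa <- msa[model$variables]
  model$dropped_variables <- dropped
  model
}

#' Select genes by communality
#'
#' Genes whose communality exceeds `floor` are considered to express the
#' essence of the factor model and are kept as network vertices.
#'
#' @param model a `"factor_model"`.
#' @param floor communality threshold.
#' @return A `"selection_report"`: `method`, `selected`, `scores`,
#'   `parameters`.
#' @export
select_by_communality <- function(model, floor = 0.5) {
  stopifnot(inherits(model, "factor_model"))
  sel <- names(model$communality)[model$communality > floor]
  new_selection_report("communality", sort(sel), model$communality,
                       list(floor = floor))
}

new_selection_report <- function(method, selected, scores, parameters) {
  structure(list(method = method, selected = selected, scores = scores,
                 parameters = parameters),
            class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat(sprintf("<selection_report> method=%s: %d of %d gene(s) selected\n",
              x$method, length(x$selected), length(x$scores)))
  invisible(x)
}

#' Write/read a selection report as JSON
#' @param report a `"selection_report"`.
#' @param path file path.
#' @return The path (write) or the report (read), invisibly/visibly.
#' @export
write_selection <- function(report, path) {
  stopifnot(inherits(report, "selection_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_selection
#' @export
read_selection <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_selection_report(x$method, x$selected, unlist(x$scores), x$parameters)
}
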