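#' Rank genes by between-class standard deviation
#'
#' For each gene, the standard deviation of its class-wise mean expression; a
#' cheap screen that keeps genes whose average level differs between classes
#' and discards flat ones before fitting a boosted model.
#'
#' @param m an [expr_matrix()] or numeric matrix.
#' @param labels per-cell class labels (default: `m$class_labels`).
#' @param top_n number of genes to keep (all, ranked, if fewer exist).
#' @return A `"selection_report"` with per-gene scores (SD of group means).
#' @export
groupwise_sd_rank <- function(m, labels = NULL, top_n = 1000) {
  m <- as_expr_matrix(m)
  labels <- as.character(labels %||% m$class_labels %||%
                           stop_("labels are required"))
  if (length(unique(labels)) < 2L) stop_("need at least 2 label groups")
  means <- rowsum(m$values, labels) / as.vector(table(labels)[sort(unique(labels))])
  scores <- apply(means, 2L, stats::sd)
  ord <- order(-scores, m$gene_ids)
  sel <- m$gene_ids[ord][seq_len(min(top_n, length(scores)))]
  new_selection_report("sd_rank", sel, scores[m$gene_ids][ord],
                       list(top_n = top_n))
}

#' Random undersampling to balanced class sizes
#'
#' Downsamples every class without replacement to the size of the smallest
#' class, so the boosted model does not underestimate minor classes.
#'
#' @inheritParams groupwise_sd_rank
#' @param seed optional seed; the same seed reproduces the same cell
#'   selection.
#' @return An [expr_matrix()] restricted to the sampled cells (original cell
#'   order preserved).
#' @export
random_undersample <- function(m, labels = NULL, seed = NULL) {
  m <- as_expr_matrix(m)
  labels <- as.character(labels %||% m$class_labels %||%
                           stop_("labels are required"))
  sizes <- table(labels)
  if (any(sizes == 0)) stop_("every class must be non-empty")
  target <- min(sizes)
  keep <- with_seed(seed, {
    unlist(lapply(sort(unique(labels)), function(cl) {
      idx <- which(labels == cl)
      if (length(idx) == target) idx else sample(idx, target)
    }))
  })
  out <- subset_cells(m, sort(keep))
  if (is.null(out$class_labels))
    out$class_labels <- stats::setNames(labels[sort(keep)], out$cell_ids)
  out
}

# assign whole groups to folds, greedily balancing size, per class
grouped_stratified_folds <- function(labels, groups, n_folds) {
  if (length(labels) != length(groups)) stop_("labels and groups must align")
  n_groups <- length(unique(groups))
  if (n_folds > n_groups)
    stop_("n_folds (", n_folds, ") exceeds group count (", n_groups, ")")
  fold <- integer(length(labels))
  for (cl in sort(unique(labels))) {
    in_cl <- labels == cl
    grp_sizes <- sort(table(groups[in_cl]), decreasing = TRUE)
    load <- stats::setNames(numeric(n_folds), seq_len(n_folds))
    for (g in names(grp_sizes)) {
      f <- as.integer(names(which.min(load)))
      fold[in_cl & groups == g] <- f
      load[f] <- load[f] + grp_sizes[[g]]
    }
  }
  for (f in seq_len(n_folds)) {
    absent <- setdiff(unique(labels), unique(labels[fold == f]))
    if (length(absent))
      stop_("class '", absent[1L], "' absent from fold ", f,
            "; too few groups per class")
  }
  fold
}

#' Gradient-boosting feature-importance selection
#'
#' Fits a multiclass gradient-boosted tree model (with L1/L2 regularization)
#' in a grouped, stratified k-fold scheme — whole groups (subclasses) stay in
#' one fold so the model must rely on features shared across subclasses — and
#' keeps only the genes whose importance is strictly positive in *every*
#' fold.  An optional small hyperparameter grid is scored by mean validation
#' loss before the per-fold importances are extracted.
#'
#' @param m an [expr_matrix()] or numeric matrix.
#' @param labels per-cell class labels (prediction target).
#' @param groups per-cell group (subclass) labels kept intact across folds.
#' @param n_folds number of folds.
#' @param learning_rate,num_leaves,reg_l1,reg_l2,nrounds booster parameters.
#' @param grid optional list of named parameter lists (entries among
#'   `learning_rate`, `num_leaves`, `reg_l1`, `reg_l2`) tried by mean
#'   validation multiclass log-loss.
#' @param seed optional seed.
#' @return A `"selection_report"`; `scores` holds the median cross-fold
#'   importance and `parameters` records folds, grid winner, and per-fold
#'   importances.
#' @export
gbdt_importance_selection <- function(m, labels = NULL, groups = NULL,
                                      n_folds = 5, learning_rate = 0.1,
                                      num_leaves = 31, reg_l1 = 0.1,
                                      reg_l2 = 0.1, nrounds = 60,
                                      grid = NULL, seed = NULL) {
  m <- as_expr_matrix(m)
  labels <- as.character(labels %||% m$class_labels %||%
                           stop_("labels are required"))
  groups <- as.character(groups %||% m$group_labels %||% m$cell_ids)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop_("need at least 2 classes")
  fold <- grouped_stratified_folds(labels, groups, n_folds)
  y <- match(labels, classes) - 1L
  X <- m$values
  params <- list(learning_rate = learning_rate, num_leaves = num_leaves,
                 reg_l1 = reg_l1, reg_l2 = reg_l2)
  if (!is.null(grid)) {
    losses <- vapply(grid, function(g) {
      g <- utils::modifyList(params, g)
      mean(vapply(seq_len(n_folds), function(f)
        xgb_fold(X, y, fold != f, length(classes), g, nrounds, seed)$loss, 0))
    }, 0)
    params <- utils::modifyList(params, grid[[which.min(losses)]])
  }
  fold_imp <- lapply(seq_len(n_folds), function(f)
    xgb_fold(X, y, fold != f, length(classes), params, nrounds, seed)$importance)
  imp_mat <- vapply(fold_imp, function(v) v[m$gene_ids], numeric(ncol(X)))
  rownames(imp_mat) <- m$gene_ids
  selected <- m$gene_ids[apply(imp_mat > 0, 1L, all)]
  med <- apply(imp_mat, 1L, stats::median)
  new_selection_report("gbdt", sort(selected), med[order(-med, names(med))],
                       list(n_folds = n_folds, params = params,
                            fold_importance = imp_mat))
}

xgb_fold <- function(X, y, train, n_class, params, nrounds, seed,
                     early_stopping = 10) {
  if (!is.null(seed)) set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(X[train, , drop = FALSE], label = y[train])
  dtest <- xgboost::xgb.DMatrix(X[!train, , drop = FALSE], label = y[!train])
  booster <- xgboost::xgb.train(
    params = list(objective = "multi:softprob", num_class = n_class,
                  eta = params$learning_rate, max_leaves = params$num_leaves,
                  max_depth = 0, grow_policy = "lossguide",
                  tree_method = "hist", alpha = params$reg_l1,
                  lambda = params$reg_l2, nthread = 1),
    data = dtrain, nrounds = nrounds,
    evals = list(test = dtest), verbose = 0,
    early_stopping_rounds = early_stopping)
  # importance of the model actually selected by validation (best iteration)
  best <- suppressWarnings(as.integer(xgboost::xgb.attr(booster, "best_iteration")))
  scored <- if (length(best) && !is.na(best) &&
                best + 1L < xgboost::xgb.get.num.boosted.rounds(booster))
    xgboost::xgb.slice.Booster(booster, 1L, best + 1L) else booster
  imp <- xgboost::xgb.importance(model = scored)
  scores <- stats::setNames(rep(0, ncol(X)), colnames(X))
  if (nrow(imp)) scores[imp$Feature] <- imp$Gain
  loss <- as.numeric(utils::tail(attr(booster, "evaluation_log")$test_mlogloss, 1L))
  if (!length(loss) || is.na(loss)) {
    pred <- matrix(predict(booster, dtest), ncol = n_class, byrow = TRUE)
    eps <- 1e-12
    loss <- -mean(log(pmax(pred[cbind(seq_len(nrow(pred)), y[!train] + 1L)], eps)))
  }
  list(importance = scores, loss = loss)
}

#' One-versus-rest classification metrics
#'
#' Per-class ROC-AUC and average precision in a one-versus-rest scheme, plus
#' the macro-averaged AUC and the micro-averaged AP (scores of all classes
#' pooled into one binary problem).
#'
#' @param true_labels character vector of true classes.
#' @param scores numeric matrix of per-class scores, one column per class
#'   (column names are the class names).
#' @return A list with `auc`, `ap` (named per-class vectors), `macro_auc`,
#'   `micro_ap`.
#' @export
ovr_metrics <- function(true_labels, scores) {
  true_labels <- as.character(true_labels)
  scores <- as.matrix(scores)
  classes <- colnames(scores)
  if (is.null(classes)) stop_("score columns must be named by class")
  if (length(unique(true_labels)) < 2L) stop_("need at least 2 classes")
  if (!all(unique(true_labels) %in% classes))
    stop_("labels without score columns: ",
          paste(setdiff(unique(true_labels), classes), collapse = ", "))
  auc <- ap <- stats::setNames(numeric(length(classes)), classes)
  for (cl in classes) {
    y <- as.integer(true_labels == cl)
    auc[cl] <- binary_auc(y, scores[, cl])
    ap[cl] <- binary_ap(y, scores[, cl])
  }
  micro_y <- as.integer(as.vector(vapply(classes, function(cl)
    true_labels == cl, logical(length(true_labels)))))
  micro_s <- as.vector(scores[, classes])
  list(auc = auc, ap = ap, macro_auc = mean(auc),
       micro_ap = binary_ap(micro_y, micro_s))
}

binary_auc <- function(y, s) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(s, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

binary_ap <- function(y, s) {
  n1 <- sum(y == 1)
  if (n1 == 0) return(NA_real_)
  ord <- order(-s, y)   # ties: pessimistic (negatives first)
  ys <- y[ord]
  precision <- cumsum(ys) / seq_along(ys)
  sum(precision[ys == 1]) / n1
}
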