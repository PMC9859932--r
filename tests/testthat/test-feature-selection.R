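test_that("the packaged marker panel is complete and well-formed", {
  panel <- marker_panel()
  expect_equal(nrow(panel), 90)
  expect_equal(anyDuplicated(panel[, c("symbol", "category")]), 0)
  expect_length(unique(panel$category), 15)
  # spot-check entries across identities
  expect_setequal(marker_panel("MGE")$symbol,
                  c("LHX6", "LHX8", "MAF", "SST", "ERBB4", "SOX6", "NKX2-1"))
  expect_setequal(marker_panel("endothelial")$symbol, c("IGFBP7", "PECAM1"))
  expect_equal(nrow(marker_panel("NPCs")), 17)
  expect_error(marker_panel("nonsense"), "unknown categories")
})

test_that("KMO/MSA matches an lm-residual partial-correlation oracle", {
  set.seed(31)
  n <- 400
  F1 <- rnorm(n)
  X <- sapply(1:5, function(i) 0.6 * F1 + rnorm(n))
  colnames(X) <- paste0("v", 1:5)
  res <- kmo_msa(X)
  # oracle: partial correlations via regression residuals
  R <- cor(X)
  P <- matrix(0, 5, 5)
  for (i in 1:4) for (j in (i + 1):5) {
    others <- setdiff(1:5, c(i, j))
    rij <- cor(resid(lm(X[, i] ~ X[, others])), resid(lm(X[, j] ~ X[, others])))
    P[i, j] <- P[j, i] <- rij
  }
  R0 <- R; diag(R0) <- 0
  msa_oracle <- colSums(R0^2) / (colSums(R0^2) + colSums(P^2))
  expect_equal(unname(res$msa), unname(msa_oracle), tolerance = 1e-8)
  expect_equal(res$overall, sum(R0^2) / (sum(R0^2) + sum(P^2)), tolerance = 1e-8)
  # equicorrelated variables share one MSA value
  expect_lt(diff(range(res$msa)), 0.05)
})

test_that("KMO degenerate cases", {
  set.seed(32)
  X <- matrix(rnorm(300), 100, 3, dimnames = list(NULL, c("a", "b", "c")))
  X_indep <- diag(3)[rep(1:3, length.out = 99), ] # orthogonal indicators
  colnames(X_indep) <- c("a", "b", "c")
  dup <- cbind(a = X[, 1], b = X[, 1], c = X[, 2])
  expect_error(kmo_msa(dup), "singular")
  expect_silent(kmo_msa(dup, ridge = TRUE))
  expect_error(kmo_msa(X[, 1:2, drop = FALSE], variables = c("a", "b")), "3 variables")
})

test_that("parallel analysis separates noise from block structure", {
  set.seed(33)
  noise <- matrix(rnorm(500 * 50), 500, 50,
                  dimnames = list(NULL, sprintf("n%02d", 1:50)))
  expect_equal(as.integer(parallel_analysis(noise, seed = 1)), 0L)
  blocks <- simulate_factor_blocks(500, c(10, 10), loading = 0.8, seed = 2)
  expect_equal(as.integer(parallel_analysis(blocks, seed = 3)), 2L)
  rank1 <- simulate_factor_blocks(500, 12, loading = 0.9, seed = 4)
  expect_equal(as.integer(parallel_analysis(rank1, seed = 5)), 1L)
})

test_that("parallel analysis retained count is non-increasing in the percentile", {
  set.seed(34)
  m <- simulate_factor_blocks(300, c(8, 8), loading = 0.6, n_noise = 10, seed = 6)
  counts <- sapply(c(0.5, 0.75, 0.95, 0.99), function(q)
    as.integer(parallel_analysis(m, percentile = q, seed = 7)))
  expect_true(all(diff(counts) <= 0))
})

test_that("iterative factor analysis recovers block structure", {
  m <- simulate_factor_blocks(500, c(10, 10), loading = 0.8, seed = 41)
  model <- iterative_factor_analysis(m, seed = 41)
  expect_equal(model$n_factors, 2)
  expect_equal(unname(model$communality + model$uniqueness),
               rep(1, length(model$variables)), tolerance = 1e-6)
  # each block loads on its own factor
  L <- model$loadings
  blk1 <- grepl("^blk1", rownames(L)); blk2 <- grepl("^blk2", rownames(L))
  f1 <- which.max(colSums(abs(L[blk1, , drop = FALSE])))
  f2 <- which.max(colSums(abs(L[blk2, , drop = FALSE])))
  expect_false(f1 == f2)
  expect_true(all(abs(L[blk1, f1]) >= 0.5))
  expect_true(all(abs(L[blk2, f2]) >= 0.5))
  sel <- select_by_communality(model, 0.5)
  expect_setequal(sel$selected, m$gene_ids)
})

test_that("noise genes are filtered out and all-noise input fails", {
  m <- simulate_factor_blocks(500, c(10, 10), loading = 0.8, n_noise = 5, seed = 42)
  model <- iterative_factor_analysis(m, seed = 42)
  sel <- select_by_communality(model, 0.5)
  noise_names <- grep("^noise", m$gene_ids, value = TRUE)
  expect_length(intersect(sel$selected, noise_names), 0)
  pure_noise <- matrix(rnorm(300 * 12), 300, 12,
                       dimnames = list(NULL, sprintf("n%02d", 1:12)))
  expect_error(iterative_factor_analysis(pure_noise, seed = 43),
               "no interpretable factors")
})

test_that("communality selection respects extreme floors", {
  m <- simulate_factor_blocks(400, c(8, 8), loading = 0.8, seed = 44)
  model <- fit_factor_model(m, n_factors = 2)
  expect_length(select_by_communality(model, 1.0)$selected, 0)
  expect_setequal(select_by_communality(model, 0)$selected, model$variables)
})

test_that("factor models agree with maximum-likelihood factanal on clean blocks", {
  m <- simulate_factor_blocks(800, c(6, 6), loading = 0.8, seed = 45)
  mine <- fit_factor_model(m, n_factors = 2, rotation = "none")
  ml <- stats::factanal(m$values, factors = 2, rotation = "none")
  # communalities from two extraction methods agree closely on clean data
  expect_equal(unname(mine$communality), unname(1 - ml$uniquenesses),
               tolerance = 0.05)
})

test_that("group-wise SD ranking favours designed markers", {
  set.seed(51)
  n <- 300
  labels <- rep(c("A", "B", "C"), each = n / 3)
  marker <- ifelse(labels == "A", 5, 0) + rnorm(n)
  X <- cbind(marker = marker, matrix(rnorm(n * 20), n, 20,
                                     dimnames = list(NULL, sprintf("ns%02d", 1:20))))
  rep <- groupwise_sd_rank(X, labels, top_n = 5)
  expect_identical(rep$selected[1], "marker")
  flat <- cbind(X, flat = rep(c(1, 2), length.out = n))  # same mean in all groups
  rep2 <- groupwise_sd_rank(flat, labels, top_n = 100)
  expect_identical(utils::tail(rep2$selected, 1), "flat")
  expect_length(rep2$selected, ncol(flat))
  expect_error(groupwise_sd_rank(X, rep("A", n)), "2 label groups")
})

test_that("random undersampling balances classes reproducibly", {
  set.seed(52)
  labels <- rep(c("A", "B", "C"), times = c(100, 50, 20))
  X <- matrix(rnorm(170 * 3), 170, 3, dimnames = list(NULL, c("a", "b", "c")))
  m <- expr_matrix(X, class_labels = labels)
  u1 <- random_undersample(m, seed = 9)
  expect_equal(unname(table(u1$class_labels)), rep(20L, 3), ignore_attr = TRUE)
  u2 <- random_undersample(m, seed = 9)
  expect_identical(u1$cell_ids, u2$cell_ids)
  mb <- expr_matrix(X[1:40, ], class_labels = rep(c("A", "B"), each = 20))
  ub <- random_undersample(mb, seed = 1)
  expect_setequal(ub$cell_ids, mb$cell_ids)
})

test_that("gbdt selection keeps only genes important in every fold", {
  set.seed(53)
  n <- 600
  cls <- rep(c("A", "B", "C"), each = n / 3)
  sep <- as.numeric(factor(cls)) + rnorm(n, sd = 0.2)
  X <- cbind(sep = sep, matrix(rnorm(n * 30), n, 30,
                               dimnames = list(NULL, sprintf("ns%02d", 1:30))))
  grp <- paste0(cls, rep(1:10, length.out = n))
  rep <- gbdt_importance_selection(X, cls, grp, n_folds = 5, seed = 1)
  expect_true("sep" %in% rep$selected)
  expect_identical(names(rep$scores)[1], "sep")   # top median importance
  imp <- rep$parameters$fold_importance
  expect_true(all(imp["sep", ] > 0))
  expect_error(gbdt_importance_selection(X, cls, rep(c("g1", "g2"), length.out = n),
                                         n_folds = 10),
               "exceeds group count")
})

test_that("pure-noise features are not stably selected", {
  hits <- sapply(1:5, function(s) {
    set.seed(s)
    n <- 300
    cls <- rep(c("A", "B"), each = n / 2)
    X <- matrix(rnorm(n * 100), n, 100,
                dimnames = list(NULL, sprintf("ns%03d", 1:100)))
    grp <- paste0(cls, rep(1:8, length.out = n))
    length(gbdt_importance_selection(X, cls, grp, n_folds = 4, seed = s)$selected)
  })
  # early stopping keeps the selected model tiny on noise: only a handful of
  # the 100 genes survive the all-folds intersection
  expect_true(all(hits < 10))
  expect_lt(mean(hits), 5)
})

test_that("one-versus-rest metrics behave at the extremes and under the null", {
  classes <- c("A", "B", "C")
  set.seed(54)
  lab <- sample(classes, 600, TRUE)
  perfect <- sapply(classes, function(cl) as.numeric(lab == cl))
  m1 <- ovr_metrics(lab, perfect)
  expect_equal(unname(m1$auc), rep(1, 3))
  expect_equal(unname(m1$ap), rep(1, 3))
  expect_equal(m1$micro_ap, 1)
  m2 <- ovr_metrics(lab, -perfect)
  expect_equal(unname(m2$auc), rep(0, 3))
  null_scores <- matrix(runif(600 * 3), 600, 3, dimnames = list(NULL, classes))
  lab_big <- sample(classes, 10000, TRUE)
  null_big <- matrix(runif(10000 * 3), 10000, 3, dimnames = list(NULL, classes))
  expect_lt(abs(ovr_metrics(lab_big, null_big)$macro_auc - 0.5), 0.02)
  expect_error(ovr_metrics(rep("A", 10), perfect[1:10, ]), "2 classes")
})

test_that("auc and ap agree with pROC on a random binary problem", {
  skip_if_not_installed("pROC")
  set.seed(55)
  y <- rbinom(200, 1, 0.4)
  s <- y + rnorm(200)
  mine <- cellcascades:::binary_auc(y, s)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE)))
  expect_equal(mine, ref, tolerance = 1e-10)
})
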