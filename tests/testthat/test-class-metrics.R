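test_that("hamming distance is the symmetric-difference size", {
  a <- cascade_set(list(cascade("x"), cascade("y"), cascade("z"),
                        cascade(c("x", "y"))),
                   universe = c("x", "y", "z"), oriented = FALSE)
  b <- cascade_set(list(cascade("x"), cascade("y"), cascade("z"),
                        cascade(c("y", "z"))),
                   universe = c("x", "y", "z"), oriented = FALSE)
  c0 <- cascade_set(list(cascade("x"), cascade("y"), cascade("z")),
                    universe = c("x", "y", "z"), oriented = FALSE)
  expect_equal(hamming_distance(a, a), 0)
  expect_equal(hamming_distance(a, b), 2)
  expect_equal(hamming_distance(a, c0), 1)
  mismatched <- cascade_set(list(cascade("x")), universe = "x", oriented = FALSE)
  expect_error(hamming_distance(a, mismatched), "universes")
})

test_that("hamming satisfies the pseudo-metric axioms on random sets", {
  set.seed(11)
  genes <- letters[1:6]
  rand_set <- function() to_undirected(
    cascades_from_dependency(random_dep_matrix(genes, 0.4), genes))
  for (i in 1:150) {
    a <- rand_set(); b <- rand_set(); c <- rand_set()
    dab <- hamming_distance(a, b)
    expect_gte(dab, 0)
    expect_identical(dab, hamming_distance(b, a))
    expect_identical(hamming_distance(a, a), 0L)
    expect_lte(dab, hamming_distance(a, c) + hamming_distance(c, b))
  }
})

test_that("d* realizes the asymmetric inclusion measure", {
  a <- cascade_set(list(cascade("x"), cascade("y"), cascade(c("x", "y"))),
                   oriented = FALSE)
  b <- cascade_set(list(cascade("x"), cascade("y")), universe = c("x", "y"),
                   oriented = FALSE)
  expect_equal(d_star(a, a), 0)
  expect_equal(d_star(a, b), 1 / 3)
  expect_equal(d_star(b, a), 0)       # b is a subset of a
  empty <- cascade_set(universe = c("x", "y"), oriented = FALSE)
  expect_error(d_star(empty, b), "denominator")
})

test_that("d* bounds, subset-zero and denominator identity hold on random sets", {
  set.seed(12)
  genes <- letters[1:6]
  for (i in 1:150) {
    a <- to_undirected(cascades_from_dependency(random_dep_matrix(genes, 0.4), genes))
    b <- to_undirected(cascades_from_dependency(random_dep_matrix(genes, 0.4), genes))
    d <- d_star(a, b)
    expect_gte(d, 0); expect_lte(d, 1)
    expect_identical(d == 0, all(a$keys %in% b$keys))
    expect_equal(length(a), length(vertexes(a)) + length(edges(a)))
    expect_equal(d_star(a, cellcascades:::cascade_union(a, b)), 0)
  }
})

make_class <- function(id, ds, keys, universe) {
  cs <- cascade_set(lapply(strsplit(keys, "+", fixed = TRUE), cascade),
                    universe = universe, oriented = FALSE)
  cell_class(id, ds, cs)
}

test_that("compare groups classes into rings and preserves ties", {
  uni <- c("x", "y", "z")
  ref <- make_class("r1", "ref", c("x", "y", "z", "x+y"), uni)
  same <- make_class("q1", "qry", c("x", "y", "z", "x+y"), uni)
  tie_a <- make_class("q2", "qry", c("x", "y", "z", "x+z"), uni)
  tie_b <- make_class("q3", "qry", c("x", "y", "z", "y+z"), uni)
  res <- compare_classes(ref, list(same, tie_a, tie_b), mode = "labeling")
  expect_length(res, 1)
  rings <- res[[1]]$rings
  expect_identical(rings$class_id[rings$value == min(rings$value)], "q1")
  expect_identical(assignment(res[[1]]), structure("q1", value = 0))
  expect_identical(rings$class_id[rings$value == 0.25], c("q2", "q3"))
  # identical eigen sets: single ring at zero
  res0 <- compare_classes(ref, same, mode = "labeling")
  expect_equal(res0[[1]]$rings$value, 0)
})

test_that("compare is invariant to input order and respects vertex subsets", {
  uni <- c("x", "y", "z")
  r <- make_class("r", "ref", c("x", "y", "z", "x+y", "y+z"), uni)
  q1 <- make_class("q1", "qry", c("x", "y", "z", "x+y"), uni)
  q2 <- make_class("q2", "qry", c("x", "y", "z"), uni)
  a <- compare_classes(r, list(q1, q2), mode = "labeling")[[1]]
  b <- compare_classes(r, list(q2, q1), mode = "labeling")[[1]]
  expect_identical(a$rings, b$rings)
  # restricting to {x, y} hides the y-z edge
  res <- compare_classes(r, list(q1), mode = "labeling", vertices = c("x", "y"))
  expect_equal(res[[1]]$rings$value, 0)
  expect_error(compare_classes(r, list(q1), mode = "labeling", vertices = "w"),
               "universe")
})

test_that("inference mode compares within a dataset and skips the center", {
  uni <- c("x", "y")
  c1 <- make_class("k1", "ds", c("x", "y", "x+y"), uni)
  c2 <- make_class("k2", "ds", c("x", "y"), uni)
  res <- compare_classes(list(c1, c2), mode = "inference")
  expect_length(res, 2)
  expect_identical(res[[1]]$rings$class_id, "k2")
  expect_equal(res[[1]]$rings$value, round(1 / 3, 4))   # ring resolution
  expect_equal(res[[2]]$rings$value, 0)   # c2 subset of c1
})

test_that("estimation assigns synthetic queries to their true references", {
  gts <- random_dag_ensemble(3, 6, 0.4, seed = 21)
  refs <- lapply(1:3, function(i)
    cell_class(paste0("ref", i), "ref",
               eigen_cascades(sample_cells(gts[[i]], 1000, seed = 100 + i))))
  qrys <- lapply(1:3, function(i)
    cell_class(paste0("qry", i), "qry",
               eigen_cascades(sample_cells(gts[[i]], 1000, seed = 200 + i))))
  res <- compare_classes(qrys, refs, mode = "estimation")
  for (i in 1:3) expect_identical(unclass(assignment(res[[i]]))[1], paste0("ref", i))
})

test_that("comparisons round-trip through JSON", {
  uni <- c("x", "y", "z")
  r <- make_class("r", "ref", c("x", "y", "z", "x+y"), uni)
  q1 <- make_class("q1", "qry", c("x", "y", "z"), uni)
  q2 <- make_class("q2", "qry", c("x", "y", "z", "x+z"), uni)
  res <- compare_classes(r, list(q1, q2), mode = "labeling")
  path <- withr::local_tempfile(fileext = ".json")
  write_comparison(res, path)
  back <- read_comparison(path)
  expect_equal(back[[1]]$rings, res[[1]]$rings)
  expect_identical(back[[1]]$center, "r")
  expect_identical(back[[1]]$mode, "labeling")
})

test_that("planet plot renders without error", {
  uni <- c("x", "y")
  r <- make_class("r", "ref", c("x", "y", "x+y"), uni)
  q <- make_class("q", "qry", c("x", "y"), uni)
  res <- compare_classes(r, list(q), mode = "labeling")
  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path)
  expect_silent(plot(res[[1]]))
  grDevices::dev.off()
  expect_true(file.exists(path))
})
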