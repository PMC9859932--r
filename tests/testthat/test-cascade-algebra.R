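keyset <- function(cs) sort(cs$keys)

test_that("possessed cascades enumerate the dependency map", {
  # total independence: singletons only
  cs <- cascades_from_dependency(function(x, y) FALSE, c("a", "b"))
  expect_identical(keyset(cs), c("a\t-", "b\t-"))
  # mutual dependence: both orientations present (feedback allowed)
  cs2 <- cascades_from_dependency(function(x, y) TRUE, c("a", "b"))
  expect_identical(keyset(cs2), c("a\t-", "a\tb", "b\t-", "b\ta"))
  # one-sided dependence
  dep <- function(x, y) x == "a" && y == "b"
  cs3 <- cascades_from_dependency(dep, c("a", "b"))
  expect_identical(keyset(cs3), c("a\t-", "a\tb", "b\t-"))
  expect_error(cascades_from_dependency(dep, character(0)), "empty universe")
})

test_that("cascade equality distinguishes the dependent gene", {
  expect_identical(cascade(c("a", "b"), "a"), cascade(c("b", "a"), "a"))
  expect_false(identical(cascade(c("a", "b"), "a"), cascade(c("a", "b"), "b")))
  expect_error(cascade(c("a", "b", "c"), "a"), "1 or 2")
  expect_error(cascade(c("a", "b"), "c"), "member")
  expect_error(cascade(EPSILON), "sentinel")
})

test_that("vertex/edge partition is by cardinality and additive", {
  cs <- cascades_from_dependency(function(x, y) x < y, c("a", "b", "c"))
  expect_identical(keyset(vertexes(cs)), c("a\t-", "b\t-", "c\t-"))
  expect_identical(keyset(edges(cs)), c("a\tb", "a\tc", "b\tc"))
  expect_equal(length(cs), length(vertexes(cs)) + length(edges(cs)))
  empty <- cascade_set(universe = "a")
  expect_equal(length(vertexes(empty)), 0)
  expect_equal(length(edges(empty)), 0)
  # complete possessed sets have one vertex per gene
  for (i in 1:10) {
    cs <- random_possessed_set()
    expect_equal(length(vertexes(cs)), length(cs$universe))
  }
})

test_that("quotient restriction collapses dropped dependents and trims members", {
  dep <- function(x, y) (x == "a" && y == "b") || (x == "b" && y == "h") ||
    (x == "h" && y == "a")
  cs <- cascades_from_dependency(dep, c("a", "b", "h"))
  out <- restrict_quotient(cs, c("a", "b"))
  expect_identical(keyset(out), c("a\t-", "a\tb", "b\t-"))
  expect_identical(out$universe, c("a", "b"))
  # keeping everything changes nothing; keeping nothing empties the set
  expect_true(restrict_quotient(cs, c("a", "b", "h")) == cs)
  expect_equal(length(restrict_quotient(cs, character(0))), 0)
  expect_error(restrict_quotient(cs, "z"), "outside the universe")
})

test_that("quotient and induced restriction agree on possessed sets", {
  set.seed(42)
  for (i in 1:300) {
    cs <- random_possessed_set()
    keep <- sample(cs$universe, sample(0:length(cs$universe), 1))
    expect_true(restrict_quotient(cs, keep) == restrict_induced(cs, keep))
  }
})

test_that("restriction is functorial and commutes with undirected conversion", {
  set.seed(7)
  for (i in 1:50) {
    cs <- random_possessed_set()
    keep1 <- sample(cs$universe, max(2, length(cs$universe) - 2))
    keep2 <- sample(keep1, max(1, length(keep1) - 2))
    two_step <- restrict_induced(restrict_induced(cs, keep1), keep2)
    expect_true(two_step == restrict_induced(cs, keep2))
    lhs <- to_undirected(restrict_induced(cs, keep1))
    rhs <- restrict_induced(to_undirected(cs), keep1)
    expect_true(lhs == rhs)
  }
})

test_that("undirected conversion merges orientations and is idempotent", {
  cs <- cascades_from_dependency(function(x, y) TRUE, c("a", "b"))
  u <- to_undirected(cs)
  expect_identical(keyset(u), c("a", "a\tb", "b"))
  expect_false(u$oriented)
  expect_true(to_undirected(u) == u)
  one_sided <- cascades_from_dependency(function(x, y) x == "a" && y == "b",
                                        c("a", "b"))
  expect_true(to_undirected(one_sided) == u)
})

# exhaustive carrier enumeration for singleton and pair cascades
carriers <- list(list(ctx = cascade("g", "g"), elems = c("g", EPSILON)),
                 list(ctx = cascade(c("g", "o"), "g"), elems = c("g", "o", EPSILON)))

test_that("the per-cascade semiring satisfies all axioms on every carrier", {
  for (cr in carriers) {
    ctx <- cr$ctx; el <- cr$elems
    g <- ctx$dependent
    for (x in el) for (y in el) {
      expect_identical(tropical_add(x, y, ctx), tropical_add(y, x, ctx))
      expect_identical(tropical_mul(x, y, ctx), tropical_mul(y, x, ctx))
      # identities: EPSILON for addition, the dependent gene for multiplication
      expect_identical(tropical_add(x, EPSILON, ctx), x)
      expect_identical(tropical_mul(x, g, ctx), x)
      expect_identical(tropical_mul(x, EPSILON, ctx), EPSILON)
      for (z in el) {
        expect_identical(tropical_add(tropical_add(x, y, ctx), z, ctx),
                         tropical_add(x, tropical_add(y, z, ctx), ctx))
        expect_identical(tropical_mul(tropical_mul(x, y, ctx), z, ctx),
                         tropical_mul(x, tropical_mul(y, z, ctx), ctx))
        expect_identical(
          tropical_mul(x, tropical_add(y, z, ctx), ctx),
          tropical_add(tropical_mul(x, y, ctx), tropical_mul(x, z, ctx), ctx))
      }
    }
    expect_error(tropical_add("q", g, ctx), "carrier")
  }
})

test_that("the coding map is a semiring homomorphism onto {0,1,Inf}", {
  for (cr in carriers) {
    ctx <- cr$ctx
    for (x in cr$elems) for (y in cr$elems) {
      zx <- tropical_code(x, ctx); zy <- tropical_code(y, ctx)
      expect_identical(tropical_code(tropical_add(x, y, ctx), ctx),
                       trop_min(zx, zy))
      expect_identical(tropical_code(tropical_mul(x, y, ctx), ctx),
                       trop_plus(zx, zy))
    }
  }
  ctx <- cascade(c("a", "b"), "a")
  expect_identical(tropical_code("a", ctx), 0)
  expect_identical(tropical_code("b", ctx), 1)
  expect_identical(tropical_code(EPSILON, ctx), Inf)
})

test_that("cascade sets round-trip through text and export to GraphML", {
  set.seed(3)
  for (i in 1:10) {
    cs <- random_possessed_set()
    path <- withr::local_tempfile(fileext = ".cascades")
    write_cascades(cs, path)
    expect_true(read_cascades(path) == cs)
    u <- to_undirected(cs)
    write_cascades(u, path)
    expect_true(read_cascades(path) == u)
  }
  gml <- withr::local_tempfile(fileext = ".graphml")
  cs <- cascades_from_dependency(function(x, y) x < y, c("a", "b", "c"))
  write_graphml(cs, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::V(g)$name, c("a", "b", "c"))
  expect_equal(igraph::ecount(g), 3)
})
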