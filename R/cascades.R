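#' The exogenous-environment sentinel
#'
#' A reserved symbol standing for the latent extracellular environment that is
#' the formal parent of every gene.  It is never stored in a cascade set (its
#' presence is implied by the model) and is only passed around inside the
#' tropical operations attached to a cascade.  Gene symbols may never equal it.
#'
#' @format A length-one character vector.
#' @export
EPSILON <- "<eps>"

check_gene_symbols <- function(symbols) {
  if (!is.character(symbols) || any(is.na(symbols)) || any(!nzchar(symbols)))
    stop_("gene symbols must be non-empty strings")
  if (any(symbols == EPSILON))
    stop_("the sentinel '", EPSILON, "' may not be used as a gene symbol")
  invisible(symbols)
}

#' Construct a single cascade
#'
#' A cascade is an unordered set of one or two genes with one distinguished
#' *dependent* gene: \code{cascade(c("a","b"), "a")} states that \code{a}
#' depends on \code{b}; the singleton \code{cascade("a")} encodes the vertex
#' \code{a}.  Two cascades are equal only when both their member sets and
#' their dependent genes agree.  Unoriented cascades (after conversion of a
#' whole set with [to_undirected()]) carry no dependent gene.
#'
#' @param members character vector of 1 or 2 gene symbols.
#' @param dependent the dependent gene (must be a member), or `NULL` for an
#'   unoriented cascade.
#' @return An object of class `"cascade"` with fields `members` (sorted) and
#'   `dependent`.
#' @examples
#' cascade(c("GAD1", "GRIP1"), dependent = "GAD1")
#' @export
cascade <- function(members, dependent = NULL) {
  members <- sort(unique(as.character(members)))
  check_gene_symbols(members)
  if (!length(members) %in% 1:2)
    stop_("a cascade has 1 or 2 member genes, got ", length(members))
  if (!is.null(dependent)) {
    if (!is_string(dependent) || !dependent %in% members)
      stop_("'dependent' must be one of the member genes")
  }
  structure(list(members = members, dependent = dependent), class = "cascade")
}

#' @export
print.cascade <- function(x, ...) {
  cat(format_cascade(x), "\n")
  invisible(x)
}

format_cascade <- function(x) {
  if (is.null(x$dependent)) paste0("{", paste(x$members, collapse = ","), "}")
  else paste0("{", paste(x$members, collapse = ","), "}_", x$dependent)
}

# canonical string keys -------------------------------------------------------
# oriented:   "dep\tother" with other == "-" for singletons
# unoriented: "g" for singletons, "g1\tg2" (sorted) for edges
cascade_key <- function(x) {
  if (is.null(x$dependent)) paste(x$members, collapse = "\t")
  else {
    other <- setdiff(x$members, x$dependent)
    paste(x$dependent, if (length(other)) other else "-", sep = "\t")
  }
}

key_to_cascade <- function(key, oriented) {
  parts <- strsplit(key, "\t", fixed = TRUE)[[1L]]
  if (oriented) {
    if (parts[2L] == "-") cascade(parts[1L], parts[1L])
    else cascade(parts, dependent = parts[1L])
  } else cascade(parts)
}

key_members <- function(keys) {
  lapply(strsplit(keys, "\t", fixed = TRUE), function(p) sort(setdiff(p, "-")))
}

key_is_singleton <- function(keys, oriented) {
  if (oriented) endsWith(keys, "\t-") else !grepl("\t", keys, fixed = TRUE)
}

#' Construct a cascade set
#'
#' A cascade set holds the possessed cascades of a cell (or the eigen-cascades
#' of a cell class) over a fixed gene universe.  A complete possessed set
#' contains the singleton cascade of every gene in the universe plus one pair
#' cascade per observed dependency.
#'
#' @param cascades a list of [cascade()] objects (may be empty).
#' @param universe character vector of gene symbols; defaults to the union of
#'   all members.
#' @param oriented logical; `FALSE` for sets produced by [to_undirected()].
#' @return An object of class `"cascade_set"`.
#' @export
cascade_set <- function(cascades = list(), universe = NULL, oriented = TRUE) {
  if (inherits(cascades, "cascade")) cascades <- list(cascades)
  members <- unlist(lapply(cascades, `[[`, "members"), use.names = FALSE)
  if (is.null(universe)) universe <- members
  universe <- sort(unique(as.character(universe)))
  if (length(universe)) check_gene_symbols(universe)
  if (!all(members %in% universe))
    stop_("cascade members outside the universe: ",
          paste(setdiff(members, universe), collapse = ", "))
  orient_bad <- vapply(cascades, function(x) is.null(x$dependent) == oriented, TRUE)
  if (any(orient_bad))
    stop_("cascade orientation inconsistent with 'oriented' flag")
  keys <- sort(unique(vapply(cascades, cascade_key, "")))
  if (!oriented) {
    # in an unoriented set the member set alone identifies a cascade
    mem <- vapply(key_members(keys), paste, "", collapse = "\t")
    if (anyDuplicated(mem)) stop_("duplicate member sets in unoriented cascade set")
  }
  new_cascade_set(keys, universe, oriented)
}

new_cascade_set <- function(keys, universe, oriented) {
  structure(list(keys = sort(unique(keys)), universe = universe,
                 oriented = oriented),
            class = "cascade_set")
}

#' @export
print.cascade_set <- function(x, ...) {
  cat(sprintf("<cascade_set> %s, %d gene(s), %d cascade(s): %d vertex, %d edge\n",
              if (x$oriented) "oriented" else "unoriented",
              length(x$universe), length(x$keys),
              length(vertexes(x)$keys), length(edges(x)$keys)))
  invisible(x)
}

#' @export
length.cascade_set <- function(x) length(x$keys)

#' @export
as.list.cascade_set <- function(x, ...) {
  lapply(x$keys, key_to_cascade, oriented = x$oriented)
}

#' @export
`==.cascade_set` <- function(e1, e2) {
  identical(e1$universe, e2$universe) && identical(e1$oriented, e2$oriented) &&
    identical(e1$keys, e2$keys)
}

check_same_frame <- function(a, b) {
  if (!identical(a$universe, b$universe))
    stop_("cascade sets have mismatched gene universes")
  if (!identical(a$oriented, b$oriented))
    stop_("cannot mix oriented and unoriented cascade sets")
  invisible(TRUE)
}

#' Possessed cascades from a dependency oracle
#'
#' Builds the complete possessed-cascade set of one cell from a dependency
#' relation over ordered gene pairs: the pair cascade with dependent `gx` is
#' present exactly when `gx` depends on `gy` (and `gx != gy`); every gene
#' always contributes its singleton cascade.
#'
#' @param dep either a function `dep(gx, gy)` returning `TRUE` when `gx`
#'   depends on `gy`, or a logical matrix with gene dimnames (`dep[gx, gy]`).
#' @param genes non-empty character vector, the gene universe.
#' @return An oriented [cascade_set()].
#' @examples
#' dep <- function(x, y) x == "b" && y == "a"   # b depends on a
#' cascades_from_dependency(dep, c("a", "b"))
#' @export
cascades_from_dependency <- function(dep, genes) {
  genes <- sort(unique(as.character(genes)))
  if (!length(genes)) stop_("empty universe")
  check_gene_symbols(genes)
  lookup <- if (is.matrix(dep)) {
    function(x, y) isTRUE(as.vector(dep[x, y]))
  } else if (is.function(dep)) {
    function(x, y) isTRUE(dep(x, y))
  } else stop_("'dep' must be a function or a logical matrix")
  keys <- paste(genes, "-", sep = "\t")
  for (gx in genes) for (gy in genes) {
    if (gx != gy && lookup(gx, gy)) keys <- c(keys, paste(gx, gy, sep = "\t"))
  }
  new_cascade_set(keys, genes, oriented = TRUE)
}

#' Vertex and edge cascades
#'
#' Partition a cascade set by cardinality: singletons are the vertices of the
#' network and pairs are its edges, so that the set size always equals
#' `length(vertexes(x)) + length(edges(x))`.
#'
#' @param cset a [cascade_set()].
#' @return A [cascade_set()] over the same universe containing only the
#'   singleton (`vertexes`) or pair (`edges`) cascades.
#' @export
vertexes <- function(cset) {
  stopifnot(inherits(cset, "cascade_set"))
  new_cascade_set(cset$keys[key_is_singleton(cset$keys, cset$oriented)],
                  cset$universe, cset$oriented)
}

#' @rdname vertexes
#' @export
edges <- function(cset) {
  stopifnot(inherits(cset, "cascade_set"))
  new_cascade_set(cset$keys[!key_is_singleton(cset$keys, cset$oriented)],
                  cset$universe, cset$oriented)
}

check_restriction <- function(cset, keep) {
  stopifnot(inherits(cset, "cascade_set"))
  keep <- sort(unique(as.character(keep)))
  if (length(keep)) check_gene_symbols(keep)
  if (!all(keep %in% cset$universe))
    stop_("kept genes outside the universe: ",
          paste(setdiff(keep, cset$universe), collapse = ", "))
  keep
}

#' Restrict a cascade set to a gene subset
#'
#' `restrict_induced()` keeps exactly the cascades whose members all lie in
#' `keep` — the induced subgraph of the network.  `restrict_quotient()`
#' realises the same restriction through the quotient construction on the
#' per-cascade tropical semiring: a cascade whose dependent gene is discarded
#' collapses entirely (its whole carrier maps to the exogenous class), while a
#' cascade with a kept dependent merely loses its discarded members.  On
#' complete possessed-cascade sets the two operations agree exactly, which is
#' what licenses treating ignored genes as exogenous factors.
#'
#' @param cset a [cascade_set()]; `restrict_quotient()` requires it oriented.
#' @param keep character vector of genes to keep (a subset of the universe).
#' @return A [cascade_set()] with universe `keep`.
#' @export
restrict_induced <- function(cset, keep) {
  keep <- check_restriction(cset, keep)
  ok <- vapply(key_members(cset$keys), function(m) all(m %in% keep), TRUE)
  new_cascade_set(cset$keys[ok], keep, cset$oriented)
}

#' @rdname restrict_induced
#' @export
restrict_quotient <- function(cset, keep) {
  keep <- check_restriction(cset, keep)
  if (!cset$oriented)
    stop_("restrict_quotient() is defined on oriented cascade sets")
  out <- character(0)
  for (key in cset$keys) {
    parts <- strsplit(key, "\t", fixed = TRUE)[[1L]]
    dep <- parts[1L]; other <- parts[2L]
    if (!dep %in% keep) next                 # whole fiber maps to the exogenous class
    if (other == "-" || !other %in% keep) {
      out <- c(out, paste(dep, "-", sep = "\t"))
    } else {
      out <- c(out, key)
    }
  }
  new_cascade_set(out, keep, oriented = TRUE)
}

#' Forget edge orientation
#'
#' Applies the equivalence identifying the two orientations of a pair cascade,
#' merging them into a single unoriented edge; singletons are unchanged.
#' Idempotent.
#'
#' @param cset a [cascade_set()].
#' @return An unoriented [cascade_set()] over the same universe.
#' @export
to_undirected <- function(cset) {
  stopifnot(inherits(cset, "cascade_set"))
  if (!cset$oriented) return(cset)
  keys <- vapply(key_members(cset$keys), paste, "", collapse = "\t")
  new_cascade_set(keys, cset$universe, oriented = FALSE)
}

cascade_union <- function(a, b) {
  check_same_frame(a, b)
  new_cascade_set(union(a$keys, b$keys), a$universe, a$oriented)
}

cascade_intersect <- function(a, b) {
  check_same_frame(a, b)
  new_cascade_set(intersect(a$keys, b$keys), a$universe, a$oriented)
}
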