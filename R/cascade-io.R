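#' Read and write cascade sets as line-oriented text
#'
#' One cascade per line.  Oriented sets use `dependent<TAB>other` with `-` in
#' place of `other` for singletons; unoriented sets use `gene` for singletons
#' and `gene1<TAB>gene2` for edges.  Two header comment lines record the
#' universe and the orientation flag so that genes without cascades survive a
#' round trip.
#'
#' @param cset a [cascade_set()].
#' @param path file path.
#' @return `write_cascades()` returns `path` invisibly; `read_cascades()`
#'   returns a [cascade_set()].
#' @export
write_cascades <- function(cset, path) {
  stopifnot(inherits(cset, "cascade_set"))
  header <- c(paste0("# universe: ", paste(cset$universe, collapse = ",")),
              paste0("# oriented: ", cset$oriented))
  writeLines(c(header, cset$keys), path)
  invisible(path)
}

#' @rdname write_cascades
#' @export
read_cascades <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  uni_line <- grep("^# universe:", lines, value = TRUE)
  ori_line <- grep("^# oriented:", lines, value = TRUE)
  if (!length(uni_line) || !length(ori_line))
    stop_("not a cascade-set file (missing header): ", path)
  universe <- strsplit(sub("^# universe:\\s*", "", uni_line[1L]), ",", fixed = TRUE)[[1L]]
  universe <- universe[nzchar(universe)]
  oriented <- as.logical(sub("^# oriented:\\s*", "", ori_line[1L]))
  keys <- lines[!hdr & nzchar(lines)]
  bad <- !vapply(strsplit(keys, "\t", fixed = TRUE), length, 0L) %in% 1:2
  if (any(bad)) stop_("malformed cascade line(s): ", paste(which(bad), collapse = ", "))
  cs <- new_cascade_set(keys, sort(unique(universe)), oriented)
  # validate membership through the constructor checks
  cascade_set(as.list(cs), universe = cs$universe, oriented = oriented)
}

#' Convert a cascade set to an igraph graph
#'
#' Vertices are the gene universe; pair cascades become edges.  In an oriented
#' set the edge is drawn from the regulator towards the dependent gene.
#'
#' @param cset a [cascade_set()].
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(cset) {
  stopifnot(inherits(cset, "cascade_set"))
  ekeys <- edges(cset)$keys
  el <- matrix(character(0), ncol = 2)
  if (length(ekeys)) {
    parts <- strsplit(ekeys, "\t", fixed = TRUE)
    if (cset$oriented) {
      # key is "dependent\tother": edge other -> dependent
      el <- t(vapply(parts, function(p) c(p[2L], p[1L]), character(2)))
    } else {
      el <- t(vapply(parts, function(p) p, character(2)))
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = cset$oriented)
  g <- igraph::add_vertices(g, length(cset$universe), name = cset$universe)
  if (nrow(el)) g <- igraph::add_edges(g, t(el))
  g
}

#' @rdname as_igraph
#' @param path output file path.
#' @export
write_graphml <- function(cset, path) {
  igraph::write_graph(as_igraph(cset), path, format = "graphml")
  invisible(path)
}
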