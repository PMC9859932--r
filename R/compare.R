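#' Compare cell classes by eigen-cascade similarity
#'
#' For every *center* class the asymmetric similarity [d_star()] to each
#' *other* class is computed on the eigen-cascade sets restricted to a common
#' vertex subset, and the other classes are grouped onto rings of equal
#' (rounded) value — the data behind a "planet plot".  The innermost ring is
#' the assignment; ties are preserved, never broken arbitrarily.
#'
#' Three modes fix which side of the asymmetric measure is centered:
#' \describe{
#'   \item{inference}{classes of one dataset compared among themselves
#'     (`others` defaults to the remaining centers);}
#'   \item{labeling}{centers are reference classes, others are query classes —
#'     "which query looks most like this reference?";}
#'   \item{estimation}{centers are query classes, others are reference classes
#'     — "which reference name fits this query?".}
#' }
#'
#' @param centers,others lists of [cell_class()] objects (a single object is
#'   accepted).  For `mode = "inference"`, `others` may be omitted.
#' @param mode `"inference"`, `"labeling"` or `"estimation"`.
#' @param vertices optional gene subset used for the comparison; `NULL` uses
#'   every vertex (and then all universes must match).
#' @param digits rounding used to group equal values into rings.
#' @return A list of `"grn_comparison"` objects, one per center, each with
#'   fields `center`, `dataset`, `mode`, `vertices` and `rings` (a data frame
#'   of `value`, `class_id`, `dataset_id` sorted by increasing value).
#' @export
compare_classes <- function(centers, others = NULL,
                            mode = c("inference", "labeling", "estimation"),
                            vertices = NULL, digits = 4) {
  mode <- match.arg(mode)
  centers <- as_class_list(centers)
  if (is.null(others)) {
    if (mode != "inference")
      stop_("'others' is required for mode '", mode, "'")
    others <- centers
  } else others <- as_class_list(others)
  universes <- lapply(c(centers, others), function(cl) cl$eigen$universe)
  if (is.null(vertices)) {
    if (length(unique(vapply(universes, paste, "", collapse = ","))) > 1L)
      stop_("mismatched gene universes; supply a common 'vertices' subset")
  } else {
    vertices <- sort(unique(as.character(vertices)))
    for (u in universes) {
      if (!length(intersect(vertices, u)))
        stop_("vertex subset is disjoint from a class's gene universe")
      if (!all(vertices %in% u))
        stop_("vertex subset contains genes absent from a class's universe: ",
              paste(setdiff(vertices, u), collapse = ", "))
    }
  }
  restrict <- function(cl) {
    if (is.null(vertices)) cl$eigen else restrict_induced(cl$eigen, vertices)
  }
  lapply(centers, function(ctr) {
    a <- restrict(ctr)
    rows <- list()
    for (oth in others) {
      if (identical(oth$class_id, ctr$class_id) &&
          identical(oth$dataset_id, ctr$dataset_id)) next
      d <- round(d_star(a, restrict(oth)), digits)
      rows[[length(rows) + 1L]] <-
        data.frame(value = d, class_id = oth$class_id,
                   dataset_id = oth$dataset_id, stringsAsFactors = FALSE)
    }
    rings <- do.call(rbind, rows)
    if (is.null(rings)) rings <- data.frame(value = numeric(0), class_id = character(0),
                                            dataset_id = character(0))
    rings <- rings[order(rings$value, rings$class_id), , drop = FALSE]
    rownames(rings) <- NULL
    structure(list(center = ctr$class_id, dataset = ctr$dataset_id,
                   mode = mode, vertices = vertices %||% a$universe,
                   rings = rings),
              class = "grn_comparison")
  })
}

as_class_list <- function(x) {
  if (inherits(x, "cell_class")) x <- list(x)
  if (!length(x) || !all(vapply(x, inherits, TRUE, "cell_class")))
    stop_("expected cell_class objects")
  ids <- vapply(x, function(cl) paste(cl$dataset_id, cl$class_id, sep = "/"), "")
  if (anyDuplicated(ids)) stop_("duplicate class ids: ",
                                paste(ids[duplicated(ids)], collapse = ", "))
  x
}

#' @export
print.grn_comparison <- function(x, ...) {
  cat(sprintf("<grn_comparison> mode=%s, center=%s @ %s\n",
              x$mode, x$center, x$dataset))
  for (v in unique(x$rings$value)) {
    sel <- x$rings$value == v
    cat(sprintf("  d* = %-8s %s\n", format(v),
                paste(x$rings$class_id[sel], collapse = ", ")))
  }
  invisible(x)
}

#' Innermost-ring assignment of a comparison
#'
#' @param x a `"grn_comparison"`.
#' @return Character vector of the class ids on the innermost ring (ties are
#'   all reported), with the ring's value as attribute `"value"`.
#' @export
assignment <- function(x) {
  stopifnot(inherits(x, "grn_comparison"))
  if (!nrow(x$rings)) return(character(0))
  v <- min(x$rings$value)
  structure(sort(x$rings$class_id[x$rings$value == v]), value = v)
}

#' Serialize comparisons to JSON
#'
#' @param comparisons a `"grn_comparison"` or list of them.
#' @param path output file.
#' @return `write_comparison()` returns `path` invisibly;
#'   `read_comparison()` returns the list of comparisons.
#' @export
write_comparison <- function(comparisons, path) {
  if (inherits(comparisons, "grn_comparison")) comparisons <- list(comparisons)
  payload <- lapply(comparisons, function(x) {
    list(center = x$center, dataset = x$dataset, mode = x$mode,
         vertices = x$vertices,
         rings = lapply(split(x$rings, x$rings$value), function(r)
           list(value = r$value[1L], classes = r$class_id,
                datasets = r$dataset_id)))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_comparison
#' @export
read_comparison <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(payload, function(x) {
    rings <- do.call(rbind, lapply(x$rings, function(r)
      data.frame(value = as.numeric(r$value),
                 class_id = unlist(r$classes),
                 dataset_id = unlist(r$datasets), stringsAsFactors = FALSE)))
    if (is.null(rings)) rings <- data.frame(value = numeric(0),
                                            class_id = character(0),
                                            dataset_id = character(0))
    rings <- rings[order(rings$value, rings$class_id), , drop = FALSE]
    rownames(rings) <- NULL
    structure(list(center = x$center, dataset = x$dataset, mode = x$mode,
                   vertices = unlist(x$vertices), rings = rings),
              class = "grn_comparison")
  })
}

#' Planet plot of a class comparison
#'
#' Draws the centered class in the middle and every compared class on a circle
#' whose radius is its d* value — classes on the innermost circle are the most
#' similar.
#'
#' @param x a `"grn_comparison"`.
#' @param cex label size.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.grn_comparison <- function(x, cex = 0.8, ...) {
  rings <- x$rings
  rmax <- max(rings$value, 0.1)
  op <- graphics::par(mar = c(1, 1, 3, 1)); on.exit(graphics::par(op))
  graphics::plot(NA, xlim = c(-1.2, 1.2) * rmax, ylim = c(-1.2, 1.2) * rmax,
                 asp = 1, axes = FALSE, xlab = "", ylab = "",
                 main = sprintf("%s (%s) — %s", x$center, x$dataset, x$mode))
  th <- seq(0, 2 * pi, length.out = 200)
  for (v in unique(rings$value)) {
    graphics::lines(v * cos(th), v * sin(th), col = "grey70")
  }
  graphics::points(0, 0, pch = 19, cex = 1.4)
  graphics::text(0, 0, x$center, pos = 3, cex = cex, font = 2)
  if (nrow(rings)) {
    ang <- seq(0, 2 * pi, length.out = nrow(rings) + 1L)[-1L] + pi / 7
    graphics::points(rings$value * cos(ang), rings$value * sin(ang), pch = 21,
                     bg = "steelblue")
    graphics::text(rings$value * cos(ang), rings$value * sin(ang),
                   rings$class_id, pos = 3, cex = cex)
  }
  invisible(x)
}
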