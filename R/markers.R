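#' Curated marker-gene panel
#'
#' The packaged panel of 90 cortical/subpallial marker genes grouped into 15
#' cellular identities (glia, astrocytes, oligodendrocytes, OPCs, microglia,
#' neurons, excitatory neurons, CGE, LGE, MGE, NPCs, NSCs, RBC, endothelial,
#' epithelial), used as candidate variables for the factor-analysis step and
#' as the default vertex subset in labeling.  Symbols are kept exactly as
#' curated, including legacy spellings.
#'
#' @param categories optional character vector restricting to some identities.
#' @return A data frame with columns `symbol` and `category`.
#' @examples
#' nrow(marker_panel())          # 90
#' marker_panel("MGE")$symbol
#' @export
marker_panel <- function(categories = NULL) {
  path <- system.file("extdata", "marker_panel.tsv", package = "cellcascades",
                      mustWork = TRUE)
  panel <- utils::read.delim(path, colClasses = "character")
  if (!is.null(categories)) {
    bad <- setdiff(categories, unique(panel$category))
    if (length(bad)) stop_("unknown categories: ", paste(bad, collapse = ", "))
    panel <- panel[panel$category %in% categories, , drop = FALSE]
    rownames(panel) <- NULL
  }
  panel
}
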