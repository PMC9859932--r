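`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop_ <- function(...) stop(..., call. = FALSE)

#' Derive a reproducible child seed
#'
#' Deterministically maps a user seed and an offset to a new seed in the
#' 32-bit integer range, so that independent simulation arms of one study can
#' be seeded from a single master seed.
#'
#' @param seed master seed (integer).
#' @param offset integer offset distinguishing the arm.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, offset = 0L) {
  as.integer((as.numeric(seed) * 10007 + offset) %% (.Machine$integer.max - 1L)) + 1L
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

is_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x) && nzchar(x)
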