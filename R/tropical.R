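#' Tropical semiring attached to a cascade
#'
#' Every cascade `l` with dependent gene `g` carries a commutative semiring on
#' the carrier `members(l) U {EPSILON}`: addition behaves like a minimum with
#' respect to the order `g < other member < EPSILON` and multiplication is a
#' truncated accumulation with `g` neutral and `EPSILON` absorbing.  The coding
#' map [tropical_code()] sends this semiring homomorphically onto the numeric
#' tropical semiring `({0, 1, Inf}, min, truncated +)` — see [trop_min()] and
#' [trop_plus()].
#'
#' @param x,y a member gene of `ctx` or [EPSILON].
#' @param ctx the [cascade()] whose semiring is used.
#' @return `tropical_add`/`tropical_mul`: a member gene or [EPSILON];
#'   `tropical_code`: one of `0`, `1`, `Inf`.
#' @examples
#' ab <- cascade(c("a", "b"), dependent = "a")
#' tropical_add("a", "b", ab)     # "a"
#' tropical_mul("b", "b", ab)     # the sentinel
#' tropical_code("b", ab)         # 1
#' @export
tropical_add <- function(x, y, ctx) {
  check_carrier(c(x, y), ctx)
  g <- ctx$dependent
  if (x == g || y == EPSILON || x == y) return(x)
  y  # y == g or x == EPSILON
}

#' @rdname tropical_add
#' @export
tropical_mul <- function(x, y, ctx) {
  check_carrier(c(x, y), ctx)
  g <- ctx$dependent
  if (y == g) return(x)
  if (x == g) return(y)
  EPSILON
}

#' @rdname tropical_add
#' @export
tropical_code <- function(x, ctx) {
  check_carrier(x, ctx)
  if (x == ctx$dependent) 0 else if (x == EPSILON) Inf else 1
}

check_carrier <- function(xs, ctx) {
  if (!inherits(ctx, "cascade") || is.null(ctx$dependent))
    stop_("'ctx' must be an oriented cascade")
  bad <- setdiff(xs, c(ctx$members, EPSILON))
  if (length(bad))
    stop_("value(s) outside the cascade's carrier: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Numeric tropical operations
#'
#' The target semiring of [tropical_code()]: `trop_min` is ordinary `min` on
#' `{0, 1, Inf}` and `trop_plus` is addition truncated above `1` (so
#' `1 + 1 = Inf`), with `0` neutral and `Inf` absorbing.
#'
#' @param a,b numbers in `{0, 1, Inf}`.
#' @return A number in `{0, 1, Inf}`.
#' @export
trop_min <- function(a, b) {
  check_tropical(c(a, b))
  min(a, b)
}

#' @rdname trop_min
#' @export
trop_plus <- function(a, b) {
  check_tropical(c(a, b))
  s <- a + b
  if (s > 1) Inf else s
}

check_tropical <- function(x) {
  if (!all(x %in% c(0, 1, Inf)))
    stop_("tropical values must be 0, 1 or Inf")
  invisible(TRUE)
}
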