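#' Pooling level sets for MSP and SPP heads
#'
#' A pooling level divides a feature map into `a` vertical times `b`
#' horizontal regions. A multilevel head stacks several such levels and
#' concatenates their outputs. Strip pooling uses elongated levels
#' (`b = 1` in horizontal mode: each strip spans the full map width);
#' pyramid pooling uses square levels (`b = a`).
#'
#' `msp_levels(c(1, 2, 3))` builds the horizontal strip levels
#' `1x1, 2x1, 3x1`; `spp_levels(c(1, 2, 3))` builds the square pyramid
#' levels `1x1, 2x2, 3x3`.
#'
#' @param a Integer vector of division counts along the height.
#' @param mode For `msp_levels()`: `"horizontal"` (strips span the width,
#'   divisions along the height), `"vertical"` (the transpose), or
#'   `"both"` (the union of horizontal and vertical levels).
#' @return A `pool_levels` object: a tibble with one row per level and
#'   integer columns `a` (vertical divisions) and `b` (horizontal
#'   divisions), carrying the mode as an attribute.
#' @examples
#' msp_levels(1:3)      # 1x1, 2x1, 3x1 -> 6 strips per map
#' spp_levels(1:3)      # 1x1, 2x2, 3x3 -> 14 bins per map
#' @name pool_levels
NULL

new_pool_levels <- function(a, b, mode) {
  lv <- tibble::tibble(a = as.integer(a), b = as.integer(b))
  if (nrow(lv) < 1L) {
    rlang::abort("at least one pooling level is required")
  }
  if (any(lv$a < 1L) || any(lv$b < 1L)) {
    rlang::abort("pooling level divisions must be positive integers")
  }
  if (anyDuplicated(lv)) {
    rlang::abort("pooling levels must be distinct")
  }
  structure(lv, class = c("pool_levels", class(lv)), mode = mode)
}

#' @rdname pool_levels
#' @export
msp_levels <- function(a, mode = c("horizontal", "vertical", "both")) {
  mode <- match.arg(mode)
  a <- check_divisions(a)
  switch(mode,
    horizontal = new_pool_levels(a, rep(1L, length(a)), mode),
    vertical   = new_pool_levels(rep(1L, length(a)), a, mode),
    both       = new_pool_levels(
      c(a, rep(1L, length(a))), c(rep(1L, length(a)), a), mode
    )
  )
}

#' @rdname pool_levels
#' @export
spp_levels <- function(a) {
  a <- check_divisions(a)
  new_pool_levels(a, a, "square")
}

check_divisions <- function(a) {
  if (length(a) < 1L || any(!is.finite(a)) || any(a < 1) || any(a != floor(a))) {
    rlang::abort("`a` must be a vector of positive integers")
  }
  as.integer(a)
}

#' @export
print.pool_levels <- function(x, ...) {
  kind <- if (identical(attr(x, "mode"), "square")) "SPP" else "MSP"
  cat(sprintf(
    "<pool_levels> %s, %d level(s) [%s], %d regions per map\n",
    kind, nrow(x),
    paste(sprintf("%dx%d", x$a, x$b), collapse = ", "),
    sum(x$a * x$b)
  ))
  invisible(x)
}

#' Fixed output length of a multilevel pooling head
#'
#' The concatenated pooling output has length `k * sum(a_n * b_n)` over the
#' levels, independent of the feature-map size — for square SPP levels this
#' is `k * sum(a_n^2)`. This is the closed form of the pooled-vector length
#' and always equals `length()` of [msp_forward()] / [spp_forward()] output.
#'
#' @param levels A [pool_levels] object.
#' @param k Number of feature maps (filters of the last conv layer).
#' @return Integer output length.
#' @examples
#' output_length(msp_levels(1:3))        # 6
#' output_length(spp_levels(c(1, 2, 3))) # 14
#' output_length(msp_levels(2:4))        # 9
#' @export
output_length <- function(levels, k = 1L) {
  stopifnot(inherits(levels, "pool_levels"))
  if (length(k) != 1L || !is.finite(k) || k < 1 || k != floor(k)) {
    rlang::abort("`k` must be a single positive integer")
  }
  as.integer(k) * sum(levels$a * levels$b)
}
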