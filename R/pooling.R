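#' Pool one feature map with one level
#'
#' Divides an `m_h x m_w` map into `a x b` windows (adaptive kernel and
#' stride, see [compute_kernel_stride()]) and reduces each window to a
#' single value. Entry `(i, j)` of the result is the reduction of window
#' row-block `i`, column-block `j`; entries are returned in row-major
#' order (`i` outer, `j` inner).
#'
#' @param map Numeric matrix (one feature map).
#' @param a,b Divisions along height and width.
#' @param reduce `"mean"` (strip-pooling convention) or `"max"`
#'   (pyramid-pooling convention).
#' @param method Window-geometry convention, see [pool_windows()].
#' @return Numeric vector of length `a * b`.
#' @examples
#' strip_pool(matrix(1:8, 2, 4, byrow = TRUE), a = 2, b = 1) # c(2.5, 6.5)
#' strip_pool(matrix(1:8, 2, 4, byrow = TRUE), a = 1, b = 1) # 4.5
#' @export
strip_pool <- function(map, a, b = 1L, reduce = c("mean", "max"),
                       method = c("msp", "spp")) {
  reduce <- match.arg(reduce)
  method <- match.arg(method)
  if (!is.matrix(map) || length(map) == 0L) {
    rlang::abort("`map` must be a non-empty numeric matrix")
  }
  if (any(!is.finite(map))) {
    rlang::abort("`map` must contain only finite values")
  }
  win <- pool_windows(nrow(map), ncol(map), a, b, method)
  f <- if (reduce == "mean") mean else max
  vapply(seq_len(nrow(win)), function(r) {
    f(map[win$row_start[r]:win$row_end[r], win$col_start[r]:win$col_end[r]])
  }, numeric(1))
}

check_stack <- function(stack) {
  if (is.matrix(stack)) {
    stack <- array(stack, dim = c(dim(stack), 1L))
  }
  if (!is.array(stack) || length(dim(stack)) != 3L || any(dim(stack) < 1L)) {
    rlang::abort("`stack` must be an m_h x m_w x k numeric array (or a matrix for k = 1)")
  }
  if (any(!is.finite(stack))) {
    rlang::abort("`stack` must contain only finite values")
  }
  stack
}

# Window spans of every level on one map size, as plain integer matrices
# (hot path: called once per image during training).
level_spans <- function(m_h, m_w, levels, method) {
  lapply(seq_len(nrow(levels)), function(n) {
    list(rows = axis_windows(m_h, levels$a[n], method),
         cols = axis_windows(m_w, levels$b[n], method))
  })
}

pool_forward <- function(stack, levels, reduce, method) {
  stack <- check_stack(stack)
  dims <- dim(stack)
  k <- dims[3]
  spans <- level_spans(dims[1], dims[2], levels, method)
  f <- if (reduce == "mean") mean else max
  # concatenation order: maps outer, levels inner, windows row-major --
  # a fixed permutation of the head's input, documented here once.
  out <- numeric(k * sum(levels$a * levels$b))
  pos <- 0L
  for (ch in seq_len(k)) {
    sl <- stack[, , ch]
    if (is.null(dim(sl))) sl <- matrix(sl, dims[1], dims[2])
    for (sp in spans) {
      for (i in seq_len(nrow(sp$rows))) {
        for (j in seq_len(nrow(sp$cols))) {
          pos <- pos + 1L
          out[pos] <- f(sl[sp$rows[i, 1]:sp$rows[i, 2],
                           sp$cols[j, 1]:sp$cols[j, 2]])
        }
      }
    }
  }
  out
}

#' Multilevel strip pooling forward pass
#'
#' Applies every level of a strip-pooling head to every map of a feature
#' stack and concatenates the results into one fixed-length vector of
#' length `k * sum(a_n * b_n)` — independent of the map size, which is
#' what lets a convolutional classifier accept arbitrary-size inputs.
#' Windows are averaged (adaptive average pooling); in the default
#' horizontal mode each strip spans the full map width.
#'
#' @param stack `m_h x m_w x k` numeric array of feature maps (a plain
#'   matrix is treated as `k = 1`).
#' @param levels A [pool_levels] object from [msp_levels()].
#' @param reduce Window reduction, `"mean"` by default.
#' @return Numeric vector of length `output_length(levels, k)`.
#' @examples
#' msp_forward(matrix(rnorm(64), 8, 8), msp_levels(1:3)) # length 6
#' @export
msp_forward <- function(stack, levels, reduce = c("mean", "max")) {
  stopifnot(inherits(levels, "pool_levels"))
  reduce <- match.arg(reduce)
  pool_forward(stack, levels, reduce, "msp")
}

#' Spatial pyramid pooling forward pass
#'
#' Square-window counterpart of [msp_forward()]: every level pools with an
#' `a_n x a_n` grid of windows of extent `ceiling(m / a_n)` and stride
#' `floor(m / a_n)` in each dimension, reduced by max (the original
#' pyramid-pooling convention; mean is available). Output length is
#' `k * sum(a_n^2)`.
#'
#' @param stack `m_h x m_w x k` numeric array (matrix for `k = 1`).
#' @param levels A [pool_levels] object from [spp_levels()].
#' @param reduce Window reduction, `"max"` by default.
#' @return Numeric vector of length `output_length(levels, k)`.
#' @examples
#' spp_forward(matrix(rnorm(64), 8, 8), spp_levels(1:3)) # length 14
#' @export
spp_forward <- function(stack, levels, reduce = c("max", "mean")) {
  stopifnot(inherits(levels, "pool_levels"))
  reduce <- match.arg(reduce)
  pool_forward(stack, levels, reduce, "spp")
}

# Gradient of mean-pooling heads: routes d(out)/d(stack) back through the
# window means. Only the "mean" reducer is differentiated -- the trainable
# heads use it; max-pooling heads reuse the window argmax instead.
pool_backward_mean <- function(dvec, dims, levels, method) {
  dx <- array(0, dim = dims)
  k <- dims[3]
  pos <- 0L
  for (ch in seq_len(k)) {
    for (n in seq_len(nrow(levels))) {
      win <- pool_windows(dims[1], dims[2], levels$a[n], levels$b[n], method)
      for (r in seq_len(nrow(win))) {
        rs <- win$row_start[r]:win$row_end[r]
        cs <- win$col_start[r]:win$col_end[r]
        pos <- pos + 1L
        dx[rs, cs, ch] <- dx[rs, cs, ch] +
          dvec[pos] / (length(rs) * length(cs))
      }
    }
  }
  dx
}
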