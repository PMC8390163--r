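#' Adaptive pooling kernel and stride for one level
#'
#' For a feature map of size `m_h x m_w` and a pooling level of `a x b`
#' divisions, the adaptive-average-pooling window and stride are
#' `s_h = floor(m_h / a)`, `k_h = m_h - (a - 1) * s_h` (and the same along
#' the width with `b`). With these choices the `a` windows tile the height
#' exactly: `(a - 1) * s_h + k_h = m_h`, the last window flush with the
#' edge. Requires `a <= m_h` and `b <= m_w`; smaller maps take the
#' index-rule fallback used by [pool_windows()].
#'
#' @param m_h,m_w Feature-map height and width (positive integers).
#' @param a,b Divisions along height and width (positive integers).
#' @return A one-row tibble with columns `s_h`, `k_h`, `s_w`, `k_w`.
#' @examples
#' compute_kernel_stride(6, 8, a = 3, b = 1)   # s_h 2, k_h 2, full-width window
#' compute_kernel_stride(7, 10, a = 3, b = 1)  # s_h 2, k_h 3
#' @export
compute_kernel_stride <- function(m_h, m_w, a, b = 1L) {
  check_map_dims(m_h, m_w)
  a <- check_divisions(a)
  b <- check_divisions(b)
  stopifnot(length(a) == 1L, length(b) == 1L)
  if (a > m_h || b > m_w) {
    rlang::abort(sprintf(
      "level %dx%d exceeds map %dx%d; use pool_windows() for the index-rule fallback",
      a, b, m_h, m_w
    ))
  }
  s_h <- m_h %/% a
  s_w <- m_w %/% b
  tibble::tibble(
    s_h = s_h, k_h = m_h - (a - 1L) * s_h,
    s_w = s_w, k_w = m_w - (b - 1L) * s_w
  )
}

check_map_dims <- function(m_h, m_w) {
  if (length(m_h) != 1L || length(m_w) != 1L ||
      !is.finite(m_h) || !is.finite(m_w) || m_h < 1 || m_w < 1 ||
      m_h != floor(m_h) || m_w != floor(m_w)) {
    rlang::abort("map dimensions must be positive integers")
  }
}

# Window start/end indices (1-based, inclusive) along one axis of extent m
# for `a` divisions.
#
# method "msp": stride floor(m/a), kernel m - (a-1)*stride (exact tiling).
# method "spp": kernel ceiling(m/a), stride floor(m/a), the original
#   pyramid-pooling convention; windows may overlap, the last is clipped
#   to the edge.
# Fallback when the floor stride is 0 (a > m): index-rule adaptive pooling,
#   window i spanning [floor(i*m/a), ceiling((i+1)*m/a)) in 0-based terms,
#   which duplicates cells gracefully and preserves the output length.
axis_windows <- function(m, a, method = c("msp", "spp")) {
  method <- match.arg(method)
  s <- m %/% a
  if (s == 0L) {
    i <- seq_len(a) - 1L
    start <- floor(i * m / a) + 1L
    end <- ceiling((i + 1L) * m / a)
    return(cbind(start = as.integer(start), end = as.integer(end)))
  }
  if (method == "msp") {
    k <- m - (a - 1L) * s
    start <- (seq_len(a) - 1L) * s + 1L
    end <- start + k - 1L
  } else {
    k <- as.integer(ceiling(m / a))
    start <- (seq_len(a) - 1L) * s + 1L
    end <- pmin(start + k - 1L, m)
  }
  cbind(start = as.integer(start), end = as.integer(end))
}

#' Window spans of one pooling level on a given map size
#'
#' Enumerates the rectangular windows that one `a x b` level lays over an
#' `m_h x m_w` map, in row-major order (row index outer, column index
#' inner). Degenerate maps smaller than the division count fall back to
#' index-rule adaptive windows so the output count stays `a * b`.
#'
#' @inheritParams compute_kernel_stride
#' @param method `"msp"` (exact-tiling stride/kernel) or
#'   `"spp"` (ceiling kernel, floor stride).
#' @return Tibble with one row per window: `i`, `j` (division indices),
#'   `row_start`, `row_end`, `col_start`, `col_end` (1-based inclusive).
#' @export
pool_windows <- function(m_h, m_w, a, b = 1L, method = c("msp", "spp")) {
  method <- match.arg(method)
  check_map_dims(m_h, m_w)
  rows <- axis_windows(as.integer(m_h), as.integer(a), method)
  cols <- axis_windows(as.integer(m_w), as.integer(b), method)
  grid <- expand.grid(j = seq_len(nrow(cols)), i = seq_len(nrow(rows)))
  tibble::tibble(
    i = grid$i, j = grid$j,
    row_start = unname(rows[grid$i, "start"]),
    row_end = unname(rows[grid$i, "end"]),
    col_start = unname(cols[grid$j, "start"]),
    col_end = unname(cols[grid$j, "end"])
  )
}

#' Tiling report for a multilevel pooling head
#'
#' Summarises, per level, the kernel/stride geometry a head would use on a
#' feature map of the given size, plus the running output count — the
#' arithmetic behind head-configuration tables such as MSP-123 = 6 strips
#' or SPP-123 = 14 bins.
#'
#' @param levels A [pool_levels] object.
#' @param m_h,m_w Feature-map size the geometry is evaluated on.
#' @param k Number of feature maps.
#' @return Tibble with one row per level: `a`, `b`, `s_h`, `k_h`, `s_w`,
#'   `k_w` (NA where the index-rule fallback applies), `regions`
#'   (`a * b`), and attribute-free column `total` giving `k * sum(a*b)` on
#'   every row.
#' @examples
#' pool_geometry(msp_levels(1:3), 8, 8)
#' @export
pool_geometry <- function(levels, m_h, m_w, k = 1L) {
  stopifnot(inherits(levels, "pool_levels"))
  check_map_dims(m_h, m_w)
  method <- if (identical(attr(levels, "mode"), "square")) "spp" else "msp"
  geo <- purrr::pmap_dfr(levels, function(a, b) {
    if (a <= m_h && b <= m_w && method == "msp") {
      ks <- compute_kernel_stride(m_h, m_w, a, b)
    } else if (a <= m_h && b <= m_w) {
      ks <- tibble::tibble(
        s_h = m_h %/% a, k_h = as.integer(ceiling(m_h / a)),
        s_w = m_w %/% b, k_w = as.integer(ceiling(m_w / b))
      )
    } else {
      ks <- tibble::tibble(
        s_h = NA_integer_, k_h = NA_integer_,
        s_w = NA_integer_, k_w = NA_integer_
      )
    }
    dplyr::bind_cols(tibble::tibble(a = a, b = b), ks,
                     tibble::tibble(regions = a * b))
  })
  geo$total <- output_length(levels, k)
  geo
}
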