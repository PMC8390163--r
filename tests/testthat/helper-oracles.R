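# Independent naive oracles, written against the pooling definitions
# directly (explicit double loops, no package internals), plus small
# fixture builders shared across tests.

# Window start indices along one axis: stride floor(m/a), kernel
# m - (a-1)*stride for the strip convention; kernel ceiling(m/a), stride
# floor(m/a), clipped at the edge, for the pyramid convention. When
# floor(m/a) = 0 both fall back to index-rule windows
# [floor(i*m/a), ceiling((i+1)*m/a)).
naive_windows <- function(m, a, method) {
  s <- floor(m / a)
  out <- vector("list", a)
  if (s == 0) {
    for (i in seq_len(a)) {
      out[[i]] <- (floor((i - 1) * m / a) + 1):ceiling(i * m / a)
    }
    return(out)
  }
  k <- if (method == "msp") m - (a - 1) * s else ceiling(m / a)
  for (i in seq_len(a)) {
    start <- (i - 1) * s + 1
    out[[i]] <- start:min(start + k - 1, m)
  }
  out
}

# Naive multilevel pooling: maps outer, levels inner, windows row-major.
naive_multipool <- function(stack, a_vec, b_vec, reduce, method) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1))
  out <- numeric(0)
  for (ch in seq_len(dim(stack)[3])) {
    map <- stack[, , ch]
    if (is.null(dim(map))) map <- matrix(map, dim(stack)[1], dim(stack)[2])
    for (n in seq_along(a_vec)) {
      rws <- naive_windows(nrow(map), a_vec[n], method)
      cws <- naive_windows(ncol(map), b_vec[n], method)
      for (rw in rws) {
        for (cw in cws) {
          vals <- numeric(0)
          for (r in rw) for (cc in cw) vals <- c(vals, map[r, cc])
          out <- c(out, if (reduce == "mean") mean(vals) else max(vals))
        }
      }
    }
  }
  out
}

# The eight head configurations of the level-selection experiment.
table2_configs <- function() {
  list(
    `MSP-123`  = list(kind = "msp", a = c(1, 2, 3), total = 6),
    `MSP-124`  = list(kind = "msp", a = c(1, 2, 4), total = 7),
    `MSP-234`  = list(kind = "msp", a = c(2, 3, 4), total = 9),
    `MSP-1234` = list(kind = "msp", a = 1:4, total = 10),
    `SPP-123`  = list(kind = "spp", a = c(1, 2, 3), total = 14),
    `SPP-124`  = list(kind = "spp", a = c(1, 2, 4), total = 21),
    `SPP-234`  = list(kind = "spp", a = c(2, 3, 4), total = 29),
    `SPP-1234` = list(kind = "spp", a = 1:4, total = 30)
  )
}

make_levels <- function(cfg) {
  if (cfg$kind == "msp") msp_levels(cfg$a) else spp_levels(cfg$a)
}

# Balanced in-memory synthetic set: n_per_class images per class.
make_synth_set <- function(n_per_class, config, seed0) {
  images <- list()
  labels <- character(0)
  for (ci in seq_along(plaque_classes())) {
    cl <- plaque_classes()[ci]
    for (i in seq_len(n_per_class)) {
      images[[length(images) + 1]] <-
        generate_plaque(cl, config, seed0 + 1000 * (ci - 1) + i)
      labels <- c(labels, cl)
    }
  }
  names(images) <- sprintf("im%03d", seq_along(images))
  list(images = images, labels = labels)
}

# Small-ROI generator config for fast training unit tests (the full
# clinical size range is exercised in the acceptance tests).
small_roi_config <- function(lambda = 1) {
  synthetic_config(h_range = c(16, 28), w_range = c(24, 56), lambda = lambda)
}
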