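#' VGG-style backbone specification
#'
#' The feature extractor is a stack of convolution blocks in the VGG
#' idiom: each block holds one or more 3x3 convolutions (stride 1,
#' padding 1, ReLU) and blocks are separated by 2x2 max-pooling with
#' stride 2, so spatial size is preserved inside a block and floor-halved
#' between blocks. Because convolutions and pooling slide over whatever
#' extent they are given, the backbone accepts images of arbitrary size
#' and emits feature maps of arbitrary size; the pooling head then fixes
#' the length.
#'
#' Two presets are provided. `"vgg16"` is the full fidelity layout: the
#' five VGG16 blocks (64, 128, 256, 512, 512 filters) with the pool after
#' the last block removed, i.e. 4 pools and k = 512 feature maps.
#' `"tiny"` is a 2-block (8/16 filter) layout with the final pool kept
#' (2 pools), small enough to train on a CPU in minutes; it is the
#' default throughout the examples and tests.
#'
#' @param preset `"tiny"` or `"vgg16"`, ignored when `blocks` is given.
#' @param blocks Custom layout: list of `c(n_conv, filters)` pairs.
#' @param include_final_pool Keep the max-pool after the last block?
#' @return A `backbone_spec` list with `blocks`, `include_final_pool`,
#'   `n_pools`, `min_input` (= `2^n_pools`) and `k` (last block's filters).
#' @export
backbone_spec <- function(preset = c("tiny", "vgg16"), blocks = NULL,
                          include_final_pool = NULL) {
  if (is.null(blocks)) {
    preset <- match.arg(preset)
    if (preset == "tiny") {
      blocks <- list(c(1L, 8L), c(1L, 16L))
      if (is.null(include_final_pool)) include_final_pool <- TRUE
    } else {
      blocks <- list(c(2L, 64L), c(2L, 128L), c(3L, 256L),
                     c(3L, 512L), c(3L, 512L))
      if (is.null(include_final_pool)) include_final_pool <- FALSE
    }
  } else {
    if (is.null(include_final_pool)) include_final_pool <- FALSE
  }
  blocks <- lapply(blocks, function(bl) {
    bl <- as.integer(bl)
    if (length(bl) != 2L || any(bl < 1L)) {
      rlang::abort("each block must be c(n_conv, filters) with positive entries")
    }
    bl
  })
  n_pools <- length(blocks) - 1L + as.integer(isTRUE(include_final_pool))
  structure(
    list(
      blocks = blocks,
      include_final_pool = isTRUE(include_final_pool),
      n_pools = n_pools,
      min_input = 2L^n_pools,
      k = blocks[[length(blocks)]][2]
    ),
    class = "backbone_spec"
  )
}

#' @export
print.backbone_spec <- function(x, ...) {
  cat(sprintf(
    "<backbone_spec> %d block(s): %s; %d pool(s), min input %dx%d, k = %d\n",
    length(x$blocks),
    paste(vapply(x$blocks, function(b) sprintf("%dx conv(%d)", b[1], b[2]),
                 character(1)), collapse = " | "),
    x$n_pools, x$min_input, x$min_input, x$k
  ))
  invisible(x)
}

#' Feature-map size produced by a backbone
#'
#' Convolutions preserve spatial size (3x3, stride 1, pad 1); each 2x2
#' stride-2 pool floor-halves it. An `h x w` input therefore yields
#' feature maps of `floor(h / 2)` iterated once per pool, and the input
#' must be at least `2^n_pools` in both dimensions so the maps stay
#' non-empty.
#'
#' @param h,w Input image height and width in pixels.
#' @param spec A [backbone_spec()].
#' @return Integer vector `c(m_h, m_w)`.
#' @examples
#' feature_map_size(224, 224, backbone_spec("vgg16")) # c(14, 14)
#' feature_map_size(19, 29, backbone_spec("vgg16"))   # c(1, 1)
#' @export
feature_map_size <- function(h, w, spec) {
  stopifnot(inherits(spec, "backbone_spec"))
  check_map_dims(h, w)
  if (h < spec$min_input || w < spec$min_input) {
    rlang::abort(sprintf(
      "input %dx%d is below the backbone minimum of %dx%d (2^%d pools)",
      h, w, spec$min_input, spec$min_input, spec$n_pools
    ))
  }
  m_h <- as.integer(h)
  m_w <- as.integer(w)
  for (p in seq_len(spec$n_pools)) {
    m_h <- m_h %/% 2L
    m_w <- m_w %/% 2L
  }
  c(m_h, m_w)
}

#' Build a strip-pooling (or pyramid-pooling) classification network
#'
#' Assembles backbone + pooling head + fully connected classifier:
#' conv blocks, the multilevel pooling head (which makes the FC input
#' length independent of image size), one hidden FC layer with ReLU,
#' dropout before the last FC layer, and a softmax over the three
#' echogenicity classes. Weights use seeded He-normal initialisation;
#' a pretrained-weight hook is available via [set_weights()].
#'
#' @param spec A [backbone_spec()].
#' @param levels A [pool_levels] head configuration; square levels select
#'   the pyramid (SPP) window convention, strip levels the MSP one.
#' @param reduce Window reduction; defaults to `"mean"` for strip levels
#'   and `"max"` for square levels.
#' @param hidden Width of the hidden FC layer.
#' @param p_retain Dropout retain probability applied before the last FC
#'   layer (each unit is kept with probability `p_retain` during
#'   training; at evaluation the standard inverted-dropout convention
#'   leaves activations unscaled).
#' @param n_classes Number of output classes.
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `msp_net`.
#' @examples
#' net <- msp_net(backbone_spec("tiny"), msp_levels(1:3), seed = 1)
#' @export
msp_net <- function(spec = backbone_spec("tiny"), levels = msp_levels(1:3),
                    reduce = NULL, hidden = 64L, p_retain = 0.5,
                    n_classes = 3L, seed = 1L) {
  stopifnot(inherits(spec, "backbone_spec"), inherits(levels, "pool_levels"))
  if (p_retain < 0 || p_retain > 1) {
    rlang::abort("`p_retain` must lie in [0, 1]")
  }
  method <- if (identical(attr(levels, "mode"), "square")) "spp" else "msp"
  if (is.null(reduce)) reduce <- if (method == "spp") "max" else "mean"
  reduce <- match.arg(reduce, c("mean", "max"))
  pooled_len <- output_length(levels, spec$k)

  params <- withr::with_seed(seed, {
    conv <- list()
    cin <- 1L
    for (bl in spec$blocks) {
      for (l in seq_len(bl[1])) {
        cout <- bl[2]
        conv[[length(conv) + 1L]] <- list(
          W = array(stats::rnorm(9L * cin * cout, sd = sqrt(2 / (9 * cin))),
                    dim = c(3L, 3L, cin, cout)),
          b = numeric(cout)
        )
        cin <- cout
      }
    }
    list(
      conv = conv,
      fc1 = list(
        W = matrix(stats::rnorm(hidden * pooled_len,
                                sd = sqrt(2 / pooled_len)), hidden, pooled_len),
        b = numeric(hidden)
      ),
      fc2 = list(
        W = matrix(stats::rnorm(n_classes * hidden, sd = sqrt(2 / hidden)),
                   n_classes, hidden),
        b = numeric(n_classes)
      )
    )
  })

  # pool after each block except (unless include_final_pool) the last
  n_blocks <- length(spec$blocks)
  layer_block <- rep(seq_len(n_blocks),
                     vapply(spec$blocks, `[`, integer(1), 1L))
  pool_after_block <- c(rep(TRUE, n_blocks - 1L), spec$include_final_pool)

  structure(
    list(
      spec = spec,
      head = list(levels = levels, reduce = reduce, method = method),
      params = params,
      layer_block = layer_block,
      pool_after_block = pool_after_block,
      hidden = as.integer(hidden),
      p_retain = p_retain,
      n_classes = as.integer(n_classes),
      pooled_len = pooled_len
    ),
    class = "msp_net"
  )
}

#' @export
print.msp_net <- function(x, ...) {
  cat(sprintf(
    "<msp_net> %s head (%s reduce), pooled length %d, hidden %d, %d classes\n",
    toupper(x$head$method), x$head$reduce, x$pooled_len, x$hidden, x$n_classes
  ))
  print(x$spec)
  invisible(x)
}

#' Replace network weights
#'
#' Hook for loading externally trained weights (e.g. converted
#' ImageNet-pretrained VGG16 parameters) or for constructing analytically
#' chosen weights in tests. The replacement must match the existing
#' parameter shapes exactly.
#'
#' @param net An [msp_net()].
#' @param params Parameter list with the same structure and shapes as
#'   `net$params`.
#' @return The network with weights replaced.
#' @export
set_weights <- function(net, params) {
  stopifnot(inherits(net, "msp_net"))
  same_shape <- function(a, b) identical(dim(a) %||% length(a),
                                         dim(b) %||% length(b))
  `%||%` <- function(x, y) if (is.null(x)) y else x
  for (i in seq_along(net$params$conv)) {
    stopifnot(same_shape(params$conv[[i]]$W, net$params$conv[[i]]$W),
              same_shape(params$conv[[i]]$b, net$params$conv[[i]]$b))
  }
  stopifnot(same_shape(params$fc1$W, net$params$fc1$W),
            same_shape(params$fc2$W, net$params$fc2$W))
  net$params <- params
  net
}

relu <- function(x) x * (x > 0)

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

#' Apply a Bernoulli dropout mask
#'
#' Training-mode dropout as a plain masking operation: each entry of `y`
#' is multiplied by an independent Bernoulli(`p`) draw, where `p` is the
#' probability of *retaining* the unit. (The network's training loop uses
#' the inverted-dropout variant, which additionally divides by `p` so that
#' evaluation-mode activations need no rescaling.)
#'
#' @param y Numeric vector of activations.
#' @param p Retain probability in `[0, 1]`.
#' @param seed Optional integer seed for the mask.
#' @return Masked vector of the same length.
#' @examples
#' dropout_apply(rep(1, 5), p = 1) # unchanged
#' dropout_apply(rep(1, 5), p = 0) # all zero
#' @export
dropout_apply <- function(y, p, seed = NULL) {
  if (length(p) != 1L || !is.finite(p) || p < 0 || p > 1) {
    rlang::abort("retain probability `p` must lie in [0, 1]")
  }
  draw <- function() stats::rbinom(length(y), 1L, p)
  r <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  r * y
}

# ---- forward / backward ---------------------------------------------------

# Backbone forward: image (h x w matrix in [0,1]) -> feature stack.
# When `cache` is TRUE, returns the intermediates needed for backprop.
backbone_forward <- function(net, image, cache = FALSE) {
  h <- nrow(image)
  w <- ncol(image)
  if (h < net$spec$min_input || w < net$spec$min_input) {
    rlang::abort(sprintf(
      "input %dx%d is below the backbone minimum of %dx%d",
      h, w, net$spec$min_input, net$spec$min_input
    ))
  }
  x <- array(image, dim = c(h, w, 1L))
  conv_in <- list()
  acts <- list()
  pools <- list()
  li <- 0L
  for (bi in seq_along(net$spec$blocks)) {
    for (l in seq_len(net$spec$blocks[[bi]][1])) {
      li <- li + 1L
      p <- net$params$conv[[li]]
      if (cache) conv_in[[li]] <- x
      x <- relu(cpp_conv3_forward(x, p$W, p$b))
      if (cache) acts[[li]] <- x
    }
    if (net$pool_after_block[bi]) {
      mp <- cpp_maxpool2_forward(x)
      if (cache) {
        pools[[bi]] <- list(idx = mp$idx, h = dim(x)[1], w = dim(x)[2])
      }
      x <- mp$y
    }
  }
  if (!cache) return(list(stack = x))
  list(stack = x, conv_in = conv_in, acts = acts, pools = pools)
}

# Pooling head forward with window bookkeeping for backprop.
head_forward_train <- function(stack, head) {
  dims <- dim(stack)
  k <- dims[3]
  lv <- head$levels
  spans <- level_spans(dims[1], dims[2], lv, head$method)
  total <- k * sum(lv$a * lv$b)
  v <- numeric(total)
  meta <- vector("list", total)
  pos <- 0L
  for (ch in seq_len(k)) {
    sl <- stack[, , ch]
    if (is.null(dim(sl))) sl <- matrix(sl, dims[1], dims[2])
    for (sp in spans) {
      for (i in seq_len(nrow(sp$rows))) {
        rs <- sp$rows[i, 1]:sp$rows[i, 2]
        for (j in seq_len(nrow(sp$cols))) {
          cs <- sp$cols[j, 1]:sp$cols[j, 2]
          block <- sl[rs, cs, drop = FALSE]
          pos <- pos + 1L
          if (head$reduce == "mean") {
            v[pos] <- mean(block)
            meta[[pos]] <- list(ch = ch, rs = rs, cs = cs)
          } else {
            am <- arrayInd(which.max(block), dim(block))
            v[pos] <- block[am[1], am[2]]
            meta[[pos]] <- list(ch = ch, r = rs[am[1]], c = cs[am[2]])
          }
        }
      }
    }
  }
  list(v = v, meta = meta, dims = dims)
}

head_backward <- function(dv, hcache, reduce) {
  dx <- array(0, dim = hcache$dims)
  for (pos in seq_along(dv)) {
    m <- hcache$meta[[pos]]
    if (reduce == "mean") {
      dx[m$rs, m$cs, m$ch] <- dx[m$rs, m$cs, m$ch] +
        dv[pos] / (length(m$rs) * length(m$cs))
    } else {
      dx[m$r, m$c, m$ch] <- dx[m$r, m$c, m$ch] + dv[pos]
    }
  }
  dx
}

# Full forward pass. train = TRUE enables dropout (inverted convention)
# and caches intermediates for net_backward().
net_forward <- function(net, image, train = FALSE) {
  bk <- backbone_forward(net, image, cache = train)
  if (train) {
    hd <- head_forward_train(bk$stack, net$head)
    v <- hd$v
  } else {
    v <- pool_forward(bk$stack, net$head$levels, net$head$reduce,
                      net$head$method)
  }
  z1 <- drop(net$params$fc1$W %*% v) + net$params$fc1$b
  h1 <- relu(z1)
  if (train) {
    p <- net$p_retain
    mask <- if (p > 0) (stats::runif(length(h1)) < p) / p else rep(0, length(h1))
    h1d <- h1 * mask
  } else {
    mask <- NULL
    h1d <- h1
  }
  z2 <- drop(net$params$fc2$W %*% h1d) + net$params$fc2$b
  prob <- softmax(z2)
  out <- list(prob = prob)
  if (train) {
    out$cache <- list(bk = bk, hd = hd, v = v, z1 = z1, h1 = h1,
                      mask = mask, h1d = h1d)
  }
  out
}

# Gradients of the cross-entropy loss at one sample. `fwd` must come from
# net_forward(train = TRUE); `label` is the 1-based class index.
net_backward <- function(net, fwd, label) {
  cache <- fwd$cache
  dz2 <- fwd$prob
  dz2[label] <- dz2[label] - 1
  g <- list(conv = vector("list", length(net$params$conv)))
  g$fc2 <- list(W = outer(dz2, cache$h1d), b = dz2)
  dh1d <- drop(crossprod(net$params$fc2$W, dz2))
  dh1 <- if (is.null(cache$mask)) dh1d else dh1d * cache$mask
  dz1 <- dh1 * (cache$z1 > 0)
  g$fc1 <- list(W = outer(dz1, cache$v), b = dz1)
  dv <- drop(crossprod(net$params$fc1$W, dz1))
  dx <- head_backward(dv, cache$hd, net$head$reduce)

  li <- length(net$params$conv)
  for (bi in rev(seq_along(net$spec$blocks))) {
    if (net$pool_after_block[bi]) {
      pc <- cache$bk$pools[[bi]]
      dx <- cpp_maxpool2_backward(dx, pc$idx, pc$h, pc$w)
    }
    for (l in seq_len(net$spec$blocks[[bi]][1])) {
      dz <- dx * (cache$bk$acts[[li]] > 0)
      bw <- cpp_conv3_backward(cache$bk$conv_in[[li]],
                               net$params$conv[[li]]$W, dz)
      g$conv[[li]] <- list(W = bw$dw, b = bw$db)
      dx <- bw$dx
      li <- li - 1L
    }
  }
  g
}

#' Predict echogenicity classes for a set of images
#'
#' Runs the network on each image (any sizes at or above the backbone
#' minimum; images are used as-is, never resized) and returns per-class
#' softmax probabilities and the argmax class.
#'
#' @param object An [msp_net()].
#' @param newdata List of normalized image matrices (values in `[0, 1]`),
#'   optionally named.
#' @param ... Unused.
#' @return Tibble with one row per image: `id`, `.pred_class`, and one
#'   `.prob_*` column per class.
#' @export
predict.msp_net <- function(object, newdata, ...) {
  stopifnot(is.list(newdata), length(newdata) > 0L)
  ids <- names(newdata)
  if (is.null(ids)) ids <- as.character(seq_along(newdata))
  probs <- t(vapply(newdata,
                    function(im) net_forward(object, im)$prob,
                    numeric(object$n_classes)))
  cls <- PLAQUE_CLASSES[seq_len(object$n_classes)]
  colnames(probs) <- paste0(".prob_", gsub("-", "_", cls))
  dplyr::bind_cols(
    tibble::tibble(
      id = ids,
      .pred_class = factor(cls[max.col(probs)], levels = cls)
    ),
    tibble::as_tibble(probs)
  )
}

#' Pooled feature vector of one image
#'
#' Runs the backbone and the pooling head only, returning the fixed-length
#' feature vector that feeds the fully connected classifier. Useful for
#' inspecting what the strip-pooling head extracts.
#'
#' @param net An [msp_net()].
#' @param image Normalized image matrix.
#' @return Numeric vector of length `net$pooled_len`.
#' @export
extract_features <- function(net, image) {
  stopifnot(inherits(net, "msp_net"))
  bk <- backbone_forward(net, image)
  pool_forward(bk$stack, net$head$levels, net$head$reduce, net$head$method)
}
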