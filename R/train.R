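#' Training configuration
#'
#' The optimization recipe: cross-entropy loss minimised by stochastic
#' gradient descent with momentum 0.9, base learning rate 0.001 divided
#' by 10 every 6 epochs, 30 epochs, and batch size 1 — variable-size
#' inputs cannot be stacked into a fixed tensor, so each step sees a
#' single image.
#'
#' @param epochs Number of passes over the training set.
#' @param base_lr Base learning rate.
#' @param momentum SGD momentum coefficient.
#' @param lr_step Epoch interval at which the learning rate is divided
#'   by `lr_factor`.
#' @param lr_factor Division factor of the schedule.
#' @param seed Integer seed governing shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 30L, base_lr = 0.001, momentum = 0.9,
                         lr_step = 6L, lr_factor = 10, seed = 1L) {
  stopifnot(epochs >= 0, base_lr > 0, momentum >= 0, momentum < 1,
            lr_step >= 1, lr_factor > 1)
  structure(
    list(epochs = as.integer(epochs), base_lr = base_lr,
         momentum = momentum, lr_step = as.integer(lr_step),
         lr_factor = lr_factor, seed = as.integer(seed)),
    class = "train_config"
  )
}

#' Learning rate at a given epoch
#'
#' `base_lr / lr_factor^(floor(e / lr_step))` for 0-based epoch `e`: with
#' the defaults, 0.001 for epochs 0-5, 0.0001 for 6-11, and so on.
#'
#' @param e 0-based epoch index, `0 <= e < epochs`.
#' @param cfg A [train_config()].
#' @return The learning rate.
#' @examples
#' lr_at_epoch(0, train_config())  # 0.001
#' lr_at_epoch(6, train_config())  # 0.0001
#' @export
lr_at_epoch <- function(e, cfg = train_config()) {
  stopifnot(inherits(cfg, "train_config"))
  if (any(e < 0) || any(e >= cfg$epochs) || any(e != floor(e))) {
    rlang::abort(sprintf("epoch must be an integer in [0, %d)", cfg$epochs))
  }
  cfg$base_lr / cfg$lr_factor^(e %/% cfg$lr_step)
}

#' Train a network by SGD with momentum
#'
#' Runs the batch-size-1 training loop: per epoch, the training set is
#' shuffled (seeded), each image is forward-propagated, the cross-entropy
#' loss gradient is backpropagated, and parameters are updated with
#' momentum at the scheduled learning rate. Training aborts with a
#' diagnostic if the loss diverges to NaN. Deterministic given the seed.
#'
#' @param net An [msp_net()].
#' @param images Named list of normalized training image matrices.
#' @param labels Factor or character vector of class labels, one per image.
#' @param cfg A [train_config()].
#' @param eval_images,eval_labels Optional held-out set evaluated after
#'   every epoch (accuracy recorded in the trace).
#' @return An object of class `mspnet_fit`: the trained `net`, the
#'   config, and `trace`, a tibble with one row per epoch (`epoch`, `lr`,
#'   `loss`, `train_acc`, `eval_acc`).
#' @export
fit_mspnet <- function(net, images, labels, cfg = train_config(),
                       eval_images = NULL, eval_labels = NULL) {
  stopifnot(inherits(net, "msp_net"), inherits(cfg, "train_config"))
  labels <- as_class_index(labels, net$n_classes)
  stopifnot(length(labels) == length(images))

  vel <- list(
    conv = lapply(net$params$conv, function(p) list(W = 0 * p$W, b = 0 * p$b)),
    fc1 = list(W = 0 * net$params$fc1$W, b = 0 * net$params$fc1$b),
    fc2 = list(W = 0 * net$params$fc2$W, b = 0 * net$params$fc2$b)
  )
  trace <- vector("list", cfg$epochs)

  withr::with_seed(cfg$seed, {
    for (e in seq_len(cfg$epochs) - 1L) {
      lr <- lr_at_epoch(e, cfg)
      ord <- sample.int(length(images))
      losses <- numeric(length(ord))
      correct <- 0L
      for (s in seq_along(ord)) {
        i <- ord[s]
        fwd <- net_forward(net, images[[i]], train = TRUE)
        loss <- -log(max(fwd$prob[labels[i]], 1e-12))
        if (!is.finite(loss)) {
          rlang::abort(sprintf(
            "training diverged (non-finite loss) at epoch %d, sample %d", e, s
          ))
        }
        losses[s] <- loss
        if (which.max(fwd$prob) == labels[i]) correct <- correct + 1L
        g <- net_backward(net, fwd, labels[i])
        for (li in seq_along(net$params$conv)) {
          vel$conv[[li]]$W <- cfg$momentum * vel$conv[[li]]$W - lr * g$conv[[li]]$W
          vel$conv[[li]]$b <- cfg$momentum * vel$conv[[li]]$b - lr * g$conv[[li]]$b
          net$params$conv[[li]]$W <- net$params$conv[[li]]$W + vel$conv[[li]]$W
          net$params$conv[[li]]$b <- net$params$conv[[li]]$b + vel$conv[[li]]$b
        }
        for (nm in c("fc1", "fc2")) {
          vel[[nm]]$W <- cfg$momentum * vel[[nm]]$W - lr * g[[nm]]$W
          vel[[nm]]$b <- cfg$momentum * vel[[nm]]$b - lr * g[[nm]]$b
          net$params[[nm]]$W <- net$params[[nm]]$W + vel[[nm]]$W
          net$params[[nm]]$b <- net$params[[nm]]$b + vel[[nm]]$b
        }
      }
      eval_acc <- NA_real_
      if (!is.null(eval_images)) {
        eval_acc <- accuracy_on(net, eval_images, eval_labels)
      }
      trace[[e + 1L]] <- tibble::tibble(
        epoch = e, lr = lr, loss = mean(losses),
        train_acc = correct / length(ord), eval_acc = eval_acc
      )
    }
  })

  structure(
    list(net = net, cfg = cfg, trace = dplyr::bind_rows(trace)),
    class = "mspnet_fit"
  )
}

as_class_index <- function(labels, n_classes) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    idx <- match(labels, PLAQUE_CLASSES[seq_len(n_classes)])
    if (any(is.na(idx))) {
      rlang::abort("labels contain classes outside the vocabulary")
    }
    return(idx)
  }
  as.integer(labels)
}

accuracy_on <- function(net, images, labels) {
  labels <- as_class_index(labels, net$n_classes)
  pred <- vapply(images, function(im) which.max(net_forward(net, im)$prob),
                 integer(1))
  mean(pred == labels)
}

#' @export
print.mspnet_fit <- function(x, ...) {
  cat(sprintf("<mspnet_fit> %d epoch(s)\n", nrow(x$trace)))
  if (nrow(x$trace) > 0) {
    last <- x$trace[nrow(x$trace), ]
    cat(sprintf("  final: loss %.4f, train acc %.3f%s\n",
                last$loss, last$train_acc,
                if (is.finite(last$eval_acc)) {
                  sprintf(", eval acc %.3f", last$eval_acc)
                } else ""))
  }
  invisible(x)
}

#' @rdname fit_mspnet
#' @param x An `mspnet_fit` object.
#' @param ... Unused.
#' @export
tidy.mspnet_fit <- function(x, ...) x$trace

#' @rdname fit_mspnet
#' @export
glance.mspnet_fit <- function(x, ...) {
  if (nrow(x$trace) == 0L) {
    return(tibble::tibble(epochs = 0L, final_loss = NA_real_,
                          final_train_acc = NA_real_, final_eval_acc = NA_real_))
  }
  last <- x$trace[nrow(x$trace), ]
  tibble::tibble(epochs = nrow(x$trace), final_loss = last$loss,
                 final_train_acc = last$train_acc,
                 final_eval_acc = last$eval_acc)
}
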