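#' Stratified k-fold cross-validation of a strip-pooling classifier
#'
#' For each fold, a fresh network is initialised (seed `seed + fold`, so
#' runs are reproducible yet folds independent), trained on the remaining
#' folds with [fit_mspnet()], and evaluated on the held-out fold. Test
#' confusion matrices are accumulated, so over all folds every sample is
#' counted exactly once.
#'
#' @param images Named list of normalized image matrices.
#' @param labels Class labels, one per image.
#' @param folds Number of folds.
#' @param spec A [backbone_spec()].
#' @param levels A [pool_levels] head configuration.
#' @param cfg A [train_config()]; its seed also drives the fold split.
#' @param hidden,p_retain Classifier-head parameters, see [msp_net()].
#' @return An object of class `mspnet_cv`: `folds` (tibble of per-fold
#'   accuracy and macro metrics), `cm` (pooled confusion matrix),
#'   `metrics` (pooled [compute_metrics()] table), `fits` (per-fold
#'   fits), `assignment` (the fold split).
#' @export
crossval_mspnet <- function(images, labels, folds = 5L,
                            spec = backbone_spec("tiny"),
                            levels = msp_levels(1:3),
                            cfg = train_config(), hidden = 64L,
                            p_retain = 0.5) {
  stopifnot(length(images) == length(labels))
  ids <- names(images)
  if (is.null(ids)) ids <- as.character(seq_along(images))
  index <- tibble::tibble(id = ids, label = as.character(labels))
  assignment <- stratified_kfold(index, folds, seed = cfg$seed)

  cls <- plaque_classes()
  pooled <- matrix(0L, length(cls), length(cls),
                   dimnames = list(truth = cls, estimate = cls))
  fold_rows <- list()
  fits <- list()
  for (f in seq_len(folds)) {
    test_i <- which(assignment$fold == f)
    train_i <- setdiff(seq_along(images), test_i)
    net <- msp_net(spec, levels, hidden = hidden, p_retain = p_retain,
                   seed = cfg$seed + f)
    fold_cfg <- cfg
    fold_cfg$seed <- cfg$seed + f
    fit <- fit_mspnet(net, images[train_i], index$label[train_i], fold_cfg,
                      eval_images = images[test_i],
                      eval_labels = index$label[test_i])
    pred <- predict(fit$net, images[test_i])
    cm <- confusion_matrix(index$label[test_i], pred$.pred_class)
    pooled <- pooled + unclass(cm)
    mac <- glance(cm)
    fold_rows[[f]] <- dplyr::bind_cols(tibble::tibble(fold = f), mac)
    fits[[f]] <- fit
  }
  pooled_cm <- as_plaque_cm(pooled)
  structure(
    list(
      folds = dplyr::bind_rows(fold_rows),
      cm = pooled_cm,
      metrics = compute_metrics(pooled_cm),
      fits = fits,
      assignment = assignment
    ),
    class = "mspnet_cv"
  )
}

#' @export
print.mspnet_cv <- function(x, ...) {
  cat(sprintf("<mspnet_cv> %d fold(s)\n", nrow(x$folds)))
  print(glance(x))
  invisible(x)
}

#' @rdname crossval_mspnet
#' @param x An `mspnet_cv` object.
#' @param ... Unused.
#' @return `tidy()`: the per-fold metric tibble; `glance()`: one row of
#'   cross-fold mean and sd of accuracy and macro metrics.
#' @export
tidy.mspnet_cv <- function(x, ...) x$folds

#' @rdname crossval_mspnet
#' @export
glance.mspnet_cv <- function(x, ...) {
  tibble::tibble(
    folds = nrow(x$folds),
    accuracy = mean(x$folds$accuracy),
    accuracy_sd = stats::sd(x$folds$accuracy),
    sensitivity = mean(x$folds$sensitivity),
    specificity = mean(x$folds$specificity),
    precision = mean(x$folds$precision),
    f1 = mean(x$folds$f1)
  )
}

#' Write cross-validation artifacts to disk
#'
#' Writes the per-fold metrics, pooled per-class metrics, pooled
#' confusion matrix, per-epoch traces and fold assignment as CSV files
#' into `dir`.
#'
#' @param cv An `mspnet_cv` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cv_artifacts <- function(cv, dir) {
  stopifnot(inherits(cv, "mspnet_cv"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    fold_metrics = file.path(dir, "fold_metrics.csv"),
    class_metrics = file.path(dir, "class_metrics.csv"),
    confusion = file.path(dir, "confusion_matrix.csv"),
    traces = file.path(dir, "traces.csv"),
    assignment = file.path(dir, "fold_assignment.csv")
  )
  readr::write_csv(cv$folds, paths["fold_metrics"])
  readr::write_csv(cv$metrics, paths["class_metrics"])
  cm_df <- tibble::as_tibble(as.data.frame.table(unclass(cv$cm),
                                                 responseName = "count"))
  readr::write_csv(cm_df, paths["confusion"])
  traces <- purrr::imap_dfr(cv$fits, function(fit, f) {
    dplyr::mutate(fit$trace, fold = f, .before = 1)
  })
  readr::write_csv(traces, paths["traces"])
  readr::write_csv(cv$assignment, paths["assignment"])
  invisible(paths)
}
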