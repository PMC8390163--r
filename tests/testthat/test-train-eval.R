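test_that("the learning-rate schedule divides by 10 every 6 epochs", {
  cfg <- train_config()
  expect_equal(lr_at_epoch(0, cfg), 0.001)
  expect_equal(lr_at_epoch(5, cfg), 0.001)
  expect_equal(lr_at_epoch(6, cfg), 0.0001)
  expect_equal(lr_at_epoch(29, cfg), 1e-7)
  expect_error(lr_at_epoch(30, cfg), "\\[0, 30\\)")
  expect_error(lr_at_epoch(-1, cfg))
})

test_that("metrics on a hand-tallied confusion matrix match one-vs-rest arithmetic", {
  cm <- matrix(c(50, 10, 0,
                 5, 40, 15,
                 0, 10, 90), nrow = 3, byrow = TRUE)
  met <- compute_metrics(cm)

  # class 1 by hand: TP 50, FN 10, FP 5, TN 155
  expect_equal(met$sensitivity[1], 50 / 60)
  expect_equal(met$precision[1], 50 / 55)
  expect_equal(met$specificity[1], 155 / 160)
  expect_equal(met$f1[1],
               2 * (50 / 55) * (50 / 60) / ((50 / 55) + (50 / 60)))

  # every class against an independent brute-force tally
  total <- sum(cm)
  for (i in 1:3) {
    tp <- cm[i, i]
    fn <- sum(cm[i, -i])
    fp <- sum(cm[-i, i])
    tn <- total - tp - fn - fp
    expect_equal(met$sensitivity[i], tp / (tp + fn))
    expect_equal(met$specificity[i], tn / (tn + fp))
    expect_equal(met$precision[i], tp / (tp + fp))
  }
  mac <- glance(compute_metrics(cm))
  expect_equal(mac$accuracy, (50 + 40 + 90) / total)
  expect_equal(mac$sensitivity, mean(met$sensitivity))

  perfect <- compute_metrics(diag(c(10, 10, 10)))
  expect_true(all(perfect$sensitivity == 1 & perfect$specificity == 1 &
                    perfect$precision == 1 & perfect$f1 == 1))
  expect_equal(glance(perfect)$accuracy, 1)
})

test_that("empty denominators are reported as 0 and flagged", {
  # nothing ever predicted as class 2 -> precision undefined there
  cm <- matrix(c(10, 0, 0,
                 8, 0, 2,
                 0, 0, 10), nrow = 3, byrow = TRUE)
  met <- compute_metrics(cm)
  expect_equal(met$precision[2], 0)
  expect_true(met$undefined[2])
  expect_false(met$undefined[1])
  mac <- glance(met)
  expect_true(is.finite(mac$precision))
})

test_that("metric identities hold on random confusion matrices", {
  set.seed(13)
  for (rep in 1:20) {
    cm <- matrix(rpois(9, 20), 3)
    met <- compute_metrics(cm)
    mac <- attr(met, "macro")
    expect_equal(mac$accuracy, sum(diag(cm)) / sum(cm))
    for (i in 1:3) {
      expect_equal(met$sensitivity[i] * (met$tp[i] + met$fn[i]), met$tp[i])
      if (!met$undefined[i]) {
        expect_gte(met$f1[i], min(met$precision[i], met$sensitivity[i]) - 1e-12)
        expect_lte(met$f1[i], max(met$precision[i], met$sensitivity[i]) + 1e-12)
      }
    }
  }
})

test_that("stratified folds are proportional partitions", {
  idx <- tibble::tibble(id = 1:15, label = rep(plaque_classes(), 5))
  split <- stratified_kfold(idx, 5, seed = 1)
  counts <- table(split$fold, split$label)
  expect_true(all(counts == 1))

  # the clinical class totals: folds of 292 or 293, class counts within 1
  big <- tibble::tibble(label = rep(plaque_classes(), c(335, 405, 723)))
  split <- stratified_kfold(big, 5, seed = 2)
  sizes <- table(split$fold)
  expect_true(all(sizes %in% c(292, 293)))
  counts <- table(split$fold, split$label)
  expect_true(all(counts[, "echo-rich"] == 67))
  expect_true(all(counts[, "intermediate"] == 81))
  expect_true(all(abs(counts[, "echolucent"] - 144.6) <= 1))
  expect_equal(sum(counts), 1463)

  expect_error(
    stratified_kfold(tibble::tibble(label = c("echo-rich", rep("echolucent", 4))), 2),
    "fewer records than folds"
  )
  expect_identical(stratified_kfold(idx, 5, seed = 9),
                   stratified_kfold(idx, 5, seed = 9))
})

test_that("training for zero epochs changes nothing and training is seed-deterministic", {
  cfg <- small_roi_config()
  tr <- make_synth_set(2, cfg, seed0 = 100)
  net <- msp_net(backbone_spec("tiny"), msp_levels(1:3), seed = 6)

  fit0 <- fit_mspnet(net, tr$images, tr$labels, train_config(epochs = 0, seed = 1))
  expect_identical(fit0$net$params, net$params)
  expect_equal(nrow(fit0$trace), 0)

  tc <- train_config(epochs = 2, seed = 17)
  f1 <- fit_mspnet(net, tr$images, tr$labels, tc)
  f2 <- fit_mspnet(net, tr$images, tr$labels, tc)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$net$params, f2$net$params)
  te <- make_synth_set(1, cfg, seed0 = 900)
  expect_identical(predict(f1$net, te$images), predict(f2$net, te$images))
})

test_that("tidy and glance expose the training trace", {
  cfg <- small_roi_config()
  tr <- make_synth_set(1, cfg, seed0 = 300)
  fit <- fit_mspnet(msp_net(backbone_spec("tiny"), msp_levels(1:3), seed = 2),
                    tr$images, tr$labels, train_config(epochs = 2, seed = 3),
                    eval_images = tr$images, eval_labels = tr$labels)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(tidy(fit)$epoch, 0:1)
  expect_equal(tidy(fit)$lr, c(0.001, 0.001))
  g <- glance(fit)
  expect_equal(g$epochs, 2)
  expect_true(is.finite(g$final_eval_acc))
})

test_that("cross-validation counts every sample exactly once and both heads run", {
  cfg <- small_roi_config()
  ds <- make_synth_set(6, cfg, seed0 = 200)   # 18 images, 6 per class
  tc <- train_config(epochs = 1, seed = 5)

  cv <- crossval_mspnet(ds$images, ds$labels, folds = 3,
                        levels = msp_levels(1:3), cfg = tc)
  expect_equal(sum(cv$cm), 18)
  expect_equal(unname(rowSums(unclass(cv$cm))), rep(6, 3))
  expect_equal(nrow(cv$folds), 3)
  expect_s3_class(glance(cv), "tbl_df")

  cv_spp <- crossval_mspnet(ds$images, ds$labels, folds = 3,
                            levels = spp_levels(1:3), cfg = tc)
  expect_equal(sum(cv_spp$cm), 18)
  # the two heads feed FC layers of different input widths: 14k vs 6k
  expect_equal(cv_spp$fits[[1]]$net$pooled_len, 14 * 16)
  expect_equal(cv$fits[[1]]$net$pooled_len, 6 * 16)

  dir <- withr::local_tempdir()
  paths <- write_cv_artifacts(cv, dir)
  expect_true(all(file.exists(paths)))
  cm_csv <- readr::read_csv(paths["confusion"], show_col_types = FALSE)
  expect_equal(sum(cm_csv$count), 18)
})

test_that("autoplot methods return ggplot objects", {
  cfg <- small_roi_config()
  tr <- make_synth_set(1, cfg, seed0 = 400)
  fit <- fit_mspnet(msp_net(seed = 1), tr$images, tr$labels,
                    train_config(epochs = 1, seed = 1),
                    eval_images = tr$images, eval_labels = tr$labels)
  expect_s3_class(autoplot(fit), "ggplot")
  cm <- confusion_matrix(tr$labels, tr$labels)
  expect_s3_class(autoplot(cm), "ggplot")
})
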