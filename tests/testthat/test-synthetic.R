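test_that("generation is deterministic given (class, config, seed)", {
  cfg <- synthetic_config()
  a <- generate_plaque("intermediate", cfg, seed = 7)
  b <- generate_plaque("intermediate", cfg, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, generate_plaque("intermediate", cfg, seed = 8)))
  expect_error(generate_plaque("calcified", cfg, 1), "unknown class")
})

test_that("images respect the configured size ranges and the 8-bit grid", {
  cfg <- synthetic_config()
  for (s in 1:10) {
    img <- generate_plaque("echolucent", cfg, seed = s)
    expect_true(nrow(img) >= 19 && nrow(img) <= 134)
    expect_true(ncol(img) >= 29 && ncol(img) <= 564)
    expect_true(all(img >= 0 & img <= 1))
    expect_equal(img, round(img * 255) / 255)
  }
  # degenerate range pins the size to the smallest clinical ROI
  tiny <- synthetic_config(h_range = c(19, 19), w_range = c(29, 29))
  img <- generate_plaque("echo-rich", tiny, seed = 1)
  expect_equal(dim(img), c(19, 29))
})

test_that("generate_dataset writes a loadable, byte-reproducible dataset", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  idx1 <- generate_dataset(5, small_roi_config(), seed = 3, dir = d1)
  idx2 <- generate_dataset(5, small_roi_config(), seed = 3, dir = d2)
  expect_equal(nrow(idx1), 15)
  expect_equal(as.vector(table(idx1$label)), rep(5L, 3))
  expect_identical(idx1, idx2)
  expect_true(file.exists(file.path(d1, "manifest.json")))
  for (f in idx1$filename) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  expect_identical(readLines(file.path(d1, "index.csv")),
                   readLines(file.path(d2, "index.csv")))
})

test_that("at full separability the class mean-intensity ordering is near-deterministic", {
  cfg <- synthetic_config(lambda = 1)
  n <- 100
  means <- lapply(plaque_classes(), function(cl) {
    vapply(seq_len(n), function(i) {
      mean(generate_plaque(cl, cfg, seed = 40000 + match(cl, plaque_classes()) * 1000 + i))
    }, numeric(1))
  })
  names(means) <- plaque_classes()
  frac_ordered <- function(lo, hi) mean(outer(means[[lo]], means[[hi]], `<`))
  expect_gte(frac_ordered("echolucent", "intermediate"), 0.99)
  expect_gte(frac_ordered("intermediate", "echo-rich"), 0.99)
  expect_gte(frac_ordered("echolucent", "echo-rich"), 0.99)
})

test_that("at lambda = 0 the class-conditional pixel distributions coincide", {
  cfg <- synthetic_config(lambda = 0)
  reps <- 25
  ok <- 0
  for (r in seq_len(reps)) {
    px <- lapply(c("echolucent", "echo-rich"), function(cl) {
      v <- numeric(0)
      i <- 0
      while (length(v) < 1e4) {
        i <- i + 1
        v <- c(v, as.vector(generate_plaque(
          cl, cfg, seed = 70000 + r * 100 + match(cl, plaque_classes()) * 10 + i
        )))
      }
      v[seq_len(1e4)]
    })
    p <- suppressWarnings(stats::ks.test(px[[1]], px[[2]])$p.value)
    if (p > 0.01) ok <- ok + 1
  }
  expect_gte(ok, 22)
})

test_that("a mean-intensity classifier's accuracy is non-decreasing in the separability knob", {
  lambdas <- c(0, 0.25, 0.5, 0.75, 1)
  acc <- vapply(lambdas, function(lam) {
    cfg <- synthetic_config(lambda = lam,
                            h_range = c(16, 40), w_range = c(24, 80))
    centers <- vapply(plaque_classes(),
                      function(cl) stripnet:::class_mean(cfg, cl), numeric(1))
    seed_acc <- vapply(1:10, function(s) {
      hits <- 0L
      tot <- 0L
      for (ci in seq_along(plaque_classes())) {
        for (i in 1:10) {
          img <- generate_plaque(plaque_classes()[ci], cfg,
                                 seed = 90000 + s * 500 + ci * 50 + i)
          pred <- which.min(abs(mean(img) - centers))
          hits <- hits + as.integer(pred == ci)
          tot <- tot + 1L
        }
      }
      hits / tot
    }, numeric(1))
    mean(seed_acc)
  }, numeric(1))
  expect_true(all(diff(acc) >= -1e-9))
  expect_gt(acc[length(acc)], acc[1])
})
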