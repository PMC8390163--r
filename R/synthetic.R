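#' Configuration of the synthetic plaque generator
#'
#' The generator emulates the qualitative structure of longitudinal
#' carotid-plaque ultrasound ROIs that a strip-pooling classifier
#' exploits: three classes differing in mean echogenicity (echolucent
#' dark, echo-rich bright, intermediate a mix of bright and dark
#' horizontal bands), horizontally elongated geometry, horizontal band
#' texture, and multiplicative speckle noise. It is a statistical
#' surrogate, not a physical ultrasound simulation.
#'
#' Class-conditional structure scales with the separability knob
#' `lambda`: pixel means are `0.5 + lambda * (mu_class - 0.5)`, and the
#' intermediate class adds alternating `+/- lambda * intermediate_contrast`
#' band offsets around its mean. At `lambda = 0` the three
#' class-conditional distributions are identical by construction; at
#' `lambda = 1` the configured class means apply in full.
#'
#' @param mean_lucent,mean_rich Mean echogenicity of echolucent and
#'   echo-rich plaques on `[0, 1]` (intermediate sits at their midpoint).
#' @param intermediate_contrast Half-amplitude of the intermediate class's
#'   alternating bright/dark bands at `lambda = 1`.
#' @param speckle_shape Shape of the multiplicative gamma speckle
#'   (mean 1, variance `1 / speckle_shape`); larger = less noisy.
#' @param n_bands Number of horizontal texture bands.
#' @param band_amplitude Amplitude of the class-independent band texture.
#' @param h_range,w_range Inclusive integer ranges the ROI height and
#'   width are drawn from; defaults span the observed clinical extremes
#'   19x29 to 134x564 (h x w), so widths dominate heights and ROIs are
#'   horizontally elongated.
#' @param lambda Class separability in `[0, 1]`.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(mean_lucent = 0.2, mean_rich = 0.8,
                             intermediate_contrast = 0.3,
                             speckle_shape = 8, n_bands = 6L,
                             band_amplitude = 0.08,
                             h_range = c(19L, 134L), w_range = c(29L, 564L),
                             lambda = 1) {
  stopifnot(
    mean_lucent >= 0, mean_rich <= 1, mean_lucent < mean_rich,
    speckle_shape > 0, n_bands >= 1, band_amplitude >= 0,
    length(h_range) == 2L, length(w_range) == 2L,
    h_range[1] >= 1, h_range[1] <= h_range[2],
    w_range[1] >= 1, w_range[1] <= w_range[2],
    lambda >= 0, lambda <= 1
  )
  structure(
    list(
      mean_lucent = mean_lucent, mean_rich = mean_rich,
      intermediate_contrast = intermediate_contrast,
      speckle_shape = speckle_shape, n_bands = as.integer(n_bands),
      band_amplitude = band_amplitude,
      h_range = as.integer(h_range), w_range = as.integer(w_range),
      lambda = lambda
    ),
    class = "synthetic_config"
  )
}

class_mean <- function(config, class) {
  mid <- (config$mean_lucent + config$mean_rich) / 2
  mu <- switch(class,
    "echolucent" = config$mean_lucent,
    "echo-rich" = config$mean_rich,
    "intermediate" = mid
  )
  mid + config$lambda * (mu - mid)
}

#' Generate one synthetic plaque ROI
#'
#' Draws an ROI size from the configured ranges, lays down the class-
#' conditional horizontal band structure, multiplies by gamma speckle
#' (mean 1), clips to `[0, 1]` and quantizes to 8 bits — so the image is
#' exactly what an 8-bit PNG round trip would produce. Deterministic
#' given `(class, config, seed)`.
#'
#' @param class One of `"echo-rich"`, `"intermediate"`, `"echolucent"`.
#' @param config A [synthetic_config()].
#' @param seed Integer seed.
#' @return Numeric matrix with values on the 8-bit grid in `[0, 1]`.
#' @export
generate_plaque <- function(class, config = synthetic_config(), seed = 1L) {
  if (!is.character(class) || length(class) != 1L ||
      !class %in% PLAQUE_CLASSES) {
    rlang::abort(sprintf("unknown class '%s' (allowed: %s)",
                         as.character(class)[1],
                         paste(PLAQUE_CLASSES, collapse = ", ")))
  }
  stopifnot(inherits(config, "synthetic_config"))
  draw_int <- function(rng) rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
  withr::with_seed(as.integer(seed), {
    h <- draw_int(config$h_range)
    w <- draw_int(config$w_range)
    band <- pmin(floor((seq_len(h) - 1L) / h * config$n_bands),
                 config$n_bands - 1L)
    alt <- ifelse(band %% 2L == 0L, 1, -1)
    # class-independent texture + class-dependent band offset (intermediate
    # mixes bright and dark bands; pure classes keep a flat mean)
    row_mean <- class_mean(config, class) +
      config$band_amplitude * alt +
      (if (class == "intermediate") {
        config$lambda * config$intermediate_contrast * alt
      } else 0)
    base <- matrix(row_mean, nrow = h, ncol = w)
    speckle <- matrix(
      stats::rgamma(h * w, shape = config$speckle_shape,
                    rate = config$speckle_shape),
      nrow = h, ncol = w
    )
    px <- pmin(pmax(base * speckle, 0), 1)
    round(px * 255) / 255
  })
}

#' Generate a labeled synthetic dataset on disk
#'
#' Writes `n_per_class` 8-bit grayscale PNGs per echogenicity class plus
#' an index CSV (`id,filename,label`) consumable by [load_dataset()], and
#' a JSON manifest recording the configuration and seed so the dataset
#' can be reproduced byte for byte. Image `i` of class `c` uses seed
#' `seed + 1000 * (c - 1) + i`, so individual images can be regenerated
#' with [generate_plaque()].
#'
#' @param n_per_class Images per class (>= 1).
#' @param config A [synthetic_config()].
#' @param seed Integer base seed.
#' @param dir Output directory (created if needed).
#' @return The dataset index as a tibble (`id`, `filename`, `label`),
#'   invisibly carrying the paths written.
#' @export
generate_dataset <- function(n_per_class, config = synthetic_config(),
                             seed = 1L, dir) {
  stopifnot(n_per_class >= 1)
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) rlang::abort(sprintf("cannot create output directory '%s'", dir))
  }
  rows <- list()
  for (ci in seq_along(PLAQUE_CLASSES)) {
    cl <- PLAQUE_CLASSES[ci]
    for (i in seq_len(n_per_class)) {
      img_seed <- as.integer(seed) + 1000L * (ci - 1L) + i
      px <- generate_plaque(cl, config, img_seed)
      id <- sprintf("%s_%03d", gsub("-", "", cl), i)
      filename <- paste0(id, ".png")
      png::writePNG(px, file.path(dir, filename))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = id, filename = filename, label = cl
      )
    }
  }
  index <- dplyr::bind_rows(rows)
  readr::write_csv(index, file.path(dir, "index.csv"))
  manifest <- c(unclass(config), list(n_per_class = n_per_class,
                                      seed = as.integer(seed)))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  index
}
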