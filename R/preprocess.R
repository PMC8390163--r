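#' Min-max normalize a grayscale ROI
#'
#' Linearly rescales pixel intensities to `[0, 1]` using the minimum and
#' maximum of *this* image: `(x - x_min) / (x_max - x_min)`. The rescaling
#' is monotone, so the intensity rank order of pixels is preserved, and it
#' makes the source bit depth (8-bit PNG, 16-bit TIFF) immaterial. A
#' constant image has no dynamic range; it is mapped to all zeros with a
#' warning.
#'
#' @param image Numeric matrix of pixel intensities (any range).
#' @return Matrix of the same dimensions with `min = 0`, `max = 1`
#'   (all zeros for constant input).
#' @examples
#' minmax_normalize(matrix(c(0, 64, 128, 255), 2))
#' @export
minmax_normalize <- function(image) {
  if (!is.matrix(image) || !is.numeric(image) || length(image) == 0L) {
    rlang::abort("`image` must be a non-empty numeric matrix")
  }
  if (any(!is.finite(image))) {
    rlang::abort("`image` must contain only finite pixel values")
  }
  lo <- min(image)
  hi <- max(image)
  if (hi == lo) {
    rlang::warn("constant image: no dynamic range, returning all zeros")
    return(array(0, dim = dim(image)))
  }
  (image - lo) / (hi - lo)
}

read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    rlang::abort(sprintf("unsupported image format '%s' (%s)", ext, path))
  )
  if (length(dim(px)) == 3L) {
    # accept a trivially-gray multi-channel image, reject true color
    ch <- dim(px)[3]
    first <- px[, , 1]
    for (c2 in seq_len(min(ch, 3L))[-1]) {
      if (any(abs(px[, , c2] - first) > 1e-9)) {
        rlang::abort(sprintf("image is not grayscale: %s", path))
      }
    }
    px <- first
  }
  px
}

#' Load a labeled ROI dataset from disk
#'
#' Reads an index CSV with columns `id`, `filename`, `label` and the
#' grayscale images (8-bit PNG or TIFF) it references. Labels are
#' validated against the three-class echogenicity vocabulary; images of
#' any size are accepted and kept at their native size. Pixels are
#' min-max normalized to `[0, 1]` on the fly; nothing is written back.
#'
#' @param index_csv Path to the index CSV.
#' @param image_dir Directory holding the image files.
#' @param normalize Normalize each image with [minmax_normalize()]?
#' @return A list with `index` (tibble `id`, `filename`, `label`, `path`,
#'   `h`, `w`) and `images` (named list of matrices, names = `id`).
#' @export
load_dataset <- function(index_csv, image_dir, normalize = TRUE) {
  if (!file.exists(index_csv)) {
    rlang::abort(sprintf("index CSV not found: %s", index_csv))
  }
  idx <- readr::read_csv(index_csv, show_col_types = FALSE,
                         col_types = readr::cols(.default = "c"))
  need <- c("id", "filename", "label")
  if (!all(need %in% names(idx))) {
    rlang::abort(sprintf("index CSV must have columns %s",
                         paste(need, collapse = ", ")))
  }
  if (nrow(idx) == 0L) {
    rlang::abort("no records in index CSV")
  }
  problems <- character(0)
  bad_label <- which(!idx$label %in% PLAQUE_CLASSES)
  for (r in bad_label) {
    problems <- c(problems, sprintf(
      "row %d: unknown label '%s' (allowed: %s)",
      r, idx$label[r], paste(PLAQUE_CLASSES, collapse = ", ")
    ))
  }
  idx$path <- file.path(image_dir, idx$filename)
  missing <- which(!file.exists(idx$path))
  for (r in missing) {
    problems <- c(problems, sprintf("row %d: missing file '%s'", r, idx$path[r]))
  }
  if (length(problems) > 0L) {
    rlang::abort(c("dataset failed to load:", problems))
  }
  images <- vector("list", nrow(idx))
  for (r in seq_len(nrow(idx))) {
    px <- tryCatch(read_gray(idx$path[r]), error = function(e) {
      rlang::abort(sprintf("row %d: %s", r, conditionMessage(e)))
    })
    if (normalize) px <- minmax_normalize(px)
    images[[r]] <- px
  }
  names(images) <- idx$id
  idx$h <- vapply(images, nrow, integer(1))
  idx$w <- vapply(images, ncol, integer(1))
  idx$label <- factor(idx$label, levels = PLAQUE_CLASSES)
  list(index = tibble::as_tibble(idx), images = images)
}
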