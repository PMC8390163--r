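#' Stratified k-fold assignment
#'
#' Partitions a labeled index into `folds` folds preserving class
#' proportions: within each class, records are shuffled (seeded) and
#' dealt round-robin, so per-fold class counts differ by at most one
#' from exact proportionality. Every record lands in exactly one fold.
#'
#' @param index Data frame with a `label` column (and any id columns).
#' @param folds Number of folds (>= 2).
#' @param seed Integer seed for the within-class shuffles.
#' @return The index as a tibble with an integer `fold` column in
#'   `1:folds`.
#' @examples
#' idx <- tibble::tibble(id = 1:15, label = rep(plaque_classes(), 5))
#' dplyr::count(stratified_kfold(idx, 5, seed = 1), fold, label)
#' @export
stratified_kfold <- function(index, folds = 5L, seed = 1L) {
  stopifnot(is.data.frame(index), "label" %in% names(index))
  folds <- as.integer(folds)
  if (folds < 2L) rlang::abort("`folds` must be at least 2")
  counts <- table(index$label)
  counts <- counts[counts > 0]
  if (any(counts < folds)) {
    small <- names(counts)[counts < folds]
    rlang::abort(sprintf(
      "class %s has fewer records than folds (%d)",
      paste(sprintf("'%s'", small), collapse = ", "), folds
    ))
  }
  index <- tibble::as_tibble(index)
  index$fold <- NA_integer_
  withr::with_seed(as.integer(seed), {
    for (cl in names(counts)) {
      rows <- which(as.character(index$label) == cl)
      rows <- rows[sample.int(length(rows))]
      index$fold[rows] <- rep_len(seq_len(folds), length(rows))
    }
  })
  index
}
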