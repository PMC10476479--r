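#' Gray image container
#'
#' A minimal container for a 2D grayscale image: an integer pixel matrix
#' (row-major, 0-based gray levels) together with the number of representable
#' gray levels `Z`.  Every pixel must lie in `[0, Z - 1]`.
#'
#' @param pixels Integer matrix of pixel intensities (rows x cols).
#' @param n_levels Number of representable gray levels `Z` (>= 2).
#'   Defaults to 256 (8-bit).
#' @return An object of class `gray_image` with fields `pixels` (integer
#'   matrix) and `n_levels`.
#' @examples
#' img <- gray_image(matrix(c(0L, 0L, 1L, 3L), 2, 2), n_levels = 4)
#' dim(img$pixels)
#' @export
gray_image <- function(pixels, n_levels = 256L) {
  if (!is.matrix(pixels)) {
    pixels <- as.matrix(pixels)
  }
  if (!is.numeric(pixels)) {
    abort_domain("`pixels` must be a numeric matrix")
  }
  n_levels <- as.integer(n_levels)
  if (length(n_levels) != 1L || is.na(n_levels) || n_levels < 2L) {
    abort_domain("`n_levels` must be a single integer >= 2")
  }
  if (nrow(pixels) < 1L || ncol(pixels) < 1L) {
    abort_domain("image must have at least one row and one column")
  }
  if (anyNA(pixels)) {
    abort_domain("pixel values must not be NA")
  }
  if (any(pixels != round(pixels))) {
    abort_domain("pixel values must be integers")
  }
  storage.mode(pixels) <- "integer"
  if (min(pixels) < 0L || max(pixels) > n_levels - 1L) {
    abort_domain(sprintf(
      "pixel values must lie in [0, %d]; observed range [%d, %d]",
      n_levels - 1L, min(pixels), max(pixels)
    ))
  }
  structure(
    list(pixels = pixels, n_levels = n_levels),
    class = "gray_image"
  )
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf(
    "<gray_image> %d x %d, Z = %d, range [%d, %d]\n",
    nrow(x$pixels), ncol(x$pixels), x$n_levels,
    min(x$pixels), max(x$pixels)
  ))
  invisible(x)
}

#' @export
dim.gray_image <- function(x) dim(x$pixels)

is_gray_image <- function(x) inherits(x, "gray_image")

#' Label map container
#'
#' Per-pixel class indices produced by threshold application.  Labels run
#' `0..m` for `m` thresholds; `NA` marks pixels left unassigned by the
#' `exclude-zero` dialect (see [apply_thresholds()]).
#'
#' @param labels Integer matrix of class indices in `[0, n_classes - 1]`
#'   (`NA` allowed).
#' @param n_classes Number of classes (`m + 1`).
#' @return An object of class `label_map` with fields `labels`, `n_classes`.
#' @export
label_map <- function(labels, n_classes) {
  if (!is.matrix(labels)) labels <- as.matrix(labels)
  n_classes <- as.integer(n_classes)
  if (n_classes < 1L) abort_domain("`n_classes` must be >= 1")
  storage.mode(labels) <- "integer"
  rng <- range(labels, na.rm = TRUE)
  if (!all(is.na(labels)) && (rng[1] < 0L || rng[2] > n_classes - 1L)) {
    abort_domain("labels must lie in [0, n_classes - 1]")
  }
  structure(
    list(labels = labels, n_classes = n_classes),
    class = "label_map"
  )
}

#' @export
print.label_map <- function(x, ...) {
  counts <- tabulate(x$labels + 1L, nbins = x$n_classes)
  cat(sprintf(
    "<label_map> %d x %d, %d classes (counts: %s)\n",
    nrow(x$labels), ncol(x$labels), x$n_classes,
    paste(counts, collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.label_map <- function(x) dim(x$labels)

is_label_map <- function(x) inherits(x, "label_map")
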