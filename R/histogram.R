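#' Normalized gray-level histogram
#'
#' Construct a normalized histogram directly from a probability vector.
#' `probs[o + 1]` is the fraction of pixels at gray level `o`; the vector
#' must be non-negative and sum to 1 (within 1e-12 before renormalization
#' is refused).
#'
#' @param probs Numeric vector of length `Z` of per-level fractions.
#' @param n_pixels Pixel count of the source image (may be `NA` when the
#'   histogram does not come from an image).
#' @return An object of class `gray_histogram` with fields `probs`,
#'   `n_pixels`, `n_levels`.
#' @seealso [compute_histogram()]
#' @export
gray_histogram <- function(probs, n_pixels = NA_integer_) {
  probs <- as.numeric(probs)
  if (length(probs) < 2L) abort_domain("histogram needs at least 2 levels")
  if (anyNA(probs) || any(probs < 0)) {
    abort_domain("histogram probabilities must be non-negative and not NA")
  }
  if (abs(sum(probs) - 1) > 1e-12) {
    abort_domain(sprintf(
      "histogram probabilities must sum to 1 (got %.15g)", sum(probs)
    ))
  }
  structure(
    list(probs = probs, n_pixels = n_pixels, n_levels = length(probs)),
    class = "gray_histogram"
  )
}

#' Compute the normalized histogram of a gray image
#'
#' `q_o` is the count of pixels at gray level `o` divided by the pixel
#' count `N * M`; the probabilities sum to exactly 1.
#'
#' @param image A [gray_image()].
#' @return A [gray_histogram()] of length `image$n_levels`.
#' @examples
#' img <- gray_image(matrix(c(0L, 0L, 1L, 3L), 2, 2), n_levels = 4)
#' compute_histogram(img)$probs  # 0.5 0.25 0 0.25
#' @export
compute_histogram <- function(image) {
  if (!is_gray_image(image)) abort_domain("`image` must be a gray_image")
  n <- length(image$pixels)
  counts <- tabulate(image$pixels + 1L, nbins = image$n_levels)
  gray_histogram(counts / n, n_pixels = n)
}

#' @export
print.gray_histogram <- function(x, ...) {
  nz <- sum(x$probs > 0)
  cat(sprintf(
    "<gray_histogram> Z = %d, %d nonzero levels, n_pixels = %s\n",
    x$n_levels, nz, format(x$n_pixels)
  ))
  invisible(x)
}

is_gray_histogram <- function(x) inherits(x, "gray_histogram")
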