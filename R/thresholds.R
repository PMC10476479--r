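#' Threshold vector
#'
#' A strictly increasing vector of integer cut points `u_1 < ... < u_m`,
#' each in `[1, Z - 1]`, partitioning the gray range into `m + 1` classes.
#'
#' @param cuts Integer vector of cut points.
#' @param n_levels Number of gray levels `Z` the cuts refer to.
#' @return Object of class `threshold_vector` with fields `cuts`,
#'   `n_levels`, `m`.
#' @export
threshold_vector <- function(cuts, n_levels = 256L) {
  cuts <- as.integer(cuts)
  n_levels <- as.integer(n_levels)
  if (length(cuts) < 1L || anyNA(cuts)) {
    abort_domain("`cuts` must be a non-empty integer vector")
  }
  if (any(diff(cuts) <= 0L)) {
    abort_domain("`cuts` must be strictly increasing")
  }
  if (cuts[1] < 1L || cuts[length(cuts)] > n_levels - 1L) {
    abort_domain(sprintf(
      "cuts must lie in [1, %d]; got [%d, %d]",
      n_levels - 1L, cuts[1], cuts[length(cuts)]
    ))
  }
  structure(
    list(cuts = cuts, n_levels = n_levels, m = length(cuts)),
    class = "threshold_vector"
  )
}

#' @export
print.threshold_vector <- function(x, ...) {
  cat(sprintf(
    "<threshold_vector> m = %d, cuts = (%s), Z = %d\n",
    x$m, paste(x$cuts, collapse = ", "), x$n_levels
  ))
  invisible(x)
}

is_threshold_vector <- function(x) inherits(x, "threshold_vector")

#' Apply a threshold vector to an image
#'
#' Assigns every pixel a class index in `0..m`.  Under the default
#' `"partition"` dialect, class `i` is the half-open interval
#' `[u_i, u_{i+1})` with sentinels `u_0 = 0` and `u_{m+1} = Z`, so for
#' `m = 1` a pixel below the cut is class 0 (black) and at or above it is
#' class 1 (white), and the classes totally partition the gray range.
#' The `"exclude-zero"` dialect is identical except that gray level 0 is
#' left unassigned (`NA` label): it mirrors criterion variants in which the
#' darkest level is excluded from the background class, and differs from
#' the partition dialect only at gray level 0.
#'
#' @param image A [gray_image()].
#' @param thresholds A [threshold_vector()] (or bare integer vector of cuts).
#' @param dialect `"partition"` (default, total partition) or
#'   `"exclude-zero"`.
#' @return A [label_map()] with `m + 1` classes.
#' @examples
#' img <- gray_image(matrix(c(10L, 200L, 100L, 30L), 2, 2))
#' apply_thresholds(img, threshold_vector(c(50L, 150L)))$labels
#' @export
apply_thresholds <- function(image, thresholds,
                             dialect = c("partition", "exclude-zero")) {
  dialect <- match.arg(dialect)
  if (!is_gray_image(image)) abort_domain("`image` must be a gray_image")
  if (!is_threshold_vector(thresholds)) {
    thresholds <- threshold_vector(thresholds, n_levels = image$n_levels)
  }
  if (thresholds$n_levels != image$n_levels) {
    abort_domain("threshold vector and image disagree on Z")
  }
  labs <- findInterval(image$pixels, thresholds$cuts)
  if (dialect == "exclude-zero") {
    labs[image$pixels == 0L] <- NA_integer_
  }
  dim(labs) <- dim(image$pixels)
  label_map(labs, n_classes = thresholds$m + 1L)
}

#' Render a label map to gray values
#'
#' `"indexed"` keeps the raw class indices; `"scaled"` maps class `i` to
#' `round(i * 255 / m)` for visual inspection (`NA` labels render as 0).
#'
#' @param labels A [label_map()].
#' @param mode `"indexed"` or `"scaled"`.
#' @return Integer matrix of rendered gray values.
#' @export
render_label_map <- function(labels, mode = c("indexed", "scaled")) {
  mode <- match.arg(mode)
  if (!is_label_map(labels)) abort_domain("`labels` must be a label_map")
  v <- labels$labels
  if (mode == "scaled") {
    m <- labels$n_classes - 1L
    v <- if (m == 0L) v * 0L else as.integer(round(v * (255 / m)))
    dim(v) <- dim(labels$labels)
  }
  v[is.na(v)] <- 0L
  v
}
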