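#' Tissue class for the synthetic phantom
#'
#' One region of the synthetic scene: a geometry painted at a mean gray
#' intensity.  Regions are painted in declaration order, later regions
#' overwriting earlier ones (e.g. tumor over liver over background), so
#' ground truth is unambiguous.
#'
#' @param name Label, e.g. `"background"`, `"liver"`, `"tumor"`,
#'   `"gallbladder"`.
#' @param geometry A list: `list(type = "full")` for the full field,
#'   `list(type = "ellipse", center = c(row, col), axes = c(a, b),
#'   rotation = radians)`, or `list(type = "disk", center = c(row, col),
#'   radius = r)`.  Coordinates are 1-based pixel centers.
#' @param mean_intensity Mean gray level of the region.
#' @param weight_sd_scale Multiplier on the phantom's `noise_sd` for this
#'   region (default 1).
#' @return Object of class `tissue_class`.
#' @export
tissue_class <- function(name, geometry, mean_intensity, weight_sd_scale = 1) {
  if (!is.list(geometry) || is.null(geometry$type) ||
      !geometry$type %in% c("full", "ellipse", "disk")) {
    abort_domain("geometry$type must be one of 'full', 'ellipse', 'disk'")
  }
  if (geometry$type == "ellipse" &&
      (length(geometry$center) != 2L || length(geometry$axes) != 2L)) {
    abort_domain("ellipse geometry needs center = c(row, col) and axes = c(a, b)")
  }
  if (geometry$type == "disk" &&
      (length(geometry$center) != 2L || is.null(geometry$radius))) {
    abort_domain("disk geometry needs center = c(row, col) and radius")
  }
  if (is.null(geometry$rotation)) geometry$rotation <- 0
  structure(
    list(
      name = as.character(name), geometry = geometry,
      mean_intensity = as.numeric(mean_intensity),
      weight_sd_scale = as.numeric(weight_sd_scale)
    ),
    class = "tissue_class"
  )
}

#' Phantom specification
#'
#' Parameterization of a synthetic abdominal-CT-like slice: image shape,
#' an ordered list of tissue classes with strictly increasing mean
#' intensities, an additive Gaussian noise level, and the gray resolution.
#' The phantom stands in for real CT slices in which liver parenchyma,
#' lesion and background occupy distinct (but noise-blurred) intensity
#' bands; it is the test substrate for threshold segmentation.
#'
#' @param shape `c(rows, cols)`.
#' @param classes List of [tissue_class()] objects, painted in order.
#' @param noise_sd Additive Gaussian noise standard deviation, in gray
#'   levels.
#' @param n_levels Gray resolution `Z`.
#' @param seed Default RNG seed used by [generate_phantom()].
#' @return Object of class `phantom_spec`.
#' @seealso [phantom_preset()] for the ready-made three-class liver scene.
#' @export
phantom_spec <- function(shape = c(256L, 256L), classes, noise_sd = 10,
                         n_levels = 256L, seed = 1L) {
  shape <- as.integer(shape)
  n_levels <- as.integer(n_levels)
  if (length(shape) != 2L || any(shape < 1L)) {
    abort_domain("`shape` must be c(rows, cols) with positive entries")
  }
  if (noise_sd < 0) abort_domain("`noise_sd` must be >= 0")
  if (!is.list(classes) || length(classes) < 1L ||
      !all(vapply(classes, inherits, logical(1), "tissue_class"))) {
    abort_domain("`classes` must be a non-empty list of tissue_class objects")
  }
  means <- vapply(classes, function(k) k$mean_intensity, numeric(1))
  if (any(diff(means) <= 0)) {
    abort_domain("class mean intensities must be strictly increasing")
  }
  if (means[1] < 0 || means[length(means)] > n_levels - 1L) {
    abort_domain(sprintf("class means must lie in [0, %d]", n_levels - 1L))
  }
  for (k in classes) {
    g <- k$geometry
    if (g$type == "ellipse") {
      if (any(g$center - max(g$axes) < 0.5) ||
          g$center[1] + max(g$axes) > shape[1] + 0.5 ||
          g$center[2] + max(g$axes) > shape[2] + 0.5) {
        abort_domain(sprintf("ellipse '%s' extends outside the image frame", k$name))
      }
    } else if (g$type == "disk") {
      if (any(g$center - g$radius < 0.5) ||
          g$center[1] + g$radius > shape[1] + 0.5 ||
          g$center[2] + g$radius > shape[2] + 0.5) {
        abort_domain(sprintf("disk '%s' extends outside the image frame", k$name))
      }
    }
  }
  structure(
    list(
      shape = shape, classes = classes, noise_sd = as.numeric(noise_sd),
      n_levels = n_levels, seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
}

#' Built-in phantom presets
#'
#' `"liver3"`: 256 x 256, Z = 256, background mean 40 (full field), liver
#' as a rotated ellipse at mean 120, tumor as a disk in the left lobe at
#' mean 200, additive Gaussian noise sd 10.  Adjacent means sit 8 noise
#' standard deviations apart, so a correct two-threshold segmentation
#' separates the classes almost perfectly.
#'
#' @param name Preset name (currently `"liver3"`).
#' @param seed Seed stored in the spec.
#' @return A [phantom_spec()].
#' @export
phantom_preset <- function(name = "liver3", seed = 1L) {
  switch(name,
    liver3 = phantom_spec(
      shape = c(256L, 256L),
      classes = list(
        tissue_class("background", list(type = "full"), 40),
        tissue_class("liver",
          list(type = "ellipse", center = c(130, 128), axes = c(92, 64),
               rotation = 0.35),
          120
        ),
        tissue_class("tumor",
          list(type = "disk", center = c(118, 92), radius = 24),
          200
        )
      ),
      noise_sd = 10, n_levels = 256L, seed = seed
    ),
    abort_domain(sprintf("unknown preset '%s'", name))
  )
}

# Paint the ground-truth label map (class index = position in spec$classes,
# 0-based), honouring declaration order.
paint_labels <- function(spec) {
  nr <- spec$shape[1]
  nc <- spec$shape[2]
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  labs <- matrix(NA_integer_, nr, nc)
  for (i in seq_along(spec$classes)) {
    g <- spec$classes[[i]]$geometry
    mask <- switch(g$type,
      full = matrix(TRUE, nr, nc),
      ellipse = {
        dr <- rows - g$center[1]
        dc <- cols - g$center[2]
        u <- dr * cos(g$rotation) + dc * sin(g$rotation)
        v <- -dr * sin(g$rotation) + dc * cos(g$rotation)
        (u / g$axes[1])^2 + (v / g$axes[2])^2 <= 1
      },
      disk = (rows - g$center[1])^2 + (cols - g$center[2])^2 <= g$radius^2
    )
    labs[mask] <- i - 1L
  }
  if (anyNA(labs)) {
    abort_domain("phantom geometry leaves pixels uncovered; first class should be full-field")
  }
  labs
}

#' Generate a synthetic phantom image with exact ground truth
#'
#' Paints the regions of `spec` in order, then adds per-pixel Gaussian
#' noise (`noise_sd * weight_sd_scale` per class), rounds and clips to
#' `[0, Z - 1]`.  A fixed seed yields an identical image on every call
#' (Mersenne-Twister stream).  If any two adjacent class means are closer
#' than four noise standard deviations, a separability warning is recorded
#' (and raised) but generation proceeds.
#'
#' @param spec A [phantom_spec()].
#' @param seed Seed overriding `spec$seed`.
#' @return List with `image` ([gray_image()]), `truth` ([label_map()]),
#'   `spec`, and `warnings` (character vector, possibly empty).
#' @examples
#' ph <- generate_phantom(phantom_preset("liver3"), seed = 7)
#' ph$image
#' @export
generate_phantom <- function(spec, seed = spec$seed) {
  if (!inherits(spec, "phantom_spec")) abort_domain("`spec` must be a phantom_spec")
  labs <- paint_labels(spec)
  means <- vapply(spec$classes, function(k) k$mean_intensity, numeric(1))
  scales <- vapply(spec$classes, function(k) k$weight_sd_scale, numeric(1))

  warnings <- character(0)
  if (spec$noise_sd > 0 && length(means) > 1L) {
    gaps <- diff(means)
    close <- gaps < 4 * spec$noise_sd
    if (any(close)) {
      msg <- sprintf(
        "class means %s are closer than 4 * noise_sd; classes may not be separable by thresholding",
        paste(which(close), collapse = ", ")
      )
      warnings <- c(warnings, msg)
      warning(msg, call. = FALSE)
    }
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister")

  vals <- means[labs + 1L]
  if (spec$noise_sd > 0) {
    vals <- vals + stats::rnorm(length(vals)) * spec$noise_sd * scales[labs + 1L]
  }
  vals <- round(vals)
  vals[vals < 0] <- 0
  vals[vals > spec$n_levels - 1L] <- spec$n_levels - 1L
  dim(vals) <- dim(labs)

  list(
    image = gray_image(vals, n_levels = spec$n_levels),
    truth = label_map(labs, n_classes = length(spec$classes)),
    spec = spec,
    warnings = warnings
  )
}

#' Analytic histogram model of a phantom
#'
#' The expected gray-level histogram: a mixture, over classes, of the
#' region's pixel fraction times a discretized Gaussian (integer rounding
#' bins) clipped to `[0, Z - 1]`.  The empirical histogram of a generated
#' phantom converges to this model as the pixel count grows; with
#' `noise_sd = 0` the mixture collapses to spikes at the class means.
#'
#' @param spec A [phantom_spec()].
#' @return A [gray_histogram()] with `n_pixels = prod(spec$shape)`.
#' @export
phantom_histogram_model <- function(spec) {
  if (!inherits(spec, "phantom_spec")) abort_domain("`spec` must be a phantom_spec")
  labs <- paint_labels(spec)
  Z <- spec$n_levels
  fractions <- tabulate(labs + 1L, nbins = length(spec$classes)) / length(labs)
  probs <- numeric(Z)
  o <- 0:(Z - 1)
  for (i in seq_along(spec$classes)) {
    mu <- spec$classes[[i]]$mean_intensity
    sd_i <- spec$noise_sd * spec$classes[[i]]$weight_sd_scale
    p <- if (sd_i <= 0) {
      v <- numeric(Z)
      v[min(max(round(mu), 0), Z - 1) + 1] <- 1
      v
    } else {
      # rounding bins (o - 0.5, o + 0.5]; clipping folds the tails into the
      # end levels
      upper <- stats::pnorm((o + 0.5 - mu) / sd_i)
      lower <- stats::pnorm((o - 0.5 - mu) / sd_i)
      v <- upper - lower
      v[1] <- upper[1]
      v[Z] <- 1 - lower[Z]
      v
    }
    probs <- probs + fractions[i] * p
  }
  gray_histogram(probs / sum(probs), n_pixels = prod(spec$shape))
}
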