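#' Read a grayscale image
#'
#' Reads an 8- or 16-bit PNG or TIFF (or one slice of a NIfTI volume) into
#' a [gray_image()].  Multi-channel inputs are refused unless
#' `convert_rgb = TRUE`, in which case Rec. 601 luminance
#' (0.299 R + 0.587 G + 0.114 B) is applied.  NIfTI slices are windowed to
#' `[0, Z - 1]` by an explicit linear window (`center`, `width`) before
#' quantization.
#'
#' @param path Input file.
#' @param format `"png"`, `"tiff"` or `"nifti"`; inferred from the file
#'   extension when `NULL`.
#' @param n_levels Gray resolution override; by default 256 for 8-bit and
#'   65536 for 16-bit sources.
#' @param convert_rgb Allow luminance conversion of multi-channel input.
#' @param slice Slice index for NIfTI volumes (third dimension).
#' @param window `c(center, width)` linear intensity window, required for
#'   NIfTI input.
#' @return A [gray_image()] with a `source` attribute recording provenance.
#' @export
read_gray_image <- function(path, format = NULL, n_levels = NULL,
                            convert_rgb = FALSE, slice = 1L, window = NULL) {
  if (!file.exists(path)) abort_format(sprintf("file not found: %s", path))
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(sub("\\.gz$", "", path))),
      png = "png", tif = "tiff", tiff = "tiff", nii = "nifti",
      abort_format(sprintf("cannot infer format of '%s'; pass `format`", path))
    )
  }
  img <- switch(format,
    png = {
      arr <- tryCatch(png::readPNG(path),
        error = function(e) abort_format(sprintf("unreadable PNG: %s", conditionMessage(e)))
      )
      decode_raster(arr, n_levels, convert_rgb, bits_hint = png_bits(arr))
    },
    tiff = {
      arr <- tryCatch(tiff::readTIFF(path, info = TRUE),
        error = function(e) abort_format(sprintf("unreadable TIFF: %s", conditionMessage(e)))
      )
      bits <- attr(arr, "bits.per.sample")
      decode_raster(arr, n_levels, convert_rgb,
        bits_hint = if (is.null(bits)) 8L else as.integer(bits)
      )
    },
    nifti = {
      if (is.null(window) || length(window) != 2L) {
        abort_format("NIfTI input needs `window = c(center, width)`")
      }
      vol <- tryCatch(RNifti::readNifti(path),
        error = function(e) abort_format(sprintf("unreadable NIfTI: %s", conditionMessage(e)))
      )
      sl <- if (length(dim(vol)) >= 3L) vol[, , slice] else vol[, , drop = TRUE]
      Z <- if (is.null(n_levels)) 256L else as.integer(n_levels)
      lo <- window[1] - window[2] / 2
      v <- (sl - lo) / window[2] * (Z - 1)
      v <- round(pmin(pmax(v, 0), Z - 1))
      gray_image(matrix(as.integer(v), nrow(sl), ncol(sl)), n_levels = Z)
    },
    abort_format(sprintf("unsupported format '%s'", format))
  )
  attr(img, "source") <- list(path = path, format = format)
  img
}

# The png package rescales to [0, 1] without reporting bit depth; treat the
# image as 8-bit if every sample sits on the 255-denominator lattice.
png_bits <- function(arr) {
  s <- arr[seq_len(min(length(arr), 4096L))]
  if (max(abs(s * 255 - round(s * 255))) < 1e-9) 8L else 16L
}

decode_raster <- function(arr, n_levels, convert_rgb, bits_hint) {
  if (length(dim(arr)) == 3L) {
    ch <- dim(arr)[3]
    if (ch == 2L) {
      arr <- arr[, , 1]  # gray + alpha
    } else if (ch %in% c(3L, 4L)) {
      if (!convert_rgb) {
        abort_format("multi-channel image; pass convert_rgb = TRUE for luminance conversion")
      }
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      abort_format(sprintf("unsupported channel count %d", ch))
    }
  }
  Z <- if (!is.null(n_levels)) as.integer(n_levels) else if (bits_hint <= 8L) 256L else 65536L
  px <- round(arr * (Z - 1))
  gray_image(matrix(as.integer(px), nrow(arr), ncol(arr)), n_levels = Z)
}

#' Write a grayscale image to PNG or TIFF
#'
#' 8-bit output for `Z <= 256`, 16-bit otherwise.  Round-trips exactly
#' through [read_gray_image()].
#'
#' @param image A [gray_image()].
#' @param path Output file; extension selects PNG or TIFF.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path) {
  if (!is_gray_image(image)) abort_domain("`image` must be a gray_image")
  denom <- if (image$n_levels <= 256L) 255 else 65535
  if (image$n_levels - 1L > denom) {
    abort_domain("n_levels exceeds 16-bit output range")
  }
  arr <- image$pixels / denom
  ext <- tolower(tools::file_ext(path))
  ok <- switch(ext,
    png = png::writePNG(arr, path),
    tif = ,
    tiff = tiff::writeTIFF(arr, path,
      bits.per.sample = if (denom == 255) 8L else 16L
    ),
    abort_format(sprintf("unsupported output extension '.%s'", ext))
  )
  invisible(path)
}

#' Write a label map to disk
#'
#' `"indexed"` mode writes raw class indices (exact round trip through
#' [read_label_map()]); `"scaled"` mode writes `round(i * 255 / m)` for
#' visual inspection.
#'
#' @param labels A [label_map()].
#' @param path Output PNG/TIFF path.
#' @param mode `"indexed"` or `"scaled"`.
#' @return `path`, invisibly.
#' @export
write_label_map <- function(labels, path, mode = c("indexed", "scaled")) {
  mode <- match.arg(mode)
  v <- render_label_map(labels, mode)
  write_gray_image(gray_image(v, n_levels = 256L), path)
}

#' Read an indexed label map written by [write_label_map()]
#'
#' @param path Indexed-mode PNG/TIFF file.
#' @param n_classes Number of classes encoded in the file.
#' @return A [label_map()].
#' @export
read_label_map <- function(path, n_classes) {
  img <- read_gray_image(path)
  label_map(img$pixels, n_classes = n_classes)
}
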