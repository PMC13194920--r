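#' Instance label masks
#'
#' A `label_mask` is a 2D integer matrix in which 0 is background and each
#' positive integer identifies one cell instance, together with the pixel size
#' in micrometres per pixel. Labels need not be consecutive. Coordinates are
#' 0-based `(row, column)` throughout the package.
#'
#' @param labels integer matrix, values >= 0.
#' @param pixel_size isotropic pixel size in um/px (default 0.065, the target
#'   resolution of the rescaled simulations and of typical 100x widefield
#'   data).
#' @param source_path provenance string, kept for bookkeeping.
#' @return A `label_mask` object.
#' @export
label_mask <- function(labels, pixel_size = 0.065, source_path = NA_character_) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  if (any(!is.finite(labels)) || any(labels < 0))
    stop("label values must be finite and >= 0")
  if (any(labels != round(labels)))
    stop("label values must be integers")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 || pixel_size <= 0)
    stop("`pixel_size` must be a single positive number")
  storage.mode(labels) <- "integer"
  structure(
    list(labels = labels, pixel_size = pixel_size, source_path = source_path),
    class = "label_mask"
  )
}

#' @export
print.label_mask <- function(x, ...) {
  labs <- mask_labels(x)
  cat(sprintf("label_mask: %d x %d px, %.4g um/px, %d instance(s)\n",
              nrow(x$labels), ncol(x$labels), x$pixel_size, length(labs)))
  invisible(x)
}

#' Instance labels present in a mask
#'
#' @param mask a `label_mask`.
#' @return Sorted integer vector of positive labels present.
#' @export
mask_labels <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  sort(unique(mask$labels[mask$labels > 0L]))
}

#' Read an instance label mask from TIFF or PNG
#'
#' Pixel values are read as stored (no intensity rescaling) and must be
#' non-negative integers; 0 is background.
#'
#' @param path path to an 8/16/32-bit single-plane TIFF or PNG file.
#' @param pixel_size pixel size in um/px.
#' @return A [label_mask()].
#' @export
read_label_mask <- function(path, pixel_size = 0.065) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, as.is = TRUE, all = TRUE)
    norm <- tiff::readTIFF(path, all = TRUE)
    if (is.list(img)) {
      if (length(img) != 1)
        stop("expected a single-plane TIFF, got ", length(img), " planes")
      img <- img[[1]]; norm <- norm[[1]]
    }
    bits <- attr(tiff::readTIFF(path, info = TRUE), "info")$bits.per.sample
    if (is.null(bits)) bits <- 16L
    # float TIFFs reinterpret to garbage under as.is; catch the mismatch
    if (!isTRUE(all.equal(as.numeric(img),
                          as.numeric(round(norm * (2^bits - 1))),
                          tolerance = 1e-6)))
      stop("non-integer pixel data in ", path, ": not a label image")
  } else if (ext == "png") {
    info <- attr(png::readPNG(path, info = TRUE), "info")
    img <- png::readPNG(path)
    depth <- if (!is.null(info$bit.depth)) info$bit.depth else 8L
    img <- img * (2^depth - 1)
  } else {
    stop("unsupported mask format: .", ext, " (use TIFF or PNG)")
  }
  if (length(dim(img)) == 3) {
    if (dim(img)[3] == 1) img <- img[, , 1] else
      stop("expected a single-channel image, got ", dim(img)[3], " channels")
  }
  if (any(abs(img - round(img)) > 1e-6))
    stop("non-integer pixel data in ", path, ": not a label image")
  label_mask(matrix(as.integer(round(img)), nrow(img), ncol(img)),
             pixel_size = pixel_size, source_path = path)
}

#' Write a label mask as a 16-bit TIFF
#'
#' @param mask a `label_mask` with labels < 65536.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  if (max(mask$labels) > 65535L) stop("labels exceed 16-bit range")
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Remove instances touching the image border
#'
#' Any instance with at least one pixel on the first/last row or column is
#' removed (set to background); interior instances are unchanged. This is the
#' standard curation step that drops truncated cells at image edges.
#'
#' @param mask a `label_mask`.
#' @return A `label_mask` with border-touching instances removed.
#' @export
filter_border_labels <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  m <- mask$labels
  border <- unique(c(m[1, ], m[nrow(m), ], m[, 1], m[, ncol(m)]))
  border <- border[border > 0L]
  if (length(border)) m[m %in% border] <- 0L
  label_mask(m, pixel_size = mask$pixel_size, source_path = mask$source_path)
}

#' Labels of instances that touch the image border
#'
#' @param mask a `label_mask`.
#' @return Integer vector of border-touching labels (possibly empty).
#' @export
border_labels <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  m <- mask$labels
  border <- unique(c(m[1, ], m[nrow(m), ], m[, 1], m[, ncol(m)]))
  sort(border[border > 0L])
}
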