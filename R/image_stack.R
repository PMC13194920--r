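#' Intensity image stacks
#'
#' An ordered list of same-shape 2D intensity planes (z order), with pixel
#' size and optional z spacing.
#'
#' @param planes list of numeric matrices, all the same shape.
#' @param pixel_size um/px.
#' @param z_spacing plane-to-plane spacing in um, or `NA` if unknown.
#' @return An `image_stack` object.
#' @export
image_stack <- function(planes, pixel_size = 0.065, z_spacing = NA_real_) {
  if (!is.list(planes) || length(planes) < 1)
    stop("`planes` must be a nonempty list of matrices")
  dims <- lapply(planes, dim)
  if (any(vapply(dims, is.null, logical(1))) ||
      length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1)
    stop("all planes must be matrices of the same shape")
  if (any(!vapply(planes, function(p) all(is.finite(p)), logical(1))))
    stop("plane intensities must be finite")
  structure(list(planes = planes, pixel_size = pixel_size,
                 z_spacing = z_spacing),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$planes[[1]])
  cat(sprintf("image_stack: %d plane(s) of %d x %d px, %.4g um/px\n",
              length(x$planes), d[1], d[2], x$pixel_size))
  invisible(x)
}

#' Read a multi-page TIFF as an image stack
#'
#' Plane order in the file is taken as z order.
#'
#' @param path multi-page TIFF path.
#' @param pixel_size um/px.
#' @param z_spacing um between planes (optional).
#' @return An [image_stack()].
#' @export
read_image_stack <- function(path, pixel_size = 0.065, z_spacing = NA_real_) {
  img <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(img)) img <- list(img)
  img <- lapply(img, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    p
  })
  image_stack(img, pixel_size = pixel_size, z_spacing = z_spacing)
}

#' Project a z-stack onto a single plane
#'
#' Per-pixel reduction across planes. Intensities are used raw; any
#' normalization is left to the caller. `sum` equals plane count times `mean`
#' elementwise.
#'
#' @param stack an [image_stack()] or a list of matrices.
#' @param mode one of `"max"`, `"mean"`, `"sum"`.
#' @return A matrix with the shape of one plane.
#' @export
project_stack <- function(stack, mode = c("max", "mean", "sum")) {
  mode <- match.arg(mode)
  planes <- if (inherits(stack, "image_stack")) stack$planes else stack
  if (!is.list(planes) || length(planes) < 1) stop("empty stack")
  switch(mode,
    max  = Reduce(pmax, planes),
    sum  = Reduce(`+`, planes),
    mean = Reduce(`+`, planes) / length(planes)
  )
}
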