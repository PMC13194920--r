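#' Euclidean distance transform of one instance
#'
#' For each pixel of the chosen instance, the exact Euclidean distance (in
#' pixels) to the nearest pixel not belonging to the instance; 0 elsewhere.
#' Along the skeleton these values are the local cell radius. Values are used
#' raw, with no half-pixel boundary adjustment.
#'
#' @param mask a [label_mask()].
#' @param label instance id present in the mask.
#' @return Numeric matrix of the mask's shape (the radius field).
#' @export
compute_radius_field <- function(mask, label) {
  stopifnot(inherits(mask, "label_mask"))
  inst <- mask$labels == label
  if (!any(inst)) stop("label ", label, " not present in mask")
  d <- EBImage::distmap(matrix(as.numeric(inst), nrow(inst), ncol(inst)))
  matrix(as.numeric(d), nrow(inst), ncol(inst))
}

# Distance transform of a plain binary matrix (internal fast path; treats
# pixels beyond the image edge as background via 1-pixel zero padding).
binary_radius_field <- function(bin) {
  nr <- nrow(bin); nc <- ncol(bin)
  padded <- matrix(0, nr + 2L, nc + 2L)
  padded[2:(nr + 1L), 2:(nc + 1L)] <- as.numeric(bin != 0)
  d <- EBImage::distmap(padded)
  matrix(as.numeric(d), nr + 2L, nc + 2L)[2:(nr + 1L), 2:(nc + 1L)]
}

# Bilinear interpolation of matrix M at fractional (row, col) positions
# (1-based). Clamped to the valid interpolation domain.
bilinear_at <- function(M, r, c) {
  r0 <- pmin(pmax(floor(r), 1), nrow(M) - 1L)
  c0 <- pmin(pmax(floor(c), 1), ncol(M) - 1L)
  fr <- r - r0; fc <- c - c0
  M[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    M[cbind(r0 + 1L, c0)] * fr * (1 - fc) +
    M[cbind(r0, c0 + 1L)] * (1 - fr) * fc +
    M[cbind(r0 + 1L, c0 + 1L)] * fr * fc
}
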