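#' Shape descriptors of a mask region
#'
#' Cross-sectional (projected) area, convex hull area, eccentricity and
#' solidity, computed directly from the binary region. The convex hull area
#' counts the pixels whose centers fall inside (or on) the convex hull of the
#' region's pixel centers, so `solidity = area / hull_area` is exactly 1 for
#' convex regions. Eccentricity comes from the second central moments of the
#' pixel centers (eccentricity of the ellipse with the same moments).
#'
#' @param region logical/0-1 matrix, nonempty.
#' @param pixel_size um/px.
#' @return list with `cross_section_um2`, `convex_hull_um2`, `eccentricity`
#'   (in `[0, 1)`), `solidity` (in `(0, 1]`).
#' @export
compute_shape_descriptors <- function(region, pixel_size = 0.065) {
  pts <- which(region != 0, arr.ind = TRUE)
  n <- nrow(pts)
  if (n == 0) stop("empty region")
  area_px <- n

  # convex hull area as a pixel count inside the hull polygon
  hull_px <- if (n <= 2) n else {
    h <- grDevices::chull(pts[, 1], pts[, 2])
    poly <- pts[h, , drop = FALSE]
    if (nrow(poly) <= 2) n else {
      rr <- range(pts[, 1]); cc <- range(pts[, 2])
      grid <- as.matrix(expand.grid(r = rr[1]:rr[2], c = cc[1]:cc[2]))
      sum(points_in_convex_polygon(grid, poly))
    }
  }
  hull_px <- max(hull_px, area_px)  # guard against grid-edge ties

  # second central moments of the pixel centers
  mu_r <- mean(pts[, 1]); mu_c <- mean(pts[, 2])
  dr <- pts[, 1] - mu_r; dc <- pts[, 2] - mu_c
  m20 <- mean(dr^2); m02 <- mean(dc^2); m11 <- mean(dr * dc)
  common <- sqrt((m20 - m02)^2 + 4 * m11^2)
  l1 <- (m20 + m02 + common) / 2
  l2 <- (m20 + m02 - common) / 2
  ecc <- if (l1 <= 0) 0 else sqrt(pmax(0, 1 - l2 / l1))

  list(
    cross_section_um2 = area_px * pixel_size^2,
    convex_hull_um2 = hull_px * pixel_size^2,
    eccentricity = min(ecc, 1 - 1e-12),
    solidity = area_px / hull_px
  )
}

# Which points lie inside or on a convex polygon (vertices in hull order)?
points_in_convex_polygon <- function(points, poly, tol = 1e-9) {
  nv <- nrow(poly)
  inside <- rep(TRUE, nrow(points))
  # orientation of the polygon
  or <- 0
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1 else i + 1
    k <- if (j == nv) 1 else j + 1
    or <- or + (poly[j, 1] - poly[i, 1]) * (poly[k, 2] - poly[j, 2]) -
               (poly[j, 2] - poly[i, 2]) * (poly[k, 1] - poly[j, 1])
  }
  s <- if (or >= 0) 1 else -1
  for (i in seq_len(nv)) {
    j <- if (i == nv) 1 else i + 1
    cross <- (poly[j, 1] - poly[i, 1]) * (points[, 2] - poly[i, 2]) -
             (poly[j, 2] - poly[i, 2]) * (points[, 1] - poly[i, 1])
    inside <- inside & (s * cross >= -tol)
  }
  inside
}

#' Sample an intensity profile along a line
#'
#' Bilinear interpolation of `length_px` samples at unit spacing along a line
#' centered at `center` with direction `direction`. Used e.g. to read the
#' double-peaked membrane signal along a short line perpendicular to a cell's
#' long axis.
#'
#' @param image numeric matrix.
#' @param center (row, col) of the line center (1-based, may be fractional).
#' @param direction direction vector (normalized internally).
#' @param length_px number of samples (default 24).
#' @param norm_max optional scalar; samples are divided by it (use the
#'   maximum across a set of profiles to normalize jointly).
#' @return Numeric vector of `length_px` samples. Errors if the line leaves
#'   the image.
#' @export
extract_intensity_profile <- function(image, center, direction,
                                      length_px = 24, norm_max = NULL) {
  if (length_px < 1) stop("`length_px` must be >= 1")
  d <- direction / sqrt(sum(direction^2))
  offs <- seq_len(length_px) - (length_px + 1) / 2
  rr <- center[1] + offs * d[1]
  cc <- center[2] + offs * d[2]
  if (any(rr < 1 | rr > nrow(image) | cc < 1 | cc > ncol(image)))
    stop("profile line exits the image")
  out <- bilinear_at(image, rr, cc)
  if (!is.null(norm_max)) out <- out / norm_max
  out
}
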