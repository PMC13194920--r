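#' @importFrom stats approx median quantile setNames
NULL

# Shift a matrix by (dr, dc), zero-filling exposed cells.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 - dr):min(nr, nr - dr)
  cs <- max(1, 1 - dc):min(nc, nc - dc)
  out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

#' One-pixel-wide skeleton of a binary region by morphological thinning
#'
#' Two-subiteration parallel thinning (Lam, Lee & Suen). Iteratively deletes
#' boundary pixels whose removal preserves connectivity until the image is
#' stable, leaving an 8-connected, unit-width centerline contained in the
#' region. Diagonal strokes are preserved in both diagonal directions, which
#' the classic Zhang-Suen scheme does not guarantee. The topological medial
#' axis is deliberately not used: it over-branches on noisy rod masks.
#'
#' @param region logical or 0/1 matrix; nonzero pixels form the region.
#' @return Integer 0/1 matrix of the same shape with the skeleton as 1s. Tiny
#'   regions may reduce to one or two pixels; callers flag those degenerate.
#' @export
skeletonize_mask <- function(region) {
  img <- matrix(as.integer(region != 0), nrow(region), ncol(region))
  if (!any(img == 1L)) return(img)
  # neighbours x1..x8 counterclockwise from east:
  # E, NE, N, NW, W, SW, S, SE (rows grow downward, so "N" is row - 1)
  offs <- list(c(0, 1), c(-1, 1), c(-1, 0), c(-1, -1),
               c(0, -1), c(1, -1), c(1, 0), c(1, 1))
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      x <- lapply(offs, function(o) shift_mat(img, o[1], o[2]))
      XH <- matrix(0L, nrow(img), ncol(img))   # Hilditch crossing number
      n1 <- n2 <- XH
      for (i in 1:4) {
        b1 <- x[[2 * i - 1]]; b2 <- x[[2 * i]]
        b3 <- x[[if (i == 4) 1 else 2 * i + 1]]
        XH <- XH + (b1 == 0L & (b2 == 1L | b3 == 1L))
        n1 <- n1 + pmax(b1, b2)
        n2 <- n2 + pmax(b2, b3)
      }
      mn <- pmin(n1, n2)
      keep_shape <- img == 1L & XH == 1L & mn >= 2L & mn <= 3L
      g3 <- if (sub == 1)
        (pmax(x[[2]], x[[3]], 1L - x[[8]]) * x[[1]]) == 0L
      else
        (pmax(x[[6]], x[[7]], 1L - x[[4]]) * x[[5]]) == 0L
      del <- keep_shape & g3
      if (any(del)) { img[del] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  img
}
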