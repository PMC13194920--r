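#' Centerline paths
#'
#' An ordered centerline with one local radius per point. The spherocylinder
#' size formulas live on this object: with successive Euclidean steps
#' `d(i, i+1)`, per-point radii `r_c`, cap radii `r_s1 = r_c[1]`,
#' `r_s2 = r_c[n]` and slab height `h` (1 px),
#' \deqn{L = r_{s1} + r_{s2} + \sum_i d(i, i+1)}
#' \deqn{\bar w = (2/n) \sum_i r_{ci}}
#' \deqn{S = 2\pi (r_{s1}^2 + r_{s2}^2 + h \sum_i r_{ci})}
#' \deqn{V = \pi (\tfrac{2}{3} r_{s1}^3 + \tfrac{2}{3} r_{s2}^3 + h \sum_i r_{ci}^2)}
#'
#' @param points numeric matrix of ordered (row, col) coordinates in pixels.
#' @param radii positive per-point radii in pixels, same length as rows of
#'   `points`.
#' @return A `centerline_path` object.
#' @export
centerline_path <- function(points, radii) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2)
  if (nrow(points) != length(radii))
    stop("`radii` must have one value per path point")
  if (nrow(points) < 1) stop("empty path")
  if (any(!is.finite(radii)) || any(radii <= 0))
    stop("radii must be positive and finite")
  structure(list(points = points, radii = as.numeric(radii)),
            class = "centerline_path")
}

#' @export
print.centerline_path <- function(x, ...) {
  cat(sprintf("centerline_path: %d point(s), radii %.2f-%.2f px\n",
              nrow(x$points), min(x$radii), max(x$radii)))
  invisible(x)
}

#' Spherocylinder metrics of a centerline path
#'
#' Applies the length/width/surface/volume formulas (see [centerline_path()])
#' to a path, in pixel units, then scales by `pixel_size`: lengths by
#' `pixel_size`, areas by its square, volumes by its cube. The slab height
#' `h` is one pixel.
#'
#' @param path a [centerline_path()].
#' @param pixel_size um/px.
#' @return A `cell_measurement`: list with `length_um`, `mean_width_um`,
#'   `width_profile_um` (ordered, `2 * r_c`), `surface_um2`, `volume_um3`,
#'   and logical flags `branched`, `degenerate`, `border_touching` (all
#'   `FALSE` here; [measure_cell()] sets them).
#' @export
measure_path <- function(path, pixel_size = 0.065) {
  stopifnot(inherits(path, "centerline_path"))
  p <- path$points
  rc <- path$radii
  n <- length(rc)
  rs1 <- rc[1]; rs2 <- rc[n]
  steps <- if (n > 1) sqrt(rowSums((p[-1, , drop = FALSE] -
                                    p[-n, , drop = FALSE])^2)) else numeric(0)
  h <- 1
  L <- rs1 + rs2 + sum(steps)
  wbar <- (2 / n) * sum(rc)
  S <- 2 * pi * (rs1^2 + rs2^2 + h * sum(rc))
  V <- pi * ((2 / 3) * rs1^3 + (2 / 3) * rs2^3 + h * sum(rc^2))
  structure(list(
    cell_label = NA_integer_,
    length_um = L * pixel_size,
    mean_width_um = wbar * pixel_size,
    width_profile_um = 2 * rc * pixel_size,
    surface_um2 = S * pixel_size^2,
    volume_um3 = V * pixel_size^3,
    branched = FALSE, degenerate = FALSE, border_touching = FALSE
  ), class = "cell_measurement")
}

#' @export
print.cell_measurement <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat(sprintf("cell_measurement (degenerate): width %.3f um\n",
                x$mean_width_um))
  } else {
    cat(sprintf(
      "cell_measurement: L %.3f um, w %.3f um, S %.3f um^2, V %.3f um^3%s\n",
      x$length_um, x$mean_width_um, x$surface_um2, x$volume_um3,
      if (isTRUE(x$branched)) " (branched)" else ""))
  }
  invisible(x)
}

# Moving-average smoothing of an ordered pixel path. The window shrinks
# symmetrically near the ends so endpoints stay fixed.
smooth_path <- function(P, window) {
  n <- nrow(P)
  if (window < 3 || n < 5) return(P)
  half <- floor(window / 2)
  out <- P
  for (i in seq_len(n)) {
    h <- min(half, i - 1, n - i)
    if (h > 0) out[i, ] <- colMeans(P[(i - h):(i + h), , drop = FALSE])
  }
  out
}

# Resample a polyline at (approximately) unit arc-length spacing.
resample_unit <- function(P) {
  n <- nrow(P)
  if (n < 2) return(P)
  d <- sqrt(rowSums((P[-1, , drop = FALSE] - P[-n, , drop = FALSE])^2))
  s <- c(0, cumsum(d))
  len <- s[n]
  if (len < 1) return(P[c(1, n), , drop = FALSE])
  ss <- seq(0, len, length.out = max(2, round(len) + 1))
  cbind(approx(s, P[, 1], ss)$y, approx(s, P[, 2], ss)$y)
}

# Axial extent of the mask beyond point `e` along unit tangent `t`:
# the largest projection of any instance pixel onto `t` within a forward
# cone (guards against picking up the far side of strongly curved cells).
tip_extent <- function(inst_pts, e, t, r_ref) {
  v <- sweep(inst_pts, 2, e)
  fwd <- as.numeric(v %*% t)
  perp <- abs(v[, 1] * (-t[2]) + v[, 2] * t[1])
  keep <- fwd >= -0.5 & perp <= pmax(fwd, r_ref)
  if (!any(keep)) return(r_ref)
  max(fwd[keep])
}

# Construct the calibrated centerline path for one candidate pixel path.
# Steps: smooth + unit-resample the raw skeleton path; sample the radius
# profile from the distance transform; robust cap radii from end-window
# medians; infer the cap junctions from the axial tip extents and
# trim/extend the profile to span exactly the cylindrical part; rescale the
# profile so the spherocylinder footprint matches the instance pixel area;
# emit one point per slab so the n-point sums are midpoint Riemann sums.
build_measurement_path <- function(raw_path, dmap, inst_pts, area_px) {
  P <- raw_path
  r_raw <- bilinear_at(dmap, P[, 1], P[, 2])
  rbar <- mean(r_raw)
  P3 <- resample_unit(smooth_path(P, 2 * round(rbar) + 1))
  np <- nrow(P3)
  rc <- bilinear_at(dmap, P3[, 1], P3[, 2])
  k <- max(2, min(np, round(rbar)))
  t1 <- P3[1, ] - P3[k, ]
  t2 <- P3[np, ] - P3[np - k + 1, ]
  n1 <- sqrt(sum(t1^2)); n2 <- sqrt(sum(t2^2))
  if (n1 == 0 || n2 == 0) { # fully folded path; fall back to raw endpoints
    t1 <- c(1, 0); t2 <- c(-1, 0); n1 <- n2 <- 1
  }
  t1 <- t1 / n1; t2 <- t2 / n2
  m <- max(2, min(np, round(1.5 * rbar)))
  rs1 <- median(rc[1:m]); rs2 <- median(rc[(np - m + 1):np])
  a1 <- tip_extent(inst_pts, P3[1, ], t1, rs1)
  a2 <- tip_extent(inst_pts, P3[np, ], t2, rs2)

  # trim/extend the radius profile to the cap junctions
  adjust <- function(rcvec, excess, rs, from_start) {
    if (excess < -0.5) {
      kk <- min(length(rcvec) - 2, round(-excess))
      if (kk > 0)
        rcvec <- if (from_start) rcvec[-seq_len(kk)]
                 else rcvec[seq_len(length(rcvec) - kk)]
    } else if (excess > 0.5) {
      add <- rep(rs, round(excess))
      rcvec <- if (from_start) c(add, rcvec) else c(rcvec, add)
    }
    rcvec
  }
  rc2 <- adjust(rc, a1 - rs1, rs1, TRUE)
  rc2 <- adjust(rc2, a2 - rs2, rs2, FALSE)
  npath <- length(rc2)

  # footprint calibration: 2h*sum(r) (trapezoid) + half-disk caps = pixel area
  nsl <- max(2, npath - 1)
  rcS <- approx(seq_len(npath), rc2, seq(1, npath, length.out = nsl))$y
  cyl <- 2 * sum(rcS) * (npath - 1) / nsl
  caps <- (pi / 2) * (rs1^2 + rs2^2)
  gam <- 1
  for (it in 1:6) {
    f <- gam * cyl + gam^2 * caps - area_px
    gam <- gam - f / (cyl + 2 * gam * caps)
  }
  if (!is.finite(gam) || gam <= 0 || abs(gam - 1) > 0.5) gam <- 1
  rcS <- gam * rcS; rs1 <- gam * rs1; rs2 <- gam * rs2
  rcS[1] <- rs1; rcS[nsl] <- rs2
  rcS <- pmax(rcS, 1e-6)

  # geometry of the final path: nsl points spanning the cylinder part, so
  # total step length is (npath - 1) and there is one point per unit slab
  axis <- cbind(approx(seq_len(np), P3[, 1], seq(1, np, length.out = nsl))$y,
                approx(seq_len(np), P3[, 2], seq(1, np, length.out = nsl))$y)
  # stretch the resampled axis so its chord sum equals the junction span
  target <- npath - 1
  dd <- sqrt(rowSums((axis[-1, , drop = FALSE] -
                      axis[-nsl, , drop = FALSE])^2))
  tot <- sum(dd)
  if (tot > 0) {
    ctr <- colMeans(axis)
    axis <- sweep(axis, 2, ctr) * (target / tot)
    axis <- sweep(axis, 2, ctr, `+`)
  }
  centerline_path(axis, rcS)
}

#' Measure one cell instance of a label mask
#'
#' Orchestrates radius field, skeletonization, skeleton-graph construction,
#' candidate-path enumeration and per-path measurement. Unbranched skeletons
#' give the single candidate's metrics. Branched skeletons give the
#' per-metric median across all endpoint-pair candidate paths (median of an
#' even count is the mean of the two middle values) and set the `branched`
#' flag. Skeletons of two pixels or fewer are degenerate: the width is
#' reported as twice the maximum radius and the other metrics are `NA`.
#' Instances split into several connected components are measured on the
#' largest component with a warning and `multi_component = TRUE`.
#'
#' @param mask a [label_mask()].
#' @param label instance id.
#' @param pixel_size um/px; defaults to the mask's.
#' @return A `cell_measurement` (see [measure_path()]) with flags set, plus
#'   `n_candidates` and `multi_component`.
#' @export
measure_cell <- function(mask, label, pixel_size = NULL) {
  stopifnot(inherits(mask, "label_mask"))
  if (is.null(pixel_size)) pixel_size <- mask$pixel_size
  inst <- mask$labels == label
  if (!any(inst)) stop("label ", label, " not present in mask")
  on_border <- label %in% border_labels(mask)

  # crop to a padded bounding box (pad guarantees background all around)
  rr <- range(which(rowSums(inst) > 0))
  cc <- range(which(colSums(inst) > 0))
  bin <- matrix(FALSE, rr[2] - rr[1] + 3L, cc[2] - cc[1] + 3L)
  bin[2:(nrow(bin) - 1L), 2:(ncol(bin) - 1L)] <-
    inst[rr[1]:rr[2], cc[1]:cc[2]]

  multi <- FALSE
  comps <- EBImage::bwlabel(matrix(as.numeric(bin), nrow(bin), ncol(bin)))
  ncomp <- max(comps)
  if (ncomp > 1) {
    warning("instance ", label, " has ", ncomp,
            " connected components; measuring the largest")
    sizes <- tabulate(comps[comps > 0], nbins = ncomp)
    bin <- comps == which.max(sizes)
    multi <- TRUE
  }

  dmap <- binary_radius_field(bin)
  skel <- skeletonize_mask(bin)
  pts <- which(skel == 1L, arr.ind = TRUE)
  degenerate_result <- function() {
    structure(list(
      cell_label = label,
      length_um = NA_real_,
      mean_width_um = 2 * max(dmap) * pixel_size,
      width_profile_um = numeric(0),
      surface_um2 = NA_real_, volume_um3 = NA_real_,
      branched = FALSE, degenerate = TRUE, border_touching = on_border,
      n_candidates = 0L, multi_component = multi
    ), class = "cell_measurement")
  }
  if (nrow(pts) <= 2) return(degenerate_result())

  sg <- build_skeleton_graph(pts)
  paths <- enumerate_candidate_paths(sg, instance = label)
  area_px <- sum(bin)
  inst_pts <- which(bin, arr.ind = TRUE)
  meas <- lapply(paths, function(P) {
    if (nrow(P) <= 2) return(NULL)
    measure_path(build_measurement_path(P, dmap, inst_pts, area_px),
                 pixel_size)
  })
  meas <- Filter(Negate(is.null), meas)
  if (!length(meas)) return(degenerate_result())

  if (length(meas) == 1) {
    out <- meas[[1]]
  } else {
    fields <- c("length_um", "mean_width_um", "surface_um2", "volume_um3")
    med <- lapply(fields, function(f)
      median(vapply(meas, `[[`, numeric(1), f)))
    names(med) <- fields
    # keep the width profile of the path whose length is closest to the median
    lens <- vapply(meas, `[[`, numeric(1), "length_um")
    rep_path <- meas[[which.min(abs(lens - med$length_um))]]
    out <- rep_path
    out[fields] <- med
    out$branched <- TRUE
  }
  out$cell_label <- label
  out$border_touching <- on_border
  out$n_candidates <- length(meas)
  out$multi_component <- multi
  out
}

#' Measure every instance of a label mask
#'
#' Runs [measure_cell()] and [compute_shape_descriptors()] on each instance
#' and assembles the standard measurement table.
#'
#' @param mask a [label_mask()].
#' @param image_id identifier written to the `image_id` column.
#' @param drop_border drop border-touching instances first (default FALSE;
#'   they are flagged either way).
#' @param pixel_size um/px; defaults to the mask's.
#' @return data.frame, one row per cell, in the standard column order. The
#'   per-cell width profiles are attached as attribute `"profiles"` (a named
#'   list of numeric vectors in um).
#' @export
measure_mask <- function(mask, image_id = "image", drop_border = FALSE,
                         pixel_size = NULL) {
  stopifnot(inherits(mask, "label_mask"))
  if (is.null(pixel_size)) pixel_size <- mask$pixel_size
  if (drop_border) mask <- filter_border_labels(mask)
  labs <- mask_labels(mask)
  if (!length(labs)) return(empty_measurement_table())
  rows <- vector("list", length(labs))
  profiles <- list()
  for (i in seq_along(labs)) {
    cm <- measure_cell(mask, labs[i], pixel_size)
    sd <- compute_shape_descriptors(mask$labels == labs[i], pixel_size)
    rows[[i]] <- data.frame(
      image_id = image_id, cell_label = labs[i],
      length_um = cm$length_um, mean_width_um = cm$mean_width_um,
      surface_um2 = cm$surface_um2, volume_um3 = cm$volume_um3,
      cross_section_um2 = sd$cross_section_um2,
      convex_hull_um2 = sd$convex_hull_um2,
      eccentricity = sd$eccentricity, solidity = sd$solidity,
      branched = cm$branched, degenerate = cm$degenerate,
      border_touching = cm$border_touching,
      stringsAsFactors = FALSE
    )
    profiles[[as.character(labs[i])]] <- cm$width_profile_um
  }
  out <- do.call(rbind, rows)[, measurement_columns]
  attr(out, "profiles") <- profiles
  out
}
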