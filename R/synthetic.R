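#' Specification of a synthetic spherocylinder scene
#'
#' Describes a field of non-overlapping rod-shaped (spherocylindrical) cells
#' with a fluorescently stained membrane, mimicking how such scenes are
#' simulated for segmentation benchmarking: cells of fixed tip-to-tip length
#' and variable width are rendered at a fine pixel size (15 nm), membrane
#' emitters are placed on 90% of contour points, blurred with the microscope
#' PSF, and the result is rescaled to the output pixel size (65 nm).
#'
#' @param n_cells number of cells (default 5).
#' @param width_um cell width in um: a single value or a `c(min, max)` range
#'   sampled uniformly per cell (default `c(0.53, 1.04)`, the width range of
#'   the E. coli calibration data).
#' @param length_um tip-to-tip length in um (single value or range; default
#'   4, the fixed simulation length).
#' @param orientation_deg orientation range in degrees (default `c(0, 180)`).
#' @param render_px render pixel size in um (default 0.015).
#' @param output_px output pixel size in um (default 0.065).
#' @param canvas_um canvas side length in um (default chosen to fit).
#' @param retention fraction of contour points kept as emitters (default
#'   0.9).
#' @param wavelength_um emission wavelength (default 0.6).
#' @param na numerical aperture (default 1.49).
#' @param refractive_index immersion refractive index (default 1.5;
#'   bookkeeping for the PSF model).
#' @param psf_sigma_um lateral PSF sigma; default `0.21 * wavelength / NA`
#'   (about 0.0846 um), the usual Gaussian approximation of a widefield PSF.
#' @param z_planes number of z planes (default 1: mid-plane only).
#' @param z_spacing_um spacing between planes (default 0.2).
#' @param noise_poisson add Poisson shot noise to rendered images (default
#'   FALSE).
#' @param noise_gaussian_sd Gaussian read-noise sd (default 0).
#' @param photons_per_emitter mean photon count scaling for shot noise
#'   (default 200).
#' @param min_gap_um minimum gap between cell surfaces (default 0.2).
#' @param seed integer seed.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(n_cells = 5, width_um = c(0.53, 1.04), length_um = 4,
                       orientation_deg = c(0, 180), render_px = 0.015,
                       output_px = 0.065, canvas_um = NULL, retention = 0.9,
                       wavelength_um = 0.6, na = 1.49,
                       refractive_index = 1.5, psf_sigma_um = NULL,
                       z_planes = 1, z_spacing_um = 0.2,
                       noise_poisson = FALSE, noise_gaussian_sd = 0,
                       photons_per_emitter = 200, min_gap_um = 0.2,
                       seed = 1) {
  if (any(width_um <= 0)) stop("widths must be positive")
  if (retention <= 0 || retention > 1) stop("retention must be in (0, 1]")
  if (render_px > output_px) stop("render_px must be <= output_px")
  if (is.null(psf_sigma_um)) psf_sigma_um <- 0.21 * wavelength_um / na
  if (is.null(canvas_um)) {
    per_cell <- max(length_um) + 2 * min_gap_um
    canvas_um <- max(2.5 * per_cell, per_cell * ceiling(sqrt(n_cells)) * 1.2)
  }
  structure(as.list(environment()), class = "scene_spec")
}

#' Closed-form spherocylinder metrics
#'
#' Analytic length, width, surface area and volume of a spherocylinder of
#' width `w` and tip-to-tip length `L_tot` (cylinder of length `L_tot - w`
#' capped with two hemispheres):
#' `S = pi w (L_tot - w) + pi w^2`, `V = pi w^2 (L_tot - w) / 4 + pi w^3 / 6`.
#'
#' @param width_um cell width (diameter) in um.
#' @param length_um tip-to-tip length in um, `>= width_um`.
#' @return list with `length_um`, `width_um`, `surface_um2`, `volume_um3`.
#' @export
analytic_spherocylinder_metrics <- function(width_um, length_um) {
  if (any(width_um <= 0)) stop("width must be positive")
  if (any(width_um > length_um))
    stop("width must not exceed tip-to-tip length")
  list(
    length_um = length_um,
    width_um = width_um,
    surface_um2 = pi * width_um * (length_um - width_um) + pi * width_um^2,
    volume_um3 = pi * width_um^2 * (length_um - width_um) / 4 +
      pi * width_um^3 / 6
  )
}

#' Rasterize one spherocylinder footprint
#'
#' Marks every pixel whose center lies within `width/2` of the cell's axis
#' segment. Coordinates are pixel centers at 0-based (row, col).
#'
#' @param nrow_px,ncol_px canvas size in pixels.
#' @param center_rc (row, col) cell center in pixels (fractional).
#' @param theta_deg orientation in degrees (0 = along columns).
#' @param width_px,length_px width and tip-to-tip length in pixels.
#' @return Logical matrix.
#' @export
rasterize_spherocylinder <- function(nrow_px, ncol_px, center_rc, theta_deg,
                                     width_px, length_px) {
  th <- theta_deg * pi / 180
  u <- c(sin(th), cos(th))                  # (row, col) axis direction
  half_axis <- max(0, (length_px - width_px) / 2)
  rows <- matrix(0:(nrow_px - 1), nrow_px, ncol_px)
  cols <- matrix(0:(ncol_px - 1), nrow_px, ncol_px, byrow = TRUE)
  pr <- rows - center_rc[1]; pc <- cols - center_rc[2]
  t <- pmin(pmax(pr * u[1] + pc * u[2], -half_axis), half_axis)
  dr <- pr - t * u[1]; dc <- pc - t * u[2]
  (dr * dr + dc * dc) <= (width_px / 2)^2
}

# closest distance between two segments (each given as center, direction,
# half-length), used for overlap rejection during placement
segment_distance <- function(c1, u1, h1, c2, u2, h2) {
  s1 <- seq(-h1, h1, length.out = max(2, ceiling(2 * h1)))
  s2 <- seq(-h2, h2, length.out = max(2, ceiling(2 * h2)))
  p1 <- cbind(c1[1] + s1 * u1[1], c1[2] + s1 * u1[2])
  p2 <- cbind(c2[1] + s2 * u2[1], c2[2] + s2 * u2[2])
  sqrt(min(outer(p1[, 1], p2[, 1], `-`)^2 + outer(p1[, 2], p2[, 2], `-`)^2))
}

#' Generate a synthetic spherocylinder scene
#'
#' Places non-overlapping spherocylinders on the canvas by rejection
#' sampling and rasterizes their exact footprints as a label mask at the
#' render resolution. Identical seeds give identical scenes.
#'
#' @param spec a [scene_spec()].
#' @return A `synthetic_scene`: list with `cells` (data.frame cell_label,
#'   row_px, col_px, theta_deg, width_um, length_um at render resolution),
#'   `mask` (render-resolution [label_mask()]), `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  set.seed(spec$seed)
  px <- spec$render_px
  side <- round(spec$canvas_um / px)
  draw1 <- function(range) if (length(range) == 1) range else
    stats::runif(1, range[1], range[2])
  cells <- NULL
  attempts <- 0
  while (is.null(cells) || nrow(cells) < spec$n_cells) {
    attempts <- attempts + 1
    if (attempts > 1e4)
      stop("could not place ", spec$n_cells,
           " non-overlapping cells in 10000 attempts; ",
           "enlarge `canvas_um` or reduce `n_cells`")
    w <- draw1(spec$width_um); l <- max(draw1(spec$length_um), w)
    th <- draw1(spec$orientation_deg)
    margin <- (l / 2 + spec$min_gap_um) / px
    if (side - 2 * margin <= 1) stop("canvas too small for cell length")
    pos <- stats::runif(2, margin, side - margin)
    ok <- TRUE
    if (!is.null(cells)) {
      u <- c(sin(th * pi / 180), cos(th * pi / 180))
      for (i in seq_len(nrow(cells))) {
        ci <- cells[i, ]
        ui <- c(sin(ci$theta_deg * pi / 180), cos(ci$theta_deg * pi / 180))
        dmin <- segment_distance(
          pos, u, (l - w) / 2 / px,
          c(ci$row_px, ci$col_px), ui,
          (ci$length_um - ci$width_um) / 2 / px)
        if (dmin * px < (w + ci$width_um) / 2 + spec$min_gap_um) {
          ok <- FALSE; break
        }
      }
    }
    if (ok)
      cells <- rbind(cells, data.frame(
        cell_label = if (is.null(cells)) 1L else nrow(cells) + 1L,
        row_px = pos[1], col_px = pos[2], theta_deg = th,
        width_um = w, length_um = l))
  }
  labels <- matrix(0L, side, side)
  for (i in seq_len(nrow(cells))) {
    ci <- cells[i, ]
    fp <- rasterize_spherocylinder(side, side,
                                   c(ci$row_px, ci$col_px), ci$theta_deg,
                                   ci$width_um / px, ci$length_um / px)
    labels[fp] <- ci$cell_label
  }
  structure(list(
    cells = cells,
    mask = label_mask(labels, pixel_size = px, source_path = "synthetic"),
    spec = spec
  ), class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("synthetic_scene: %d cell(s) at %.3g um/px (%d x %d px)\n",
              nrow(x$cells), x$mask$pixel_size,
              nrow(x$mask$labels), ncol(x$mask$labels)))
  invisible(x)
}

# contour points of one cell's cross-section outline at axial plane offset
# dz (um): the capsule outline with radius sqrt(r^2 - dz^2), sampled at
# roughly one render pixel spacing
capsule_contour <- function(center_rc, theta_deg, width_px, length_px, dz_px) {
  r <- width_px / 2
  if (abs(dz_px) >= r) return(NULL)
  rz <- sqrt(r^2 - dz_px^2)
  half_axis <- max(0, (length_px - width_px) / 2)
  th <- theta_deg * pi / 180
  u <- c(sin(th), cos(th)); v <- c(-u[2], u[1])
  # two straight flanks
  nstraight <- max(2, ceiling(2 * half_axis))
  tt <- seq(-half_axis, half_axis, length.out = nstraight)
  flank1 <- cbind(center_rc[1] + tt * u[1] + rz * v[1],
                  center_rc[2] + tt * u[2] + rz * v[2])
  flank2 <- cbind(center_rc[1] + tt * u[1] - rz * v[1],
                  center_rc[2] + tt * u[2] - rz * v[2])
  # two semicircular cap arcs: from one flank end, over the pole, to the
  # other flank end
  narc <- max(4, ceiling(pi * rz))
  a <- seq(-pi / 2, pi / 2, length.out = narc)
  tip1 <- center_rc + half_axis * u
  tip2 <- center_rc - half_axis * u
  arc1 <- cbind(tip1[1] + rz * (cos(a) * u[1] + sin(a) * v[1]),
                tip1[2] + rz * (cos(a) * u[2] + sin(a) * v[2]))
  arc2 <- cbind(tip2[1] - rz * (cos(a) * u[1] + sin(a) * v[1]),
                tip2[2] - rz * (cos(a) * u[2] + sin(a) * v[2]))
  rbind(flank1, flank2, arc1, arc2)
}

#' Render fluorescent-membrane images for a scene
#'
#' For each z plane, point emitters are placed on a random subset
#' (`retention`, default 90%) of each cell's cross-section contour points,
#' the emitter image is convolved with an isotropic Gaussian PSF
#' (sigma = 0.21 lambda / NA per plane, with a mild defocus broadening of
#' sigma with |dz|), and optional Poisson/Gaussian noise is added. The
#' mid-plane peak membrane intensity lies on the true cell contour.
#'
#' @param scene a [generate_scene()] result.
#' @param spec optional override of `scene$spec`.
#' @return An [image_stack()] at render resolution (one plane if
#'   `z_planes = 1`).
#' @export
render_membrane_stack <- function(scene, spec = scene$spec) {
  stopifnot(inherits(scene, "synthetic_scene"))
  set.seed(spec$seed + 1L)
  px <- spec$render_px
  side <- nrow(scene$mask$labels)
  nz <- spec$z_planes
  dz_um <- (seq_len(nz) - (nz + 1) / 2) * spec$z_spacing_um
  sigma0 <- spec$psf_sigma_um / px
  planes <- vector("list", nz)
  for (zi in seq_len(nz)) {
    img <- matrix(0, side, side)
    for (i in seq_len(nrow(scene$cells))) {
      ci <- scene$cells[i, ]
      contour <- capsule_contour(c(ci$row_px, ci$col_px), ci$theta_deg,
                                 ci$width_um / px, ci$length_um / px,
                                 dz_um[zi] / px)
      if (is.null(contour)) next
      keep <- sample.int(nrow(contour),
                         round(spec$retention * nrow(contour)))
      kp <- contour[keep, , drop = FALSE]
      rr <- pmin(pmax(round(kp[, 1]) + 1L, 1L), side)
      cc <- pmin(pmax(round(kp[, 2]) + 1L, 1L), side)
      for (k in seq_along(rr)) img[rr[k], cc[k]] <- img[rr[k], cc[k]] + 1
    }
    # defocus: PSF widens away from the emitter plane on the axial
    # depth-of-field scale n * lambda / NA^2
    zr <- spec$refractive_index * spec$wavelength_um / spec$na^2
    sigma_z <- sigma0 * sqrt(1 + (dz_um[zi] / zr)^2)
    if (any(img > 0)) img <- EBImage::gblur(img, sigma = sigma_z)
    if (spec$noise_poisson)
      img <- stats::rpois(length(img), img * spec$photons_per_emitter) /
        spec$photons_per_emitter
    if (spec$noise_gaussian_sd > 0)
      img <- img + stats::rnorm(length(img), 0, spec$noise_gaussian_sd)
    planes[[zi]] <- matrix(img, side, side)
  }
  image_stack(planes, pixel_size = px, z_spacing = spec$z_spacing_um)
}

# assign fine pixels to coarse pixels through pixel-center membership
coarse_index <- function(n_fine, ratio) pmin(floor((seq_len(n_fine) - 0.5) / ratio) + 1L, ceiling(n_fine / ratio))

#' Rescale a scene (mask and/or images) to the output pixel size
#'
#' Intensity images are block-averaged (area-weighted through pixel-center
#' assignment, which also handles non-integer scale ratios); label masks are
#' downsampled by majority vote per output pixel (background competes like
#' any label). Ground-truth cell parameters are unchanged.
#'
#' @param scene a `synthetic_scene`.
#' @param stack optional [image_stack()] rendered from the scene.
#' @param output_px target pixel size in um (default from the spec).
#' @return List with `mask` (output-resolution [label_mask()]), `stack`
#'   (output-resolution [image_stack()] or NULL), `cells` (ground truth with
#'   positions rescaled to output pixels), `scale` (the ratio used).
#' @export
rescale_scene <- function(scene, stack = NULL,
                          output_px = scene$spec$output_px) {
  stopifnot(inherits(scene, "synthetic_scene"))
  px <- scene$mask$pixel_size
  ratio <- output_px / px
  if (ratio < 1) stop("output pixel size must be >= render pixel size")
  lab <- scene$mask$labels
  nr <- nrow(lab); nc <- ncol(lab)
  ri <- coarse_index(nr, ratio); ci <- coarse_index(nc, ratio)
  nro <- max(ri); nco <- max(ci)
  group <- (rep(ci, each = nr) - 1L) * nro + rep(ri, nc)

  # majority vote per coarse pixel
  out_lab <- matrix(0L, nro, nco)
  tab <- table(group, lab)
  lab_levels <- as.integer(colnames(tab))
  win <- lab_levels[max.col(tab, ties.method = "first")]
  out_lab[as.integer(rownames(tab))] <- win

  out_stack <- NULL
  if (!is.null(stack)) {
    planes <- lapply(stack$planes, function(p) {
      sums <- tapply(as.vector(p), group, mean)
      m <- matrix(0, nro, nco)
      m[as.integer(names(sums))] <- sums
      m
    })
    out_stack <- image_stack(planes, pixel_size = output_px,
                             z_spacing = stack$z_spacing)
  }
  cells <- scene$cells
  cells$row_px <- cells$row_px / ratio
  cells$col_px <- cells$col_px / ratio
  list(mask = label_mask(out_lab, pixel_size = output_px,
                         source_path = "synthetic-rescaled"),
       stack = out_stack, cells = cells, scale = ratio)
}
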