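test_that("analytic spherocylinder metrics match closed forms and limits", {
  m <- analytic_spherocylinder_metrics(1, 4)
  expect_equal(m$surface_um2, 4 * pi)
  expect_equal(m$volume_um3, 3 * pi / 4 + pi / 6)
  expect_equal(m$length_um, 4)

  # sphere limit: w = L
  s <- analytic_spherocylinder_metrics(2, 2)
  expect_equal(s$surface_um2, pi * 4)
  expect_equal(s$volume_um3, pi * 8 / 6)

  # vanishing width
  tiny <- analytic_spherocylinder_metrics(1e-6, 4)
  expect_lt(tiny$volume_um3, 1e-9)

  expect_error(analytic_spherocylinder_metrics(5, 4), "exceed")
})

test_that("generated scenes honour the requested geometry and are deterministic", {
  spec <- scene_spec(n_cells = 2, width_um = 0.9, length_um = 4,
                     canvas_um = 10, seed = 42)
  scene <- generate_scene(spec)
  expect_equal(nrow(scene$cells), 2)
  expect_equal(scene$mask$pixel_size, 0.015)

  # a 4 um cell spans about 4 / 0.015 = 267 render pixels
  for (lb in scene$cells$cell_label) {
    pts <- which(scene$mask$labels == lb, arr.ind = TRUE)
    span <- max(dist(pts[grDevices::chull(pts), , drop = FALSE]))
    expect_lt(abs(span - 4 / 0.015), 3)
  }

  # same seed: bit-identical
  scene2 <- generate_scene(scene_spec(n_cells = 2, width_um = 0.9,
                                      length_um = 4, canvas_um = 10,
                                      seed = 42))
  expect_identical(scene$mask$labels, scene2$mask$labels)
  expect_identical(scene$cells, scene2$cells)

  # no two cells overlap
  expect_equal(sum(scene$mask$labels > 0),
               sum(vapply(scene$cells$cell_label,
                          function(l) sum(scene$mask$labels == l),
                          numeric(1))))
})

test_that("footprint areas match the closed-form capsule footprint", {
  spec <- scene_spec(n_cells = 3, width_um = c(0.6, 1.0), length_um = 4,
                     canvas_um = 14, seed = 7)
  scene <- generate_scene(spec)
  px <- scene$mask$pixel_size
  for (i in seq_len(nrow(scene$cells))) {
    ci <- scene$cells[i, ]
    area <- sum(scene$mask$labels == ci$cell_label) * px^2
    want <- ci$width_um * (ci$length_um - ci$width_um) +
      pi * ci$width_um^2 / 4
    expect_lt(abs(area - want) / want, 0.03)
  }
})

test_that("placement failure on an impossible canvas is informative", {
  spec <- scene_spec(n_cells = 30, width_um = 1, length_um = 4,
                     canvas_um = 6, seed = 1)
  expect_error(generate_scene(spec), "attempts|too small")
})

test_that("membrane rendering puts emitters on the contour", {
  spec <- scene_spec(n_cells = 1, width_um = 0.8, length_um = 4,
                     canvas_um = 7, orientation_deg = 0, seed = 3)
  scene <- generate_scene(spec)
  st <- render_membrane_stack(scene)
  expect_length(st$planes, 1)
  img <- st$planes[[1]]
  expect_gt(max(img), 0)

  # mid-plane perpendicular profile through the center shows two maxima
  # within one render pixel of +/- w/2
  ci <- scene$cells[1, ]
  px <- spec$render_px
  w_half_px <- ci$width_um / 2 / px
  n <- floor(2 * w_half_px + 20)
  prof <- extract_intensity_profile(img, c(ci$row_px + 1, ci$col_px + 1),
                                    c(1, 0), length_px = n)
  mid <- (n + 1) / 2
  left <- which.max(prof[seq_len(floor(mid))])
  right <- floor(mid) + which.max(prof[(floor(mid) + 1):n])
  expect_lt(abs((mid - left) - w_half_px), 1)
  expect_lt(abs((right - mid) - w_half_px), 1)
})

test_that("zero-cell scenes render blank images", {
  spec <- scene_spec(n_cells = 0, width_um = 0.8, length_um = 4,
                     canvas_um = 5, seed = 2)
  spec$n_cells <- 0
  scene <- structure(list(
    cells = data.frame(cell_label = integer(0), row_px = numeric(0),
                       col_px = numeric(0), theta_deg = numeric(0),
                       width_um = numeric(0), length_um = numeric(0)),
    mask = label_mask(matrix(0L, 100, 100), pixel_size = spec$render_px),
    spec = spec), class = "synthetic_scene")
  st <- render_membrane_stack(scene)
  expect_true(all(st$planes[[1]] == 0))
})

test_that("rescaling conserves area and is the identity at ratio 1", {
  spec <- scene_spec(n_cells = 2, width_um = c(0.7, 1.0), length_um = 3.5,
                     canvas_um = 10, seed = 9)
  scene <- generate_scene(spec)
  out <- rescale_scene(scene)           # 15 nm -> 65 nm
  expect_equal(out$mask$pixel_size, 0.065)
  a_render <- sum(scene$mask$labels > 0) * spec$render_px^2
  a_out <- sum(out$mask$labels > 0) * spec$output_px^2
  expect_lt(abs(a_out - a_render) / a_render, 0.03)
  expect_setequal(unique(as.vector(out$mask$labels)),
                  c(0L, scene$cells$cell_label))

  same <- rescale_scene(scene, output_px = spec$render_px)
  expect_identical(same$mask$labels, scene$mask$labels)
})

test_that("retention controls the emitter count per contour", {
  # count point emitters before blurring by rendering with a delta PSF
  spec <- scene_spec(n_cells = 1, width_um = 0.8, length_um = 3,
                     canvas_um = 6, retention = 0.9, seed = 4)
  scene <- generate_scene(spec)
  ci <- scene$cells[1, ]
  contour <- rodmorph:::capsule_contour(
    c(ci$row_px, ci$col_px), ci$theta_deg,
    ci$width_um / spec$render_px, ci$length_um / spec$render_px, 0)
  spec_delta <- spec; spec_delta$psf_sigma_um <- 1e-9
  st <- render_membrane_stack(scene, spec_delta)
  expect_equal(sum(st$planes[[1]]), round(0.9 * nrow(contour)),
               tolerance = 1e-9)
})

test_that("measured width peaks at the mid-plane of a z-stack", {
  spec <- scene_spec(n_cells = 1, width_um = 1.0, length_um = 4,
                     canvas_um = 7, z_planes = 5, z_spacing_um = 0.2,
                     orientation_deg = 40, seed = 6)
  scene <- generate_scene(spec)
  st <- render_membrane_stack(scene)
  widths <- vapply(st$planes, function(pl) {
    if (max(pl) <= 0) return(0)
    # segment the region enclosed by the membrane ridge: threshold + fill
    bin <- EBImage::fillHull(pl >= 0.5 * max(pl))
    lab <- label_mask(matrix(as.integer(bin), nrow(bin), ncol(bin)),
                      pixel_size = spec$render_px)
    if (!length(mask_labels(lab))) return(0)
    cm <- suppressWarnings(measure_cell(lab, 1))
    cm$mean_width_um
  }, numeric(1))
  expect_equal(which.max(widths), 3)   # mid plane of 5
  expect_true(all(widths[3] >= widths))
})

test_that("projection mode hardly changes the measured width", {
  spec <- scene_spec(n_cells = 1, width_um = 0.9, length_um = 4,
                     canvas_um = 7, z_planes = 5, z_spacing_um = 0.2,
                     orientation_deg = 110, seed = 8)
  scene <- generate_scene(spec)
  st <- render_membrane_stack(scene)
  width_of <- function(img, px) {
    bin <- EBImage::fillHull(img >= 0.5 * max(img))
    lab <- label_mask(matrix(as.integer(bin), nrow(bin), ncol(bin)),
                      pixel_size = px)
    suppressWarnings(measure_cell(lab, 1))$mean_width_um
  }
  res <- rescale_scene(scene, st)
  px_out <- res$stack$pixel_size
  w <- vapply(c("max", "mean", "sum"), function(mode)
    width_of(project_stack(res$stack, mode), px_out), numeric(1))
  expect_lt(max(w) - min(w), px_out)   # within one output pixel
})

test_that("end-to-end: output-resolution ground truth recovers the cells", {
  spec <- scene_spec(n_cells = 3, width_um = c(0.6, 1.0),
                     length_um = c(2.5, 5), canvas_um = 14, seed = 13)
  scene <- generate_scene(spec)
  out <- rescale_scene(scene)
  tab <- measure_mask(out$mask)
  px <- out$mask$pixel_size
  tab <- tab[order(tab$cell_label), ]
  cells <- scene$cells[order(scene$cells$cell_label), ]
  expect_true(all(abs(tab$mean_width_um - cells$width_um) / px < 1.5))
  expect_true(all(abs(tab$length_um - cells$length_um) / px < 2))
})
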