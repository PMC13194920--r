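# Shared fixtures and independent oracles, built in code.

# Ideal digital spherocylinder as a single-instance label_mask.
ideal_rod_mask <- function(width_um, length_um, theta_deg,
                           pixel_size = 0.065,
                           center_jitter = c(0, 0), pad_px = 10) {
  w_px <- width_um / pixel_size
  l_px <- length_um / pixel_size
  side <- ceiling(l_px) + 2 * pad_px
  ctr <- c(side / 2 + center_jitter[1], side / 2 + center_jitter[2])
  bin <- rasterize_spherocylinder(side, side, ctr, theta_deg, w_px, l_px)
  label_mask(matrix(as.integer(bin), side, side), pixel_size = pixel_size)
}

# Brute-force Euclidean distance transform (exhaustive over background).
brute_force_edt <- function(bin) {
  out <- matrix(0, nrow(bin), ncol(bin))
  bg <- which(bin == 0, arr.ind = TRUE)
  fg <- which(bin != 0, arr.ind = TRUE)
  for (k in seq_len(nrow(fg))) {
    p <- fg[k, ]
    out[p[1], p[2]] <- sqrt(min((bg[, 1] - p[1])^2 + (bg[, 2] - p[2])^2))
  }
  out
}

# Exhaustive one-to-one assignment maximizing total IoU; returns TP/FP/FN
# at a threshold. Only for small matrices.
brute_force_match <- function(iou, threshold) {
  ng <- nrow(iou); np <- ncol(iou)
  best <- list(weight = -1, pairs = NULL)
  assign_rec <- function(gi, used_pred, pairs, weight) {
    if (gi > ng) {
      if (weight > best$weight) best <<- list(weight = weight, pairs = pairs)
      return(invisible())
    }
    assign_rec(gi + 1, used_pred, pairs, weight)  # gt gi unmatched
    for (pj in seq_len(np)) {
      if (!used_pred[pj] && iou[gi, pj] > 0) {
        used_pred[pj] <- TRUE
        assign_rec(gi + 1, used_pred, rbind(pairs, c(gi, pj)),
                   weight + iou[gi, pj])
        used_pred[pj] <- FALSE
      }
    }
  }
  assign_rec(1, rep(FALSE, max(np, 1)), NULL, 0)
  tp <- if (is.null(best$pairs)) 0 else
    sum(iou[best$pairs] >= threshold - 1e-9)
  list(tp = tp, fp = np - tp, fn = ng - tp)
}

# Random label image with n disjoint rectangular instances.
random_instance_mask <- function(n, side = 30) {
  lab <- matrix(0L, side, side)
  placed <- 0; guard <- 0
  while (placed < n && guard < 200) {
    guard <- guard + 1
    h <- sample(3:7, 1); w <- sample(3:7, 1)
    r <- sample(seq_len(side - h), 1); c <- sample(seq_len(side - w), 1)
    if (all(lab[r:(r + h), c:(c + w)] == 0L)) {
      placed <- placed + 1
      lab[r:(r + h), c:(c + w)] <- placed
    }
  }
  label_mask(lab, pixel_size = 0.065)
}

# Y-shaped skeleton pixel set: three arms from a center whose directions are
# at least 135 degrees apart, so the <1.5 px rule yields a tree with exactly
# one degree-3 node. Returns the pixel matrix.
y_skeleton <- function(arm_lengths = c(4, 4, 4), center = c(10, 10),
                       dirs = list(c(-1, 1), c(-1, -1), c(1, 0))) {
  pts <- matrix(center, 1, 2)
  for (a in seq_along(arm_lengths)) {
    d <- dirs[[a]]
    for (k in seq_len(arm_lengths[a]))
      pts <- rbind(pts, center + k * d)
  }
  pts
}
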