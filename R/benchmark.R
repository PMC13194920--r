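#' IoU matrix between ground-truth and predicted instances
#'
#' Entry (i, j) is the intersection-over-union of ground-truth instance i and
#' predicted instance j (pixel sets; background excluded).
#'
#' @param gt,pred [label_mask()] objects (or integer matrices) of the same
#'   shape.
#' @return Numeric matrix with `dimnames` giving the gt and pred labels.
#' @export
instance_iou_matrix <- function(gt, pred) {
  g <- if (inherits(gt, "label_mask")) gt$labels else gt
  p <- if (inherits(pred, "label_mask")) pred$labels else pred
  if (!identical(dim(g), dim(p)))
    stop("gt and pred masks must have the same shape")
  gl <- sort(unique(g[g > 0L])); pl <- sort(unique(p[p > 0L]))
  out <- matrix(0, length(gl), length(pl), dimnames = list(gl, pl))
  if (!length(gl) || !length(pl)) return(out)
  gsz <- tabulate(match(g[g > 0L], gl), length(gl))
  psz <- tabulate(match(p[p > 0L], pl), length(pl))
  both <- g > 0L & p > 0L
  if (any(both)) {
    gi <- match(g[both], gl); pi <- match(p[both], pl)
    inter <- table(factor(gi, levels = seq_along(gl)),
                   factor(pi, levels = seq_along(pl)))
    inter <- matrix(as.numeric(inter), length(gl), length(pl))
    uni <- outer(gsz, psz, `+`) - inter
    out[] <- ifelse(uni > 0, inter / uni, 0)
  }
  out
}

#' Match instances at an IoU threshold
#'
#' One-to-one assignment between ground-truth and predicted instances
#' maximizing total matched IoU (maximum-weight bipartite matching, the
#' behaviour of the usual average-precision routines). A matched pair counts
#' as a true positive when its IoU is at least `threshold - 1e-9` (the slack
#' lets threshold 1.0 admit exact matches despite floating point).
#'
#' @param iou_matrix from [instance_iou_matrix()].
#' @param threshold IoU threshold in `[0, 1]`.
#' @param method `"optimal"` (default) or `"greedy"` (repeatedly take the
#'   best remaining pair; for comparison).
#' @return A `match_result`: list with `threshold`, `tp`, `fp`, `fn`, and
#'   `matches` (data.frame gt, pred, iou of pairs counted as TP).
#' @export
match_at_threshold <- function(iou_matrix, threshold,
                               method = c("optimal", "greedy")) {
  method <- match.arg(method)
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  ng <- nrow(iou_matrix); np <- ncol(iou_matrix)
  pairs <- NULL
  if (ng > 0 && np > 0 && any(iou_matrix > 0)) {
    pairs <- if (method == "optimal") optimal_pairs(iou_matrix)
             else greedy_pairs(iou_matrix)
  }
  tp_idx <- if (is.null(pairs)) integer(0) else
    which(pairs$iou >= threshold - 1e-9)
  tp <- length(tp_idx)
  structure(list(
    threshold = threshold, tp = tp, fp = np - tp, fn = ng - tp,
    matches = if (tp) pairs[tp_idx, , drop = FALSE] else
      data.frame(gt = integer(0), pred = integer(0), iou = numeric(0))
  ), class = "match_result")
}

# maximum-weight bipartite matching over positive-IoU pairs
optimal_pairs <- function(iou) {
  ng <- nrow(iou); np <- ncol(iou)
  pos <- which(iou > 0, arr.ind = TRUE)
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, ng), rep(TRUE, np)),
    edges = as.vector(t(cbind(pos[, 1], ng + pos[, 2])))
  )
  igraph::E(g)$weight <- iou[pos]
  mm <- igraph::max_bipartite_match(g, weights = igraph::E(g)$weight)
  gt_to_pred <- mm$matching[seq_len(ng)] - ng
  keep <- which(!is.na(gt_to_pred) & gt_to_pred >= 1)
  data.frame(gt = keep, pred = gt_to_pred[keep],
             iou = iou[cbind(keep, gt_to_pred[keep])])
}

greedy_pairs <- function(iou) {
  out <- NULL
  m <- iou
  while (any(m > 0)) {
    ij <- which(m == max(m), arr.ind = TRUE)[1, ]
    out <- rbind(out, data.frame(gt = ij[1], pred = ij[2],
                                 iou = m[ij[1], ij[2]]))
    m[ij[1], ] <- 0; m[, ij[2]] <- 0
  }
  out
}

#' Default IoU threshold grid
#'
#' Eleven thresholds spanning 0.5 to 1 in 0.05 steps.
#' @return Numeric vector of length 11.
#' @export
default_iou_thresholds <- function() seq(0.5, 1.0, by = 0.05)

#' F1 curve over IoU thresholds
#'
#' For each image pair and threshold, `F1 = 2 TP / (2 TP + FP + FN)` (0 when
#' the denominator is 0); the aggregate curve is the unweighted mean of
#' per-image F1 at each threshold. Pooled-count aggregation (sum TP/FP/FN
#' over images first) is available via `pooled = TRUE`.
#'
#' @param gt_masks,pred_masks lists of [label_mask()] (or matrices), paired
#'   by position.
#' @param thresholds IoU grid (default [default_iou_thresholds()]).
#' @param method matching method, see [match_at_threshold()].
#' @param pooled aggregate by pooled counts instead of mean per-image F1.
#' @return A `benchmark_curve`: list with `thresholds`, `per_image` (images x
#'   thresholds F1 matrix), `mean_f1`, `counts` (data.frame image, threshold,
#'   tp, fp, fn, f1).
#' @export
f1_curve <- function(gt_masks, pred_masks,
                     thresholds = default_iou_thresholds(),
                     method = "optimal", pooled = FALSE) {
  if (!is.list(gt_masks)) gt_masks <- list(gt_masks)
  if (!is.list(pred_masks)) pred_masks <- list(pred_masks)
  if (!length(gt_masks) || length(gt_masks) != length(pred_masks))
    stop("need matching, nonempty lists of gt and pred masks")
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  nim <- length(gt_masks); nth <- length(thresholds)
  f1m <- matrix(NA_real_, nim, nth)
  counts <- NULL
  for (i in seq_len(nim)) {
    iou <- instance_iou_matrix(gt_masks[[i]], pred_masks[[i]])
    for (j in seq_len(nth)) {
      mr <- match_at_threshold(iou, thresholds[j], method = method)
      denom <- 2 * mr$tp + mr$fp + mr$fn
      f1m[i, j] <- if (denom == 0) 0 else 2 * mr$tp / denom
      counts <- rbind(counts, data.frame(
        image = i, threshold = thresholds[j],
        tp = mr$tp, fp = mr$fp, fn = mr$fn, f1 = f1m[i, j]))
    }
  }
  mean_f1 <- if (pooled) {
    vapply(seq_len(nth), function(j) {
      cj <- counts[counts$threshold == thresholds[j], ]
      denom <- 2 * sum(cj$tp) + sum(cj$fp) + sum(cj$fn)
      if (denom == 0) 0 else 2 * sum(cj$tp) / denom
    }, numeric(1))
  } else colMeans(f1m)
  structure(list(thresholds = thresholds, per_image = f1m,
                 mean_f1 = mean_f1, counts = counts),
            class = "benchmark_curve")
}

#' @export
print.benchmark_curve <- function(x, ...) {
  cat(sprintf("benchmark_curve: %d image(s), %d threshold(s)\n",
              nrow(x$per_image), length(x$thresholds)))
  cat("  mean F1:", paste(sprintf("%.3f", x$mean_f1), collapse = " "), "\n")
  invisible(x)
}

#' Write a benchmark curve as CSV
#'
#' Per-image rows plus an aggregate section keyed `image_id = ALL`.
#'
#' @param curve a [f1_curve()] result.
#' @param path output CSV.
#' @param image_ids optional image names (default 1..n).
#' @return `path`, invisibly.
#' @export
write_benchmark_curve <- function(curve, path, image_ids = NULL) {
  stopifnot(inherits(curve, "benchmark_curve"))
  co <- curve$counts
  ids <- if (is.null(image_ids)) as.character(co$image)
         else image_ids[co$image]
  per <- data.frame(image_id = ids, threshold = co$threshold, tp = co$tp,
                    fp = co$fp, fn = co$fn, f1 = co$f1)
  agg <- data.frame(image_id = "ALL", threshold = curve$thresholds,
                    tp = NA, fp = NA, fn = NA, f1 = curve$mean_f1)
  utils::write.csv(rbind(per, agg), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
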