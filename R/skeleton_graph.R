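#' Build the skeleton graph of a set of skeleton pixels
#'
#' Every skeleton pixel is a node; undirected edges join exactly those pairs
#' whose Euclidean distance is below 1.5 pixels, i.e. horizontal/vertical
#' neighbours (distance 1) and diagonal neighbours (distance sqrt(2)).
#' Endpoints are the degree-1 nodes.
#'
#' @param pixels integer matrix with one skeleton pixel (row, col) per row,
#'   0-based or 1-based as long as it is consistent (the graph only uses
#'   relative offsets).
#' @return A `skeleton_graph`: list with `nodes` (the pixel matrix), `graph`
#'   (an igraph object), `endpoints` (node indices of degree 1).
#' @export
build_skeleton_graph <- function(pixels) {
  if (is.null(dim(pixels))) pixels <- matrix(pixels, ncol = 2)
  n <- nrow(pixels)
  if (n == 0) stop("empty skeleton pixel set")
  key <- paste(pixels[, 1], pixels[, 2])
  if (anyDuplicated(key)) stop("duplicate skeleton pixels")
  idx <- setNames(seq_len(n), key)
  ends <- NULL
  # half the 8-neighbourhood; the other half arises by symmetry
  for (o in list(c(-1, 0), c(-1, 1), c(0, 1), c(1, 1))) {
    nb <- paste(pixels[, 1] + o[1], pixels[, 2] + o[2])
    hit <- which(nb %in% key)
    if (length(hit))
      ends <- rbind(ends, cbind(idx[key[hit]], idx[nb[hit]]))
  }
  g <- if (is.null(ends))
    igraph::make_empty_graph(n = n, directed = FALSE)
  else
    igraph::make_undirected_graph(t(ends), n = n)
  structure(
    list(nodes = pixels, graph = g,
         endpoints = which(igraph::degree(g) == 1)),
    class = "skeleton_graph"
  )
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("skeleton_graph: %d node(s), %d edge(s), %d endpoint(s)\n",
              nrow(x$nodes), igraph::ecount(x$graph), length(x$endpoints)))
  invisible(x)
}

#' Enumerate candidate centerline paths of a skeleton graph
#'
#' An unbranched skeleton (two endpoints) yields exactly one path covering the
#' whole skeleton. A branched skeleton yields one simple path per unordered
#' endpoint pair, each found by depth-first traversal of the skeleton tree.
#' Cycles (possible on noisy masks) are broken by taking a spanning tree
#' first, with a warning. If there are more than `max_endpoints` endpoints,
#' only the `max_endpoints` endpoints of largest graph eccentricity are
#' paired, with a warning, so pathological masks cannot stall the pipeline.
#'
#' @param skel_graph a [build_skeleton_graph()] result.
#' @param max_endpoints endpoint guard (default 12).
#' @param instance optional instance id used in error messages.
#' @return List of integer matrices of (row, col) path coordinates, endpoints
#'   first and last. Single-node skeletons yield one single-point path.
#' @export
enumerate_candidate_paths <- function(skel_graph, max_endpoints = 12,
                                      instance = NULL) {
  stopifnot(inherits(skel_graph, "skeleton_graph"))
  g <- skel_graph$graph
  pts <- skel_graph$nodes
  n <- nrow(pts)
  if (n == 1) return(list(pts))
  comp <- igraph::components(g)
  if (comp$no > 1)
    stop("disconnected skeleton",
         if (!is.null(instance)) paste0(" for instance ", instance) else "",
         " (", comp$no, " components)")
  if (igraph::ecount(g) >= n) {
    warning("skeleton graph contains cycles; using a spanning tree")
    g <- igraph::mst(g)
  }
  eps <- which(igraph::degree(g) == 1)
  if (length(eps) > max_endpoints) {
    warning(length(eps), " skeleton endpoints; keeping the ", max_endpoints,
            " most eccentric")
    ecc <- igraph::eccentricity(g, vids = eps)
    eps <- eps[order(ecc, decreasing = TRUE)[seq_len(max_endpoints)]]
  }
  if (length(eps) == 2) {
    vp <- igraph::shortest_paths(g, eps[1], eps[2])$vpath[[1]]
    return(list(pts[as.integer(vp), , drop = FALSE]))
  }
  pairs <- utils::combn(eps, 2)
  lapply(seq_len(ncol(pairs)), function(j) {
    vp <- igraph::shortest_paths(g, pairs[1, j], pairs[2, j])$vpath[[1]]
    pts[as.integer(vp), , drop = FALSE]
  })
}
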