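#' Re-cluster a focal cell subset
#'
#' Runs the full embedding pipeline on the subset only — highly variable
#' genes re-selected, covariates re-regressed, PCA re-computed in the
#' subset's own space — and clusters at the sub-clustering resolution
#' (default 0.5), as for a focal cluster of interest.
#'
#' @param norm a `normalized_matrix` (full data).
#' @param covariates covariates data.frame aligned with `norm`.
#' @param cells index or barcode vector of the focal subset.
#' @param hvg_par an [hvg_params] for re-selection.
#' @param n_pcs PCs for the subset embedding; capped at the subset's rank.
#' @param params a [cluster_params] (resolution defaults to 0.5).
#' @return list with `assignment` (labels), `embedding` (subset PC
#'   scores), `cells` (barcodes used).
#' @export
subcluster <- function(norm, covariates, cells,
                       hvg_par = hvg_params(),
                       n_pcs = 25,
                       params = cluster_params(resolution = 0.5)) {
  stopifnot(inherits(norm, "normalized_matrix"))
  if (is.character(cells)) cells <- match(cells, colnames(norm$N))
  if (length(cells) < params$n_neighbors) {
    stop("focal subset smaller than n_neighbors")
  }
  sub <- structure(list(N = norm$N[, cells, drop = FALSE],
                        scale_factor = norm$scale_factor,
                        totals = norm$totals[cells],
                        cell_meta = norm$cell_meta[cells, , drop = FALSE],
                        gene_meta = norm$gene_meta),
                   class = "normalized_matrix")
  hvg <- select_hvg(sub, hvg_par)
  scaled <- regress_and_scale(sub, covariates[cells, , drop = FALSE])
  n_pcs <- min(n_pcs, length(hvg) - 1, length(cells) - 1)
  emb <- pca_embed(scaled, hvg, n_pcs = n_pcs)
  list(assignment = cluster_cells(emb, params), embedding = emb,
       cells = colnames(sub$N))
}

# Kruskal MST with deterministic (weight, node-id) lexicographic tie-break
kruskal_mst <- function(w) {
  n <- nrow(w)
  ids <- rownames(w)
  pairs <- which(upper.tri(w), arr.ind = TRUE)
  ord <- order(w[pairs], ids[pairs[, 1]], ids[pairs[, 2]])
  pairs <- pairs[ord, , drop = FALSE]
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  edges <- list()
  for (r in seq_len(nrow(pairs))) {
    a <- pairs[r, 1]; b <- pairs[r, 2]
    ra <- find(a); rb <- find(b)
    if (ra != rb) {
      parent[ra] <- rb
      edges[[length(edges) + 1]] <- c(a, b)
      if (length(edges) == n - 1) break
    }
  }
  do.call(rbind, edges)
}

#' Minimum spanning tree over sub-cluster centroids
#'
#' Computes the PC-space centroid of every sub-cluster, builds the
#' complete graph with Euclidean edge weights, and extracts its minimum
#' spanning tree (Kruskal; equal-weight edges resolved in lexicographic
#' node-id order, so the tree is deterministic). Each node carries its
#' size and composition by experimental condition; nodes in which no
#' condition reaches half the cells are flagged as having dispersed
#' composition.
#'
#' @param assignment sub-cluster labels per cell.
#' @param embedding cells x PCs matrix the centroids are taken in.
#' @param conditions per-cell condition labels.
#' @param dispersed_below a node is dispersed when its top condition
#'   fraction is below this value (default 0.5).
#' @return an `mst_trajectory`: list with `nodes` (id, size,
#'   dominant_condition, dominant_fraction, dispersed), `composition`
#'   (nodes x conditions fractions, rows sum to 1), `centroids`,
#'   `edges` (from, to, weight).
#' @export
mst_over_centroids <- function(assignment, embedding, conditions,
                               dispersed_below = 0.5) {
  stopifnot(length(assignment) == nrow(embedding),
            length(conditions) == nrow(embedding))
  ks <- sort(unique(assignment))
  centroids <- t(vapply(ks, function(k) {
    colMeans(embedding[assignment == k, , drop = FALSE])
  }, numeric(ncol(embedding))))
  rownames(centroids) <- paste0("sub", ks)
  levs <- sort(unique(conditions))
  comp <- matrix(0, length(ks), length(levs),
                 dimnames = list(rownames(centroids), levs))
  for (idx in seq_along(ks)) {
    tab <- table(factor(conditions[assignment == ks[idx]], levels = levs))
    comp[idx, ] <- as.numeric(tab) / sum(tab)
  }
  sizes <- as.integer(table(factor(assignment, levels = ks)))
  dom <- apply(comp, 1, which.max)
  nodes <- data.frame(id = rownames(centroids), size = sizes,
                      dominant_condition = colnames(comp)[dom],
                      dominant_fraction = comp[cbind(seq_along(dom), dom)],
                      stringsAsFactors = FALSE)
  nodes$dispersed <- nodes$dominant_fraction < dispersed_below
  if (length(ks) < 2) {
    warning("single sub-cluster: degenerate single-node trajectory")
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0))
  } else {
    w <- as.matrix(stats::dist(centroids))
    e <- kruskal_mst(w)
    edges <- data.frame(from = rownames(centroids)[pmin(e[, 1], e[, 2])],
                        to = rownames(centroids)[pmax(e[, 1], e[, 2])],
                        weight = w[e], stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), ]
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, composition = comp, centroids = centroids,
                 edges = edges),
            class = "mst_trajectory")
}

#' @method print mst_trajectory
#' @export
print.mst_trajectory <- function(x, ...) {
  cat(sprintf("mst_trajectory: %d nodes, %d edges, total weight %.4g\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

#' Backbone path and composition summary of an MST trajectory
#'
#' Reports the weighted diameter path of the tree (the longest shortest
#' path between any two nodes) as the trajectory backbone — the natural
#' one-dimensional ordering of transcriptional states — with each node's
#' dominant condition (plurality of its composition) and dispersed flag.
#' Ties in path length are broken by lexicographic endpoint order.
#'
#' @param trajectory an `mst_trajectory` with >= 2 nodes.
#' @return list with `backbone` (ordered node ids), `length` (path
#'   weight), and `nodes` (the trajectory's node table restricted to the
#'   backbone, in path order).
#' @export
trajectory_report <- function(trajectory) {
  stopifnot(inherits(trajectory, "mst_trajectory"))
  if (nrow(trajectory$nodes) < 2) stop("trajectory has fewer than 2 nodes")
  g <- igraph::graph_from_data_frame(trajectory$edges, directed = FALSE,
                                     vertices = trajectory$nodes$id)
  d <- igraph::distances(g, weights = igraph::E(g)$weight)
  ids <- rownames(d)
  best <- c(NA, NA); best_len <- -Inf
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i < j && (d[i, j] > best_len ||
                    (d[i, j] == best_len &&
                     paste(ids[i], ids[j]) < paste(best[1], best[2])))) {
        best <- c(ids[i], ids[j]); best_len <- d[i, j]
      }
    }
  }
  path <- igraph::shortest_paths(g, from = best[1], to = best[2],
                                 weights = igraph::E(g)$weight)$vpath[[1]]
  backbone <- igraph::V(g)$name[path]
  nd <- trajectory$nodes[match(backbone, trajectory$nodes$id), ]
  rownames(nd) <- NULL
  list(backbone = backbone, length = best_len, nodes = nd)
}
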