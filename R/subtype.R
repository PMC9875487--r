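#' PCA embedding of deregulation features
#'
#' Centers (optionally scales) the samples-by-genes feature matrix, drops
#' constant features with a warning, and keeps the first `n_pcs` principal
#' components. With `n_pcs = "auto"` the count is the smallest `m` for which
#' the relative drop `(var_m - var_{m+1}) / var_1` falls below `elbow_tol`
#' (a reproducible elbow rule); the default of 6 components matches the
#' published analysis.
#'
#' @param dereg a `dereg_matrix` (samples x genes) or plain matrix.
#' @param n_pcs integer, or `"auto"` for the elbow rule.
#' @param scale. scale features to unit variance before decomposition
#'   (default FALSE: deregulation features already share a scale).
#' @param elbow_tol threshold of the auto elbow rule.
#' @return list with `embedding` (an `embedding_model`: `feature_means`,
#'   `feature_scales`, `loadings`, `n_pcs`, `explained_variance`,
#'   `model_fingerprint`) and `coords` (samples x n_pcs scores).
#' @export
fit_pca <- function(dereg, n_pcs = 6, scale. = FALSE, elbow_tol = 0.02) {
  X <- unclass(dereg)
  attr(X, "model_fingerprint") <- NULL
  keep <- apply(X, 2, stats::sd) > 1e-12
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " constant feature(s) before PCA")
    X <- X[, keep, drop = FALSE]
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = scale.)
  ev <- pc$sdev^2
  if (identical(n_pcs, "auto")) {
    drops <- (ev[-length(ev)] - ev[-1]) / ev[1]
    m <- which(drops < elbow_tol)
    n_pcs <- if (length(m)) m[1] else length(ev)
  }
  n_pcs <- min(n_pcs, ncol(pc$rotation))
  if (nrow(X) < n_pcs + 1) stop("need more samples than components")
  emb <- structure(list(
    feature_means = pc$center,
    feature_scales = if (scale.) pc$scale else stats::setNames(rep(1, ncol(X)), colnames(X)),
    loadings = pc$rotation[, seq_len(n_pcs), drop = FALSE],
    n_pcs = n_pcs,
    explained_variance = ev[seq_len(n_pcs)],
    model_fingerprint = attr(dereg, "model_fingerprint")),
    class = "embedding_model")
  list(embedding = emb, coords = pc$x[, seq_len(n_pcs), drop = FALSE])
}

#' Shared-nearest-neighbor graph
#'
#' Each sample's neighborhood is itself plus its `k` nearest neighbors by
#' Euclidean distance in PC space (ties broken by sample index); edges
#' connect samples with overlapping neighborhoods, weighted by the Jaccard
#' index of the neighborhoods; zero-weight edges are pruned.
#'
#' @param coords samples x dims coordinate matrix.
#' @param k neighborhood size (0 < k < n_samples).
#' @return an [igraph::graph] with vertex name attributes and `weight`
#'   edge attributes in (0, 1].
#' @export
build_snn_graph <- function(coords, k = 20) {
  n <- nrow(coords)
  if (k <= 0) stop("`k` must be positive")
  if (k >= n) stop("`k` must be smaller than the number of samples")
  d <- as.matrix(stats::dist(coords))
  nb <- Matrix::Matrix(0, n, n, sparse = TRUE)
  for (i in seq_len(n)) {
    ord <- order(d[i, ], seq_len(n))       # self first (distance 0)
    nb[i, ord[seq_len(k + 1)]] <- 1
  }
  shared <- as.matrix(nb %*% Matrix::t(nb))
  jac <- shared / (2 * (k + 1) - shared)
  diag(jac) <- 0
  jac[shared == 0] <- 0
  g <- igraph::graph_from_adjacency_matrix(jac, mode = "max", weighted = TRUE)
  ids <- rownames(coords)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  igraph::set_vertex_attr(g, "name", value = ids)
}

#' Louvain community detection at a given resolution
#'
#' Modularity-based community detection on the SNN graph with a resolution
#' parameter; labels are relabeled `0..K-1` by decreasing cluster size (ties
#' by first member index) and the RNG is seeded for determinism.
#'
#' @param graph weighted graph from [build_snn_graph()].
#' @param resolution modularity resolution (> 0); larger gives more clusters.
#' @param seed integer RNG seed.
#' @return named integer vector of 0-based cluster labels.
#' @export
cluster_at_resolution <- function(graph, resolution = 0.8, seed = 0) {
  if (igraph::vcount(graph) == 0) stop("empty graph")
  withr_seed(seed, {
    cl <- igraph::cluster_louvain(graph, resolution = resolution)
  })
  relabel_by_size(stats::setNames(igraph::membership(cl),
                                  igraph::V(graph)$name))
}

relabel_by_size <- function(labels) {
  tab <- table(labels)
  first_member <- vapply(names(tab), function(l) which(labels == l)[1], numeric(1))
  ord <- names(tab)[order(-tab, first_member)]
  stats::setNames(match(as.character(labels), ord) - 1L, names(labels))
}

#' Resolution-stability cluster selection
#'
#' Clusters the graph at every resolution in `res_grid`, then finds the
#' longest contiguous run of resolutions over which both the cluster count
#' and the memberships are constant (adjusted Rand index 1 between adjacent
#' resolutions). Returns the labels at the midpoint of that run. If no run of
#' length >= 2 exists, falls back to the modal cluster count with a warning.
#'
#' @param graph weighted SNN graph.
#' @param res_grid numeric grid of >= 3 resolutions (default 0.4-1.2 by 0.1).
#' @param seed integer RNG seed (shared across resolutions).
#' @return list with `resolution` (chosen value), `labels`, `k` (cluster
#'   count) and `stability_table` (data.frame: resolution, n_clusters,
#'   ari_with_next, plus one label column per sample).
#' @export
stability_select <- function(graph, res_grid = seq(0.4, 1.2, by = 0.1),
                             seed = 0) {
  if (length(res_grid) < 3) stop("res_grid needs >= 3 points")
  res_grid <- sort(res_grid)
  lab <- lapply(res_grid, function(r) cluster_at_resolution(graph, r, seed))
  ks <- vapply(lab, function(l) length(unique(l)), integer(1))
  m <- length(res_grid)
  ari_next <- c(vapply(seq_len(m - 1), function(i)
    mclust::adjustedRandIndex(lab[[i]], lab[[i + 1]]), numeric(1)), NA)
  stable_step <- ks[-m] == ks[-1] & abs(ari_next[-m] - 1) < 1e-12
  runs <- rle(stable_step)
  if (any(runs$values)) {
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    best <- which(runs$values)[which.max(runs$lengths[runs$values])]
    i0 <- starts[best]; i1 <- ends[best] + 1    # run of steps -> run of points
    mid <- i0 + floor((i1 - i0) / 2)
  } else {
    warning("no stable resolution interval; falling back to modal cluster count")
    kmode <- as.integer(names(which.max(table(ks))))
    mid <- which(ks == kmode)[1]
  }
  st <- data.frame(resolution = res_grid, n_clusters = ks,
                   ari_with_next = ari_next)
  st <- cbind(st, do.call(rbind, lab))
  list(resolution = res_grid[mid], labels = lab[[mid]],
       k = ks[mid], stability_table = st)
}

#' Top PCA-loading genes per component
#'
#' For each of the first `n_pcs` components, the `top_k` genes by absolute
#' loading; the union is ranked by the sum of absolute loadings over the
#' components where the gene is in the top `top_k` (other cells are NA,
#' mirroring a sparse loading table).
#'
#' @param embedding an `embedding_model`.
#' @param n_pcs number of leading components to scan (default 6).
#' @param top_k genes per component (default 5; clamped to the gene count).
#' @return data.frame: `gene`, `sum_abs_loading`, then one `PC<i>` column per
#'   scanned component holding the loading where the gene ranked top-k,
#'   sorted by decreasing `sum_abs_loading`.
#' @export
top_loading_genes <- function(embedding, n_pcs = 6, top_k = 5) {
  if (n_pcs > embedding$n_pcs)
    stop("n_pcs exceeds the embedding's component count")
  L <- embedding$loadings[, seq_len(n_pcs), drop = FALSE]
  top_k <- min(top_k, nrow(L))
  sel <- lapply(seq_len(n_pcs), function(j)
    rownames(L)[order(-abs(L[, j]), rownames(L))[seq_len(top_k)]])
  genes <- sort(unique(unlist(sel)))
  tab <- matrix(NA_real_, length(genes), n_pcs,
                dimnames = list(genes, paste0("PC", seq_len(n_pcs))))
  for (j in seq_len(n_pcs)) tab[sel[[j]], j] <- L[sel[[j]], j]
  s <- rowSums(abs(tab), na.rm = TRUE)
  out <- data.frame(gene = genes, sum_abs_loading = s, tab,
                    row.names = NULL, check.names = FALSE)
  out[order(-out$sum_abs_loading, out$gene), , drop = FALSE]
}

#' Discover subtypes from a deregulation matrix
#'
#' Convenience wrapper: PCA, SNN graph, resolution-stability clustering.
#'
#' @param dereg a `dereg_matrix`.
#' @param n_pcs components for the embedding (or `"auto"`).
#' @param snn_k SNN neighborhood size.
#' @param res_grid resolution grid for [stability_select()].
#' @param seed integer RNG seed.
#' @return a `subtype_model`: `embedding`, `coords`, `labels`, `snn_k`,
#'   `resolution`, `k`, `stability_table`, `seed`.
#' @export
discover_subtypes <- function(dereg, n_pcs = 6, snn_k = 20,
                              res_grid = seq(0.4, 1.2, by = 0.1), seed = 0) {
  pca <- fit_pca(dereg, n_pcs = n_pcs)
  g <- build_snn_graph(pca$coords, k = snn_k)
  sel <- stability_select(g, res_grid, seed = seed)
  structure(list(embedding = pca$embedding, coords = pca$coords,
                 labels = sel$labels, snn_k = snn_k,
                 resolution = sel$resolution, k = sel$k,
                 stability_table = sel$stability_table, seed = seed),
            class = "subtype_model")
}

#' @export
print.subtype_model <- function(x, ...) {
  cat(sprintf("<subtype_model> %d samples, %d clusters at resolution %.2f (%d PCs, snn k=%d)\n",
              nrow(x$coords), x$k, x$resolution, x$embedding$n_pcs, x$snn_k))
  print(table(cluster = x$labels))
  invisible(x)
}
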