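#' Re-fit reference regressions on a new cohort, structure frozen
#'
#' The learned graph and Markov blankets are kept fixed; only the regression
#' coefficients and residual SDs are re-estimated on the new cohort's own
#' reference samples, so cohort-wide location/scale differences are absorbed
#' without re-learning structure. Genes absent from the new cohort (>= 90%
#' overlap required) are dropped from the model and from other genes'
#' blankets with a warning.
#'
#' @param new_ref_expr [expression_matrix()] of the new cohort's reference
#'   samples, normalized on that cohort's reference statistics.
#' @param model a `gene_network_model` (regressions may be stale).
#' @param blanket_cap see [fit_reference_regressions()].
#' @return a `gene_network_model` with refreshed regressions.
#' @export
refit_on_new_reference <- function(new_ref_expr, model, blanket_cap = NULL) {
  new_ref_expr <- as_expr_matrix(new_ref_expr)
  shared <- intersect(model$genes, rownames(new_ref_expr))
  if (length(shared) < 0.9 * length(model$genes))
    stop("new cohort covers only ", length(shared), "/", length(model$genes),
         " model genes (< 90%); refusing to refit")
  if (length(shared) < length(model$genes)) {
    warning("dropping ", length(model$genes) - length(shared),
            " gene(s) absent from the new cohort")
    model <- drop_genes(model, setdiff(model$genes, shared))
  }
  fit_reference_regressions(new_ref_expr[model$genes, , drop = FALSE],
                            model, blanket_cap = blanket_cap)
}

#' Project deregulation features into a frozen PCA embedding
#'
#' `coords = (features - stored means) / stored scales %*% loadings`; nothing
#' is re-fit. Features the embedding knows but the matrix lacks are imputed
#' at the stored mean (zero after centering) with a warning. A fingerprint
#' mismatch between the deregulation matrix and the embedding lineage is
#' refused unless `force = TRUE`.
#'
#' @param dereg_new a `dereg_matrix` for the new samples.
#' @param embedding an `embedding_model` from [fit_pca()].
#' @param force skip the model-fingerprint lineage check.
#' @return samples x n_pcs coordinate matrix.
#' @export
project_to_embedding <- function(dereg_new, embedding, force = FALSE) {
  fp_d <- attr(dereg_new, "model_fingerprint")
  fp_e <- embedding$model_fingerprint
  if (!force && !is.null(fp_d) && !is.null(fp_e) && !identical(fp_d, fp_e))
    stop("deregulation matrix and embedding come from different models; ",
         "use force = TRUE to override")
  feats <- names(embedding$feature_means)
  X <- matrix(0, nrow(dereg_new), length(feats),
              dimnames = list(rownames(dereg_new), feats))
  have <- intersect(feats, colnames(dereg_new))
  if (length(have) < length(feats))
    warning("imputing ", length(feats) - length(have),
            " missing feature(s) at the stored mean")
  X[, have] <- unclass(dereg_new)[, have, drop = FALSE]
  X[, setdiff(feats, have)] <-
    rep(embedding$feature_means[setdiff(feats, have)], each = nrow(X))
  Xc <- sweep(sweep(X, 2, embedding$feature_means), 2,
              embedding$feature_scales, "/")
  Xc %*% embedding$loadings
}

#' kNN subtype assignment in PC space
#'
#' Euclidean k-nearest-neighbor majority vote over the training coordinates;
#' a tied vote is resolved by the label of the single nearest neighbor.
#' Neighbor ties in distance are broken by training-sample order.
#'
#' @param coords_new query samples x dims matrix.
#' @param coords_train training samples x dims matrix.
#' @param labels_train per-training-sample cluster labels.
#' @param k neighborhood size (1 <= k <= n_train; even k draws a warning).
#' @return data.frame: `sample_id`, `cluster`, `vote_share`, `nearest_dist`.
#' @export
knn_assign <- function(coords_new, coords_train, labels_train, k = 3) {
  if (k <= 0) stop("`k` must be positive")
  if (k > nrow(coords_train)) stop("`k` exceeds the training-set size")
  if (k %% 2 == 0) warning("even k makes vote ties more likely")
  labels_train <- as.integer(labels_train)
  n <- nrow(coords_new)
  cl <- integer(n); share <- numeric(n); nd <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- colSums((t(coords_train) - coords_new[i, ])^2)
    ord <- order(d2, seq_along(d2))[seq_len(k)]
    votes <- table(labels_train[ord])
    top <- names(votes)[votes == max(votes)]
    win <- if (length(top) > 1) as.character(labels_train[ord[1]]) else top
    cl[i] <- as.integer(win)
    share[i] <- votes[[win]] / k
    nd[i] <- sqrt(d2[ord[1]])
  }
  ids <- rownames(coords_new)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  data.frame(sample_id = ids, cluster = cl, vote_share = share,
             nearest_dist = nd, row.names = NULL)
}

#' Stability scan over kNN neighborhood sizes
#'
#' Assigns the query samples at every `k` in the grid and chooses the
#' smallest `k` from which the assignments are identical (ARI = 1) across at
#' least two consecutive grid points. If none is stable, the smallest grid
#' `k` is returned with a warning.
#'
#' @param coords_new,coords_train,labels_train as in [knn_assign()].
#' @param k_grid nonempty increasing grid of neighborhood sizes.
#' @return list with `k` (chosen), `assignments` (data.frame from
#'   [knn_assign()] at the chosen k) and `stability_table` (data.frame:
#'   k, ari_with_next).
#' @export
k_stability_scan <- function(coords_new, coords_train, labels_train,
                             k_grid = 1:10) {
  if (!length(k_grid)) stop("`k_grid` must be nonempty")
  k_grid <- sort(unique(as.integer(k_grid)))
  asg <- lapply(k_grid, function(k)
    suppressWarnings(knn_assign(coords_new, coords_train, labels_train, k)))
  m <- length(k_grid)
  if (m == 1) {
    warning("k_grid has a single value; no stability information")
    return(list(k = k_grid, assignments = asg[[1]],
                stability_table = data.frame(k = k_grid, ari_with_next = NA)))
  }
  ari_next <- c(vapply(seq_len(m - 1), function(i)
    mclust::adjustedRandIndex(asg[[i]]$cluster, asg[[i + 1]]$cluster),
    numeric(1)), NA)
  stable <- which(abs(ari_next[-m] - 1) < 1e-12)
  if (length(stable)) {
    i <- stable[1]
  } else {
    warning("no stable k in the grid; returning the smallest")
    i <- 1
  }
  list(k = k_grid[i], assignments = asg[[i]],
       stability_table = data.frame(k = k_grid, ari_with_next = ari_next))
}
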