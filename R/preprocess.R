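#' Reference-sample selection criteria
#'
#' Operationalizes the conservative control definition used to learn the
#' baseline network from former smokers: both study visits present, normal
#' spirometry (FEV1/FVC >= 0.70 and FEV1 percent predicted >= 80) at both
#' visits, below-threshold CT emphysema at both visits, and a bounded decline
#' in FEV1 percent predicted between visits. Samples failing any enabled
#' criterion become cases; samples with missing spirometry can be forced into
#' the case group (the rule used for cohorts with incomplete spirometry).
#'
#' @param require_both_visits require `has_both_visits` to be TRUE.
#' @param normal_spirometry_both require normal spirometry at both visits.
#' @param max_emphysema_pct emphysema threshold in percent (strict `<`).
#' @param max_fev1pp_decline allowed drop in FEV1 percent predicted between
#'   visits (strict `<`; 5 for the discovery/validation rule, 3 for the
#'   stricter variant).
#' @param include_missing_spirometry_as_case send samples with any missing
#'   spirometry field to the case group instead of erroring.
#' @return a `reference_criteria` list.
#' @export
reference_criteria <- function(require_both_visits = TRUE,
                               normal_spirometry_both = TRUE,
                               max_emphysema_pct = 5,
                               max_fev1pp_decline = 5,
                               include_missing_spirometry_as_case = TRUE) {
  if (max_emphysema_pct < 0 || max_fev1pp_decline < 0)
    stop("criteria thresholds must be >= 0")
  structure(list(require_both_visits = require_both_visits,
                 normal_spirometry_both = normal_spirometry_both,
                 max_emphysema_pct = max_emphysema_pct,
                 max_fev1pp_decline = max_fev1pp_decline,
                 include_missing_spirometry_as_case = include_missing_spirometry_as_case),
            class = "reference_criteria")
}

#' Partition samples into reference (control) and case groups
#'
#' A sample is reference iff every enabled criterion passes. The required
#' phenotype columns are `has_both_visits`, `visit1_fev1_fvc`,
#' `visit2_fev1_fvc`, `visit1_fev1pp`, `visit2_fev1pp`, `visit1_emph_pct`,
#' `visit2_emph_pct` (only those named by enabled criteria are required).
#'
#' @param phenotypes data.frame with sample IDs as rownames.
#' @param criteria a [reference_criteria()].
#' @return list with `reference_ids` and `case_ids` (character vectors that
#'   partition `rownames(phenotypes)`).
#' @export
select_reference <- function(phenotypes, criteria = reference_criteria()) {
  if (nrow(phenotypes) == 0)
    return(list(reference_ids = character(), case_ids = character()))
  need <- c()
  if (criteria$require_both_visits) need <- c(need, "has_both_visits")
  if (criteria$normal_spirometry_both)
    need <- c(need, "visit1_fev1_fvc", "visit2_fev1_fvc",
              "visit1_fev1pp", "visit2_fev1pp")
  if (is.finite(criteria$max_emphysema_pct))
    need <- c(need, "visit1_emph_pct", "visit2_emph_pct")
  if (is.finite(criteria$max_fev1pp_decline))
    need <- c(need, "visit1_fev1pp", "visit2_fev1pp")
  missing_cols <- setdiff(unique(need), colnames(phenotypes))
  if (length(missing_cols))
    stop("phenotype table lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  spiro_cols <- intersect(unique(need), colnames(phenotypes))
  has_na <- Reduce(`|`, lapply(phenotypes[spiro_cols], is.na))
  ok <- rep(TRUE, nrow(phenotypes))
  if (criteria$require_both_visits)
    ok <- ok & phenotypes$has_both_visits %in% TRUE
  if (criteria$normal_spirometry_both)
    ok <- ok &
      phenotypes$visit1_fev1_fvc >= 0.70 & phenotypes$visit2_fev1_fvc >= 0.70 &
      phenotypes$visit1_fev1pp >= 80 & phenotypes$visit2_fev1pp >= 80
  if (is.finite(criteria$max_emphysema_pct))
    ok <- ok & phenotypes$visit1_emph_pct < criteria$max_emphysema_pct &
      phenotypes$visit2_emph_pct < criteria$max_emphysema_pct
  if (is.finite(criteria$max_fev1pp_decline))
    ok <- ok & (phenotypes$visit1_fev1pp - phenotypes$visit2_fev1pp) <
      criteria$max_fev1pp_decline
  if (any(has_na)) {
    if (!criteria$include_missing_spirometry_as_case)
      stop("missing spirometry for ",
           sum(has_na), " sample(s); set include_missing_spirometry_as_case")
    ok[has_na] <- FALSE
  }
  ok[is.na(ok)] <- FALSE
  ids <- rownames(phenotypes)
  list(reference_ids = ids[ok], case_ids = ids[!ok])
}

#' Filter genes and normalize expression on reference statistics
#'
#' Removes genes expressed (non-zero) in fewer than `min_nonzero_frac` of all
#' samples, ranks the survivors by variance across the *reference* samples
#' and keeps the `top_n_variable` most variable, applies `log2(CPM + 1)` if
#' the input looks like integer counts, then centers and scales each gene
#' using the reference-sample mean and SD only — case samples never
#' contribute to any statistic used here.
#'
#' @param expr an [expression_matrix()].
#' @param ref_ids reference sample IDs (subset of colnames).
#' @param min_nonzero_frac minimum fraction of samples with non-zero signal.
#' @param top_n_variable number of genes to keep (clamped with a warning if
#'   fewer survive filtering).
#' @return an [expression_matrix()] with attributes `ref_means`/`ref_sds`
#'   (the reference statistics used) and `ref_ids`.
#' @export
filter_and_normalize <- function(expr, ref_ids, min_nonzero_frac = 0.2,
                                 top_n_variable = 500) {
  expr <- as_expr_matrix(expr)
  if (!all(ref_ids %in% colnames(expr)))
    stop("`ref_ids` must be a subset of the sample IDs")
  Y <- unclass_expr(expr)
  if (all(Y == round(Y)) && all(Y >= 0) && any(Y > 30)) {
    # integer counts: library-size normalize before the Gaussian-scale steps
    cpm <- sweep(Y, 2, pmax(colSums(Y), 1), "/") * 1e6
    Y <- log2(cpm + 1)
  }
  keep <- rowMeans(Y != 0) >= min_nonzero_frac
  Y <- Y[keep, , drop = FALSE]
  v <- apply(Y[, ref_ids, drop = FALSE], 1, stats::var)
  if (top_n_variable > nrow(Y)) {
    warning("top_n_variable exceeds surviving genes; keeping all ", nrow(Y))
    top_n_variable <- nrow(Y)
  }
  ord <- order(v, decreasing = TRUE)
  Y <- Y[sort(ord[seq_len(top_n_variable)]), , drop = FALSE]
  mu <- rowMeans(Y[, ref_ids, drop = FALSE])
  sd <- apply(Y[, ref_ids, drop = FALSE], 1, stats::sd)
  sd[sd < 1e-12] <- 1
  Y <- (Y - mu) / sd
  out <- expr_like(Y, expr)
  attr(out, "ref_means") <- mu
  attr(out, "ref_sds") <- sd
  attr(out, "ref_ids") <- ref_ids
  out
}

#' Guided-PCA batch-effect detection
#'
#' Quantifies how much of the leading expression variance is aligned with
#' batch: `delta` is the variance of the data along the first right singular
#' vector of the batch-mean matrix (PCA guided by batch indicators) divided
#' by the variance along the first unguided principal component, so
#' `delta` is in `[0, 1]`. Significance comes from permuting batch labels;
#' the p-value uses +1 smoothing.
#'
#' @param expr an [expression_matrix()] (genes x samples).
#' @param batch per-sample batch labels (>= 2 batches, each >= 2 samples).
#' @param n_perm number of label permutations.
#' @param seed integer RNG seed for the permutations.
#' @return list with `delta` and `p`.
#' @export
gpca_batch_delta <- function(expr, batch = attr(expr, "batch"),
                             n_perm = 500, seed = 1) {
  expr <- as_expr_matrix(expr)
  if (is.null(batch)) stop("no batch labels supplied")
  batch <- as.character(batch)
  if (length(batch) != ncol(expr)) stop("batch must cover all samples")
  tb <- table(batch)
  if (length(tb) < 2) stop("guided PCA needs >= 2 batches")
  if (any(tb < 2)) stop("each batch needs >= 2 samples")
  X <- t(unclass_expr(expr))                       # samples x genes
  X <- sweep(X, 2, colMeans(X))
  sv1 <- function(M) svd(M, nu = 0, nv = 1)$v[, 1]
  var_along <- function(v) sum((X %*% v)^2)
  v_un <- sv1(X)
  denom <- var_along(v_un)
  guided_var <- function(b) {
    H <- stats::model.matrix(~ 0 + factor(b))
    var_along(sv1(crossprod(H, X)))                # batch-sum projection
  }
  obs <- guided_var(batch) / denom
  withr_seed(seed, {
    perm <- vapply(seq_len(n_perm),
                   function(i) guided_var(sample(batch)) / denom, numeric(1))
  })
  list(delta = obs, p = (1 + sum(perm >= obs)) / (n_perm + 1))
}

#' Location-scale batch correction
#'
#' Adjusts each gene within each batch to the gene's pooled mean and SD:
#' values are centered at the batch mean, rescaled by pooled SD / batch SD,
#' and recentered at the pooled mean. Purely additive batch offsets are
#' removed exactly. Batches with a single sample get the location step only.
#'
#' @param expr an [expression_matrix()].
#' @param batch per-sample batch labels; `NULL` returns the input unchanged.
#' @return an [expression_matrix()] with the same dimensions.
#' @export
correct_batch <- function(expr, batch = attr(expr, "batch")) {
  expr <- as_expr_matrix(expr)
  if (is.null(batch)) return(expr)
  batch <- as.character(batch)
  if (length(batch) != ncol(expr)) stop("batch must cover all samples")
  if (length(unique(batch)) < 2) return(expr)
  Y <- unclass_expr(expr)
  pooled_mu <- rowMeans(Y)
  pooled_sd <- apply(Y, 1, stats::sd)
  for (b in unique(batch)) {
    j <- which(batch == b)
    mu_b <- rowMeans(Y[, j, drop = FALSE])
    if (length(j) > 1) {
      sd_b <- apply(Y[, j, drop = FALSE], 1, stats::sd)
      scale <- ifelse(sd_b > 1e-12, pooled_sd / sd_b, 1)
    } else {
      warning("batch '", b, "' has a single sample; scale step skipped")
      scale <- 1
    }
    Y[, j] <- (Y[, j, drop = FALSE] - mu_b) * scale + pooled_mu
  }
  expr_like(Y, expr)
}
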