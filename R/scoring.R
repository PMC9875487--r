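#' Score one sample against the reference network
#'
#' The deregulation of gene `g` in a sample is the standardized absolute
#' residual `d_g = |y_g - yhat_g| / residual_sd_g`, where `yhat_g` is the
#' reference regression prediction from the sample's own Markov-blanket
#' values. Zero iff the sample sits exactly on every reference regression;
#' for a sample drawn from the reference population the expected value is
#' `E|Z| = sqrt(2/pi)` per gene.
#'
#' @param sample named numeric vector covering all model genes, on the
#'   model's normalized scale.
#' @param model a `gene_network_model` with fitted regressions.
#' @return named nonnegative numeric vector over the model genes.
#' @export
score_sample <- function(sample, model) {
  if (is.null(model$regressions))
    stop("model has no fitted regressions; run fit_reference_regressions()")
  missing <- setdiff(model$genes, names(sample))
  if (length(missing))
    stop("sample is missing model gene(s): ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ..." else "")
  y <- sample[model$genes]
  if (!all(is.finite(y))) stop("non-finite values in sample")
  d <- vapply(model$genes, function(g) {
    r <- model$regressions[[g]]
    pred <- r$intercept +
      if (length(r$coef)) sum(r$coef * y[names(r$coef)]) else 0
    abs(y[[g]] - pred) / r$residual_sd
  }, numeric(1))
  stats::setNames(d, model$genes)
}

#' Score a cohort into a deregulation matrix
#'
#' Row-wise application of [score_sample()] over the columns of `expr`.
#' Gene sets may differ from the model by up to 10% (intersected with a
#' warning); larger mismatches are refused.
#'
#' @param expr [expression_matrix()] normalized consistently with the
#'   model's training data.
#' @param model a `gene_network_model` with fitted regressions.
#' @return a `dereg_matrix`: samples x genes nonnegative matrix with
#'   attribute `model_fingerprint`.
#' @export
score_cohort <- function(expr, model) {
  expr <- as_expr_matrix(expr)
  if (is.null(model$regressions))
    stop("model has no fitted regressions; run fit_reference_regressions()")
  shared <- intersect(model$genes, rownames(expr))
  if (length(shared) < 0.9 * length(model$genes))
    stop("expression covers only ", length(shared), "/", length(model$genes),
         " model genes (< 90%); refusing to score")
  if (length(shared) < length(model$genes)) {
    warning("scoring on ", length(shared), "/", length(model$genes),
            " shared genes")
    model <- drop_genes(model, setdiff(model$genes, shared))
  }
  Y <- unclass_expr(expr)[model$genes, , drop = FALSE]
  # vectorized over samples: prediction = intercept + coef . blanket values
  D <- matrix(0, ncol(Y), length(model$genes),
              dimnames = list(colnames(Y), model$genes))
  for (g in model$genes) {
    r <- model$regressions[[g]]
    pred <- r$intercept +
      if (length(r$coef)) drop(crossprod(Y[names(r$coef), , drop = FALSE], r$coef)) else 0
    D[, g] <- abs(Y[g, ] - pred) / r$residual_sd
  }
  dereg_matrix(D, model_fingerprint(model))
}

dereg_matrix <- function(values, fingerprint) {
  stopifnot(all(values >= 0))
  structure(values, model_fingerprint = fingerprint,
            class = c("dereg_matrix", "matrix"))
}

#' @export
print.dereg_matrix <- function(x, ...) {
  cat(sprintf("<dereg_matrix> %d samples x %d genes (model %s)\n",
              nrow(x), ncol(x),
              substr(attr(x, "model_fingerprint"), 1, 8)))
  invisible(x)
}

# Remove genes from a model: drops their regressions and their occurrences
# in other genes' blankets/coefficients.
drop_genes <- function(model, drop) {
  keep <- setdiff(model$genes, drop)
  model$genes <- keep
  model$edges <- model$edges[model$edges$from %in% keep &
                             model$edges$to %in% keep, , drop = FALSE]
  model$blankets <- lapply(model$blankets[keep], function(b) setdiff(b, drop))
  if (!is.null(model$regressions)) {
    model$regressions <- lapply(model$regressions[keep], function(r) {
      r$coef <- r$coef[setdiff(names(r$coef), drop)]
      r
    })
  }
  model
}

#' Write / read a deregulation matrix as TSV + fingerprint sidecar
#'
#' @param dereg a `dereg_matrix`.
#' @param path TSV path; a JSON sidecar `<path>.json` carries the model
#'   fingerprint.
#' @return `path` (write) or the restored `dereg_matrix` (read).
#' @export
write_dereg <- function(dereg, path) {
  df <- data.frame(sample_id = rownames(dereg),
                   unclass(dereg)[, , drop = FALSE], check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(model_fingerprint = attr(dereg, "model_fingerprint")),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_dereg
#' @export
read_dereg <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dereg_matrix(m, side$model_fingerprint)
}
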