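#' Learn a reference gene network by greedy penalized-BIC search
#'
#' Score-based structure learning over Gaussian DAG models. The forward phase
#' repeatedly adds the directed edge with the largest positive gain in
#' penalized Gaussian BIC (no cycles allowed); the backward phase repeatedly
#' deletes the edge whose removal most improves the score; the resulting DAG
#' is then converted to its completed partially directed graph (CPDAG) so
#' that only compelled edge directions are reported. All scoring runs on the
#' sample covariance of the reference data, so the result is invariant to
#' sample order; ties in gain are broken lexicographically by gene ID for
#' determinism.
#'
#' The local score of gene `j` with parent set `P` is
#' `-n/2 * log(sigma2_hat(j | P)) - penalty * (|P| + 1)/2 * log(n)`,
#' with the conditional variance computed from the covariance matrix.
#'
#' @param ref_expr reference-sample [expression_matrix()] (genes x samples),
#'   expected on the standardized scale produced by [filter_and_normalize()].
#' @param penalty multiplier (> 0) on the BIC complexity term; 1 is standard
#'   BIC, larger values give sparser graphs.
#' @param min_samples refuse to learn below this many reference samples.
#' @return a `gene_network_model`: list with `genes`, `edges` (data.frame
#'   `from`, `to`, `directed`; undirected edges stored once with
#'   `from < to`), `blankets` (named list of gene-ID vectors), empty
#'   `regressions` (see [fit_reference_regressions()]), `penalty`, and a
#'   `score_trace` of total-score values across forward-phase steps.
#' @export
learn_network <- function(ref_expr, penalty = 1, min_samples = 20) {
  ref_expr <- as_expr_matrix(ref_expr)
  n <- ncol(ref_expr)
  if (n < min_samples)
    stop("need at least ", min_samples, " reference samples to learn a network (got ", n, ")")
  Y <- unclass_expr(ref_expr)
  if (!all(is.finite(Y))) stop("non-finite expression values")
  genes <- rownames(Y)
  p <- length(genes)
  S <- stats::cov(t(Y)) * (n - 1) / n        # MLE covariance
  dag <- greedy_dag_search(S, n, penalty, genes)
  cp <- dag_to_cpdag(dag$parents, p)
  edges <- cpdag_edges(cp, genes)
  blankets <- all_markov_blankets(cp, genes)
  structure(list(genes = genes, edges = edges, blankets = blankets,
                 regressions = NULL, penalty = penalty,
                 score_trace = dag$trace,
                 meta = list(n_ref = n)),
            class = "gene_network_model")
}

#' @export
print.gene_network_model <- function(x, ...) {
  cat(sprintf("<gene_network_model> %d genes, %d edges (%d directed), penalty %.2f\n",
              length(x$genes), nrow(x$edges), sum(x$edges$directed), x$penalty))
  if (!is.null(x$regressions)) cat("  reference regressions fitted\n")
  invisible(x)
}

# Conditional variance of node j given parent set P, from covariance S.
cond_var <- function(S, j, P) {
  if (!length(P)) return(max(S[j, j], 1e-12))
  b <- solve(S[P, P, drop = FALSE], S[P, j])
  max(S[j, j] - sum(S[P, j] * b), 1e-12)
}

local_score <- function(S, n, penalty, j, P)
  -n / 2 * log(cond_var(S, j, P)) - penalty * (length(P) + 1) / 2 * log(n)

# Hill-climbing DAG search with an incrementally maintained gain cache.
# Returns parent-set list (indices) and the total-score trace of the forward
# phase (monotone nondecreasing by construction).
greedy_dag_search <- function(S, n, penalty, genes) {
  p <- nrow(S)
  parents <- vector("list", p)
  for (j in seq_len(p)) parents[[j]] <- integer(0)
  complexity <- penalty / 2 * log(n)
  # gain[i, j]: score change from adding i -> j given current parents[[j]]
  R <- stats::cov2cor(S)
  gain <- -n / 2 * log(pmax(1 - R^2, 1e-12)) - complexity
  diag(gain) <- -Inf
  reach <- diag(p) == 1                     # reach[i, j]: i reaches j
  sig2 <- vapply(seq_len(p), function(j) max(S[j, j], 1e-12), numeric(1))
  refresh_gains <- function(j) {
    P <- parents[[j]]
    cand <- setdiff(which(!reach[j, ]), c(j, P))
    gain[P, j] <<- -Inf
    if (!length(cand)) return(invisible())
    if (!length(P)) {
      gain[cand, j] <<- -n / 2 * log(pmax(1 - R[cand, j]^2, 1e-12)) - complexity
      return(invisible())
    }
    b <- solve(S[P, P, drop = FALSE], S[P, j])
    B <- solve(S[P, P, drop = FALSE], S[P, cand, drop = FALSE])
    v <- pmax(diag(S)[cand] - colSums(S[P, cand, drop = FALSE] * B), 1e-12)
    cv <- S[cand, j] - drop(crossprod(S[P, cand, drop = FALSE], b))
    s_new <- pmax(sig2[j] - cv^2 / v, 1e-12)
    gain[cand, j] <<- -n / 2 * log(s_new / sig2[j]) - complexity
  }
  total <- sum(-n / 2 * log(sig2) - complexity)
  trace <- total
  # forward phase
  repeat {
    g <- max(gain)
    if (g <= 1e-9) break
    hits <- which(gain >= g - 1e-12, arr.ind = TRUE)
    hit <- hits[order(genes[hits[, 1]], genes[hits[, 2]])[1], ]
    i <- hit[[1]]; j <- hit[[2]]
    parents[[j]] <- sort(c(parents[[j]], i))
    anc <- c(which(reach[, i]), i)
    desc <- c(which(reach[j, ]), j)
    reach[anc, desc] <- TRUE
    gain[t(reach)] <- -Inf                     # cycle-forbidden pairs
    sig2[j] <- cond_var(S, j, parents[[j]])
    refresh_gains(j)
    total <- total + g
    trace <- c(trace, total)
  }
  # backward phase: delete while score improves
  repeat {
    best <- NULL; best_gain <- 1e-9
    for (j in seq_len(p)) {
      P <- parents[[j]]
      if (!length(P)) next
      s_cur <- -n / 2 * log(sig2[j]) - (length(P) + 1) * complexity
      for (i in P) {
        s_new <- local_score(S, n, penalty, j, setdiff(P, i))
        if (s_new - s_cur > best_gain + 1e-12 ||
            (s_new - s_cur > best_gain - 1e-12 && !is.null(best) &&
             order_pair(genes, c(i, j), best))) {
          best <- c(i, j); best_gain <- s_new - s_cur
        }
      }
    }
    if (is.null(best)) break
    j <- best[2]
    parents[[j]] <- setdiff(parents[[j]], best[1])
    sig2[j] <- cond_var(S, j, parents[[j]])
  }
  list(parents = parents, trace = trace)
}

# TRUE if pair a should be preferred over pair b lexicographically by gene ID
order_pair <- function(genes, a, b) {
  ka <- paste(genes[a[1]], genes[a[2]]); kb <- paste(genes[b[1]], genes[b[2]])
  ka < kb
}

# DAG (parent lists) -> CPDAG adjacency coding:
# amat[i, j] = 1 and amat[j, i] = 0  means i -> j;
# amat[i, j] = amat[j, i] = 1        means i - j (undirected).
# Start from skeleton + v-structure orientations, close under Meek R1-R3.
dag_to_cpdag <- function(parents, p) {
  amat <- matrix(0L, p, p)
  for (j in seq_len(p)) if (length(parents[[j]])) {
    amat[parents[[j]], j] <- 1L
    amat[j, parents[[j]]] <- 1L
  }
  oriented <- matrix(FALSE, p, p)       # oriented[i, j]: i -> j compelled
  for (j in seq_len(p)) {
    P <- parents[[j]]
    if (length(P) < 2) next
    for (a in P) for (b in P) {
      if (a < b && amat[a, b] == 0L) {  # unshielded collider a -> j <- b
        oriented[a, j] <- TRUE
        oriented[b, j] <- TRUE
      }
    }
  }
  repeat {
    changed <- FALSE
    und <- which(amat == 1L & t(amat) == 1L & !oriented & !t(oriented),
                 arr.ind = TRUE)
    for (r in seq_len(nrow(und))) {
      a <- und[r, 1]; b <- und[r, 2]
      if (oriented[a, b] || oriented[b, a]) next
      # R1: c -> a, a - b, c and b nonadjacent  =>  a -> b
      r1 <- any(oriented[, a] & amat[, b] == 0L & seq_len(p) != b)
      # R2: a -> c -> b and a - b  =>  a -> b
      r2 <- any(oriented[a, ] & oriented[, b])
      # R3: a - c1 -> b, a - c2 -> b, c1,c2 nonadjacent, a - b  =>  a -> b
      und_a <- amat[a, ] == 1L & !oriented[a, ] & !oriented[, a]
      cs <- which(und_a & oriented[, b])
      r3 <- length(cs) >= 2 &&
        any(amat[cs, cs, drop = FALSE] == 0L & !diag(length(cs)))
      if (r1 || r2 || r3) {
        oriented[a, b] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # encode: compelled keeps one direction, everything else undirected
  out <- amat
  out[t(oriented)] <- 0L
  out
}

cpdag_edges <- function(amat, genes) {
  p <- length(genes)
  from <- character(0); to <- character(0); directed <- logical(0)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (amat[i, j] == 1L && amat[j, i] == 0L) {
      from <- c(from, genes[i]); to <- c(to, genes[j]); directed <- c(directed, TRUE)
    } else if (i < j && amat[i, j] == 1L && amat[j, i] == 1L) {
      from <- c(from, genes[i]); to <- c(to, genes[j]); directed <- c(directed, FALSE)
    }
  }
  df <- data.frame(from = from, to = to, directed = directed,
                   stringsAsFactors = FALSE)
  df[order(df$from, df$to), , drop = FALSE]
}

# Markov blanket of every gene from the CPDAG adjacency: parents, children
# and co-parents. Undirected neighbors count as both parent and child, but
# co-parents are collected from compelled (directed) edges only — in every
# DAG of the equivalence class an undirected chain neighbor is never forced
# to be a spouse.
all_markov_blankets <- function(amat, genes) {
  p <- length(genes)
  dir_parents_of <- function(j) which(amat[, j] == 1L & amat[j, ] == 0L)
  bl <- vector("list", p)
  for (g in seq_len(p)) {
    nbrs <- which(amat[, g] == 1L | amat[g, ] == 1L)
    ch <- which(amat[g, ] == 1L)                     # directed out + undirected
    spouses <- unlist(lapply(ch, dir_parents_of))
    bl[[g]] <- sort(genes[setdiff(unique(c(nbrs, spouses)), g)])
  }
  names(bl) <- genes
  bl
}

#' Markov blankets from an oriented edge list
#'
#' Recomputes every gene's blanket from a `data.frame(from, to, directed)`
#' edge list using the same parent/child/co-parent rules as
#' [learn_network()]; useful for hand-built models and deserialization.
#'
#' @param genes gene ID vector.
#' @param edges data.frame with `from`, `to`, `directed` columns (undirected
#'   edges listed once).
#' @return named list of blanket gene-ID vectors.
#' @export
blankets_from_edges <- function(genes, edges) {
  p <- length(genes)
  amat <- matrix(0L, p, p, dimnames = list(genes, genes))
  if (nrow(edges)) {
    amat[cbind(edges$from, edges$to)] <- 1L
    und <- !edges$directed
    if (any(und)) amat[cbind(edges$to[und], edges$from[und])] <- 1L
  }
  all_markov_blankets(amat, genes)
}

#' Markov blanket of a gene
#'
#' Parents, children and co-parents in the learned graph; undirected
#' neighbors count as both parent and child.
#'
#' @param model a `gene_network_model`.
#' @param gene gene ID present in the model.
#' @return character vector of blanket gene IDs (never contains `gene`).
#' @export
markov_blanket <- function(model, gene) {
  if (!gene %in% model$genes) stop("unknown gene: ", gene)
  model$blankets[[gene]]
}

#' Fit per-gene reference regressions over Markov blankets
#'
#' For every gene, ordinary least squares of the gene on its Markov blanket
#' across the reference samples; `residual_sd` uses denominator
#' `n - p - 1` and is floored at 1e-6. Genes with an empty blanket get an
#' intercept-only model whose `residual_sd` is the reference SD. Blankets
#' larger than `min(n/5, 20)` (or `n - 3`) are truncated to the members with
#' the largest absolute standardized coefficients (marginal screen), with a
#' warning.
#'
#' @param ref_expr reference [expression_matrix()] on the same gene set and
#'   normalized scale the model was learned on.
#' @param model a `gene_network_model`.
#' @param blanket_cap maximum regressors per gene; default `min(n/5, 20)`.
#' @return the model with `regressions` populated: per gene a list with
#'   `intercept`, `coef` (named over blanket members used) and `residual_sd`.
#' @export
fit_reference_regressions <- function(ref_expr, model, blanket_cap = NULL) {
  ref_expr <- as_expr_matrix(ref_expr)
  if (!setequal(rownames(ref_expr), model$genes))
    stop("reference expression gene set must match the model gene set")
  Y <- t(unclass_expr(ref_expr))[, model$genes, drop = FALSE]   # samples x genes
  n <- nrow(Y)
  if (is.null(blanket_cap)) blanket_cap <- max(1, min(floor(n / 5), 20))
  blanket_cap <- min(blanket_cap, n - 3)
  regs <- vector("list", length(model$genes))
  names(regs) <- model$genes
  truncated <- character(0)
  for (g in model$genes) {
    bl <- model$blankets[[g]]
    if (length(bl) > blanket_cap) {
      sc <- abs(stats::cor(Y[, g], Y[, bl]))
      bl <- bl[order(-sc)][seq_len(blanket_cap)]
      bl <- sort(bl)
      truncated <- c(truncated, g)
    }
    if (!length(bl)) {
      regs[[g]] <- list(intercept = mean(Y[, g]), coef = stats::setNames(numeric(0), character(0)),
                        residual_sd = max(stats::sd(Y[, g]), 1e-6))
      next
    }
    X <- cbind(1, Y[, bl, drop = FALSE])
    fit <- stats::lm.fit(X, Y[, g])
    rss <- sum(fit$residuals^2)
    df <- max(n - length(bl) - 1, 1)
    regs[[g]] <- list(intercept = unname(fit$coefficients[1]),
                      coef = stats::setNames(unname(fit$coefficients[-1]), bl),
                      residual_sd = max(sqrt(rss / df), 1e-6))
  }
  if (length(truncated))
    warning("blanket truncated to ", blanket_cap, " regressors for ",
            length(truncated), " gene(s)")
  model$regressions <- regs
  model$meta$n_ref <- n
  model
}

#' Serialize / restore a gene network model
#'
#' The JSON document carries genes, oriented edges, blankets, fitted
#' regressions, the penalty and training metadata, and is the hand-off
#' artifact between discovery and projection.
#'
#' @param model a `gene_network_model`.
#' @param path JSON file path.
#' @return `path` (write) or the restored model (read).
#' @export
write_network_model <- function(model, path) {
  regs <- model$regressions
  if (!is.null(regs))
    regs <- lapply(regs, function(r)
      list(intercept = r$intercept, coef = as.list(r$coef),
           residual_sd = r$residual_sd))
  doc <- list(genes = model$genes, edges = model$edges,
              blankets = model$blankets,
              regressions = regs,
              penalty = model$penalty, meta = model$meta)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_network_model
#' @export
read_network_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  regs <- NULL
  if (!is.null(doc$regressions)) {
    regs <- lapply(doc$regressions, function(r)
      list(intercept = r$intercept,
           coef = stats::setNames(as.numeric(unlist(r$coef)),
                                  names(unlist(r$coef))),
           residual_sd = r$residual_sd))
  }
  blankets <- lapply(doc$blankets, function(b) as.character(unlist(b)))
  names(blankets) <- doc$genes
  structure(list(genes = doc$genes,
                 edges = as.data.frame(doc$edges),
                 blankets = blankets, regressions = regs,
                 penalty = doc$penalty, meta = doc$meta),
            class = "gene_network_model")
}

#' Fingerprint of a fitted network model
#'
#' MD5 over the canonical JSON serialization; used to tie deregulation
#' matrices and embeddings to the exact model that produced them.
#'
#' @param model a `gene_network_model`.
#' @return character MD5 string.
#' @export
model_fingerprint <- function(model) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  write_network_model(model, tf)
  unname(tools::md5sum(tf))
}
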