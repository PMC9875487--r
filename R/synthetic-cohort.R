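#' Simulate a random gene-regulatory DAG
#'
#' Genes are placed in a fixed topological order and each forward edge is
#' included independently with probability `expected_degree / (n_genes - 1)`,
#' giving an Erdos-Renyi-style DAG with the requested expected in+out degree.
#' Edge weights are drawn uniformly from +/-\[0.5, 1.5\] so that no edge sits
#' in the near-zero band where structure recovery is hopeless at realistic
#' sample sizes.
#'
#' @param n_genes number of genes (>= 2).
#' @param expected_degree expected total degree per gene (> 0; 0 gives an
#'   empty graph).
#' @param seed integer RNG seed; identical seeds give identical networks.
#' @param noise_sd per-gene structural noise SD (recycled; default 1).
#' @return a `true_network`: list with `genes` (IDs `g001`, ...), `edges`
#'   (data.frame `from`, `to`, `weight`, parent before child in topological
#'   order) and `noise_sd` (named per gene).
#' @export
generate_dag <- function(n_genes, expected_degree, seed, noise_sd = 1) {
  if (!is.numeric(n_genes) || n_genes < 2) stop("`n_genes` must be >= 2")
  if (expected_degree < 0) stop("`expected_degree` must be >= 0")
  genes <- sprintf("g%03d", seq_len(n_genes))
  p_edge <- min(1, expected_degree / (n_genes - 1))
  withr_seed(seed, {
    pairs <- which(upper.tri(matrix(0, n_genes, n_genes)), arr.ind = TRUE)
    keep <- stats::runif(nrow(pairs)) < p_edge
    pairs <- pairs[keep, , drop = FALSE]
    w <- stats::runif(nrow(pairs), 0.5, 1.5) *
      sample(c(-1, 1), nrow(pairs), replace = TRUE)
  })
  edges <- data.frame(from = genes[pairs[, 1]], to = genes[pairs[, 2]],
                      weight = w, stringsAsFactors = FALSE)
  noise_sd <- stats::setNames(rep_len(noise_sd, n_genes), genes)
  if (any(noise_sd <= 0)) stop("`noise_sd` must be positive")
  structure(list(genes = genes, edges = edges, noise_sd = noise_sd),
            class = "true_network")
}

#' @export
print.true_network <- function(x, ...) {
  cat(sprintf("<true_network> %d genes, %d edges\n",
              length(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Define a subtype perturbation
#'
#' A subtype perturbs a distinct subset of genes by adding `mean_shift` to
#' their structural equations and multiplying their incoming edge weights by
#' `weight_scale`; it also carries the subtype's survival hazard and clinical
#' effects used by [simulate_clinical()].
#'
#' @param subtype_id small integer label (0-based in the default design).
#' @param perturbed_genes character vector of gene IDs.
#' @param mean_shift additive shift applied to each perturbed gene.
#' @param weight_scale multiplier (>= 0) on incoming edges of perturbed genes.
#' @param hazard_rate exponential event hazard (> 0, per time unit).
#' @param clinical_effect named numeric vector of per-variable subtype means /
#'   rates consumed by [simulate_clinical()] (`lung_function`,
#'   `symptom_score`, `medication` probability).
#' @return a `subtype_spec` list.
#' @export
subtype_spec <- function(subtype_id, perturbed_genes, mean_shift = 0,
                         weight_scale = 1, hazard_rate = 0.1,
                         clinical_effect = c(lung_function = 0,
                                             symptom_score = 1,
                                             medication = 0.05)) {
  if (weight_scale < 0) stop("`weight_scale` must be >= 0")
  if (hazard_rate <= 0) stop("`hazard_rate` must be > 0")
  structure(list(subtype_id = as.integer(subtype_id),
                 perturbed_genes = as.character(perturbed_genes),
                 mean_shift = mean_shift, weight_scale = weight_scale,
                 hazard_rate = hazard_rate,
                 clinical_effect = clinical_effect),
            class = "subtype_spec")
}

# Weighted adjacency (parents x children) of a true_network, optionally
# perturbed by a subtype spec.
network_weights <- function(net, spec = NULL) {
  p <- length(net$genes)
  W <- matrix(0, p, p, dimnames = list(net$genes, net$genes))
  if (nrow(net$edges))
    W[cbind(net$edges$from, net$edges$to)] <- net$edges$weight
  if (!is.null(spec) && spec$weight_scale != 1)
    W[, spec$perturbed_genes] <- W[, spec$perturbed_genes] * spec$weight_scale
  W
}

sem_shift_vector <- function(net, spec) {
  s <- stats::setNames(numeric(length(net$genes)), net$genes)
  if (!is.null(spec)) s[spec$perturbed_genes] <- spec$mean_shift
  s
}

#' Closed-form moments of the linear-Gaussian network model
#'
#' For the structural model `y = W' y + shift + eps` the implied mean is
#' `(I - W')^{-1} shift` and the covariance `(I - W)^{-T} D (I - W)^{-1}`
#' with `D = diag(noise_sd^2)`. Used as the analytic oracle for the
#' simulator.
#'
#' @param net a `true_network`.
#' @param spec optional `subtype_spec` perturbation.
#' @return list with `mean` (named vector) and `cov` (gene x gene matrix).
#' @export
sem_moments <- function(net, spec = NULL) {
  W <- network_weights(net, spec)
  p <- length(net$genes)
  A <- solve(diag(p) - t(W))           # y = A (shift + eps)
  mu <- drop(A %*% sem_shift_vector(net, spec))
  D <- diag(net$noise_sd^2, p)
  V <- A %*% D %*% t(A)
  dimnames(V) <- list(net$genes, net$genes)
  list(mean = stats::setNames(mu, net$genes), cov = V)
}

#' Simulate expression by ancestral sampling
#'
#' Each sample is drawn gene-by-gene in topological order:
#' `y_g = sum_p w_pg y_p + shift_g + eps_g`, `eps_g ~ N(0, noise_sd_g^2)`.
#' A `NULL` spec means the control population (all shifts 0, weights
#' unscaled).
#'
#' @param net a `true_network`.
#' @param n_samples number of samples (>= 1).
#' @param spec optional `subtype_spec`; must reference known genes.
#' @param seed integer RNG seed.
#' @param sample_prefix prefix for generated sample IDs.
#' @return an [expression_matrix()] (genes x samples).
#' @export
simulate_expression <- function(net, n_samples, spec = NULL, seed = 1,
                                sample_prefix = "s") {
  if (n_samples < 1) stop("`n_samples` must be >= 1")
  if (!is.null(spec) && !all(spec$perturbed_genes %in% net$genes))
    stop("subtype spec references unknown genes")
  W <- network_weights(net, spec)
  shift <- sem_shift_vector(net, spec)
  p <- length(net$genes)
  withr_seed(seed, {
    E <- matrix(stats::rnorm(p * n_samples, sd = net$noise_sd), p, n_samples)
  })
  Y <- matrix(0, p, n_samples)
  # genes were generated in topological order, so a single forward sweep works
  for (g in seq_len(p)) {
    par <- which(W[, g] != 0)
    Y[g, ] <- shift[g] + E[g, ] +
      if (length(par)) drop(W[par, g] %*% Y[par, , drop = FALSE]) else 0
  }
  dimnames(Y) <- list(net$genes,
                      sprintf("%s%04d", sample_prefix, seq_len(n_samples)))
  expression_matrix(Y)
}

#' Simulate clinical covariates and survival outcomes
#'
#' Emits per sample: a continuous lung-function-like variable (subtype mean +
#' Gaussian noise), an ordinal symptom score (Poisson around the subtype
#' mean, capped at 4), a binary medication flag (Bernoulli with subtype
#' rate), an exponential survival time at the subtype's hazard with
#' independent uniform censoring on `[0, 3 / median(hazard)]`, and the event
#' indicator. Optional distractor variables are standard normal, independent
#' of subtype. With `spirometry = TRUE`, also emits two-visit spirometry /
#' emphysema fields consistent with the subtype labels so that
#' [select_reference()] recovers the designated control samples.
#'
#' @param truth a `synthetic_truth` (see [synthetic_truth()]).
#' @param specs list of `subtype_spec` covering every non-control label.
#' @param seed integer RNG seed.
#' @param n_distractors number of null noise variables to append.
#' @param spirometry emit reference-selection columns as well?
#' @param lung_sd,control_clinical SD of the lung-function variable and the
#'   control group's clinical parameter vector.
#' @return data.frame with rownames = sample IDs; with zero distractors and
#'   `spirometry = FALSE` it has exactly the five core columns
#'   `lung_function`, `symptom_score`, `medication`, `surv_time`, `event`.
#' @export
simulate_clinical <- function(truth, specs, seed = 1, n_distractors = 0,
                              spirometry = FALSE, lung_sd = 10,
                              control_clinical = c(lung_function = 99,
                                                   symptom_score = 0.4,
                                                   medication = 0.023)) {
  labels <- truth$labels
  n <- length(labels)
  ids <- names(labels)
  spec_ids <- vapply(specs, function(s) s$subtype_id, integer(1))
  unknown <- setdiff(setdiff(unique(labels), truth$control_label), spec_ids)
  if (length(unknown))
    stop("labels contain subtypes with no spec: ", paste(unknown, collapse = ", "))
  eff <- function(var) {
    v <- stats::setNames(rep(control_clinical[[var]], n), ids)
    for (s in specs) v[labels == s$subtype_id] <- s$clinical_effect[[var]]
    v
  }
  hz <- stats::setNames(rep(NA_real_, n), ids)
  hz[labels == truth$control_label] <- min(vapply(specs, `[[`, numeric(1), "hazard_rate")) / 2
  for (s in specs) hz[labels == s$subtype_id] <- s$hazard_rate
  withr_seed(seed, {
    lung <- stats::rnorm(n, eff("lung_function"), lung_sd)
    sym <- pmin(stats::rpois(n, eff("symptom_score")), 4L)
    med <- as.integer(stats::runif(n) < eff("medication"))
    t_event <- stats::rexp(n, rate = hz)
    cens_cap <- 3 / stats::median(hz)
    t_cens <- stats::runif(n, 0, cens_cap)
    df <- data.frame(lung_function = lung, symptom_score = sym,
                     medication = med,
                     surv_time = pmin(t_event, t_cens),
                     event = as.integer(t_event <= t_cens),
                     row.names = ids)
    if (n_distractors > 0) {
      Z <- matrix(stats::rnorm(n * n_distractors), n, n_distractors)
      colnames(Z) <- sprintf("null_var_%03d", seq_len(n_distractors))
      df <- cbind(df, Z)
    }
    if (spirometry) df <- cbind(df, simulate_spirometry(labels, truth$control_label))
  })
  df
}

# Two-visit spirometry consistent with reference criteria: controls pass all
# four criteria; every case fails at least one, with failure modes mixed to
# mimic a realistic GOLD-stage composition (obstructed, PRISm, rapid
# decliner, emphysema). Called inside simulate_clinical's seeded block.
simulate_spirometry <- function(labels, control_label) {
  n <- length(labels)
  is_ref <- labels == control_label
  ratio1 <- stats::runif(n, 0.72, 0.85)
  fev1pp1 <- stats::runif(n, 85, 115)
  decline <- stats::runif(n, -3, 4.5)
  emph <- stats::runif(n, 0, 4.5)
  mode <- sample(c("obstructed", "prism", "decliner", "emphysema"), n,
                 replace = TRUE, prob = c(0.55, 0.13, 0.17, 0.15))
  mode[is_ref] <- "none"
  i <- mode == "obstructed"; ratio1[i] <- stats::runif(sum(i), 0.35, 0.68)
  i <- mode == "prism";      fev1pp1[i] <- stats::runif(sum(i), 50, 78)
  i <- mode == "decliner";   decline[i] <- stats::runif(sum(i), 5.5, 15)
  i <- mode == "emphysema";  emph[i] <- stats::runif(sum(i), 6, 30)
  data.frame(has_both_visits = TRUE,
             visit1_fev1_fvc = ratio1, visit2_fev1_fvc = ratio1,
             visit1_fev1pp = fev1pp1, visit2_fev1pp = fev1pp1 - decline,
             visit1_emph_pct = emph, visit2_emph_pct = emph)
}

#' Bundle ground truth for a synthetic cohort
#'
#' @param network the generating `true_network`.
#' @param labels named integer vector of per-sample subtype labels
#'   (`control_label` marks reference samples).
#' @param batch optional named per-sample batch labels.
#' @param control_label the label reserved for reference samples.
#' @return a `synthetic_truth` list.
#' @export
synthetic_truth <- function(network, labels, batch = NULL,
                            control_label = -1L) {
  if (is.null(names(labels))) stop("`labels` must be named by sample ID")
  if (!any(labels == control_label)) stop("control label absent from labels")
  structure(list(network = network, labels = labels, batch = batch,
                 control_label = as.integer(control_label)),
            class = "synthetic_truth")
}

#' Add per-(gene, batch) additive offsets
#'
#' @param expr an [expression_matrix()].
#' @param batch per-sample batch assignment covering every sample.
#' @param shift_sd SD of the Normal(0, shift_sd^2) gene-by-batch offsets;
#'   0 returns the input unchanged.
#' @param seed integer RNG seed.
#' @return an [expression_matrix()] with `batch` attached.
#' @export
add_batch_effect <- function(expr, batch, shift_sd, seed = 1) {
  expr <- as_expr_matrix(expr)
  if (length(batch) != ncol(expr)) stop("batch assignment must cover all samples")
  batch <- as.character(batch)
  out <- unclass_expr(expr)
  if (shift_sd > 0) {
    ub <- sort(unique(batch))
    withr_seed(seed, {
      off <- matrix(stats::rnorm(nrow(expr) * length(ub), sd = shift_sd),
                    nrow(expr), length(ub), dimnames = list(rownames(expr), ub))
    })
    out <- out + off[, batch, drop = FALSE]
    colnames(out) <- colnames(expr)
  }
  expression_matrix(out, batch = batch, cohort = attr(expr, "cohort"))
}

#' Default synthetic study design
#'
#' Mirrors the published COPDGene discovery analysis at desk scale: 128
#' reference samples, four case subtypes of 181/156/79/73 samples (the
#' reported cluster sizes), 200 genes at expected degree 2, each subtype
#' perturbing 12 distinct genes with mean shift 3, subtype hazards
#' 0.08/0.10/0.30/0.12 per year, clinical means per subtype taken from the
#' reported cluster summaries, and two sequencing batches with additive
#' offsets of SD 1.
#'
#' @param n_genes,expected_degree network size parameters.
#' @param n_reference reference-group size.
#' @param case_sizes per-subtype case counts (subtypes labelled `0..K-1`).
#' @param mean_shift,weight_scale,genes_per_subtype perturbation parameters.
#' @param batch_sd additive batch-offset SD (0 disables batch structure).
#' @param n_distractors null clinical variables appended by the simulator.
#' @return a list of class `study_design`.
#' @export
default_design <- function(n_genes = 200, expected_degree = 2,
                           n_reference = 128,
                           case_sizes = c(181L, 156L, 79L, 73L),
                           mean_shift = 3, weight_scale = 1,
                           genes_per_subtype = 12, batch_sd = 1,
                           n_distractors = 0) {
  hazards <- c(0.08, 0.10, 0.30, 0.12)
  lung <- c(74, 73, 65, 65)
  sympt <- c(1.05, 1.14, 1.7, 1.4)
  medic <- c(0.051, 0.013, 0.115, 0.137)
  k <- length(case_sizes)
  structure(list(
    n_genes = n_genes, expected_degree = expected_degree,
    n_reference = n_reference, case_sizes = as.integer(case_sizes),
    mean_shift = mean_shift, weight_scale = weight_scale,
    genes_per_subtype = genes_per_subtype, batch_sd = batch_sd,
    n_distractors = n_distractors,
    hazards = rep_len(hazards, k), lung = rep_len(lung, k),
    symptom = rep_len(sympt, k), medication = rep_len(medic, k)),
    class = "study_design")
}

#' Simulate a full synthetic study cohort
#'
#' Draws a generating network, a reference population and `K` perturbed case
#' subtypes, clinical covariates, survival outcomes and (optionally) batch
#' structure. Perturbed gene sets are disjoint across subtypes, interleaved
#' across the topological order so each subtype touches both hubs and leaves.
#'
#' @param design a [default_design()] (possibly modified).
#' @param seed integer master seed; all stage seeds derive from it.
#' @param network optional `true_network` to reuse (a validation cohort drawn
#'   from the same biology as a discovery cohort); default draws a fresh DAG.
#' @param specs optional subtype-spec list to reuse alongside `network`.
#' @return list with `expr` (genes x samples, batch attached), `phenotypes`
#'   (clinical + spirometry data.frame), `truth` (`synthetic_truth`), and
#'   `specs` (subtype spec list).
#' @export
simulate_study <- function(design = default_design(), seed = 1,
                           network = NULL, specs = NULL) {
  d <- design
  net <- if (is.null(network)) generate_dag(d$n_genes, d$expected_degree, seed = seed)
         else network
  k <- length(d$case_sizes)
  if (is.null(specs)) {
    gene_pool <- net$genes[seq_len(min(length(net$genes),
                                       k * d$genes_per_subtype * 2))]
    specs <- lapply(seq_len(k), function(i) {
      idx <- seq(i, by = k, length.out = d$genes_per_subtype)
      subtype_spec(i - 1L, gene_pool[idx], mean_shift = d$mean_shift,
                   weight_scale = d$weight_scale, hazard_rate = d$hazards[i],
                   clinical_effect = c(lung_function = d$lung[i],
                                       symptom_score = d$symptom[i],
                                       medication = d$medication[i]))
    })
  }
  ref <- simulate_expression(net, d$n_reference, spec = NULL,
                             seed = seed + 1000L, sample_prefix = "ref")
  cases <- lapply(seq_len(k), function(i)
    simulate_expression(net, d$case_sizes[i], spec = specs[[i]],
                        seed = seed + 1000L + i,
                        sample_prefix = sprintf("c%d_", i - 1L)))
  Y <- do.call(cbind, c(list(unclass_expr(ref)), lapply(cases, unclass_expr)))
  labels <- stats::setNames(
    rep(c(-1L, seq_len(k) - 1L), times = c(d$n_reference, d$case_sizes)),
    colnames(Y))
  n <- ncol(Y)
  batch <- NULL
  expr <- expression_matrix(Y)
  if (d$batch_sd > 0) {
    withr_seed(seed + 77L, {
      batch <- stats::setNames(sample(c("b1", "b2"), n, replace = TRUE),
                               colnames(Y))
    })
    expr <- add_batch_effect(expr, batch, shift_sd = d$batch_sd,
                             seed = seed + 78L)
  }
  truth <- synthetic_truth(net, labels, batch = batch)
  pheno <- simulate_clinical(truth, specs, seed = seed + 2000L,
                             n_distractors = d$n_distractors,
                             spirometry = TRUE)
  list(expr = expr, phenotypes = pheno, truth = truth, specs = specs)
}

# Run `code` under a fixed RNG state without disturbing the caller's stream.
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  eval.parent(substitute(code))
}
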