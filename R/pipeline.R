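#' Default pipeline configuration
#'
#' A nested list with one section per stage plus a global seed from which all
#' stage seeds are derived deterministically. Any subset can be overridden;
#' [run_simulate()], [run_discover()] and [run_project()] accept either this
#' list or a YAML file path with the same structure.
#'
#' @param seed global integer seed.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    simulate = list(design = list()),           # overrides for default_design()
    preprocess = list(min_nonzero_frac = 0, top_n_variable = 200,
                      max_fev1pp_decline = 5, n_perm = 200),
    network = list(penalty = 1),
    subtype = list(n_pcs = 6, snn_k = 20,
                   res_grid = seq(0.4, 1.2, by = 0.1)),
    project = list(k = 3),
    associate = list(q_threshold = 0.05)
  )
}

load_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_config(seed = if (!is.null(config$seed)) config$seed else 1)
  modifyList(base, config)
}

stage_seed <- function(config, stage) {
  offsets <- c(simulate = 11, discover = 23, project = 37)
  as.integer((as.numeric(config$seed) %% 1000003) * 1009 + offsets[[stage]])
}

#' Simulate a synthetic study to disk
#'
#' Generates the default synthetic cohort (see [simulate_study()]), writes
#' the expression matrix (TSV), phenotype table, truth labels and batch
#' assignment (CSV), plus a manifest JSON with the seeds, parameters and MD5
#' content hashes of every artifact.
#'
#' @param config configuration list or YAML path (see [default_config()]).
#' @param out_dir output directory (created if missing).
#' @return invisibly, the manifest list.
#' @export
run_simulate <- function(config = default_config(), out_dir) {
  config <- load_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  design <- do.call(default_design, config$simulate$design)
  sim <- simulate_study(design, seed = stage_seed(config, "simulate"))
  paths <- file.path(out_dir, c(expr = "expression.tsv",
                                pheno = "phenotypes.csv",
                                truth = "truth_labels.csv"))
  write_expression(sim$expr, paths[1])
  utils::write.csv(data.frame(sample_id = rownames(sim$phenotypes),
                              sim$phenotypes), paths[2], row.names = FALSE)
  truth_df <- data.frame(sample_id = names(sim$truth$labels),
                         subtype = unname(sim$truth$labels))
  if (!is.null(sim$truth$batch))
    truth_df$batch <- unname(sim$truth$batch[truth_df$sample_id])
  utils::write.csv(truth_df, paths[3], row.names = FALSE)
  manifest <- list(stage = "simulate", seed = config$seed,
                   stage_seed = stage_seed(config, "simulate"),
                   design = unclass(design),
                   files = as.list(tools::md5sum(paths)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Run the discovery pipeline on a simulated or loaded study
#'
#' Reference selection, reference-statistic normalization, batch detection
#' and correction (when batch labels are present), network learning,
#' reference regression fitting, cohort deregulation scoring, PCA, SNN
#' clustering with resolution-stability selection, and top-loading gene
#' ranking.
#'
#' @param expr [expression_matrix()] for all samples (genes x samples).
#' @param phenotypes phenotype data.frame (rownames = sample IDs) with the
#'   reference-selection columns.
#' @param config configuration list or YAML path.
#' @param out_dir optional directory; when given, labels CSV, model JSON,
#'   stability table, loadings TSV, batch report and a manifest are written.
#' @return list with `reference_ids`, `case_ids`, `normalized`, `model`,
#'   `dereg`, `subtypes` (a `subtype_model`), `loadings`, `batch_report`.
#' @export
run_discover <- function(expr, phenotypes, config = default_config(),
                         out_dir = NULL) {
  config <- load_config(config)
  pp <- config$preprocess
  sel <- select_reference(phenotypes, reference_criteria(
    max_fev1pp_decline = pp$max_fev1pp_decline))
  if (length(sel$reference_ids) < 20)
    stop("discovery aborted at network stage: only ", length(sel$reference_ids),
         " reference samples")
  norm <- filter_and_normalize(expr, sel$reference_ids,
                               min_nonzero_frac = pp$min_nonzero_frac,
                               top_n_variable = pp$top_n_variable)
  batch <- attr(norm, "batch")
  batch_report <- NULL
  if (!is.null(batch) && length(unique(batch)) > 1) {
    seedd <- stage_seed(config, "discover")
    before <- gpca_batch_delta(norm, batch, n_perm = pp$n_perm, seed = seedd)
    norm <- correct_batch(norm, batch)
    after <- gpca_batch_delta(norm, batch, n_perm = pp$n_perm, seed = seedd)
    batch_report <- list(before = before, after = after)
  }
  ref_expr <- norm[, sel$reference_ids, drop = FALSE]
  ref_expr <- expr_like(ref_expr, norm)
  model <- learn_network(ref_expr, penalty = config$network$penalty)
  model <- fit_reference_regressions(ref_expr, model)
  case_expr <- expr_like(norm[, sel$case_ids, drop = FALSE], norm)
  dereg <- score_cohort(case_expr, model)
  st <- config$subtype
  subtypes <- discover_subtypes(dereg, n_pcs = st$n_pcs, snn_k = st$snn_k,
                                res_grid = st$res_grid,
                                seed = stage_seed(config, "discover"))
  loadings <- top_loading_genes(subtypes$embedding,
                                n_pcs = min(6, subtypes$embedding$n_pcs))
  out <- list(reference_ids = sel$reference_ids, case_ids = sel$case_ids,
              normalized = norm, model = model, dereg = dereg,
              subtypes = subtypes, loadings = loadings,
              batch_report = batch_report, phenotypes = phenotypes,
              config = config)
  if (!is.null(out_dir)) write_discovery(out, out_dir, config)
  out
}

write_discovery <- function(res, out_dir, config) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  labs <- data.frame(sample_id = names(res$subtypes$labels),
                     cluster = unname(res$subtypes$labels))
  paths <- c(labels = file.path(out_dir, "labels.csv"),
             model = file.path(out_dir, "model.json"),
             stability = file.path(out_dir, "stability.csv"),
             loadings = file.path(out_dir, "loadings.tsv"),
             coords = file.path(out_dir, "coords.tsv"))
  utils::write.csv(labs, paths["labels"], row.names = FALSE)
  write_network_model(res$model, paths["model"])
  utils::write.csv(res$subtypes$stability_table, paths["stability"],
                   row.names = FALSE)
  utils::write.table(res$loadings, paths["loadings"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = rownames(res$subtypes$coords),
                                res$subtypes$coords),
                     paths["coords"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- list(stage = "discover", seed = config$seed,
                   parameters = config[c("preprocess", "network", "subtype")],
                   batch_report = res$batch_report,
                   n_reference = length(res$reference_ids),
                   n_case = length(res$case_ids),
                   k = res$subtypes$k,
                   resolution = res$subtypes$resolution,
                   files = as.list(tools::md5sum(unname(paths))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Project a new cohort onto discovered subtypes
#'
#' Selects the new cohort's reference group, normalizes on its reference
#' statistics, refits the frozen network's regressions on that reference
#' group, scores the cohort, projects into the discovery embedding and
#' assigns subtypes by kNN; optionally runs the clinical association scan on
#' the assigned labels and a per-cluster concordance summary against the
#' discovery cohort.
#'
#' @param expr_new new cohort [expression_matrix()].
#' @param phenotypes_new new cohort phenotype data.frame.
#' @param discovery result list from [run_discover()].
#' @param config configuration list or YAML path.
#' @param variable_manifest optional manifest for [association_scan()].
#' @return list with `assignments` (data.frame), `dereg`, `coords`,
#'   `model` (refit), `association` (or NULL), `concordance` (or NULL:
#'   per-cluster means of the scanned continuous variables in both cohorts).
#' @export
run_project <- function(expr_new, phenotypes_new, discovery,
                        config = default_config(),
                        variable_manifest = NULL) {
  config <- load_config(config)
  pp <- config$preprocess
  sel <- select_reference(phenotypes_new, reference_criteria(
    max_fev1pp_decline = pp$max_fev1pp_decline))
  norm <- filter_and_normalize(expr_new, sel$reference_ids,
                               min_nonzero_frac = pp$min_nonzero_frac,
                               top_n_variable = pp$top_n_variable)
  batch <- attr(norm, "batch")
  if (!is.null(batch) && length(unique(batch)) > 1)
    norm <- correct_batch(norm, batch)
  shared <- intersect(discovery$model$genes, rownames(norm))
  ref_expr <- expr_like(norm[shared, sel$reference_ids, drop = FALSE], norm)
  model <- refit_on_new_reference(ref_expr, discovery$model)
  case_expr <- expr_like(norm[shared, sel$case_ids, drop = FALSE], norm)
  dereg <- score_cohort(case_expr, model)
  coords <- project_to_embedding(dereg, discovery$subtypes$embedding,
                                 force = TRUE)   # refit changes the fingerprint by design
  asg <- knn_assign(coords, discovery$subtypes$coords,
                    discovery$subtypes$labels, k = config$project$k)
  association <- concord <- NULL
  if (!is.null(variable_manifest)) {
    labels <- stats::setNames(asg$cluster, asg$sample_id)
    association <- association_scan(phenotypes_new, labels, variable_manifest,
                                    q_threshold = config$associate$q_threshold)
    concord <- cluster_concordance(
      phenotypes_new, labels,
      discovery_pheno = discovery$phenotypes,
      discovery_labels = discovery$subtypes$labels,
      variable_manifest = variable_manifest)
  }
  list(assignments = asg, dereg = dereg, coords = coords, model = model,
       association = association, concordance = concord, k = config$project$k)
}

# Per-cluster means of continuous/ordinal manifest variables in the new
# cohort, alongside the discovery cohort's (when its phenotypes are known);
# used to check that cross-cohort cluster trends replicate.
cluster_concordance <- function(phenotypes_new, labels_new,
                                discovery_pheno = NULL,
                                discovery_labels = NULL,
                                variable_manifest) {
  vars <- variable_manifest$variable[variable_manifest$kind != "binary"]
  per_cluster <- function(ph, lab) {
    ids <- intersect(rownames(ph), names(lab))
    sapply(vars, function(v)
      tapply(as.numeric(ph[ids, v]), factor(lab[ids]), mean, na.rm = TRUE))
  }
  out <- list(new = per_cluster(phenotypes_new, labels_new))
  if (!is.null(discovery_pheno) && !is.null(discovery_labels))
    out$discovery <- per_cluster(discovery_pheno, discovery_labels)
  out
}

#' Manifest of the simulator's core clinical variables
#'
#' @param n_distractors number of `null_var_*` distractors to include.
#' @return data.frame with `variable` and `kind`, suitable for
#'   [association_scan()].
#' @export
core_variable_manifest <- function(n_distractors = 0) {
  df <- data.frame(
    variable = c("lung_function", "symptom_score", "medication"),
    kind = c("continuous", "ordinal", "binary"))
  if (n_distractors > 0)
    df <- rbind(df, data.frame(
      variable = sprintf("null_var_%03d", seq_len(n_distractors)),
      kind = "continuous"))
  df
}
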