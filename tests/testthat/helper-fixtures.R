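# Shared fixtures and small oracles used across test files.

# Hand-built network container (bypasses generate_dag for exact structures).
manual_network <- function(genes, from, to, weight = 1, noise_sd = 1) {
  structure(list(
    genes = genes,
    edges = data.frame(from = from, to = to,
                       weight = rep_len(weight, length(from)),
                       stringsAsFactors = FALSE),
    noise_sd = stats::setNames(rep_len(noise_sd, length(genes)), genes)),
    class = "true_network")
}

# Standardize a genes x samples matrix by its own row means/SDs.
standardize_rows <- function(Y) {
  Y <- unclass(Y)
  attr(Y, "batch") <- NULL; attr(Y, "cohort") <- NULL; attr(Y, "class") <- NULL
  s <- apply(Y, 1, stats::sd)
  expression_matrix((Y - rowMeans(Y)) / ifelse(s > 0, s, 1))
}

# Standardize using the generating model's exact moments (for held-out data).
standardize_by_moments <- function(Y, net, spec = NULL) {
  mo <- sem_moments(net, spec)
  expression_matrix((unclass(Y) - mo$mean) / sqrt(diag(mo$cov)))
}

# Ground-truth Markov blankets of a true_network DAG.
true_blankets <- function(tn) {
  p <- length(tn$genes)
  W <- matrix(0, p, p, dimnames = list(tn$genes, tn$genes))
  if (nrow(tn$edges)) W[cbind(tn$edges$from, tn$edges$to)] <- 1
  tb <- lapply(tn$genes, function(g) {
    pa <- tn$genes[W[, g] != 0]; ch <- tn$genes[W[g, ] != 0]
    sp <- unlist(lapply(ch, function(c) tn$genes[W[, c] != 0]))
    setdiff(unique(c(pa, ch, sp)), g)
  })
  names(tb) <- tn$genes
  tb
}

blanket_f1 <- function(est, tru, genes) {
  tp <- fp <- fn <- 0
  for (g in genes) {
    tp <- tp + length(intersect(est[[g]], tru[[g]]))
    fp <- fp + length(setdiff(est[[g]], tru[[g]]))
    fn <- fn + length(setdiff(tru[[g]], est[[g]]))
  }
  2 * tp / (2 * tp + fp + fn)
}

# Map recovered cluster labels to majority truth labels, then score accuracy.
label_accuracy <- function(pred, truth) {
  tab <- table(pred, truth)
  map <- colnames(tab)[apply(tab, 1, which.max)]
  names(map) <- rownames(tab)
  mean(map[as.character(pred)] == as.character(truth))
}

# Rewrap a plain matrix as a dereg_matrix carrying a template's fingerprint.
dereg_like <- function(values, template) {
  structure(values, model_fingerprint = attr(template, "model_fingerprint"),
            class = c("dereg_matrix", "matrix"))
}

# Six-sample phenotype table: rows 1-4 each violate one criterion, row 5
# has missing spirometry, row 6 passes everything.
toy_phenotypes <- function() {
  data.frame(
    has_both_visits = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE),
    visit1_fev1_fvc = c(0.80, 0.60, 0.80, 0.80, 0.80, 0.80),
    visit2_fev1_fvc = c(0.80, 0.60, 0.80, 0.80, 0.80, 0.80),
    visit1_fev1pp   = c(95, 95, 95, 95, NA, 95),
    visit2_fev1pp   = c(95, 95, 95, 88, NA, 93),
    visit1_emph_pct = c(1, 1, 8, 1, 1, 1),
    visit2_emph_pct = c(1, 1, 8, 1, 1, 1),
    row.names = paste0("p", 1:6))
}

# Small, fast end-to-end synthetic study shared by several files.
small_design <- function(...) {
  default_design(n_genes = 60, n_reference = 60,
                 case_sizes = c(45L, 40L, 30L, 25L),
                 genes_per_subtype = 8, batch_sd = 0, ...)
}
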