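#' Published COPDGene/MESA study-group and cluster counts
#'
#' Sample counts reported for the blood RNA-seq network-perturbation COPD
#' subtyping analysis: reference/case sizes of the COPDGene discovery,
#' COPDGene validation and MESA validation groups, and the per-cluster case
#' counts in each cohort. Shipped as plain CSV under `extdata` so that
#' arithmetic consistency checks (cluster-size percentages, cohort totals)
#' can be recomputed from the printed counts.
#'
#' @return `study_group_counts()`: data.frame with `cohort`, `reference_n`,
#'   `case_n`. `cluster_counts()`: data.frame with `cohort`, `cluster`, `n`.
#' @export
study_group_counts <- function() {
  utils::read.csv(system.file("extdata", "study_group_counts.csv",
                              package = "netperturb"))
}

#' @rdname study_group_counts
#' @export
cluster_counts <- function() {
  utils::read.csv(system.file("extdata", "cluster_counts.csv",
                              package = "netperturb"))
}

#' Cluster-size percentages for one cohort
#'
#' @param cohort one of the cohorts in [cluster_counts()].
#' @param digits rounding applied to the percentages (1 matches the printed
#'   precision).
#' @return named numeric vector of percentages summing to ~100.
#' @export
cluster_size_percent <- function(cohort = "copdgene_discovery", digits = 1) {
  cc <- cluster_counts()
  cc <- cc[cc$cohort == cohort, , drop = FALSE]
  if (!nrow(cc)) stop("unknown cohort: ", cohort)
  stats::setNames(round(100 * cc$n / sum(cc$n), digits),
                  paste0("cluster", cc$cluster))
}

#' Cohort sample-accounting totals
#'
#' Reference + case sizes per cohort (the discovery group's 128 + 489 former
#' smokers, and the two validation groups).
#'
#' @return named numeric vector of totals per cohort.
#' @export
cohort_totals <- function() {
  gc <- study_group_counts()
  stats::setNames(gc$reference_n + gc$case_n, gc$cohort)
}
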