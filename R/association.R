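#' Kruskal-Wallis rank test across clusters
#'
#' Thin wrapper over [stats::kruskal.test()] (midrank tie correction,
#' chi-square reference with `groups - 1` df) with the degenerate all-equal
#' case mapped to `(H = 0, p = 1)`.
#'
#' @param values numeric observations.
#' @param groups parallel group labels (>= 2 non-empty groups).
#' @return list with `statistic` (H) and `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  if (nlevels(groups) < 2) stop("need >= 2 groups with observations")
  if (length(unique(values)) == 1) return(list(statistic = 0, p = 1))
  kt <- stats::kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), p = kt$p.value)
}

#' Pearson chi-squared test of independence
#'
#' [stats::chisq.test()] without continuity correction on a groups-by-levels
#' contingency table; a warning flag is raised when any expected cell is
#' below 1.
#'
#' @param contingency counts matrix (all margins > 0).
#' @return list with `statistic` (X^2), `p`, and `low_expected` flag.
#' @export
chi_square_test <- function(contingency) {
  contingency <- as.matrix(contingency)
  if (any(rowSums(contingency) == 0) || any(colSums(contingency) == 0))
    stop("contingency table has an empty margin")
  ct <- suppressWarnings(stats::chisq.test(contingency, correct = FALSE))
  low <- any(ct$expected < 1)
  if (low) warning("expected cell count below 1; chi-squared approximation is poor")
  list(statistic = unname(ct$statistic), p = ct$p.value, low_expected = low)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment via [stats::p.adjust()]; NA p-values are excluded
#' from the family size with a warning and returned as NA.
#'
#' @param pvals numeric p-values in \[0, 1\] (NAs allowed).
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvals) {
  if (any(is.na(pvals))) warning("NA p-values excluded from the BH family")
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvals))
  out[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  out
}

#' Pairwise two-sided Wilcoxon rank-sum tests
#'
#' Mann-Whitney test with normal approximation and tie/continuity correction
#' for every unordered pair of groups; p-values are reported unadjusted.
#' Pairs involving a group with fewer than 2 observations are NA.
#'
#' @param values numeric observations.
#' @param groups parallel group labels.
#' @return symmetric matrix of p-values (diagonal NA).
#' @export
pairwise_wilcoxon <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  lev <- levels(groups)
  if (length(lev) < 2) stop("need >= 2 groups")
  P <- matrix(NA_real_, length(lev), length(lev), dimnames = list(lev, lev))
  for (i in seq_along(lev)) for (j in seq_along(lev)) {
    if (j <= i) next
    a <- values[groups == lev[i]]; b <- values[groups == lev[j]]
    if (length(a) < 2 || length(b) < 2) next
    p <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    P[i, j] <- P[j, i] <- p
  }
  P
}

#' Kaplan-Meier curves and K-group log-rank test
#'
#' Product-limit estimates per group via [survival::survfit()] and the
#' log-rank score test via [survival::survdiff()] (chi-square with
#' `groups - 1` df). Groups with zero events are retained.
#'
#' @param time nonnegative follow-up times.
#' @param event event indicator (1 = event, 0 = right-censored).
#' @param groups per-sample group labels.
#' @return a `survival_result`: list with `curves` (per group: `time`,
#'   `n_risk`, `n_event`, `estimate`), `statistic`, `df`, `p`.
#' @export
km_logrank <- function(time, event, groups) {
  if (any(time < 0)) stop("`time` must be nonnegative")
  if (!all(event %in% c(0, 1))) stop("`event` must be 0/1")
  groups <- factor(groups)
  sf <- survival::survfit(survival::Surv(time, event) ~ groups)
  ss <- summary(sf, censored = TRUE)
  strata <- if (is.null(ss$strata)) factor(rep(levels(groups)[1], length(ss$time)))
            else ss$strata
  curves <- lapply(split(seq_along(ss$time), strata), function(i)
    data.frame(time = ss$time[i], n_risk = ss$n.risk[i],
               n_event = ss$n.event[i], estimate = ss$surv[i]))
  names(curves) <- sub("^groups=", "", names(curves))
  if (nlevels(groups) > 1 && sum(event) > 0) {
    sd <- survival::survdiff(survival::Surv(time, event) ~ groups)
    stat <- unname(sd$chisq); df <- nlevels(groups) - 1
    p <- stats::pchisq(stat, df, lower.tail = FALSE)
  } else {
    stat <- 0; df <- max(nlevels(groups) - 1, 0); p <- 1
  }
  structure(list(curves = curves, statistic = stat, df = df, p = p),
            class = "survival_result")
}

#' @export
print.survival_result <- function(x, ...) {
  cat(sprintf("<survival_result> %d groups, log-rank chi^2 = %.3f (df %d), p = %.3g\n",
              length(x$curves), x$statistic, x$df, x$p))
  invisible(x)
}

#' Scan clinical variables for association with subtype labels
#'
#' Dispatches Kruskal-Wallis (continuous, ordinal) or chi-squared (binary)
#' per variable according to the manifest, adjusts all p-values jointly with
#' Benjamini-Hochberg, and reports per-cluster summaries (mean (SD) for
#' continuous/ordinal, n (%) for binary). Variables with more than 50%
#' missing values are tested on complete cases and flagged.
#'
#' @param phenotypes data.frame, sample IDs as rownames.
#' @param labels named per-sample cluster labels (names matched to
#'   rownames of `phenotypes`).
#' @param variable_manifest data.frame with columns `variable` and `kind`
#'   (`"continuous"`, `"ordinal"` or `"binary"`).
#' @param q_threshold significance flag threshold (default 0.05).
#' @return an `association_table` data.frame: `variable`, `var_kind`,
#'   `test_name`, `statistic`, `p`, `q`, `significant`, `high_missing`, one
#'   summary column per cluster; rows sorted by ascending q then p.
#' @export
association_scan <- function(phenotypes, labels, variable_manifest,
                             q_threshold = 0.05) {
  if (nrow(variable_manifest) == 0) {
    out <- data.frame(variable = character(), var_kind = character(),
                      test_name = character(), statistic = numeric(),
                      p = numeric(), q = numeric(), significant = logical(),
                      high_missing = logical())
    class(out) <- c("association_table", class(out))
    return(out)
  }
  ids <- intersect(rownames(phenotypes), names(labels))
  ph <- phenotypes[ids, , drop = FALSE]
  lab <- factor(labels[ids])
  rows <- lapply(seq_len(nrow(variable_manifest)), function(r) {
    v <- variable_manifest$variable[r]
    kind <- variable_manifest$kind[r]
    if (!v %in% colnames(ph)) stop("manifest variable not in phenotypes: ", v)
    x <- ph[[v]]
    high_missing <- mean(is.na(x)) > 0.5
    ok <- !is.na(x)
    res <- if (kind == "binary") {
      tab <- table(lab[ok], factor(x[ok]))
      if (ncol(tab) < 2 || any(rowSums(tab) == 0))
        list(statistic = NA_real_, p = NA_real_)
      else suppressWarnings(chi_square_test(tab))
    } else {
      kruskal_wallis(as.numeric(x[ok]), lab[ok])
    }
    summaries <- vapply(levels(lab), function(cl) {
      xi <- x[ok & lab == cl]
      if (kind == "binary")
        sprintf("%d (%.1f%%)", sum(xi == 1), 100 * mean(xi == 1))
      else
        sprintf("%.2f (%.2f)", mean(as.numeric(xi)), stats::sd(as.numeric(xi)))
    }, character(1))
    c(list(variable = v, var_kind = kind,
           test_name = if (kind == "binary") "chi-squared" else "kruskal-wallis",
           statistic = res$statistic, p = res$p,
           high_missing = high_missing),
      as.list(stats::setNames(summaries, paste0("cluster_", levels(lab)))))
  })
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  out$q <- bh_fdr(out$p)
  out$significant <- !is.na(out$q) & out$q < q_threshold
  front <- c("variable", "var_kind", "test_name", "statistic", "p", "q",
             "significant", "high_missing")
  out <- out[c(front, setdiff(colnames(out), front))]
  out <- out[order(out$q, out$p, na.last = TRUE), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("association_table", class(out))
  out
}
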