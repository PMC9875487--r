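test_that("Kruskal-Wallis matches the hand-rank oracle and degenerates cleanly", {
  # ranks 1,2,3 vs 4,5,6: H = 12/42 * (3*(2-3.5)^2 + 3*(5-3.5)^2) = 27/7
  res <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$statistic, 27 / 7, tolerance = 1e-12)
  flat <- kruskal_wallis(rep(2, 8), rep(c("a", "b"), each = 4))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)
  expect_error(kruskal_wallis(1:4, rep("a", 4)), "2 groups")
})

test_that("Kruskal-Wallis is calibrated and reduces to squared rank-sum Z for 2 groups", {
  rej <- vapply(1:500, function(i) {
    set.seed(i)
    kruskal_wallis(rnorm(60), sample(rep(c("a", "b", "c"), 20)))$p <= 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 2.58 * sqrt(0.05 * 0.95 / 500))
  # H ~ Z^2 (no ties, large n): compare against normal-approx Wilcoxon Z
  set.seed(77)
  x <- rnorm(400); g <- rep(c("a", "b"), each = 200)
  H <- kruskal_wallis(x, g)$statistic
  w <- stats::wilcox.test(x[g == "a"], x[g == "b"], exact = FALSE, correct = FALSE)
  n1 <- 200; n2 <- 200
  z <- (w$statistic - n1 * n2 / 2) / sqrt(n1 * n2 * (n1 + n2 + 1) / 12)
  expect_equal(H, unname(z^2), tolerance = 1e-6)
})

test_that("chi-squared matches the closed-form diagonal table", {
  indep <- chi_square_test(matrix(c(10, 10, 10, 10), 2))
  expect_equal(indep$statistic, 0)
  expect_equal(indep$p, 1)
  diag40 <- chi_square_test(matrix(c(20, 0, 0, 20), 2))
  expect_equal(diag40$statistic, 40)    # all expected cells 10, 4 * 100/10
  expect_error(chi_square_test(matrix(c(5, 5, 0, 0), 2)), "empty margin")
  expect_warning(chi_square_test(matrix(c(1, 0, 0, 1), 2)), "below 1")
})

test_that("BH q-values follow the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.03), 0.03)
  set.seed(8)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p - 1e-15))
  expect_true(all(diff(q[order(p)]) >= -1e-15))     # monotone over sorted p
  expect_warning(qna <- bh_fdr(c(0.01, NA, 0.5)), "NA")
  expect_true(is.na(qna[2]))
  expect_equal(qna[c(1, 3)], stats::p.adjust(c(0.01, 0.5), "BH"))
})

test_that("pairwise Wilcoxon is symmetric, unadjusted, and flags tiny groups", {
  set.seed(9)
  v <- c(rnorm(30), rnorm(30), rnorm(30) + 5)
  g <- rep(c("a", "b", "c"), each = 30)
  P <- pairwise_wilcoxon(v, g)
  expect_equal(P["a", "b"], P["b", "a"])
  expect_gt(P["a", "b"], 0.05)
  expect_lt(P["a", "c"], 1e-6)
  sep <- pairwise_wilcoxon(c(1:10, 101:110), rep(c("a", "b"), each = 10))
  expect_lt(sep["a", "b"], 0.001)
  small <- pairwise_wilcoxon(c(1, 5, 6, 7, 8), c("a", "b", "b", "b", "b"))
  expect_true(is.na(small["a", "b"]))
})

test_that("Kaplan-Meier and log-rank match the product-limit toys", {
  # one event at t=2 among 4 subjects, rest censored later
  sr <- km_logrank(c(2, 3, 4, 5), c(1, 0, 0, 0), rep("g", 4))
  cv <- sr$curves[["g"]]
  expect_equal(cv$estimate[cv$time == 2], 0.75)
  expect_true(all(cv$estimate >= 0 & cv$estimate <= 1))
  expect_true(all(diff(cv$estimate) <= 1e-12))
  # mirrored groups: identical survival data -> statistic 0
  tt <- c(1, 2, 3, 4, 5, 6); ee <- c(1, 0, 1, 1, 0, 1)
  mir <- km_logrank(c(tt, tt), c(ee, ee), rep(c("x", "y"), each = 6))
  expect_equal(mir$statistic, 0, tolerance = 1e-12)
  expect_equal(mir$df, 1)
  # relabeling invariance
  mir2 <- km_logrank(c(tt, tt), c(ee, ee), rep(c("y", "x"), each = 6))
  expect_equal(mir2$statistic, mir$statistic)
  # no censoring: KM equals the empirical survival function
  times <- c(1, 2, 2, 3, 5)
  sr2 <- km_logrank(times, rep(1, 5), rep("g", 5))
  cv2 <- sr2$curves[["g"]]
  ecdf_surv <- vapply(cv2$time, function(t) mean(times > t), numeric(1))
  expect_equal(cv2$estimate, ecdf_surv, tolerance = 1e-12)
  expect_error(km_logrank(c(-1, 2), c(1, 1), c("a", "b")), "nonnegative")
  expect_error(km_logrank(c(1, 2), c(1, 2), c("a", "b")), "0/1")
})

test_that("log-rank detects a fourfold hazard difference", {
  set.seed(10)
  t1 <- rexp(100, 0.1); t2 <- rexp(100, 0.4)
  cens <- runif(200, 0, 15)
  tt <- pmin(c(t1, t2), cens); ee <- as.integer(c(t1, t2) <= cens)
  sr <- km_logrank(tt, ee, rep(c("lo", "hi"), each = 100))
  expect_lt(sr$p, 0.001)
})

test_that("association_scan dispatches by type, adjusts jointly, and isolates missingness", {
  set.seed(11)
  n <- 240
  lab <- stats::setNames(sample(0:3, n, replace = TRUE), paste0("s", 1:n))
  ph <- data.frame(
    linked = rnorm(n, mean = c(0, 0, 2, 2)[lab + 1]),
    nullv = rnorm(n),
    bin = rbinom(n, 1, 0.3),
    row.names = names(lab))
  man <- data.frame(variable = c("linked", "nullv", "bin"),
                    kind = c("continuous", "continuous", "binary"))
  tab <- association_scan(ph, lab, man)
  expect_identical(tab$variable[1], "linked")
  expect_true(tab$significant[tab$variable == "linked"])
  expect_true(all(tab$q >= tab$p - 1e-15))
  expect_true(all(diff(tab$q) >= -1e-15))
  expect_identical(tab$test_name[tab$variable == "bin"], "chi-squared")
  expect_match(tab$cluster_0[tab$variable == "bin"], "%")
  # missing values in one variable never alter other rows
  ph2 <- ph; ph2$nullv[1:150] <- NA
  tab2 <- association_scan(ph2, lab, man)
  expect_true(tab2$high_missing[tab2$variable == "nullv"])
  expect_equal(tab2$p[tab2$variable == "linked"], tab$p[tab$variable == "linked"])
  expect_equal(tab2$p[tab2$variable == "bin"], tab$p[tab$variable == "bin"])
  # empty manifest
  expect_equal(nrow(association_scan(ph, lab, man[0, ])), 0)
})

test_that("a null panel rarely yields q < 0.05 and a linked variable always does", {
  hits <- vapply(1:100, function(i) {
    set.seed(600 + i)
    n <- 120
    lab <- stats::setNames(sample(0:3, n, replace = TRUE), paste0("s", 1:n))
    ph <- as.data.frame(matrix(rnorm(n * 20), n,
                               dimnames = list(names(lab), paste0("v", 1:20))))
    man <- data.frame(variable = paste0("v", 1:20), kind = "continuous")
    sum(association_scan(ph, lab, man)$significant)
  }, numeric(1))
  # under the global null, BH keeps the familywise discovery rate near alpha
  expect_lt(mean(hits > 0), 0.05 + 2.58 * sqrt(0.05 * 0.95 / 100))
  set.seed(12)
  n <- 200
  lab <- stats::setNames(sample(0:3, n, replace = TRUE), paste0("s", 1:n))
  ph <- data.frame(big = rnorm(n, mean = 3 * (lab %in% c(2, 3))),
                   row.names = names(lab))
  ph[paste0("noise", 1:9)] <- replicate(9, rnorm(n))
  man <- data.frame(variable = colnames(ph),
                    kind = "continuous")
  tab <- association_scan(ph, lab, man)
  expect_true(tab$significant[tab$variable == "big"])
})
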