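# Independent oracle: exhaustively score every 3-node DAG with the penalized
# Gaussian BIC computed from lm() residuals, and return the best DAG's
# skeleton and v-structure signature (the equivalence-class invariants).
best_dag_3node <- function(Y) {
  stopifnot(nrow(Y) == 3)
  n <- ncol(Y)
  genes <- rownames(Y)
  pairs <- rbind(c(1, 2), c(1, 3), c(2, 3), c(2, 1), c(3, 1), c(3, 2))
  node_score <- function(j, parents) {
    fit <- if (length(parents)) stats::lm(Y[j, ] ~ t(Y[parents, , drop = FALSE]))
           else stats::lm(Y[j, ] ~ 1)
    sig2 <- mean(stats::residuals(fit)^2)
    -n / 2 * log(sig2) - (length(parents) + 1) / 2 * log(n)
  }
  best <- NULL; best_score <- -Inf
  for (mask in 0:(2^6 - 1)) {
    sel <- pairs[bitwAnd(mask, 2^(0:5)) > 0, , drop = FALSE]
    A <- matrix(0, 3, 3); A[sel] <- 1
    if (any(diag(A %*% A %*% A) > 0) || any(A + t(A) > 1)) next  # cyclic
    sc <- sum(vapply(1:3, function(j) node_score(j, which(A[, j] == 1)), numeric(1)))
    if (sc > best_score) { best_score <- sc; best <- A }
  }
  vstr <- character(0)
  for (j in 1:3) {
    P <- which(best[, j] == 1)
    if (length(P) == 2 && best[P[1], P[2]] == 0 && best[P[2], P[1]] == 0)
      vstr <- paste0(genes[P[1]], "->", genes[j], "<-", genes[P[2]])
  }
  skel <- which((best + t(best)) > 0 & upper.tri(best), arr.ind = TRUE)
  list(skeleton = paste(genes[skel[, 1]], genes[skel[, 2]], sep = "-"),
       vstructures = vstr)
}

test_that("independent genes yield an empty network", {
  set.seed(1)
  Z <- matrix(rnorm(2000), 2, 1000,
              dimnames = list(c("gA", "gB"), paste0("s", 1:1000)))
  m <- learn_network(expression_matrix(Z))
  expect_equal(nrow(m$edges), 0)
  # direct score audit: the single-edge gain is negative
  r <- cor(Z[1, ], Z[2, ])
  expect_lt(-1000 / 2 * log(1 - r^2) - log(1000) / 2, 0)
})

test_that("a chain is recovered as skeleton A-B-C without an A-C edge", {
  net <- manual_network(c("A", "B", "C"), from = c("A", "B"), to = c("B", "C"))
  Y <- simulate_expression(net, 2000, seed = 42)
  m <- learn_network(standardize_rows(Y))
  skel <- paste(pmin(m$edges$from, m$edges$to), pmax(m$edges$from, m$edges$to))
  expect_setequal(skel, c("A B", "B C"))
  expect_setequal(markov_blanket(m, "B"), c("A", "C"))
  expect_identical(markov_blanket(m, "A"), "B")
})

test_that("a collider is oriented and matches the exhaustive-score oracle", {
  net <- manual_network(c("A", "B", "C"), from = c("A", "B"), to = c("C", "C"))
  Y <- simulate_expression(net, 2000, seed = 7)
  Ys <- standardize_rows(Y)
  m <- learn_network(Ys)
  dir <- m$edges[m$edges$directed, ]
  expect_setequal(paste(dir$from, dir$to), c("A C", "B C"))
  expect_setequal(markov_blanket(m, "A"), c("B", "C"))
  oracle <- best_dag_3node(unclass(Ys))
  expect_setequal(oracle$skeleton, c("A-C", "B-C"))
  expect_identical(oracle$vstructures, "A->C<-B")
})

test_that("learn_network is invariant to sample order and refuses bad input", {
  net <- generate_dag(20, 2, seed = 8)
  Y <- standardize_rows(simulate_expression(net, 300, seed = 8))
  m1 <- learn_network(Y)
  perm <- sample(ncol(Y))
  m2 <- learn_network(expression_matrix(unclass(Y)[, perm]))
  expect_identical(m1$edges, m2$edges)
  expect_error(learn_network(Y[, 1:10]), "at least 20")
  bad <- unclass(Y); bad[1, 1] <- NA
  expect_error(learn_network(expression_matrix(bad)), "finite")
})

test_that("forward-phase total score is monotone nondecreasing", {
  net <- generate_dag(30, 2, seed = 10)
  Y <- standardize_rows(simulate_expression(net, 500, seed = 10))
  m <- learn_network(Y)
  expect_true(all(diff(m$score_trace) > 0))
})

test_that("Markov blankets follow the parent/child/co-parent rules", {
  chain <- structure(list(
    genes = c("A", "B", "C"),
    edges = data.frame(from = c("A", "B"), to = c("B", "C"),
                       directed = TRUE),
    blankets = NULL, regressions = NULL, penalty = 1),
    class = "gene_network_model")
  chain$blankets <- blankets_from_edges(chain$genes, chain$edges)
  expect_setequal(markov_blanket(chain, "B"), c("A", "C"))
  expect_identical(markov_blanket(chain, "A"), "B")
  collider <- chain
  collider$edges <- data.frame(from = c("A", "B"), to = c("C", "C"),
                               directed = TRUE)
  collider$blankets <- blankets_from_edges(collider$genes, collider$edges)
  expect_setequal(markov_blanket(collider, "A"), c("B", "C"))
  expect_error(markov_blanket(chain, "Z"), "unknown gene")
})

test_that("reference regressions recover coefficients and residual scale", {
  # exact linear relation: coefficient 2, residual sd floored near 0
  set.seed(3)
  x <- rnorm(200)
  Y <- rbind(gx = x, gy = 2 * x)
  colnames(Y) <- paste0("s", 1:200)
  mod <- structure(list(genes = c("gx", "gy"),
                        edges = data.frame(from = "gx", to = "gy", directed = TRUE),
                        blankets = list(gx = "gy", gy = "gx"),
                        regressions = NULL, penalty = 1, meta = list()),
                   class = "gene_network_model")
  fit <- fit_reference_regressions(expression_matrix(Y), mod)
  expect_equal(unname(fit$regressions$gy$coef["gx"]), 2, tolerance = 1e-10)
  expect_lt(fit$regressions$gy$residual_sd, 1e-3)
  # noisy relation: residual sd ~ 0.5
  set.seed(4)
  x2 <- rnorm(2000); y2 <- x2 + rnorm(2000, sd = 0.5)
  Y2 <- rbind(gx = x2, gy = y2); colnames(Y2) <- paste0("s", 1:2000)
  fit2 <- fit_reference_regressions(expression_matrix(Y2), mod)
  expect_gt(fit2$regressions$gy$residual_sd, 0.45)
  expect_lt(fit2$regressions$gy$residual_sd, 0.55)
  # empty blanket on standardized input: intercept 0, residual_sd 1
  z <- scale(rnorm(100))[, 1]
  Yz <- rbind(gz = z, gw = scale(rnorm(100))[, 1])
  colnames(Yz) <- paste0("s", 1:100)
  modz <- structure(list(genes = c("gz", "gw"), edges = data.frame(),
                         blankets = list(gz = character(0), gw = character(0)),
                         regressions = NULL, penalty = 1, meta = list()),
                    class = "gene_network_model")
  fz <- fit_reference_regressions(expression_matrix(Yz), modz)
  expect_equal(fz$regressions$gz$intercept, 0, tolerance = 1e-12)
  expect_equal(fz$regressions$gz$residual_sd, 1, tolerance = 1e-12)
})

test_that("model JSON round-trips through write/read", {
  net <- generate_dag(15, 2, seed = 5)
  Y <- standardize_rows(simulate_expression(net, 200, seed = 5))
  m <- fit_reference_regressions(Y, learn_network(Y))
  path <- withr::local_tempfile(fileext = ".json")
  write_network_model(m, path)
  back <- read_network_model(path)
  expect_identical(back$genes, m$genes)
  expect_equal(back$edges$from, m$edges$from)
  expect_identical(back$blankets, m$blankets)
  g <- m$genes[[1]]
  expect_equal(back$regressions[[g]]$coef, m$regressions[[g]]$coef)
  expect_equal(back$regressions[[g]]$residual_sd, m$regressions[[g]]$residual_sd)
})

test_that("blanket recovery reaches F1 >= 0.8 on 50-gene degree-2 networks", {
  f1 <- vapply(1:10, function(s) {
    tn <- generate_dag(50, 2, seed = s)
    ref <- simulate_expression(tn, 1000, seed = s + 100)
    mod <- learn_network(standardize_rows(ref))
    blanket_f1(mod$blankets, true_blankets(tn), tn$genes)
  }, numeric(1))
  expect_gte(stats::median(f1), 0.8)
})
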