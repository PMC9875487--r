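# Fixture: discovery study + trained model, reused across blocks.
projection_fixture <- local({
  sim <- simulate_study(small_design(), seed = 21)
  sel <- select_reference(sim$phenotypes)
  norm <- filter_and_normalize(sim$expr, sel$reference_ids,
                               min_nonzero_frac = 0, top_n_variable = 60)
  ref <- expression_matrix(unclass(norm)[, sel$reference_ids])
  model <- suppressWarnings(fit_reference_regressions(ref, learn_network(ref)))
  D <- score_cohort(expression_matrix(unclass(norm)[, sel$case_ids]), model)
  st <- discover_subtypes(D, seed = 0)
  list(sim = sim, sel = sel, norm = norm, ref = ref, model = model,
       dereg = D, subtypes = st)
})

test_that("refitting on the original reference reproduces the coefficients", {
  fx <- projection_fixture
  refit <- suppressWarnings(refit_on_new_reference(fx$ref, fx$model))
  g <- fx$model$genes[[5]]
  expect_equal(refit$regressions[[g]]$coef, fx$model$regressions[[g]]$coef,
               tolerance = 1e-10)
  expect_equal(refit$regressions[[g]]$residual_sd,
               fx$model$regressions[[g]]$residual_sd, tolerance = 1e-10)
})

test_that("refit absorbs a global cohort scale change", {
  fx <- projection_fixture
  net <- fx$sim$truth$network
  new_ref <- simulate_expression(net, 300, seed = 99, sample_prefix = "v")
  scaled <- expression_matrix(2 * unclass(new_ref))           # cohort-wide x2
  # normalize on the new cohort's own reference statistics
  norm_new <- standardize_rows(scaled)
  shared <- intersect(fx$model$genes, rownames(norm_new))
  refit <- suppressWarnings(refit_on_new_reference(
    expression_matrix(unclass(norm_new)[shared, 1:200]), fx$model))
  held <- expression_matrix(unclass(norm_new)[shared, 201:300])
  D <- score_cohort(held, refit)
  expect_lt(abs(mean(D) - sqrt(2 / pi)), 0.06)
})

test_that("dropping one gene keeps the refit model scoring", {
  fx <- projection_fixture
  drop1 <- unclass(fx$ref)[-1, , drop = FALSE]
  ws <- capture_warnings(refit <- refit_on_new_reference(expression_matrix(drop1), fx$model))
  expect_match(ws, "absent", all = FALSE)
  expect_false(rownames(unclass(fx$ref))[1] %in% refit$genes)
  expect_false(any(vapply(refit$regressions, function(r)
    rownames(unclass(fx$ref))[1] %in% names(r$coef), logical(1))))
  D <- score_cohort(expression_matrix(drop1[, 1:5]), refit)
  expect_equal(dim(D), c(5, length(refit$genes)))
  tiny <- unclass(fx$ref)[1:30, , drop = FALSE]
  expect_error(suppressWarnings(refit_on_new_reference(expression_matrix(tiny), fx$model)),
               "90%")
})

test_that("projection is exact on training data and linear in the features", {
  fx <- projection_fixture
  coords <- project_to_embedding(fx$dereg, fx$subtypes$embedding)
  expect_lt(max(abs(coords - fx$subtypes$coords)), 1e-8)
  # feature vector at the stored means maps to the origin
  mu <- matrix(fx$subtypes$embedding$feature_means, 1,
               dimnames = list("m", names(fx$subtypes$embedding$feature_means)))
  expect_lt(max(abs(project_to_embedding(dereg_like(mu, fx$dereg),
                                         fx$subtypes$embedding))), 1e-12)
  # duplicated sample -> duplicated coords
  dup <- unclass(fx$dereg)[c(1, 1), , drop = FALSE]
  rownames(dup) <- c("a", "b")
  cd <- project_to_embedding(dereg_like(dup, fx$dereg), fx$subtypes$embedding)
  expect_equal(cd["a", ], cd["b", ])
  # fingerprint lineage guard
  alien <- dereg_like(unclass(fx$dereg), fx$dereg)
  attr(alien, "model_fingerprint") <- "not-the-same"
  expect_error(project_to_embedding(alien, fx$subtypes$embedding), "different models")
  expect_silent(project_to_embedding(alien, fx$subtypes$embedding, force = TRUE))
})

test_that("knn_assign follows the majority-with-nearest-tiebreak contract", {
  train <- rbind(a = c(0, 0), b = c(1, 0), c = c(0.9, 0), d = c(5, 5))
  labs <- c(2, 2, 0, 1)
  # query identical to a training point at k=1
  expect_equal(knn_assign(rbind(q = c(5, 5)), train, labs, k = 1)$cluster, 1)
  # k=3 neighbors labeled (2,2,0) -> majority 2, share 2/3
  res <- knn_assign(rbind(q = c(0.5, 0)), train, labs, k = 3)
  expect_equal(res$cluster, 2)
  expect_equal(res$vote_share, 2 / 3)
  # tie at k=2 resolved by single nearest neighbor
  expect_warning(tie <- knn_assign(rbind(q = c(0.95, 0)), train, c(0, 1, 2, 1), k = 2),
                 "even k")
  expect_equal(tie$cluster, 2)      # c at distance 0.05 is nearest
  expect_error(knn_assign(rbind(q = c(0, 0)), train, labs, k = 0), "positive")
  expect_error(knn_assign(rbind(q = c(0, 0)), train, labs, k = 9), "exceeds")
})

test_that("k-stability scan settles on the smallest stable k", {
  set.seed(6)
  train <- rbind(matrix(rnorm(60), 30, 2), matrix(rnorm(60, mean = 40), 30, 2))
  rownames(train) <- paste0("t", 1:60)
  labs <- rep(c(0, 1), each = 30)
  query <- rbind(matrix(rnorm(20), 10, 2), matrix(rnorm(20, mean = 40), 10, 2))
  rownames(query) <- paste0("q", 1:20)
  scan <- k_stability_scan(query, train, labs, k_grid = 1:8)
  expect_equal(scan$k, 1)
  expect_true(all(scan$assignments$cluster == rep(c(0, 1), each = 10)))
  expect_warning(one <- k_stability_scan(query, train, labs, k_grid = 3),
                 "single value")
  expect_equal(one$k, 3)
})

test_that("held-out projection matches full-cohort clustering labels", {
  # needs the full-scale design: half-cohorts of the small fixture are too
  # thin for stable four-way clustering
  sim <- simulate_study(seed = 41)
  disc <- suppressWarnings(run_discover(sim$expr, sim$phenotypes,
                                        default_config(seed = 41)))
  ids <- rownames(disc$dereg)
  set.seed(31)
  half <- sample(ids, length(ids) %/% 2)
  rest <- setdiff(ids, half)
  pca <- fit_pca(dereg_like(unclass(disc$dereg)[half, ], disc$dereg), n_pcs = 6)
  g <- build_snn_graph(pca$coords, k = 20)
  labs <- stability_select(g, seed = 0)$labels
  coords_rest <- project_to_embedding(dereg_like(unclass(disc$dereg)[rest, ], disc$dereg),
                                      pca$embedding)
  asg <- knn_assign(coords_rest, pca$coords, labs, k = 3)
  full_labels <- disc$subtypes$labels[rest]
  expect_gte(label_accuracy(asg$cluster, full_labels), 0.9)
})
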