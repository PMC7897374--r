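test_that("balanced bootstrap matrices are exactly balanced and seeded", {
  cm <- generate_decay_matrix(separable_spec(seed = 2, n = 6))
  thin <- make_imbalanced(cm, 0.5, seed = 1)
  bm <- bootstrap_balanced_matrix(thin, m = 150, seed = 9)
  expect_identical(nrow(bm$values), 300L)
  expect_identical(sum(bm$group == "A"), 150L)
  expect_identical(sum(bm$group == "B"), 150L)
  # degenerate m
  bm1 <- bootstrap_balanced_matrix(thin, m = 1, seed = 9)
  expect_identical(nrow(bm1$values), 2L)
  expect_setequal(bm1$group, c("A", "B"))
  # same seed -> identical matrix; different seed -> different draw
  expect_identical(bootstrap_balanced_matrix(thin, 20, seed = 4),
                   bootstrap_balanced_matrix(thin, 20, seed = 4))
  expect_false(identical(bootstrap_balanced_matrix(thin, 20, seed = 4),
                         bootstrap_balanced_matrix(thin, 20, seed = 5)))
  only_a <- thin
  only_a$group <- rep("A", length(thin$group))
  expect_error(bootstrap_balanced_matrix(only_a, 5), "both groups")
})

test_that("inner grid search maximizes inner AUC with stated tie-breaks", {
  cm <- generate_decay_matrix(separable_spec(seed = 6, n = 6))
  cm <- normalize_unit_variance(cm)
  # single grid point: trivially selected
  one <- classifier_spec("svm_rbf",
                         grid = data.frame(gamma = 0.03, cost = 5))
  gs <- inner_grid_search(cm, one, k = 3, seed = 1)
  expect_equal(gs$best$gamma, 0.03)
  expect_equal(gs$best$cost, 5)
  # cleanly separable data: some grid point reaches inner AUC 1
  gs2 <- inner_grid_search(cm, small_svm_spec(), k = 3, seed = 1)
  expect_equal(gs2$best_auc, 1.0)
  # ties break toward smaller cost then smaller gamma
  expect_equal(gs2$best$cost, min(gs2$table$cost[
    gs2$table$mean_auc >= gs2$best_auc - 1e-12]))
  # k beyond minority sample count fails loudly
  small <- generate_decay_matrix(separable_spec(seed = 6, n = 2))
  expect_error(inner_grid_search(small, one, k = 3, seed = 1),
               "at least 3 samples")
})

test_that("hyperparameter mode is the joint componentwise mode", {
  spec <- classifier_spec("svm_rbf")
  sel <- data.frame(gamma = c(0.03, 0.03, 0.1), cost = c(5, 5, 1))
  expect_equal(unlist(hyperparameter_mode(sel, spec)),
               c(gamma = 0.03, cost = 5))
  # single selection is its own mode
  expect_equal(hyperparameter_mode(sel[3, ], spec)$cost, 1)
  # exact tie: smaller cost wins
  tie <- data.frame(gamma = c(0.03, 0.03), cost = c(5, 1))
  expect_equal(hyperparameter_mode(tie, spec)$cost, 1)
})

test_that("outer folds stratify by sample and never leak replicates", {
  cm <- generate_decay_matrix(separable_spec(seed = 3, n = 10))
  for (r in 1:3) {
    folds <- relaxlearn:::make_stratified_folds(cm$sample_id, cm$group, 5,
                                                seed = r)
    # replicates stay together
    expect_true(all(tapply(folds, cm$sample_id,
                           function(f) length(unique(f))) == 1))
    # each fold holds both groups
    expect_true(all(table(folds, cm$group) > 0))
  }
  expect_error(relaxlearn:::make_stratified_folds(
    cm$sample_id, rep(NA_character_, length(cm$sample_id)), 5, 1),
    "group label")
})

test_that("double CV separates separable data and not permuted labels", {
  cm <- generate_decay_matrix(separable_spec(seed = 13, n = 8))
  cfg <- fast_config(seed = 13)
  rep1 <- double_cv(cm, small_svm_spec(), cfg)
  expect_gte(rep1$metrics["auc", "mean"], 0.99)
  # outer train/test never share a biological sample (leakage guard is a
  # hard assertion inside the loop); records cover every curve each repeat
  expect_identical(nrow(rep1$records), nrow(cm$values))
  # an uninformative constant-signal matrix scores at chance, accuracy at
  # the majority fraction
  flat <- cm
  set.seed(1)
  flat$values <- matrix(rnorm(length(cm$values), 0, 1e-6) + 1,
                        nrow(cm$values))
  repf <- double_cv(flat, small_svm_spec(), fast_config(seed = 4))
  expect_lt(abs(repf$metrics["auc", "mean"] - 0.5), 0.25)
})

test_that("framework with B=1 and degenerate rng equals a single model", {
  # integration sanity: averaging identical replicas changes nothing
  cm <- generate_decay_matrix(separable_spec(seed = 19, n = 6))
  cfg <- fast_config(seed = 19, n_bootstrap = 1, m_per_group = 8)
  fw <- relaxometric_learn(cm, small_svm_spec(), cfg)
  expect_identical(nrow(fw$records), nrow(cm$values))
  expect_gte(fw$metrics["auc", "mean"], 0.99)
})

test_that("mean-score integration of identical replicas is one model's score", {
  cm <- generate_decay_matrix(separable_spec(seed = 23, n = 5))
  cm <- normalize_unit_variance(cm)
  spec <- small_svm_spec()
  hyper <- data.frame(gamma = 0.03, cost = 5)
  bm <- bootstrap_balanced_matrix(cm, 10, seed = 7)
  m1 <- train_backend(bm$values, bm$group, spec, hyper)
  # B identical replicas (same bootstrap seed) -> mean score == single score
  scores <- sapply(1:5, function(b) {
    bmb <- bootstrap_balanced_matrix(cm, 10, seed = 7)
    predict_scores(train_backend(bmb$values, bmb$group, spec, hyper),
                   cm$values)
  })
  expect_equal(rowMeans(scores), predict_scores(m1, cm$values),
               tolerance = 1e-10)
})

test_that("vote integration yields vote-fraction scores in [0,1]", {
  cm <- generate_decay_matrix(separable_spec(seed = 29, n = 6))
  cfg <- fast_config(seed = 29, integration = "vote", n_bootstrap = 7,
                     m_per_group = 8)
  fw <- relaxometric_learn(cm, small_svm_spec(), cfg)
  expect_true(all(fw$records$score >= 0 & fw$records$score <= 1))
  expect_gte(fw$metrics["auc", "mean"], 0.99)
})

test_that("usage-rate ladder evaluates the canonical column counts", {
  rates <- seq(1, 0.1, by = -0.1)
  expect_identical(vapply(rates, function(r) n_retained_variables(256, r),
                          integer(1)),
                   c(256L, 230L, 204L, 179L, 153L, 128L, 102L, 76L, 51L,
                     25L))
})

test_that("nested rate search prefers truncation when late columns are noise", {
  # early-time group signal + late columns of pure noise
  spec <- decay_population_spec(
    n_per_group = 8, groups = list(
      A = list(fraction = c(0.75, 0.25), t2 = c(0.03, 0.08)),
      B = list(fraction = c(0.25, 0.75), t2 = c(0.03, 0.08))),
    time_points = 40, replicates_per_sample = 2, noise_sd = 0.04,
    seed = 37)
  cm <- generate_decay_matrix(spec)  # signal gone by ~0.4 s; 60% is noise
  cfg <- fast_config(seed = 37, n_bootstrap = 3, m_per_group = 10,
                     usage_rates = c(1, 0.4))
  fw <- relaxometric_learn(cm, small_svm_spec(), cfg)
  expect_lt(fw$chosen_rate, 1.0)
  expect_true(all(fw$records$usage_rate %in% c(1, 0.4)))
})

test_that("global rate optimization returns the per-rate profile", {
  cm <- generate_decay_matrix(separable_spec(seed = 41, n = 5,
                                             time_points = 20))
  cfg <- fast_config(seed = 41, n_bootstrap = 2, m_per_group = 6,
                     usage_rates = c(1, 0.5))
  out <- optimize_usage_rate(cm, small_svm_spec(), cfg, mode = "global")
  expect_identical(nrow(out$summary), 2L)
  expect_identical(out$summary$n_variables, c(20L, 10L))
  expect_true(out$chosen_rate %in% c(1, 0.5))
  # ties in AUC (separable at both rates) go to fewer variables
  if (abs(diff(out$summary$auc)) < 1e-12)
    expect_equal(out$chosen_rate, 0.5)
})

test_that("random forest and PLS-DA run through the same engine", {
  skip_if_not_installed("mixOmics")
  cm <- generate_decay_matrix(separable_spec(seed = 43, n = 6,
                                             time_points = 20))
  cfg <- fast_config(seed = 43, n_bootstrap = 2, m_per_group = 8)
  rf <- relaxometric_learn(cm, classifier_spec("random_forest"), cfg)
  expect_gte(rf$metrics["auc", "mean"], 0.99)
  pls <- relaxometric_learn(cm, classifier_spec("pls_da"), cfg)
  expect_gte(pls$metrics["auc", "mean"], 0.99)
})

test_that("rf scores are reproducible under a fixed seed", {
  cm <- generate_decay_matrix(separable_spec(seed = 47, n = 4,
                                             time_points = 16))
  spec <- classifier_spec("random_forest")
  h <- spec$grid[1, , drop = FALSE]
  m1 <- train_backend(cm$values, cm$group, spec, h, seed = 99)
  m2 <- train_backend(cm$values, cm$group, spec, h, seed = 99)
  expect_identical(predict_scores(m1, cm$values),
                   predict_scores(m2, cm$values))
})

test_that("pls_da scores are monotone in the single latent direction", {
  skip_if_not_installed("mixOmics")
  # one informative direction: x2 = 2 * x1, classes split along it
  set.seed(5)
  base <- c(rnorm(10, -2), rnorm(10, 2))
  x <- cbind(base, 2 * base) + matrix(rnorm(40, 0, 1e-3), 20)
  y <- rep(c("A", "B"), each = 10)
  spec <- classifier_spec("pls_da", grid = data.frame(ncomp = 1))
  m <- train_backend(x, y, spec, data.frame(ncomp = 1))
  sc <- predict_scores(m, x)
  expect_true(all(diff(sc[order(base)]) > 0))
})

test_that("the whole pipeline is deterministic given one master seed", {
  cm <- generate_decay_matrix(separable_spec(seed = 53, n = 5,
                                             time_points = 16))
  cfg <- fast_config(seed = 53, n_bootstrap = 3, m_per_group = 6)
  r1 <- relaxometric_learn(cm, small_svm_spec(), cfg)
  r2 <- relaxometric_learn(cm, small_svm_spec(), cfg)
  expect_identical(r1$records, r2$records)
  expect_identical(r1$metrics, r2$metrics)
})

test_that("fitted ensembles score new curves with stored preprocessing", {
  cm <- generate_decay_matrix(separable_spec(seed = 59, n = 6,
                                             time_points = 20))
  cfg <- fast_config(seed = 59, n_bootstrap = 4, m_per_group = 8)
  ens <- fit_ensemble(cm, small_svm_spec(), cfg,
                      hyper = data.frame(gamma = 0.03, cost = 5),
                      usage_rate = 0.5)
  expect_identical(ens$n_vars, 10L)
  new <- generate_decay_matrix(separable_spec(seed = 60, n = 3,
                                              time_points = 20))
  pred <- predict(ens, new)
  acc <- accuracy_and_ccr(pred$predicted, new$group)
  expect_gte(acc$accuracy, 0.9)
})
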