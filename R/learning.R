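`%||%` <- function(a, b) if (is.null(a)) b else a

#' Framework configuration
#'
#' Collects every tunable of the relaxometric-learning engine. Defaults are
#' the canonical settings of the method: 100 balanced bootstrap matrices of
#' 150 resamples per group (300 rows each), usage rates from 100 % down to
#' 10 % in 10 % steps, 5-fold outer / 3-fold inner repeated (10x) double
#' cross-validation, mean-score ensemble integration.
#'
#' @param n_bootstrap number of balanced bootstrap matrices B (default 100).
#' @param m_per_group resamples per group in each matrix (default 150).
#' @param usage_rates variable usage rates searched, each in (0, 1]
#'   (default `seq(1, 0.1, by = -0.1)`).
#' @param outer_folds outer CV folds for performance evaluation (default 5).
#' @param inner_folds inner CV folds for hyperparameter search (default 3).
#' @param repeats double-CV repetitions (default 10).
#' @param seed master integer seed; all randomness flows from it through
#'   named sub-streams (see [substream_seed()]).
#' @param integration ensemble integration rule, `"mean_score"` (default;
#'   average of continuous replica scores) or `"vote"` (majority class
#'   vote; the B-vote fraction serves as the ROC score).
#' @param normalization `"per_variable"` (default; train-fold unit-variance
#'   column scaling applied to the test fold), `"per_curve"`, or `"none"`.
#' @param center subtract column means when normalizing (default FALSE).
#' @return An object of class `framework_config`.
#' @export
framework_config <- function(n_bootstrap = 100, m_per_group = 150,
                             usage_rates = seq(1, 0.1, by = -0.1),
                             outer_folds = 5, inner_folds = 3, repeats = 10,
                             seed = 1,
                             integration = c("mean_score", "vote"),
                             normalization = c("per_variable", "per_curve",
                                               "none"),
                             center = FALSE) {
  integration <- match.arg(integration)
  normalization <- match.arg(normalization)
  if (!is_count(n_bootstrap)) abort_validation("n_bootstrap must be >= 1")
  if (!is_count(m_per_group)) abort_validation("m_per_group must be >= 1")
  if (any(usage_rates <= 0 | usage_rates > 1))
    abort_validation("usage rates must lie in (0, 1]")
  if (!is_count(outer_folds) || outer_folds < 2 ||
      !is_count(inner_folds) || inner_folds < 2)
    abort_validation("outer_folds and inner_folds must be >= 2")
  if (!is_count(repeats)) abort_validation("repeats must be >= 1")
  structure(list(n_bootstrap = as.integer(n_bootstrap),
                 m_per_group = as.integer(m_per_group),
                 usage_rates = as.numeric(usage_rates),
                 outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 repeats = as.integer(repeats), seed = as.integer(seed),
                 integration = integration, normalization = normalization,
                 center = center),
            class = "framework_config")
}

# Stratified sample-level fold assignment: all replicates of a biological
# sample land in one fold, and each fold receives a near-equal share of each
# group. Returns an integer fold id per row.
make_stratified_folds <- function(sample_id, group, k, seed) {
  if (anyNA(group))
    abort_validation("all curves must carry a group label for cross-validation")
  tab <- unique(data.frame(sample_id = sample_id, group = group))
  sizes <- table(tab$group)
  if (length(sizes) < 2)
    abort_validation("both groups must be present")
  if (min(sizes) < k)
    abort_validation(sprintf(
      "stratified %d-fold CV needs at least %d samples per group (minority has %d)",
      k, k, min(sizes)))
  fold_of <- integer(nrow(tab)); names(fold_of) <- tab$sample_id
  with_seed(seed, {
    for (g in names(sizes)) {
      sids <- sample(tab$sample_id[tab$group == g])
      fold_of[sids] <- rep(seq_len(k), length.out = length(sids))
    }
  })
  unname(fold_of[sample_id])
}

#' Balanced bootstrap matrixing
#'
#' Constructs one class-balanced subtraining matrix by drawing, with
#' replacement and within each group independently, exactly `m` curve rows
#' per group; the combined rows are shuffled. With the canonical m = 150
#' this yields 300-row matrices regardless of how skewed the source class
#' sizes are.
#'
#' @param train a labeled [curve_matrix] with both groups present.
#' @param m resamples per group.
#' @param seed integer seed; identical seeds give identical matrices.
#' @return A [curve_matrix] with exactly `m` rows per group.
#' @export
bootstrap_balanced_matrix <- function(train, m, seed = 1) {
  stopifnot(inherits(train, "curve_matrix"))
  if (!is_count(m)) abort_validation("'m' must be a positive count")
  idx_a <- which(train$group == "A"); idx_b <- which(train$group == "B")
  if (length(idx_a) == 0 || length(idx_b) == 0)
    abort_validation("both groups must be present in the training matrix")
  with_seed(seed, {
    pick <- c(sample(idx_a, m, replace = TRUE),
              sample(idx_b, m, replace = TRUE))
    cm_rows(train, sample(pick))
  })
}

#' Inner-loop hyperparameter grid search
#'
#' Stratified, sample-grouped k-fold cross-validation over the classifier's
#' hyperparameter grid; the grid point maximizing the mean held-out-fold AUC
#' wins, with ties broken toward the simpler model (for the SVM: smaller
#' cost, then smaller gamma).
#'
#' @param train a labeled, preprocessed [curve_matrix].
#' @param spec a [classifier_spec].
#' @param k inner folds (default 3).
#' @param seed integer seed for fold assignment and stochastic backends.
#' @return List with `best` (one-row grid data.frame), `best_auc` and
#'   `table` (the grid with its mean inner AUC per point).
#' @export
inner_grid_search <- function(train, spec, k = 3, seed = 1) {
  stopifnot(inherits(train, "curve_matrix"), inherits(spec, "classifier_spec"))
  folds <- make_stratified_folds(train$sample_id, train$group, k, seed)
  g <- nrow(spec$grid)
  auc_mat <- matrix(NA_real_, nrow = k, ncol = g)
  for (f in seq_len(k)) {
    tr <- cm_rows(train, which(folds != f))
    te <- cm_rows(train, which(folds == f))
    if (length(unique(tr$group)) < 2 || length(unique(te$group)) < 2)
      abort_validation("stratification failure: an inner fold lost a class")
    for (j in seq_len(g)) {
      model <- train_backend(tr$values, tr$group, spec, spec$grid[j, , drop = FALSE],
                             seed = substream_seed(seed, "fit", f, j))
      sc <- predict_scores(model, te$values)
      auc_mat[f, j] <- roc_and_auc(sc, te$group)$auc
    }
  }
  mean_auc <- colMeans(auc_mat)
  best_val <- max(mean_auc)
  cand <- which(mean_auc >= best_val - 1e-12)
  pref <- grid_preference(spec)
  best_j <- cand[which.min(pref[cand])]
  list(best = spec$grid[best_j, , drop = FALSE], best_auc = mean_auc[best_j],
       table = cbind(spec$grid, mean_auc = mean_auc))
}

#' Componentwise-joint mode of selected hyperparameters
#'
#' Tallies the grid points selected across the double-CV folds and repeats
#' and returns the most frequent one, with ties broken exactly as in
#' [inner_grid_search()].
#'
#' @param selections data.frame of selected grid rows (one per selection
#'   event).
#' @param spec the [classifier_spec] whose grid the selections came from.
#' @return One-row data.frame: the modal grid point.
#' @export
hyperparameter_mode <- function(selections, spec) {
  stopifnot(is.data.frame(selections), nrow(selections) >= 1)
  key <- function(df) do.call(paste, c(df, sep = "\r"))
  ks <- key(selections)
  tab <- table(ks)
  winners <- names(tab)[tab == max(tab)]
  grid_keys <- key(spec$grid)
  cand <- which(grid_keys %in% winners)
  if (length(cand) == 0) {  # selections from a custom grid: fall back
    return(selections[match(winners[1], ks), , drop = FALSE])
  }
  pref <- grid_preference(spec)
  spec$grid[cand[which.min(pref[cand])], , drop = FALSE]
}

# Shared outer double-CV skeleton. `fold_fun(tr, te, r, f)` must return a
# list(records = data.frame rows for the test fold, selection = chosen grid
# row, extra columns allowed).
run_outer_cv <- function(data, spec, config, fold_fun) {
  stopifnot(inherits(data, "curve_matrix"), inherits(spec, "classifier_spec"),
            inherits(config, "framework_config"))
  all_records <- list(); selections <- list(); per_repeat <- list()
  thr <- score_threshold(spec$kind, config$integration)
  for (r in seq_len(config$repeats)) {
    folds <- make_stratified_folds(data$sample_id, data$group,
                                   config$outer_folds,
                                   substream_seed(config$seed, "outer", r))
    rep_records <- list()
    for (f in seq_len(config$outer_folds)) {
      tr <- cm_rows(data, which(folds != f))
      te <- cm_rows(data, which(folds == f))
      stopifnot(length(intersect(tr$sample_id, te$sample_id)) == 0)
      out <- fold_fun(tr, te, r, f)
      rec <- out$records
      rec$repeat_idx <- r; rec$fold <- f
      rep_records[[f]] <- rec
      selections[[length(selections) + 1]] <- out$selection
    }
    rep_df <- do.call(rbind, rep_records)
    roc <- roc_and_auc(rep_df$score, rep_df$label)
    acc <- accuracy_and_ccr(rep_df$predicted, rep_df$label)
    per_repeat[[r]] <- data.frame(repeat_idx = r, auc = roc$auc,
                                  accuracy = acc$accuracy,
                                  ccr_a = acc$ccr_a, ccr_b = acc$ccr_b)
    all_records[[r]] <- rep_df
  }
  records <- do.call(rbind, all_records)
  per_repeat <- do.call(rbind, per_repeat)
  metric_mean <- vapply(per_repeat[, c("auc", "accuracy", "ccr_a", "ccr_b")],
                        mean, numeric(1))
  metric_sd <- vapply(per_repeat[, c("auc", "accuracy", "ccr_a", "ccr_b")],
                      stats::sd, numeric(1))
  sel_df <- do.call(rbind, selections)
  structure(list(
    kind = spec$kind,
    metrics = data.frame(mean = metric_mean, sd = metric_sd,
                         row.names = c("auc", "accuracy", "ccr_a", "ccr_b")),
    per_repeat = per_repeat,
    records = records,
    hyper_selections = sel_df,
    hyper_mode = hyperparameter_mode(
      sel_df[, setdiff(names(sel_df), "usage_rate"), drop = FALSE], spec),
    roc = roc_and_auc(records$score, records$label)$roc,
    threshold = thr,
    config = config), class = "eval_report")
}

normalize_pair <- function(tr, te, config) {
  if (config$normalization == "per_variable") {
    st <- uv_stats(tr$values, "per_variable", config$center)
    tr$values <- uv_apply(tr$values, st)
    te$values <- uv_apply(te$values, st)
  } else if (config$normalization == "per_curve") {
    st <- list(mode = "per_curve", center = FALSE)
    tr$values <- uv_apply(tr$values, st)
    te$values <- uv_apply(te$values, st)
  }
  list(tr = tr, te = te)
}

#' Conventional repeated double cross-validation
#'
#' The baseline the framework is compared against: repeated, stratified,
#' sample-grouped 5-fold outer evaluation; on each outer training portion an
#' inner 3-fold grid search picks the hyperparameters, one model is trained
#' and the held-out fold is scored. Replicates of one biological sample
#' never straddle an outer split, and normalization statistics are computed
#' on the training portion only.
#'
#' @param data a labeled [curve_matrix].
#' @param spec a [classifier_spec].
#' @param config a [framework_config] (its bootstrap/usage-rate fields are
#'   ignored here).
#' @return An `eval_report`: per-repeat and aggregate AUC, accuracy, CCR-A,
#'   CCR-B, pooled ROC points, hyperparameter selection tally.
#' @export
double_cv <- function(data, spec, config = framework_config()) {
  thr <- score_threshold(spec$kind)
  run_outer_cv(data, spec, config, function(tr, te, r, f) {
    nm <- normalize_pair(tr, te, config)
    gs <- inner_grid_search(nm$tr, spec, config$inner_folds,
                            substream_seed(config$seed, "inner", r, f))
    model <- train_backend(nm$tr$values, nm$tr$group, spec, gs$best,
                           seed = substream_seed(config$seed, "fit", r, f))
    sc <- predict_scores(model, nm$te$values)
    list(records = data.frame(sample_id = te$sample_id,
                              replicate_id = te$replicate_id,
                              label = te$group, score = sc,
                              predicted = ifelse(sc > thr, "B", "A"),
                              usage_rate = 1),
         selection = gs$best)
  })
}

#' Relaxometric learning: the full framework
#'
#' Identical outer structure to [double_cv()], but on each outer training
#' portion: (i) the variable usage rate is chosen by the inner grid search
#' (nested search over `usage_rates`; the rate with the best inner AUC wins,
#' ties toward fewer variables); (ii) B class-balanced bootstrap matrices of
#' m rows per group are drawn from the (truncated, normalized) training
#' portion; (iii) B classifier replicas sharing the selected hyperparameters
#' are trained; (iv) the test fold's score is the mean of the B continuous
#' replica scores (`mean_score`) or the B-vote fraction (`vote`), and the
#' evaluation metrics are computed from these integrated scores.
#'
#' @param data a labeled [curve_matrix].
#' @param spec a [classifier_spec].
#' @param config a [framework_config].
#' @param usage_rates optional override of `config$usage_rates`; give a
#'   single rate to run the framework at a fixed truncation.
#' @return An `eval_report` whose records carry the per-fold chosen
#'   `usage_rate`; `rate_tally` summarizes how often each rate was chosen.
#' @export
relaxometric_learn <- function(data, spec, config = framework_config(),
                               usage_rates = NULL) {
  rates <- usage_rates %||% config$usage_rates
  p_full <- ncol(data$values)
  n_vars <- vapply(rates, function(r) n_retained_variables(p_full, r),
                   integer(1))
  if (any(n_vars < 2))
    abort_validation("every usage rate must retain at least 2 variables")
  report <- run_outer_cv(data, spec, config, function(tr, te, r, f) {
    best <- NULL
    for (i in seq_along(rates)) {
      tr_r <- truncate_variables(tr, rates[i])
      nm_tr <- if (config$normalization == "per_variable") {
        st <- uv_stats(tr_r$values, "per_variable", config$center)
        tmp <- tr_r; tmp$values <- uv_apply(tr_r$values, st); tmp
      } else if (config$normalization == "per_curve") {
        tmp <- tr_r
        tmp$values <- uv_apply(tr_r$values, list(mode = "per_curve")); tmp
      } else tr_r
      gs <- inner_grid_search(nm_tr, spec, config$inner_folds,
                              substream_seed(config$seed, "inner", r, f, i))
      better <- is.null(best) || gs$best_auc > best$auc + 1e-12 ||
        (abs(gs$best_auc - best$auc) <= 1e-12 && n_vars[i] < best$n_vars)
      if (better)
        best <- list(rate = rates[i], n_vars = n_vars[i], auc = gs$best_auc,
                     hyper = gs$best)
    }
    tr_u <- truncate_variables(tr, best$rate)
    te_u <- truncate_variables(te, best$rate)
    nm <- normalize_pair(tr_u, te_u, config)
    score_mat <- matrix(NA_real_, nrow = nrow(te_u$values),
                        ncol = config$n_bootstrap)
    for (b in seq_len(config$n_bootstrap)) {
      bm <- bootstrap_balanced_matrix(nm$tr, config$m_per_group,
                                      substream_seed(config$seed, "boot",
                                                     r, f, b))
      stopifnot(sum(bm$group == "A") == config$m_per_group,
                sum(bm$group == "B") == config$m_per_group)
      model <- train_backend(bm$values, bm$group, spec, best$hyper,
                             seed = substream_seed(config$seed, "bfit",
                                                   r, f, b))
      score_mat[, b] <- predict_scores(model, nm$te$values)
    }
    if (config$integration == "mean_score") {
      sc <- rowMeans(score_mat)
      thr <- score_threshold(spec$kind)
      pred <- ifelse(sc > thr, "B", "A")
    } else {
      thr0 <- score_threshold(spec$kind)
      sc <- rowMeans(score_mat > thr0)
      pred <- ifelse(sc > 0.5, "B", "A")
    }
    list(records = data.frame(sample_id = te_u$sample_id,
                              replicate_id = te_u$replicate_id,
                              label = te_u$group, score = sc,
                              predicted = pred, usage_rate = best$rate),
         selection = cbind(best$hyper, usage_rate = best$rate))
  })
  fold_rates <- report$hyper_selections$usage_rate
  report$rate_tally <- table(factor(fold_rates, levels = sort(unique(rates))))
  report$chosen_rate <- as.numeric(names(which.max(report$rate_tally)))
  report
}

#' Usage-rate optimization across the full ladder
#'
#' Two search modes around [relaxometric_learn()]:
#' \describe{
#'   \item{nested (default)}{the rate is re-selected inside every outer
#'     training portion by the inner grid search; the report's chosen rate
#'     is the modal selection. Avoids the optimistic bias of picking the
#'     rate on the same data that scores it.}
#'   \item{global}{the full pipeline is evaluated once per rate and the
#'     rate maximizing the mean outer AUC is chosen (ties toward fewer
#'     variables); returns the per-rate report table, the shape of the
#'     usage-rate performance profile.}
#' }
#'
#' @param data a labeled [curve_matrix].
#' @param spec a [classifier_spec].
#' @param config a [framework_config] (its `usage_rates` field is the
#'   ladder searched).
#' @param mode `"nested"` or `"global"`.
#' @return For nested mode, the `eval_report` (with `chosen_rate`). For
#'   global mode, a list with `summary` (data.frame rate, n_variables, auc,
#'   accuracy, ccr_a, ccr_b), `reports`, `chosen_rate` and `report` (the
#'   chosen rate's report).
#' @export
optimize_usage_rate <- function(data, spec, config = framework_config(),
                                mode = c("nested", "global")) {
  mode <- match.arg(mode)
  if (mode == "nested") return(relaxometric_learn(data, spec, config))
  rates <- config$usage_rates
  p_full <- ncol(data$values)
  reports <- list(); rows <- list()
  for (r in rates) {
    rep_r <- relaxometric_learn(data, spec, config, usage_rates = r)
    key <- sprintf("%.10g", r)
    reports[[key]] <- rep_r
    rows[[key]] <- data.frame(rate = r,
                              n_variables = n_retained_variables(p_full, r),
                              auc = rep_r$metrics["auc", "mean"],
                              accuracy = rep_r$metrics["accuracy", "mean"],
                              ccr_a = rep_r$metrics["ccr_a", "mean"],
                              ccr_b = rep_r$metrics["ccr_b", "mean"])
  }
  summary <- do.call(rbind, rows); rownames(summary) <- NULL
  best_auc <- max(summary$auc)
  cand <- which(summary$auc >= best_auc - 1e-12)
  chosen <- cand[which.min(summary$n_variables[cand])]
  list(mode = mode, summary = summary, reports = reports,
       chosen_rate = summary$rate[chosen],
       report = reports[[sprintf("%.10g", summary$rate[chosen])]])
}

#' Fit a deployable balanced-bootstrap ensemble on all labeled data
#'
#' After evaluation, the model actually kept is an ensemble of B replicas
#' trained on balanced bootstrap matrices drawn from the full labeled
#' dataset, at a fixed usage rate and hyperparameters (typically the modal
#' values from an `eval_report`). Truncation and normalization statistics
#' are stored so new curves are preprocessed identically.
#'
#' @param data a labeled [curve_matrix].
#' @param spec a [classifier_spec].
#' @param config a [framework_config].
#' @param hyper one-row grid data.frame; default: re-run
#'   [inner_grid_search()] on the full data.
#' @param usage_rate truncation applied before fitting (default 1).
#' @return An object of class `ensemble_model`.
#' @export
fit_ensemble <- function(data, spec, config = framework_config(),
                         hyper = NULL, usage_rate = 1) {
  du <- truncate_variables(data, usage_rate)
  st <- if (config$normalization == "per_variable")
    uv_stats(du$values, "per_variable", config$center) else
      list(mode = config$normalization, center = FALSE)
  dn <- du
  if (config$normalization != "none") dn$values <- uv_apply(du$values, st)
  if (is.null(hyper))
    hyper <- inner_grid_search(dn, spec, config$inner_folds,
                               substream_seed(config$seed, "final"))$best
  replicas <- lapply(seq_len(config$n_bootstrap), function(b) {
    bm <- bootstrap_balanced_matrix(dn, config$m_per_group,
                                    substream_seed(config$seed, "fboot", b))
    train_backend(bm$values, bm$group, spec, hyper,
                  seed = substream_seed(config$seed, "ffit", b))
  })
  structure(list(replicas = replicas, spec = spec, hyper = hyper,
                 usage_rate = usage_rate, n_vars = ncol(du$values),
                 norm = st, integration = config$integration,
                 threshold = score_threshold(spec$kind, config$integration)),
            class = "ensemble_model")
}

#' Score new curves with a fitted ensemble
#' @param object an `ensemble_model`.
#' @param newdata a [curve_matrix] on the same time grid as the training
#'   data (it is truncated to the model's usage rate).
#' @param ... unused.
#' @return data.frame with the integrated `score` and `predicted` class per
#'   row of `newdata`.
#' @export
predict.ensemble_model <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "curve_matrix"))
  v <- newdata$values[, seq_len(object$n_vars), drop = FALSE]
  if (object$norm$mode != "none") v <- uv_apply(v, object$norm)
  scores <- vapply(object$replicas, function(m) predict_scores(m, v),
                   numeric(nrow(v)))
  scores <- matrix(scores, nrow = nrow(v))
  if (object$integration == "mean_score") {
    sc <- rowMeans(scores)
    thr0 <- score_threshold(object$spec$kind)
    pred <- ifelse(sc > thr0, "B", "A")
  } else {
    thr0 <- score_threshold(object$spec$kind)
    sc <- rowMeans(scores > thr0)
    pred <- ifelse(sc > 0.5, "B", "A")
  }
  data.frame(sample_id = newdata$sample_id,
             replicate_id = newdata$replicate_id, score = sc,
             predicted = pred)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report (%s backend)\n", x$kind))
  m <- x$metrics
  for (nm in rownames(m))
    cat(sprintf("  %-9s %.3f +/- %.3f\n", nm, m[nm, "mean"], m[nm, "sd"]))
  if (!is.null(x$chosen_rate))
    cat(sprintf("  chosen usage rate: %.2g\n", x$chosen_rate))
  hp <- x$hyper_mode
  cat("  modal hyperparameters:",
      paste(names(hp), unlist(hp), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Serialize an evaluation report
#'
#' Writes the aggregate metrics and configuration as JSON and the per-fold
#' prediction records plus ROC points as CSV into a directory.
#'
#' @param report an `eval_report`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  m <- report$metrics
  jsonlite::write_json(list(
    backend = report$kind,
    metrics = lapply(rownames(m), function(nm)
      list(metric = nm, mean = m[nm, "mean"], sd = m[nm, "sd"])),
    chosen_rate = report$chosen_rate,
    modal_hyperparameters = as.list(report$hyper_mode),
    config = unclass(report$config)),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  utils::write.csv(report$records, file.path(dir, "fold_records.csv"),
                   row.names = FALSE)
  utils::write.csv(report$roc, file.path(dir, "roc_points.csv"),
                   row.names = FALSE)
  utils::write.csv(report$per_repeat, file.path(dir, "per_repeat.csv"),
                   row.names = FALSE)
  invisible(dir)
}
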