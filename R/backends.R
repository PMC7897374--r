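#' Classifier backend specification
#'
#' Names the classification algorithm and its hyperparameter grid for the
#' inner cross-validation search. Default grids:
#' \describe{
#'   \item{svm_rbf}{RBF-kernel SVM; log-spaced grid gamma
#'     \{1e-4, 3e-4, 1e-3, 3e-3, 0.01, 0.03, 0.1, 0.3, 1\} by cost
#'     \{1, 5, 10, 50, 100, 500, 1000\} — spanning gamma 0.0001-1 and cost
#'     1-1000. Ties in the grid search break toward smaller cost, then
#'     smaller gamma (the simpler model).}
#'   \item{random_forest}{500 trees, variables-per-split rule in
#'     \{sqrt(P), P/3\}.}
#'   \item{pls_da}{PLS discriminant analysis with 1-3 latent components
#'     (group dummy-coded; the predicted response is the score).}
#' }
#'
#' @param kind one of `"svm_rbf"`, `"random_forest"`, `"pls_da"`.
#' @param grid optional data.frame replacing the default grid (columns
#'   `gamma`/`cost`, `ntree`/`mtry_rule`, or `ncomp`).
#' @return An object of class `classifier_spec` with elements `kind`,
#'   `grid` and `tie_order` (the preference order used to break ties).
#' @export
classifier_spec <- function(kind = c("svm_rbf", "random_forest", "pls_da"),
                            grid = NULL) {
  kind <- match.arg(kind)
  if (is.null(grid)) {
    grid <- switch(kind,
      svm_rbf = expand.grid(
        gamma = c(1e-4, 3e-4, 1e-3, 3e-3, 0.01, 0.03, 0.1, 0.3, 1),
        cost = c(1, 5, 10, 50, 100, 500, 1000)),
      random_forest = expand.grid(ntree = 500,
                                  mtry_rule = c("sqrt", "third"),
                                  stringsAsFactors = FALSE),
      pls_da = data.frame(ncomp = 1:3))
  }
  if (!is.data.frame(grid) || nrow(grid) == 0)
    abort_validation("hyperparameter grid must be a non-empty data.frame")
  if (kind == "svm_rbf") {
    if (!all(c("gamma", "cost") %in% names(grid)))
      abort_validation("svm_rbf grid needs columns gamma and cost")
    if (any(grid$gamma <= 0) || any(grid$cost <= 0))
      abort_validation("svm_rbf gamma and cost must be positive")
  }
  tie_order <- switch(kind,
    svm_rbf = order(grid$cost, grid$gamma),
    random_forest = seq_len(nrow(grid)),
    pls_da = order(grid$ncomp))
  structure(list(kind = kind, grid = grid, tie_order = tie_order),
            class = "classifier_spec")
}

# Preference rank of each grid row (1 = most preferred on ties).
grid_preference <- function(spec) {
  pref <- integer(nrow(spec$grid))
  pref[spec$tie_order] <- seq_len(nrow(spec$grid))
  pref
}

resolve_mtry <- function(rule, p) {
  v <- switch(as.character(rule),
              sqrt = floor(sqrt(p)),
              third = floor(p / 3),
              as.integer(rule))
  max(1L, min(as.integer(v), p))
}

#' Fit one classifier replica
#'
#' All backends share the score-orientation contract: larger continuous
#' score means "more B-like". The decision threshold separating predicted
#' classes is stored on the model (0 for the SVM decision value, 0.5 for the
#' probability-like RF and PLS-DA scores).
#'
#' @param x numeric feature matrix (rows = curves).
#' @param y class labels in `{"A","B"}` (both present).
#' @param spec a [classifier_spec].
#' @param hyper one-row data.frame of hyperparameters (a row of
#'   `spec$grid`).
#' @param seed integer seed for stochastic backends (random forest).
#' @return An object of class `relax_model`.
#' @export
train_backend <- function(x, y, spec, hyper, seed = 1) {
  stopifnot(inherits(spec, "classifier_spec"))
  y <- factor(as.character(y), levels = c("A", "B"))
  if (nlevels(droplevels(y)) < 2)
    abort_validation("training data must contain both classes")
  fit <- switch(spec$kind,
    svm_rbf = e1071::svm(x = x, y = y, type = "C-classification",
                         kernel = "radial", gamma = hyper$gamma,
                         cost = hyper$cost, scale = FALSE),
    random_forest = with_seed(seed,
      randomForest::randomForest(
        x = x, y = y, ntree = hyper$ntree,
        mtry = resolve_mtry(hyper$mtry_rule, ncol(x)))),
    pls_da = {
      if (!requireNamespace("mixOmics", quietly = TRUE))
        stop("the pls_da backend requires the mixOmics package")
      ncomp <- min(hyper$ncomp, nrow(x) - 1, ncol(x))
      colnames(x) <- paste0("V", seq_len(ncol(x)))
      fit <- mixOmics::plsda(X = x, Y = y, ncomp = ncomp)
      fit$relaxlearn_ncomp <- ncomp
      fit
    })
  structure(list(kind = spec$kind, fit = fit, hyper = hyper,
                 threshold = if (spec$kind == "svm_rbf") 0 else 0.5),
            class = "relax_model")
}

#' Continuous classification scores of a fitted backend
#'
#' @param model a `relax_model` from [train_backend()].
#' @param newx feature matrix to score.
#' @return Numeric vector, one score per row of `newx`; larger = more
#'   "B"-like.
#' @export
predict_scores <- function(model, newx) {
  stopifnot(inherits(model, "relax_model"))
  switch(model$kind,
    svm_rbf = {
      pr <- stats::predict(model$fit, newx, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # e1071's decision value is positive for the class named first in the
      # column label ("A/B" or "B/A"); orient so that larger means B.
      if (colnames(dv)[1] == "A/B") -dv[, 1] else dv[, 1]
    },
    random_forest = unname(
      stats::predict(model$fit, newx, type = "prob")[, "B"]),
    pls_da = {
      nc <- model$fit$relaxlearn_ncomp
      colnames(newx) <- paste0("V", seq_len(ncol(newx)))
      pr <- stats::predict(model$fit, newdata = newx)
      unname(pr$predict[, "B", nc])
    })
}

#' Predicted class labels from a fitted backend
#' @param model a `relax_model`.
#' @param newx feature matrix.
#' @return Character vector in `{"A","B"}`.
#' @export
predict_class <- function(model, newx) {
  ifelse(predict_scores(model, newx) > model$threshold, "B", "A")
}

score_threshold <- function(kind, integration = "mean_score") {
  if (integration == "vote") return(0.5)
  if (kind == "svm_rbf") 0 else 0.5
}
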