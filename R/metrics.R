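#' ROC curve and AUC for a binary score vector
#'
#' Class "B" is the positive class by default (the majority, tender-muscle
#' group in the hard/tender setting); scores are oriented so that larger
#' values mean "more B-like" (the contract every classifier backend in this
#' package follows). The AUC is computed as the Mann-Whitney concordance
#' probability with ties counted 1/2, which equals the trapezoidal area
#' under the returned ROC polygon.
#'
#' @param scores numeric scores, larger = more positive-class-like.
#' @param labels class labels with exactly the two levels `"A"` and `"B"`
#'   (both present).
#' @param positive positive class for the ROC (default `"B"`).
#' @return List with `auc` (scalar) and `roc`, a data.frame of
#'   `(fpr, tpr, threshold)` points running from (0,0) to (1,1).
#' @export
roc_and_auc <- function(scores, labels, positive = "B") {
  stopifnot(length(scores) == length(labels))
  labels <- as.character(labels)
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    abort_validation("both classes must be present to compute ROC/AUC")
  r <- rank(scores)  # midranks: ties count 1/2 in the concordance sum
  auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  ord <- order(scores, decreasing = TRUE)
  s_sorted <- scores[ord]
  tp <- cumsum(pos[ord]); fp <- cumsum(!pos[ord])
  last_of_tie <- c(diff(s_sorted) != 0, TRUE)
  roc <- data.frame(
    fpr = c(0, fp[last_of_tie] / n_neg),
    tpr = c(0, tp[last_of_tie] / n_pos),
    threshold = c(Inf, s_sorted[last_of_tie]))
  list(auc = auc, roc = roc)
}

#' Accuracy and per-class correct classification rates
#'
#' CCR-A is the fraction of group-A curves classified as A, CCR-B likewise
#' for B; accuracy is the overall correct fraction, so that
#' `accuracy = (n_A * ccr_a + n_B * ccr_b) / n`. A class absent from the
#' labels has an undefined CCR, reported as `NA`.
#'
#' @param predicted predicted labels in `{"A","B"}`.
#' @param labels true labels in `{"A","B"}`.
#' @return List with `accuracy`, `ccr_a`, `ccr_b` and the 2x2 `confusion`
#'   table.
#' @export
accuracy_and_ccr <- function(predicted, labels) {
  stopifnot(length(predicted) == length(labels))
  predicted <- as.character(predicted); labels <- as.character(labels)
  ok <- predicted == labels
  n_a <- sum(labels == "A"); n_b <- sum(labels == "B")
  list(
    accuracy = mean(ok),
    ccr_a = if (n_a > 0) sum(ok & labels == "A") / n_a else NA_real_,
    ccr_b = if (n_b > 0) sum(ok & labels == "B") / n_b else NA_real_,
    confusion = table(truth = factor(labels, c("A", "B")),
                      predicted = factor(predicted, c("A", "B"))))
}

#' Per-variable permutation robustness of an evaluation pipeline
#'
#' Quantifies how much the classification performance depends on any single
#' time-point variable: for each selected variable, its column is permuted
#' across curves (`n_perm` independent permutations, the identity
#' permutation is rejected and redrawn) and the full evaluation pipeline is
#' re-run; the change in AUC and accuracy relative to the unpermuted
#' baseline is reported.
#'
#' @param data a labeled [curve_matrix].
#' @param pipeline function `curve_matrix -> list(auc =, accuracy =)`
#'   (must be internally seeded/deterministic so deltas reflect only the
#'   permutation). See [evaluate_pipeline()] for a ready-made one.
#' @param variables integer column indices to probe.
#' @param n_perm permutations per variable (default 10).
#' @param seed integer seed for the permutation draws.
#' @return List with `baseline` (the unpermuted metrics), `summary`
#'   (data.frame variable, time, mean/sd of delta AUC and delta accuracy)
#'   and `deltas` (all per-permutation rows).
#' @export
permutation_robustness <- function(data, pipeline, variables, n_perm = 10,
                                   seed = 1) {
  stopifnot(inherits(data, "curve_matrix"), is.function(pipeline))
  p <- ncol(data$values); n <- nrow(data$values)
  if (any(variables < 1 | variables > p))
    abort_validation(sprintf("variable index out of range 1..%d", p))
  if (n < 2) abort_validation("need at least 2 curves to permute")
  base <- pipeline(data)
  rows <- list()
  for (v in variables) {
    for (j in seq_len(n_perm)) {
      perm <- with_seed(substream_seed(seed, "perm", v, j), {
        pm <- sample(n)
        while (identical(pm, seq_len(n))) pm <- sample(n)
        pm
      })
      d2 <- data
      d2$values[, v] <- d2$values[perm, v]
      res <- pipeline(d2)
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, time = data$time[v], perm = j,
        delta_auc = res$auc - base$auc,
        delta_accuracy = res$accuracy - base$accuracy)
    }
  }
  deltas <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(deltas, deltas$variable), function(d) {
    data.frame(variable = d$variable[1], time = d$time[1],
               mean_delta_auc = mean(d$delta_auc),
               sd_delta_auc = stats::sd(d$delta_auc),
               mean_delta_accuracy = mean(d$delta_accuracy),
               sd_delta_accuracy = stats::sd(d$delta_accuracy))
  }))
  rownames(summary) <- NULL
  list(baseline = base, summary = summary, deltas = deltas)
}

#' Ready-made evaluation pipeline for robustness analysis
#'
#' Wraps [double_cv()] (conventional) or [relaxometric_learn()] (framework)
#' into the `curve_matrix -> list(auc, accuracy)` closure that
#' [permutation_robustness()] expects.
#'
#' @param spec a [classifier_spec].
#' @param config a [framework_config].
#' @param mode `"framework"` or `"conventional"`.
#' @return A function of one `curve_matrix` argument.
#' @export
evaluate_pipeline <- function(spec, config, mode = c("framework",
                                                     "conventional")) {
  mode <- match.arg(mode)
  function(data) {
    rep <- if (mode == "framework") relaxometric_learn(data, spec, config)
           else double_cv(data, spec, config)
    list(auc = rep$metrics["auc", "mean"],
         accuracy = rep$metrics["accuracy", "mean"])
  }
}
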