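#' Detect the sample-contact point in a force-time trace
#'
#' The contact (zero) point is the first index at which the force exceeds
#' `baseline mean + k_sd * baseline sd` and stays above it for `run_length`
#' consecutive points. The baseline is estimated from the first `baseline_n`
#' points, which must precede loading.
#'
#' @param curve a [force_curve].
#' @param baseline_n number of leading points used as baseline (default 20).
#' @param k_sd threshold in baseline standard deviations (default 5).
#' @param run_length consecutive above-threshold points required (default 3).
#' @return Integer index of the contact point.
#' @export
detect_contact <- function(curve, baseline_n = 20, k_sd = 5, run_length = 3) {
  stopifnot(inherits(curve, "force_curve"))
  n <- length(curve$force)
  baseline_n <- min(baseline_n, n)
  base <- curve$force[seq_len(baseline_n)]
  thr <- mean(base) + k_sd * stats::sd(base)
  if (is.na(thr)) thr <- mean(base)
  above <- curve$force > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= run_length)
  if (length(hit) > 0) return(ends[hit[1]] - r$lengths[hit[1]] + 1L)
  stop(structure(
    class = c("relaxlearn_no_contact", "error", "condition"),
    list(message = sprintf(
      "no contact detected in curve %s/%s (force never exceeds baseline + %g sd)",
      curve$sample_id, curve$replicate_id, k_sd), call = NULL)))
}

#' Transform a force-time curve to the distance domain
#'
#' Converts elapsed time after contact to crosshead travel,
#' `distance = loading_rate / 60 * (t - t_contact)` in mm, discards the
#' pre-contact points and re-baselines the force by subtracting the
#' pre-contact mean.
#'
#' @param curve a [force_curve].
#' @param contact list of arguments passed to [detect_contact()].
#' @return An object of class `distance_curve` with fields `distance` (mm,
#'   starting at 0), `force`, `contact_index`, `sample_id`, `replicate_id`.
#' @export
to_distance_curve <- function(curve, contact = list()) {
  stopifnot(inherits(curve, "force_curve"))
  ci <- do.call(detect_contact, c(list(curve), contact))
  pre_mean <- if (ci > 1) mean(curve$force[seq_len(ci - 1)]) else 0
  idx <- seq(ci, length(curve$time))
  structure(
    list(distance = (curve$time[idx] - curve$time[ci]) *
           curve$loading_rate / 60,
         force = curve$force[idx] - pre_mean,
         contact_index = ci,
         sample_id = curve$sample_id, replicate_id = curve$replicate_id),
    class = "distance_curve"
  )
}

#' Exponential fit of a force-distance curve over a fixed window
#'
#' Fits `y = a * exp(b * x)` to the portion of the curve with
#' `0 <= x <= x_max` by ordinary least squares on `ln(y) = ln(a) + b x`
#' (the log-linear method equivalent to a spreadsheet exponential
#' trendline). Points with non-positive force inside the window are dropped
#' from the fit. Curves not reaching `x_max` are rejected as too short, the
#' mechanism by which a sample slice thinner than the window is excluded.
#'
#' @param dcurve a `distance_curve` from [to_distance_curve()].
#' @param x_max window end in mm (default 3.63).
#' @return On success an object of class `exp_fit` (fields `a`, `b`, `r2`,
#'   `n_points`, `accepted = TRUE`); otherwise a rejection record
#'   (`accepted = FALSE`, `reason`).
#' @export
window_and_fit <- function(dcurve, x_max = 3.63) {
  stopifnot(inherits(dcurve, "distance_curve"))
  rejection <- function(reason) {
    structure(list(accepted = FALSE, reason = reason,
                   sample_id = dcurve$sample_id,
                   replicate_id = dcurve$replicate_id),
              class = "exp_fit")
  }
  if (max(dcurve$distance) < x_max)
    return(rejection("insufficient length"))
  in_win <- dcurve$distance >= 0 & dcurve$distance <= x_max
  pos <- in_win & dcurve$force > 0
  if (sum(pos) < 3)
    return(rejection("fewer than 3 positive-force points in window"))
  x <- dcurve$distance[pos]
  y <- dcurve$force[pos]
  fit <- stats::lm(log(y) ~ x)
  ly <- log(y)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else NA_real_
  structure(list(accepted = TRUE,
                 a = unname(exp(stats::coef(fit)[1])),
                 b = unname(stats::coef(fit)[2]),
                 r2 = r2,
                 n_points = length(x),
                 sample_id = dcurve$sample_id,
                 replicate_id = dcurve$replicate_id),
            class = "exp_fit")
}

#' Run the full force-curve preprocessing pipeline
#'
#' Contact detection, distance transform and windowed exponential fit for a
#' set of curves, with bookkeeping: every input curve ends up either in the
#' fit table or in the rejection log (curves with no detectable contact are
#' rejected, not dropped silently).
#'
#' @param curves list of [force_curve] objects (or the `curves` element of
#'   [generate_force_curves()] output).
#' @param contact arguments for [detect_contact()].
#' @param x_max fitting window end in mm (default 3.63).
#' @return List with `fits` (data.frame sample_id, replicate_id, a, b, r2,
#'   n_points), `rejections` (data.frame sample_id, replicate_id, reason)
#'   and `counts` (input, accepted, rejected).
#' @export
fit_force_curves <- function(curves, contact = list(), x_max = 3.63) {
  if (!is.null(curves$curves)) curves <- curves$curves
  fits <- list(); rej <- list()
  for (cv in curves) {
    res <- tryCatch(
      window_and_fit(to_distance_curve(cv, contact), x_max),
      relaxlearn_no_contact = function(e) {
        structure(list(accepted = FALSE, reason = "no contact detected",
                       sample_id = cv$sample_id,
                       replicate_id = cv$replicate_id),
                  class = "exp_fit")
      })
    if (res$accepted) {
      fits[[length(fits) + 1]] <- data.frame(
        sample_id = res$sample_id, replicate_id = res$replicate_id,
        a = res$a, b = res$b, r2 = res$r2, n_points = res$n_points)
    } else {
      rej[[length(rej) + 1]] <- data.frame(
        sample_id = res$sample_id, replicate_id = res$replicate_id,
        reason = res$reason)
    }
  }
  empty_fit <- data.frame(sample_id = character(), replicate_id = character(),
                          a = numeric(), b = numeric(), r2 = numeric(),
                          n_points = integer())
  empty_rej <- data.frame(sample_id = character(), replicate_id = character(),
                          reason = character())
  fits <- if (length(fits)) do.call(rbind, fits) else empty_fit
  rej <- if (length(rej)) do.call(rbind, rej) else empty_rej
  list(fits = fits, rejections = rej,
       counts = c(input = length(curves), accepted = nrow(fits),
                  rejected = nrow(rej)))
}

#' Data-driven hard/tender labeling by hierarchical clustering
#'
#' Aggregates replicate exponential fits to one `(a, b)` per sample (median),
#' standardizes the two coefficients (they carry incommensurate units),
#' clusters with Ward-linkage agglomerative clustering and cuts the tree at
#' k = 2. The cluster with the larger median fitted force at the reference
#' distance — `a * exp(b * x_ref)` — is named "A" (hard muscle), the other
#' "B" (tender).
#'
#' @param fits data.frame with columns `sample_id`, `a`, `b` (replicate rows
#'   allowed; aggregated by median).
#' @param linkage `"ward2"` (default; squared-distance Ward update,
#'   `hclust` method `ward.D2`) or `"ward"` (`ward.D`).
#' @param standardize scale the `(a, b)` features to zero mean / unit
#'   variance before clustering (default TRUE).
#' @param x_ref reference distance in mm for the hardness orientation rule
#'   (default 3.63, the fitting-window end).
#' @return List of class `group_labeling`: `labels` (data.frame sample_id,
#'   group), `hclust` (the linkage tree), `features` (the per-sample
#'   feature table used).
#' @export
label_by_hca <- function(fits, linkage = c("ward2", "ward"),
                         standardize = TRUE, x_ref = 3.63) {
  linkage <- match.arg(linkage)
  stopifnot(is.data.frame(fits), all(c("sample_id", "a", "b") %in% names(fits)))
  if (length(unique(fits$sample_id)) < 2)
    abort_validation("at least 2 samples required for clustering")
  feats <- stats::aggregate(cbind(a, b) ~ sample_id, data = fits,
                            FUN = stats::median)
  m <- as.matrix(feats[, c("a", "b")])
  if (all(apply(m, 2, function(v) diff(range(v)) == 0)))
    abort_validation("degenerate feature table: all samples identical in (a, b)")
  if (standardize) {
    m <- apply(m, 2, function(v) {
      s <- stats::sd(v)
      if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
    })
  }
  hc <- stats::hclust(stats::dist(m),
                      method = if (linkage == "ward2") "ward.D2" else "ward.D")
  cl <- stats::cutree(hc, k = 2)
  hardness <- feats$a * exp(feats$b * x_ref)
  med1 <- stats::median(hardness[cl == 1])
  med2 <- stats::median(hardness[cl == 2])
  hard_cluster <- if (med1 >= med2) 1 else 2
  labels <- data.frame(
    sample_id = feats$sample_id,
    group = ifelse(cl == hard_cluster, "A", "B"))
  structure(list(labels = labels, hclust = hc,
                 features = cbind(feats, hardness = hardness)),
            class = "group_labeling")
}

#' @export
print.group_labeling <- function(x, ...) {
  tab <- table(x$labels$group)
  cat(sprintf("group_labeling: %d samples -> A (hard): %d, B (tender): %d\n",
              nrow(x$labels), tab[["A"]], tab[["B"]]))
  invisible(x)
}
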