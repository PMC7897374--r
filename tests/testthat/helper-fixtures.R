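# Shared fixtures, built in code at test time.

# Two-compartment population with a large, cleanly separable group effect.
separable_spec <- function(seed = 1, n = 8, time_points = 32,
                           noise_sd = 0.01) {
  decay_population_spec(
    n_per_group = n,
    groups = list(
      A = list(fraction = c(0.8, 0.2), t2 = c(0.04, 0.2)),
      B = list(fraction = c(0.2, 0.8), t2 = c(0.04, 0.2))),
    time_points = time_points, acquisition_time = 1.024,
    replicates_per_sample = 2, noise_sd = noise_sd, seed = seed)
}

# Tiny labeled matrix built directly (no generator) for I/O and fold tests.
tiny_matrix <- function(n_per_group = 4, p = 8, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_group
  curve_matrix(matrix(rnorm(n * p), n, p), time = (1:p) * 0.01,
               sample_id = sprintf("s%02d", 1:n),
               group = rep(c("A", "B"), each = n_per_group))
}

# Small evaluation configuration that keeps CV tests fast.
fast_config <- function(seed = 1, ...) {
  args <- list(n_bootstrap = 5, m_per_group = 10, usage_rates = 1,
               outer_folds = 3, inner_folds = 2, repeats = 1, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(framework_config, args)
}

small_svm_spec <- function() {
  classifier_spec("svm_rbf",
                  grid = expand.grid(gamma = c(0.01, 0.1),
                                     cost = c(1, 10)))
}

# Brute-force pairwise-concordance AUC (independent oracle): probability
# that a positive-class score exceeds a negative-class one, ties 1/2.
auc_bruteforce <- function(scores, labels, positive = "B") {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  tot <- 0
  for (b in sp) for (a in sn) tot <- tot + (b > a) + 0.5 * (b == a)
  tot / (length(sp) * length(sn))
}

# Trapezoidal area under an ROC polygon (second independent route).
auc_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

# Exhaustive optimal 2-partition under the Ward objective (total
# within-cluster sum of squares), for small point sets.
best_two_partition <- function(m) {
  n <- nrow(m)
  wss <- function(idx) {
    if (length(idx) == 0) return(0)
    sub <- m[idx, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }
  best <- NULL; best_val <- Inf
  for (code in 1:(2^(n - 1) - 1)) {
    memb <- as.integer(intToBits(code))[1:n]
    val <- wss(which(memb == 1)) + wss(which(memb == 0))
    if (val < best_val) { best_val <- val; best <- memb }
  }
  best
}

same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}

# A clean pre-contact + exponential force trace with known parameters.
exact_force_curve <- function(a, b, loading_rate = 2, pre = 15,
                              total_distance = 5, dt = 0.5, sid = "s1",
                              rid = "1") {
  time <- seq(0, pre + total_distance / (loading_rate / 60), by = dt)
  dist <- pmax(0, time - pre) * loading_rate / 60
  force <- ifelse(time < pre, 0, a * exp(b * dist))
  force_curve(time, force, loading_rate, sid, rid)
}
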