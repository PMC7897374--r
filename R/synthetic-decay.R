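#' Specification of a synthetic T2 decay-curve population
#'
#' Describes a two-group population of multi-exponential CPMG decay curves.
#' Each group is a mixture of water compartments `(fraction, t2)`; a
#' noise-free curve is `y(t) = sum_i f_i * exp(-t / T2_i)` so that `y(0) = 1`
#' when the fractions sum to one. Stored time point k (k = 1..P) sits at
#' `k * acquisition_time / P`: the t = 0 sample is not stored, so the grid
#' matches a 256-point, 1.024 s acquisition where 230 retained points end at
#' exactly 0.92 s.
#'
#' @param n_per_group number of biological samples per group; a single count
#'   or a named vector like `c(A = 10, B = 40)`.
#' @param groups named list (names `"A"`, `"B"`) of compartment tables; each
#'   a list/data.frame with numeric `fraction` (summing to 1 within 1e-9)
#'   and `t2` (seconds, all positive).
#' @param time_points number of stored points P (default 256).
#' @param acquisition_time total acquisition time in seconds (default 1.024).
#' @param replicates_per_sample technical replicates per sample (default 3).
#' @param noise_sd standard deviation of additive i.i.d. Gaussian noise per
#'   point, in amplitude units of the unit-height decay (default 0.01).
#' @param fraction_jitter_sd optional per-sample biological variation: sd of
#'   Gaussian jitter added to compartment fractions (renormalized to sum 1);
#'   default 0 (replicates differ by noise only).
#' @param seed integer seed; generation is deterministic given the spec.
#' @return An object of class `decay_population_spec`.
#' @export
decay_population_spec <- function(n_per_group, groups,
                                  time_points = 256,
                                  acquisition_time = 1.024,
                                  replicates_per_sample = 3,
                                  noise_sd = 0.01,
                                  fraction_jitter_sd = 0,
                                  seed = 1) {
  if (!is.list(groups) || is.null(names(groups)) ||
      !setequal(names(groups), c("A", "B")))
    abort_validation("'groups' must be a named list with elements 'A' and 'B'")
  for (g in names(groups)) {
    comp <- groups[[g]]
    f <- as.numeric(comp$fraction); t2 <- as.numeric(comp$t2)
    if (length(f) == 0 || length(f) != length(t2))
      abort_validation(sprintf("group %s: fraction/t2 lengths differ", g))
    if (abs(sum(f) - 1) > 1e-9)
      abort_validation(sprintf(
        "group %s: compartment fractions sum to %.10g, not 1", g, sum(f)))
    if (any(t2 <= 0))
      abort_validation(sprintf("group %s: all t2 must be positive", g))
    groups[[g]] <- data.frame(fraction = f, t2 = t2)
  }
  if (length(n_per_group) == 1) {
    n_per_group <- c(A = n_per_group, B = n_per_group)
  }
  if (!setequal(names(n_per_group), c("A", "B")) ||
      !all(vapply(n_per_group, is_count, logical(1))))
    abort_validation("'n_per_group' must be positive counts named A and B")
  stopifnot(is_count(time_points), time_points >= 2,
            acquisition_time > 0, is_count(replicates_per_sample),
            noise_sd >= 0, fraction_jitter_sd >= 0)
  structure(
    list(n_per_group = n_per_group[c("A", "B")], groups = groups,
         time_points = as.integer(time_points),
         acquisition_time = acquisition_time,
         replicates_per_sample = as.integer(replicates_per_sample),
         noise_sd = noise_sd, fraction_jitter_sd = fraction_jitter_sd,
         seed = as.integer(seed)),
    class = "decay_population_spec"
  )
}

#' Time grid of a decay population spec
#' @param spec a [decay_population_spec].
#' @return Numeric vector of P acquisition times (seconds).
#' @export
decay_time_grid <- function(spec) {
  seq_len(spec$time_points) * (spec$acquisition_time / spec$time_points)
}

#' Noise-free multi-exponential decay signal
#'
#' Evaluates `y(t) = sum_i fraction_i * exp(-t / t2_i)` — the compartment
#' model every synthetic curve is built from.
#'
#' @param time numeric vector of times (seconds).
#' @param fraction compartment amplitude fractions.
#' @param t2 compartment relaxation times (seconds, positive).
#' @return Numeric vector of amplitudes, same length as `time`.
#' @export
decay_signal <- function(time, fraction, t2) {
  stopifnot(length(fraction) == length(t2), all(t2 > 0))
  as.numeric(exp(-outer(time, 1 / t2)) %*% fraction)
}

#' Generate a synthetic relaxation-curve matrix
#'
#' Draws `n_per_group` biological samples per group, each measured
#' `replicates_per_sample` times. Replicates of one sample share compartment
#' parameters and differ only by additive Gaussian noise (plus optional
#' per-sample fraction jitter). Output rows carry true group labels.
#'
#' @param spec a [decay_population_spec].
#' @return A [curve_matrix] with `group` set to the generating class.
#' @export
generate_decay_matrix <- function(spec) {
  stopifnot(inherits(spec, "decay_population_spec"))
  time <- decay_time_grid(spec)
  with_seed(substream_seed(spec$seed, "decay"), {
    rows <- list(); meta <- list(); k <- 0
    for (g in c("A", "B")) {
      comp <- spec$groups[[g]]
      for (s in seq_len(spec$n_per_group[[g]])) {
        f <- comp$fraction
        if (spec$fraction_jitter_sd > 0) {
          f <- pmax(f + stats::rnorm(length(f), 0, spec$fraction_jitter_sd),
                    1e-6)
          f <- f / sum(f)
        }
        clean <- decay_signal(time, f, comp$t2)
        sid <- sprintf("%s%03d", g, s)
        for (r in seq_len(spec$replicates_per_sample)) {
          k <- k + 1
          rows[[k]] <- clean +
            stats::rnorm(length(time), 0, spec$noise_sd)
          meta[[k]] <- c(sid, as.character(r), g)
        }
      }
    }
    m <- do.call(rbind, rows)
    md <- do.call(rbind, meta)
    curve_matrix(m, time, sample_id = md[, 1], replicate_id = md[, 2],
                 group = md[, 3])
  })
}

#' Subsample one group to create class imbalance
#'
#' Emulates the biased between-group sample sizes the framework is designed
#' for: the designated minority group is subsampled without replacement at
#' the whole-sample level (all replicates of a sample are kept or dropped
#' together); the other group is untouched.
#'
#' @param x a labeled [curve_matrix] with both groups present.
#' @param keep_fraction_minority fraction of minority-group samples to keep,
#'   in `(0, 1]`.
#' @param minority which group to thin, `"A"` (default) or `"B"`.
#' @param seed integer seed for the subsample draw.
#' @return A [curve_matrix]; identical to `x` when the fraction is 1.
#' @export
make_imbalanced <- function(x, keep_fraction_minority, minority = "A",
                            seed = 1) {
  stopifnot(inherits(x, "curve_matrix"))
  minority <- match.arg(minority, c("A", "B"))
  if (!all(c("A", "B") %in% x$group))
    abort_validation("matrix must contain both labeled groups")
  if (!is.numeric(keep_fraction_minority) || keep_fraction_minority <= 0 ||
      keep_fraction_minority > 1)
    abort_validation("'keep_fraction_minority' must be in (0, 1]")
  if (keep_fraction_minority == 1) return(x)
  sids <- unique(x$sample_id[x$group == minority])
  n_keep <- floor(length(sids) * keep_fraction_minority)
  if (n_keep < 1)
    abort_validation(sprintf(
      "keep fraction %.3g would leave group %s empty",
      keep_fraction_minority, minority))
  keep_sids <- with_seed(substream_seed(seed, "imbalance"),
                         sample(sids, n_keep))
  keep <- x$group != minority | x$sample_id %in% keep_sids
  cm_rows(x, which(keep))
}
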