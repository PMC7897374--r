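#' Specification of a synthetic compressive-force curve population
#'
#' Emulates stress-test traces from a materials tester pushing a cutter bit
#' into a muscle slice at constant loading rate: a flat near-zero
#' pre-contact segment followed by an exponentially rising force
#' `y = a * exp(b * x)` in the distance domain, plus additive Gaussian
#' noise. The true `(a, b)` of every sample are recorded for recovery tests.
#'
#' @param n_per_group biological samples per group; single count or named
#'   vector `c(A = ..., B = ...)`.
#' @param groups named list (`"A"`, `"B"`) of coefficient distributions,
#'   each a list with `a_mean`, `a_sd` (force units, `a` truncated to > 0)
#'   and `b_mean`, `b_sd` (per mm).
#' @param replicates_per_sample stress tests per sample (default 5).
#' @param sampling_rate acquisition rate in Hz (default 10).
#' @param loading_rate crosshead speed in mm/min (default 2).
#' @param pre_contact_duration seconds of flat baseline before contact
#'   (default 5).
#' @param total_distance mm of travel after contact (default 5).
#' @param noise_sd force-noise standard deviation (default 0.02).
#' @param seed integer seed.
#' @return An object of class `force_population_spec`.
#' @export
force_population_spec <- function(n_per_group, groups,
                                  replicates_per_sample = 5,
                                  sampling_rate = 10,
                                  loading_rate = 2,
                                  pre_contact_duration = 5,
                                  total_distance = 5,
                                  noise_sd = 0.02,
                                  seed = 1) {
  if (!is.list(groups) || !setequal(names(groups), c("A", "B")))
    abort_validation("'groups' must be a named list with elements 'A' and 'B'")
  for (g in names(groups)) {
    d <- groups[[g]]
    if (!all(c("a_mean", "a_sd", "b_mean", "b_sd") %in% names(d)))
      abort_validation(sprintf(
        "group %s: need a_mean, a_sd, b_mean, b_sd", g))
    if (d$a_mean <= 0)
      abort_validation(sprintf("group %s: a_mean must be positive", g))
  }
  if (length(n_per_group) == 1) n_per_group <- c(A = n_per_group, B = n_per_group)
  if (loading_rate <= 0) abort_validation("'loading_rate' must be positive")
  stopifnot(sampling_rate > 0, pre_contact_duration >= 0, total_distance > 0,
            noise_sd >= 0, is_count(replicates_per_sample))
  structure(
    list(n_per_group = n_per_group[c("A", "B")], groups = groups,
         replicates_per_sample = as.integer(replicates_per_sample),
         sampling_rate = sampling_rate, loading_rate = loading_rate,
         pre_contact_duration = pre_contact_duration,
         total_distance = total_distance, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "force_population_spec"
  )
}

#' A single force-time trace
#'
#' @param time seconds, strictly increasing.
#' @param force force units (N).
#' @param loading_rate mm/min.
#' @param sample_id,replicate_id identifiers.
#' @return An object of class `force_curve`.
#' @export
force_curve <- function(time, force, loading_rate, sample_id = "s1",
                        replicate_id = "1") {
  if (length(time) != length(force))
    abort_validation("time and force must have equal length")
  if (any(diff(time) <= 0))
    abort_validation("time must be strictly increasing")
  if (loading_rate <= 0)
    abort_validation("'loading_rate' must be positive")
  structure(list(time = as.numeric(time), force = as.numeric(force),
                 loading_rate = loading_rate,
                 sample_id = as.character(sample_id),
                 replicate_id = as.character(replicate_id)),
            class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf("force_curve %s/%s: %d points, %.1f s, rate %.3g mm/min\n",
              x$sample_id, x$replicate_id, length(x$time),
              max(x$time), x$loading_rate))
  invisible(x)
}

#' Generate synthetic force curves
#'
#' @param spec a [force_population_spec].
#' @return A list with `curves` (list of [force_curve]) and `truth`
#'   (data.frame of sample_id, group and the true `a`, `b` per sample).
#' @export
generate_force_curves <- function(spec) {
  stopifnot(inherits(spec, "force_population_spec"))
  dt <- 1 / spec$sampling_rate
  post_dur <- spec$total_distance / (spec$loading_rate / 60)
  with_seed(substream_seed(spec$seed, "force"), {
    curves <- list(); truth <- list(); k <- 0
    for (g in c("A", "B")) {
      d <- spec$groups[[g]]
      for (s in seq_len(spec$n_per_group[[g]])) {
        a <- -1
        while (a <= 0) a <- stats::rnorm(1, d$a_mean, d$a_sd)
        b <- stats::rnorm(1, d$b_mean, d$b_sd)
        sid <- sprintf("%s%03d", g, s)
        truth[[length(truth) + 1]] <-
          data.frame(sample_id = sid, group = g, a = a, b = b)
        for (r in seq_len(spec$replicates_per_sample)) {
          k <- k + 1
          time <- seq(0, spec$pre_contact_duration + post_dur, by = dt)
          dist <- pmax(0, (time - spec$pre_contact_duration)) *
            spec$loading_rate / 60
          clean <- ifelse(time < spec$pre_contact_duration, 0,
                          a * exp(b * dist))
          force <- clean + stats::rnorm(length(time), 0, spec$noise_sd)
          curves[[k]] <- force_curve(time, force, spec$loading_rate,
                                     sid, as.character(r))
        }
      }
    }
    list(curves = curves, truth = do.call(rbind, truth))
  })
}
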