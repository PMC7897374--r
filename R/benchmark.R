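#' Canonical imbalanced synthetic benchmark population
#'
#' The reference conditions used throughout the package's tests and in the
#' acceptance script to exercise the framework the way it is meant to be
#' used: a 1:4 imbalanced two-group population of two-compartment decays
#' whose groups differ by a shift of amplitude between the short-T2
#' ("bound water") and long-T2 ("free water") compartments, with per-sample
#' biological variation of the compartment fractions on top of per-point
#' measurement noise. Long-T2 tail points decay into the noise floor, so
#' late variables are nearly uninformative — the premise of usage-rate
#' optimization.
#'
#' Defaults: 10 minority (A) and 40 majority (B) samples, 3 replicates each,
#' 64 points over 1.024 s, compartments at T2 = 0.045 s and 0.18 s with
#' fractions `0.5 +/- effect/2` (A short-heavy, B long-heavy), fraction
#' jitter sd 0.05, noise sd 0.02. The effect size of 0.10 places the
#' conventional classifier in the moderate-performance regime (AUC roughly
#' 0.8) where balanced matrixing has room to help the minority class.
#'
#' @param seed integer seed.
#' @param n_a,n_b samples in the minority (A) and majority (B) group.
#' @param effect between-group difference of the bound-water fraction.
#' @param fraction_jitter_sd per-sample biological variation of fractions.
#' @param noise_sd per-point measurement noise.
#' @param time_points,replicates_per_sample grid and replication.
#' @return A [decay_population_spec].
#' @export
benchmark_decay_spec <- function(seed = 1, n_a = 10, n_b = 40, effect = 0.10,
                                 fraction_jitter_sd = 0.05, noise_sd = 0.02,
                                 time_points = 64,
                                 replicates_per_sample = 3) {
  decay_population_spec(
    n_per_group = c(A = n_a, B = n_b),
    groups = list(
      A = list(fraction = c(0.5 + effect / 2, 0.5 - effect / 2),
               t2 = c(0.045, 0.18)),
      B = list(fraction = c(0.5 - effect / 2, 0.5 + effect / 2),
               t2 = c(0.045, 0.18))),
    time_points = time_points, acquisition_time = 1.024,
    replicates_per_sample = replicates_per_sample,
    noise_sd = noise_sd, fraction_jitter_sd = fraction_jitter_sd,
    seed = seed)
}

#' Canonical two-group force-curve population
#'
#' Hard (A) and tender (B) muscle archetypes for the compressive-force
#' pipeline: hard samples have both a larger contact-force coefficient `a`
#' and a steeper exponential rise `b`.
#'
#' @param seed integer seed.
#' @param n_per_group samples per group (default 12).
#' @param noise_sd force noise (default 0.02 N).
#' @return A [force_population_spec].
#' @export
benchmark_force_spec <- function(seed = 1, n_per_group = 12,
                                 noise_sd = 0.02) {
  force_population_spec(
    n_per_group = n_per_group,
    groups = list(
      A = list(a_mean = 2.0, a_sd = 0.25, b_mean = 0.60, b_sd = 0.05),
      B = list(a_mean = 1.0, a_sd = 0.15, b_mean = 0.35, b_sd = 0.05)),
    replicates_per_sample = 5, noise_sd = noise_sd, seed = seed)
}
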