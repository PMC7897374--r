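#' @keywords internal
"_PACKAGE"

# Validation errors carry a dedicated condition class so the command-line
# wrapper can map them to exit code 2 (vs 3 for runtime failures).
abort_validation <- function(msg, call. = FALSE) {
  cnd <- structure(
    class = c("relaxlearn_validation", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1) else NULL)
  )
  stop(cnd)
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

#' Derive a reproducible sub-stream seed
#'
#' All stochastic steps in the package (fold assignment, bootstrap draws,
#' backend fitting, noise generation) draw their seed from one master seed
#' through this helper, so that a whole pipeline run is exactly reproducible
#' while its components remain independently re-runnable. Mixing uses a
#' Lehmer-style multiplicative congruence modulo 2^31 - 1; the result always
#' fits a 32-bit R integer.
#'
#' @param seed master integer seed.
#' @param ... labels (strings) and/or integers naming the sub-stream, e.g.
#'   `substream_seed(1, "outer", repeat_idx, fold_idx)`.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, ...) {
  parts <- lapply(list(...), function(p) {
    if (is.character(p)) sum(utf8ToInt(p)) else as.integer(p)
  })
  s <- (as.double(seed) %% 2147483646) + 1
  for (p in parts) {
    for (pi in p) s <- (s * 48271 + abs(as.double(pi)) + 1) %% 2147483647
  }
  as.integer(s %% 2147483645 + 1)
}

# Run expr with a temporary RNG state seeded from `seed`.
with_seed <- function(seed, expr) {
  withr::with_seed(seed, expr)
}
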