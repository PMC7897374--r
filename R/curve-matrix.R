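#' Relaxation-curve matrix
#'
#' The central container of the package: a samples-by-time-points matrix of
#' T2 decay amplitudes on a uniform time grid, with per-row sample and
#' replicate identifiers and an optional binary group label ("A"/"B").
#' Replicate rows belonging to one biological sample share a `sample_id`;
#' cross-validation code uses that identifier to keep replicates together.
#'
#' @param values numeric matrix, one row per recorded curve, one column per
#'   time point. No missing values; at least 2 columns.
#' @param time numeric vector of acquisition times in seconds, one per
#'   column; strictly increasing and uniformly spaced (relative spacing
#'   deviation below 1e-6).
#' @param sample_id character/factor vector, one per row: the biological
#'   sample a curve belongs to.
#' @param replicate_id optional per-row replicate identifier (defaults to a
#'   running index within each sample).
#' @param group optional per-row class label in `{"A","B"}` (`NA` allowed
#'   for unlabeled rows); replicates of one sample must agree.
#' @return An object of class `curve_matrix`.
#' @export
curve_matrix <- function(values, time, sample_id, replicate_id = NULL,
                         group = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    abort_validation("'values' must be a numeric matrix")
  if (ncol(values) < 2)
    abort_validation("curve matrix needs at least 2 time points")
  if (anyNA(values))
    abort_validation("curve matrix must not contain missing amplitudes")
  if (length(time) != ncol(values))
    abort_validation("'time' length must equal the number of columns")
  validate_time_axis(time)
  sample_id <- as.character(sample_id)
  if (length(sample_id) != nrow(values))
    abort_validation("'sample_id' length must equal the number of rows")
  if (is.null(replicate_id)) {
    replicate_id <- stats::ave(seq_along(sample_id), sample_id,
                               FUN = seq_along)
  }
  replicate_id <- as.character(replicate_id)
  if (length(replicate_id) != nrow(values))
    abort_validation("'replicate_id' length must equal the number of rows")
  if (is.null(group)) {
    group <- rep(NA_character_, nrow(values))
  } else {
    group <- as.character(group)
    if (length(group) != nrow(values))
      abort_validation("'group' length must equal the number of rows")
    bad <- !is.na(group) & !group %in% c("A", "B")
    if (any(bad))
      abort_validation(sprintf("group labels must be 'A' or 'B' (found: %s)",
                               paste(unique(group[bad]), collapse = ", ")))
    per_sample <- tapply(group, sample_id, function(g) length(unique(g)))
    if (any(per_sample > 1))
      abort_validation("replicates of one sample carry conflicting group labels")
  }
  structure(
    list(values = unname(values), time = as.numeric(time),
         sample_id = sample_id, replicate_id = replicate_id, group = group),
    class = "curve_matrix"
  )
}

validate_time_axis <- function(time) {
  if (anyNA(time) || !is.numeric(time))
    abort_validation("time axis must be numeric with no missing values")
  dt <- diff(time)
  if (any(dt <= 0))
    abort_validation("time axis not increasing")
  if (max(abs(dt - mean(dt))) / mean(dt) >= 1e-6)
    abort_validation("time axis must be uniformly spaced")
  invisible(time)
}

#' @export
dim.curve_matrix <- function(x) dim(x$values)

#' @export
print.curve_matrix <- function(x, ...) {
  g <- table(factor(x$group, levels = c("A", "B")), useNA = "ifany")
  cat(sprintf("curve_matrix: %d curves x %d time points (%.4g-%.4g s)\n",
              nrow(x$values), ncol(x$values), x$time[1],
              x$time[length(x$time)]))
  cat(sprintf("  samples: %d   group A: %d rows, group B: %d rows, unlabeled: %d\n",
              length(unique(x$sample_id)), g[["A"]], g[["B"]],
              sum(is.na(x$group))))
  invisible(x)
}

# Row subset preserving metadata.
cm_rows <- function(x, i) {
  curve_matrix(x$values[i, , drop = FALSE], x$time, x$sample_id[i],
               x$replicate_id[i], x$group[i])
}

#' Write a curve matrix as delimited text
#'
#' Layout: columns `sample_id`, `replicate_id`, `group`, then one column per
#' time point whose header is the acquisition time in seconds. Amplitudes are
#' written with 17 significant digits so that write/read round-trips are
#' value-exact.
#'
#' @param x a [curve_matrix].
#' @param path output file.
#' @param sep field separator, `","` (default) or `"\t"`.
#' @export
write_curve_matrix <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "curve_matrix"))
  num <- function(v) formatC(v, digits = 17, format = "g", width = -1)
  header <- c("sample_id", "replicate_id", "group", num(x$time))
  body <- vapply(seq_len(nrow(x$values)), function(i) {
    paste(c(x$sample_id[i], x$replicate_id[i],
            ifelse(is.na(x$group[i]), "", x$group[i]),
            num(x$values[i, ])), collapse = sep)
  }, character(1))
  writeLines(c(paste(header, collapse = sep), body), path)
  invisible(path)
}

#' Read a curve matrix from delimited text
#'
#' Expects the layout written by [write_curve_matrix()]. Rows containing
#' non-numeric amplitudes are rejected with an error naming the row.
#'
#' @param path input file.
#' @param sep field separator (default `","`).
#' @return A [curve_matrix].
#' @export
read_curve_matrix <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  need <- c("sample_id", "replicate_id", "group")
  if (!all(need %in% names(df)[1:3]))
    abort_validation("expected leading columns sample_id, replicate_id, group")
  time <- suppressWarnings(as.numeric(names(df)[-(1:3)]))
  if (anyNA(time))
    abort_validation("non-numeric time values in header")
  if (any(diff(time) <= 0))
    abort_validation("time axis not increasing")
  amp_chr <- as.matrix(df[, -(1:3), drop = FALSE])
  amp <- suppressWarnings(matrix(as.numeric(amp_chr), nrow = nrow(df)))
  if (anyNA(amp)) {
    bad <- which(apply(amp, 1, anyNA))
    abort_validation(sprintf("non-numeric amplitude in data row(s): %s",
                             paste(bad, collapse = ", ")))
  }
  grp <- df$group
  grp[grp == ""] <- NA_character_
  curve_matrix(amp, time, df$sample_id, df$replicate_id, grp)
}

# Column scaling statistics used both by the public normalizer and by the
# train-only normalization inside cross-validation.
uv_stats <- function(values, mode = c("per_variable", "per_curve"),
                     center = FALSE) {
  mode <- match.arg(mode)
  if (mode == "per_variable") {
    sds <- apply(values, 2, stats::sd)
    if (any(sds == 0)) {
      abort_validation(sprintf("zero-variance column(s): %s",
                               paste(which(sds == 0), collapse = ", ")))
    }
    list(mode = mode, center = center,
         means = if (center) colMeans(values) else NULL, sds = sds)
  } else {
    list(mode = mode, center = center)
  }
}

uv_apply <- function(values, stats) {
  if (stats$mode == "per_variable") {
    if (isTRUE(stats$center))
      values <- sweep(values, 2, stats$means, "-")
    sweep(values, 2, stats$sds, "/")
  } else {
    sds <- apply(values, 1, stats::sd)
    if (any(sds == 0))
      abort_validation(sprintf("zero-variance row(s): %s",
                               paste(which(sds == 0), collapse = ", ")))
    sweep(values, 1, sds, "/")
  }
}

#' Unit-variance normalization of a curve matrix
#'
#' Chemometric UV scaling of the raw decay amplitudes. The default
#' (`per_variable`) scales every time-point column to standard deviation 1
#' without centering, so the non-negative decay shape is preserved;
#' `per_curve` instead divides each curve by its own standard deviation.
#' Inside cross-validation the scaling statistics are always computed on the
#' training portion only (see [double_cv()]).
#'
#' @param x a [curve_matrix].
#' @param mode `"per_variable"` (default) or `"per_curve"`.
#' @param center logical; subtract column means first (per_variable mode
#'   only). Default `FALSE`.
#' @return A normalized [curve_matrix].
#' @export
normalize_unit_variance <- function(x, mode = c("per_variable", "per_curve"),
                                    center = FALSE) {
  stopifnot(inherits(x, "curve_matrix"))
  mode <- match.arg(mode)
  st <- uv_stats(x$values, mode, center)
  out <- x
  out$values <- uv_apply(x$values, st)
  out
}

#' Truncate a curve matrix to its earliest time points
#'
#' Variable-optimization primitive: retains the first
#' `floor(P * usage_rate)` columns of a P-column matrix — the shortest
#' relaxation-time components — and drops the late, long-T2 portion of the
#' curve. The floor convention reproduces the canonical column counts of a
#' 256-point acquisition: 230 variables at 90 % usage and 25 at 10 %.
#'
#' @param x a [curve_matrix].
#' @param usage_rate fraction of variables to keep, in `(0, 1]`.
#' @return A [curve_matrix] with the truncated value matrix and time axis.
#' @export
truncate_variables <- function(x, usage_rate) {
  stopifnot(inherits(x, "curve_matrix"))
  if (!is.numeric(usage_rate) || length(usage_rate) != 1 ||
      is.na(usage_rate) || usage_rate <= 0 || usage_rate > 1)
    abort_validation("'usage_rate' must be a single number in (0, 1]")
  p <- n_retained_variables(ncol(x$values), usage_rate)
  if (p < 2)
    abort_validation(sprintf(
      "usage rate %.3g retains %d column(s); at least 2 required",
      usage_rate, p))
  if (p == ncol(x$values)) return(x)
  curve_matrix(x$values[, seq_len(p), drop = FALSE], x$time[seq_len(p)],
               x$sample_id, x$replicate_id, x$group)
}

#' Number of variables retained at a usage rate
#'
#' @param p total number of variables (columns).
#' @param usage_rate fraction in `(0, 1]`.
#' @return `floor(p * usage_rate)` as an integer.
#' @export
n_retained_variables <- function(p, usage_rate) {
  as.integer(floor(p * usage_rate + 1e-9))
}
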