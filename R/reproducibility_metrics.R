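# Between-replicate reproducibility metrics: empirical CDFs, one-sample
# Kolmogorov-Smirnov statistics against a pooled reference, 1-D Wasserstein
# distance, and the mean absolute vertical ECDF gap. The KS D, Wasserstein
# and ECDF-gap computations are exact (evaluated at step breakpoints), not
# grid approximations.

#' Empirical cumulative distribution function
#'
#' Thin wrapper over [stats::ecdf()]: the right-continuous step function with
#' height k/n at the k-th order statistic.
#'
#' @param values At least one numeric value.
#' @return A `stats::ecdf` function (query its jump points with
#'   [stats::knots()]).
#' @export
ecdf_step <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("ecdf needs at least one value", call. = FALSE)
  stats::ecdf(values)
}

# number of elements of sorted vector `sx` strictly less than / at most q
.count_le <- function(sx, q) findInterval(q, sx)
.count_lt <- function(sx, q) findInterval(q, sx, left.open = TRUE)

#' One-sample Kolmogorov-Smirnov statistic against a step reference
#'
#' Computes the exact supremum vertical distance D between the sample's ECDF
#' and a reference distribution function, evaluating both one-sided gaps
#' (the function value and the left limit) at every jump point of either
#' function, so the statistic is exact for step references such as the ECDF
#' of pooled experimental replicates. The p-value uses the asymptotic
#' Kolmogorov distribution at the sample size
#' \eqn{p = 2\sum_{k\ge 1} (-1)^{k-1} e^{-2 k^2 n D^2}}, appropriate for the
#' sample sizes in routine use (n of order 30+).
#'
#' @param sample Numeric vector (an individual experimental replicate).
#' @param reference A `stats::ecdf` function or the numeric vector to build
#'   one from (e.g. all replicates pooled; the pooled reference conventionally
#'   includes the evaluated replicate's own observations).
#' @return A `ks_result` list: `d_statistic`, `p_value`, `n`.
#' @export
ks_one_sample <- function(sample, reference) {
  sample <- sample[!is.na(sample)]
  if (length(sample) < 1) stop("sample must be non-empty", call. = FALSE)
  if (!inherits(reference, "ecdf")) reference <- ecdf_step(reference)

  sx <- sort(sample)
  n <- length(sx)
  rx <- sort(stats::knots(reference))
  pts <- sort(unique(c(sx, rx)))
  gs_right <- .count_le(sx, pts) / n
  gs_left <- .count_lt(sx, pts) / n
  f_right <- reference(pts)
  # left limit of the step reference: its value at the largest knot below
  idx <- .count_lt(rx, pts)
  f_left <- c(0, reference(rx))[idx + 1]
  d <- max(abs(gs_right - f_right), abs(gs_left - f_left))

  p <- .kolmogorov_p(sqrt(n) * d)
  structure(list(d_statistic = d, p_value = p, n = n), class = "ks_result")
}

.kolmogorov_p <- function(t) {
  if (t < 1e-8) {
    return(1)
  }
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))
  min(1, max(0, p))
}

#' Exact 1-D Wasserstein distance
#'
#' The earth mover's distance between two empirical distributions,
#' \eqn{W_1 = \int |F_a(x) - F_b(x)|\,dx}, computed exactly by summing the
#' ECDF gap over the intervals between consecutive breakpoints of either
#' sample. Equivariant under common translation of both samples.
#'
#' @param a,b Non-empty numeric vectors (in readout units).
#' @return The distance, in the same units as the inputs.
#' @export
wasserstein_1d <- function(a, b) {
  a <- sort(a[!is.na(a)])
  b <- sort(b[!is.na(b)])
  if (length(a) == 0 || length(b) == 0) stop("inputs must be non-empty", call. = FALSE)
  pts <- sort(unique(c(a, b)))
  if (length(pts) == 1) {
    return(0)
  }
  fa <- findInterval(pts, a) / length(a)
  fb <- findInterval(pts, b) / length(b)
  m <- length(pts)
  sum(abs(fa[-m] - fb[-m]) * diff(pts))
}

#' Mean absolute vertical ECDF gap
#'
#' The mean of \eqn{|F_a(x) - F_b(x)|} over an evaluation grid: by default
#' the union of both samples' jump points (each distinct point counted
#' once); alternatively a uniform grid of `k` points spanning the pooled
#' range. Symmetric in its arguments and, like the KS statistic, invariant
#' under any strictly increasing transform applied to both inputs (for the
#' union grid).
#'
#' @param a,b Non-empty numeric vectors.
#' @param grid `"union"` (default) or `"uniform"`.
#' @param k Grid size for `grid = "uniform"`.
#' @return A value in `[0, 1]`.
#' @export
mean_ecdf_difference <- function(a, b, grid = c("union", "uniform"), k = 512) {
  grid <- match.arg(grid)
  a <- sort(a[!is.na(a)])
  b <- sort(b[!is.na(b)])
  if (length(a) == 0 || length(b) == 0) stop("inputs must be non-empty", call. = FALSE)
  pts <- switch(grid,
    union = sort(unique(c(a, b))),
    uniform = seq(min(a[1], b[1]), max(a[length(a)], b[length(b)]), length.out = k)
  )
  fa <- findInterval(pts, a) / length(a)
  fb <- findInterval(pts, b) / length(b)
  mean(abs(fa - fb))
}

#' Per-replicate reproducibility against the pooled reference
#'
#' Splits a table's readout by a grouping column (typically `batch_id`, one
#' group per experimental replicate), pools all groups into the reference
#' distribution, and reports each replicate's one-sample KS statistic and
#' p-value plus its Wasserstein distance and mean ECDF gap versus the pooled
#' data.
#'
#' @param table An `assay_table`.
#' @param group_by Grouping column name (default `"batch_id"`).
#' @param readout Per-disk readout (see [summarize_scheme()]).
#' @param condition_id Optional condition filter.
#' @param leave_one_out If `FALSE` (default, the conventional choice) the
#'   pooled reference includes the evaluated replicate's own observations;
#'   `TRUE` excludes them.
#' @return A tibble with one row per replicate: `replicate`, `n`,
#'   `d_statistic`, `p_value`, `wasserstein`, `mean_ecdf_diff`.
#' @export
replicate_reproducibility <- function(table, group_by = "batch_id",
                                      readout = "green", condition_id = NULL,
                                      leave_one_out = FALSE) {
  readout <- match.arg(readout, .readouts)
  df <- tibble::as_tibble(as.data.frame(table))
  if (!is.null(condition_id)) df <- df[df$condition_id %in% condition_id, , drop = FALSE]
  if (!group_by %in% names(df)) stop("grouping column not present: ", group_by, call. = FALSE)
  vals <- .readout_values(df$green, df$red, readout)
  keep <- !is.na(vals)
  groups <- split(vals[keep], as.character(df[[group_by]])[keep])
  pooled <- unlist(groups, use.names = FALSE)
  rows <- lapply(names(groups), function(g) {
    x <- groups[[g]]
    ref_vals <- if (leave_one_out) {
      unlist(groups[setdiff(names(groups), g)], use.names = FALSE)
    } else {
      pooled
    }
    ks <- ks_one_sample(x, ecdf_step(ref_vals))
    tibble::tibble(
      replicate = g, n = length(x),
      d_statistic = ks$d_statistic, p_value = ks$p_value,
      wasserstein = wasserstein_1d(x, ref_vals),
      mean_ecdf_diff = mean_ecdf_difference(x, ref_vals)
    )
  })
  dplyr::bind_rows(rows)
}
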