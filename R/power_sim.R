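# Monte Carlo power-analysis engine. Variability propagates the way it does
# in a real assay: an experiment-level (batch) CV is drawn from an empirical
# distribution of batch CVs, plant CVs scatter around it, and each plant
# contributes the mean of 8 simulated leaf disks. Two conditions are compared
# with a two-tailed Student's (pooled-variance) t-test; power is the fraction
# of simulated replicate experiments reaching significance.

#' Per-plant coefficients of variation
#'
#' One CV per plant, computed over all of the plant's disks regardless of
#' leaf. Plants with fewer than two usable disks or zero mean are dropped.
#'
#' @param table An `assay_table`.
#' @param channel `"green"` or `"red"`.
#' @return A tibble: `batch_id`, `condition_id`, `plant_id`, `n_disks`, `cv`.
#' @export
per_plant_cvs <- function(table, channel = "green") {
  stopifnot(channel %in% c("green", "red"))
  g <- per_plant_groups(table)
  vals <- lapply(g[[channel]], function(x) x[!is.na(x)])
  cv <- vapply(vals, function(x) {
    if (length(x) < 2 || mean(x) == 0) NA_real_ else sd(x) / mean(x)
  }, numeric(1))
  out <- tibble::tibble(
    batch_id = g$batch_id, condition_id = g$condition_id,
    plant_id = g$plant_id,
    n_disks = vapply(vals, length, integer(1)), cv = cv
  )
  out[!is.na(out$cv), , drop = FALSE]
}

#' Construct a batch-CV distribution
#'
#' @param batch_cv_values Non-empty vector of batch-level CVs (stored
#'   sorted).
#' @param plant_dispersion SD of plant CVs around their batch CV.
#' @param plant_cv_values Optional vector of the raw per-plant CVs behind
#'   the batch summaries; required only for the direct plant-sampling
#'   variant of the power engine.
#' @param source Provenance list (strain, thresholds, ...).
#' @return A `cv_distribution`.
#' @export
cv_distribution <- function(batch_cv_values, plant_dispersion = 0,
                            plant_cv_values = NULL, source = list()) {
  batch_cv_values <- sort(batch_cv_values[!is.na(batch_cv_values)])
  if (length(batch_cv_values) == 0) {
    stop("batch_cv_values must be non-empty", call. = FALSE)
  }
  stopifnot(all(batch_cv_values >= 0), plant_dispersion >= 0)
  if (!is.null(plant_cv_values)) {
    plant_cv_values <- sort(plant_cv_values[!is.na(plant_cv_values)])
    stopifnot(all(plant_cv_values >= 0))
  }
  structure(list(
    batch_cv_values = batch_cv_values,
    plant_dispersion = plant_dispersion,
    plant_cv_values = plant_cv_values,
    source = source
  ), class = "cv_distribution")
}

#' @export
print.cv_distribution <- function(x, ...) {
  cat(sprintf(
    "<cv_distribution> %d batch CVs in [%.3f, %.3f], median %.3f | plant dispersion %.3f\n",
    length(x$batch_cv_values), min(x$batch_cv_values), max(x$batch_cv_values),
    stats::median(x$batch_cv_values), x$plant_dispersion
  ))
  invisible(x)
}

#' Build the empirical batch-CV distribution from assay data
#'
#' Per-plant CVs are computed over all disks of each plant; batches with
#' fewer than `min_plants` plants are dropped; the distribution's support is
#' the per-batch mean plant CV, and the plant dispersion is the pooled SD of
#' plant CVs about their batch mean.
#'
#' @param table An `assay_table` (e.g. a longitudinal compilation of
#'   unnormalized reporter experiments).
#' @param strain Optional strain filter (e.g. `"GV3101"` or `"EHA105"`).
#' @param min_plants Minimum plants per qualifying batch (default 30).
#' @param channel Fluorescence channel.
#' @return A `cv_distribution`.
#' @export
build_cv_distribution <- function(table, strain = NULL, min_plants = 30,
                                  channel = "green") {
  df <- tibble::as_tibble(as.data.frame(table))
  if (!is.null(strain)) df <- df[df$strain %in% strain, , drop = FALSE]
  if (nrow(df) == 0) stop("no records after strain filter", call. = FALSE)
  cvs <- per_plant_cvs(.assay_rewrap(df, table), channel)
  counts <- table(cvs$batch_id)
  keep <- names(counts)[counts >= min_plants]
  if (length(keep) == 0) {
    stop("no batch has at least ", min_plants, " plants", call. = FALSE)
  }
  cvs <- cvs[cvs$batch_id %in% keep, , drop = FALSE]
  bm <- tapply(cvs$cv, cvs$batch_id, mean)
  resid <- cvs$cv - bm[cvs$batch_id]
  n <- nrow(cvs)
  b <- length(bm)
  dispersion <- if (n > b) sqrt(sum(resid^2) / (n - b)) else 0
  cv_distribution(
    as.numeric(bm), dispersion,
    plant_cv_values = cvs$cv,
    source = list(strain = strain, min_plants = min_plants, channel = channel)
  )
}

#' Draw batch CVs from the empirical distribution
#'
#' A uniform percentile is generated and mapped through the empirical
#' quantile function with linear interpolation between order statistics
#' (quantile type 7), so `u = 0` and `u = 1` return the minimum and maximum
#' observed batch CV.
#'
#' @param dist A `cv_distribution`.
#' @param n Number of draws.
#' @return Numeric vector of batch CVs.
#' @export
sample_batch_cv <- function(dist, n = 1) {
  stopifnot(inherits(dist, "cv_distribution"))
  u <- runif(n)
  quantile(dist$batch_cv_values, probs = u, type = 7, names = FALSE)
}

#' Draw plant CVs around a batch CV
#'
#' Plant CVs are Normal(`batch_cv`, `dispersion`^2), truncated at zero by
#' resampling (so no negative CV is ever returned and, at realistic values,
#' the mean of the draws converges to `batch_cv`).
#'
#' @param batch_cv Nonnegative batch-level CV.
#' @param n_plants Number of plants.
#' @param dispersion SD of the plant-level noise.
#' @return Numeric vector of length `n_plants`.
#' @export
sample_plant_cvs <- function(batch_cv, n_plants, dispersion) {
  stopifnot(batch_cv >= 0, dispersion >= 0)
  x <- rnorm(n_plants, batch_cv, dispersion)
  bad <- x < 0
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), batch_cv, dispersion)
    bad <- x < 0
  }
  x
}

# reps x n matrix of truncated-normal plant CVs; row r uses batch_cv[r]
.plant_cv_matrix <- function(batch_cv, n, dispersion) {
  reps <- length(batch_cv)
  x <- matrix(rnorm(reps * n, mean = batch_cv, sd = dispersion), nrow = reps)
  bad <- x < 0
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean = rep(batch_cv, n)[bad], sd = dispersion)
    bad <- x < 0
  }
  x
}

# Vectorized Monte Carlo engine: returns n_reps two-tailed p-values.
# plant_sampling = "batch_noise" draws a batch-average CV and layers plant
# noise (the default variability model); "direct" draws every plant's CV
# independently from the stored empirical plant-CV values.
.power_engine <- function(n_plants, effect_pct, dist, n_reps,
                          mean_expression, disks_per_plant,
                          unit = c("plant", "disk"),
                          shared_batch = TRUE,
                          plant_sampling = c("batch_noise", "direct")) {
  unit <- match.arg(unit)
  plant_sampling <- match.arg(plant_sampling)
  mA <- mean_expression
  mB <- mean_expression * (1 + effect_pct / 100)
  if (plant_sampling == "direct") {
    if (is.null(dist$plant_cv_values)) {
      stop("direct plant sampling needs plant_cv_values in the distribution",
        call. = FALSE
      )
    }
    draw <- function() {
      matrix(
        quantile(dist$plant_cv_values, runif(n_reps * n_plants),
          type = 7, names = FALSE
        ),
        nrow = n_reps
      )
    }
    cvA <- draw()
    cvB <- draw()
  } else {
    if (shared_batch) {
      bcvA <- bcvB <- sample_batch_cv(dist, n_reps)
    } else {
      bcvA <- sample_batch_cv(dist, n_reps)
      bcvB <- sample_batch_cv(dist, n_reps)
    }
    cvA <- .plant_cv_matrix(bcvA, n_plants, dist$plant_dispersion)
    cvB <- .plant_cv_matrix(bcvB, n_plants, dist$plant_dispersion)
  }

  d <- disks_per_plant
  disks <- function(cv, m) {
    # one row per (rep, plant), d disk values each
    eps <- matrix(rnorm(length(cv) * d), ncol = d)
    m + as.vector(cv) * m * eps
  }
  dA <- disks(cvA, mA)
  dB <- disks(cvB, mB)

  if (unit == "plant") {
    xA <- matrix(rowMeans(dA), nrow = n_reps)
    xB <- matrix(rowMeans(dB), nrow = n_reps)
    k <- n_plants
  } else {
    xA <- matrix(as.vector(dA), nrow = n_reps)
    xB <- matrix(as.vector(dB), nrow = n_reps)
    k <- n_plants * d
  }
  mAh <- rowMeans(xA)
  mBh <- rowMeans(xB)
  ssA <- rowSums((xA - mAh)^2)
  ssB <- rowSums((xB - mBh)^2)
  df_t <- 2 * k - 2
  sp2 <- (ssA + ssB) / df_t
  tstat <- (mAh - mBh) / sqrt(sp2 * 2 / k)
  2 * pt(-abs(tstat), df_t)
}

#' Simulate one two-condition experiment
#'
#' One experimental replicate: a shared batch CV is drawn (both conditions of
#' a real experiment share a batch), `n_plants` plant CVs per condition
#' scatter around it, each plant contributes `disks_per_plant` disk values
#' Normal(condition mean, (plant CV x condition mean)^2), and the two
#' conditions are compared by a two-tailed pooled-variance Student's t-test
#' on the per-plant means (set `unit = "disk"` to test on disks instead).
#' Uses the current RNG state.
#'
#' @param n_plants Plants per condition (>= 2).
#' @param effect_pct Percent difference of condition means,
#'   `100 * (mu_B / mu_A - 1)`.
#' @param dist A `cv_distribution`.
#' @param mean_expression Construct-specific mean expression (a.u.).
#' @param disks_per_plant Disks per simulated plant (default 8).
#' @param unit Experimental unit for the t-test: `"plant"` (default) or
#'   `"disk"`.
#' @param shared_batch Share one batch CV between the two conditions
#'   (default `TRUE`); set `FALSE` for independent batch draws.
#' @param plant_sampling `"batch_noise"` (default: batch-average CV plus
#'   plant-level noise) or `"direct"` (plant CVs drawn straight from the
#'   stored empirical per-plant values, no batch structure).
#' @return The two-tailed p-value.
#' @export
simulate_experiment <- function(n_plants, effect_pct, dist,
                                mean_expression = 10000, disks_per_plant = 8,
                                unit = "plant", shared_batch = TRUE,
                                plant_sampling = "batch_noise") {
  stopifnot(n_plants >= 2)
  .power_engine(
    n_plants, effect_pct, dist, 1L, mean_expression,
    disks_per_plant, unit, shared_batch, plant_sampling
  )[1]
}

#' Estimate power by Monte Carlo
#'
#' Simulates `n_reps` independent experimental replicates and reports the
#' fraction reaching `p < alpha`. Seeded and reproducible.
#'
#' @inheritParams simulate_experiment
#' @param n_reps Number of simulated replicates (default 1000).
#' @param alpha Significance level (default 0.05).
#' @param seed Optional seed applied before simulation.
#' @return A `power_point` list: `effect_pct`, `n_plants`, `power`,
#'   `n_reps`, `alpha`.
#' @export
estimate_power <- function(n_plants, effect_pct, dist, n_reps = 1000,
                           alpha = 0.05, seed = NULL,
                           mean_expression = 10000, disks_per_plant = 8,
                           unit = "plant", shared_batch = TRUE,
                           plant_sampling = "batch_noise") {
  stopifnot(n_plants >= 2, n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- .power_engine(
    n_plants, effect_pct, dist, n_reps, mean_expression,
    disks_per_plant, unit, shared_batch, plant_sampling
  )
  structure(list(
    effect_pct = effect_pct, n_plants = n_plants,
    power = mean(p < alpha), n_reps = n_reps, alpha = alpha
  ), class = "power_point")
}

#' Minimum number of plants for a target power
#'
#' Incremental search from `n = 2` upward for the smallest per-condition
#' plant count whose estimated power reaches `power_target`. Each `n` uses a
#' fixed seed derived from the master seed, so the bracketing property
#' (power at the returned `n` is >= target, at `n - 1` it was below) holds
#' under re-evaluation.
#'
#' @inheritParams estimate_power
#' @param power_target Required fraction of significant replicates
#'   (default 0.95).
#' @param n_cap Largest plant count to try (default 50).
#' @param seed Master seed for the per-`n` seed schedule.
#' @return A list: `n_min` (or `NA` when the cap is exceeded), `power` at
#'   `n_min`, `capped`, and the searched `powers` (tibble of `n`, `power`).
#' @export
find_min_n <- function(effect_pct, dist, power_target = 0.95, n_cap = 50,
                       n_reps = 1000, alpha = 0.05, seed = 1,
                       mean_expression = 10000, disks_per_plant = 8,
                       unit = "plant", shared_batch = TRUE,
                       plant_sampling = "batch_noise") {
  stopifnot(effect_pct > 0, n_cap >= 2)
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_cap)
  ns <- integer(0)
  pows <- numeric(0)
  for (n in 2:n_cap) {
    pp <- estimate_power(n, effect_pct, dist,
      n_reps = n_reps, alpha = alpha,
      seed = seeds[n], mean_expression = mean_expression,
      disks_per_plant = disks_per_plant, unit = unit,
      shared_batch = shared_batch, plant_sampling = plant_sampling
    )
    ns <- c(ns, n)
    pows <- c(pows, pp$power)
    if (pp$power >= power_target) {
      return(list(
        n_min = n, power = pp$power, capped = FALSE,
        powers = tibble::tibble(n = ns, power = pows)
      ))
    }
  }
  list(
    n_min = NA_integer_, power = pows[length(pows)], capped = TRUE,
    powers = tibble::tibble(n = ns, power = pows)
  )
}

#' Fit an exponential decay curve to (effect size, minimum n) points
#'
#' Least-squares fit of `n_min = a * exp(-b * effect) + c` with `a, c >= 0`
#' and `b > 0` (so the fitted curve is nonincreasing), via
#' [minpack.lm::nlsLM()] from a log-linear starting point.
#'
#' @param points A data frame with columns `effect_pct` and `n_min`
#'   (at least 4 points).
#' @return A `power_curve_fit` list: `a`, `b`, `c`, `rss`, `fitted`
#'   (function of effect), and the input points.
#' @seealso [min_detectable_effect()]
#' @export
fit_power_curve <- function(points) {
  points <- tibble::as_tibble(points)
  stopifnot(all(c("effect_pct", "n_min") %in% names(points)))
  points <- points[is.finite(points$n_min), , drop = FALSE]
  if (nrow(points) < 4) stop("need at least 4 (effect, n_min) points", call. = FALSE)
  e <- points$effect_pct
  n <- points$n_min

  c0 <- max(0, min(n) * 0.9)
  r <- pmax(n - c0, 1e-6)
  lf <- stats::lm(log(r) ~ e)
  b0 <- max(1e-6, -coef(lf)[2])
  a0 <- max(1e-6, exp(coef(lf)[1]))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      n ~ a * exp(-b * e) + c,
      start = list(a = a0, b = b0, c = c0),
      lower = c(0, 1e-9, 0),
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14, ptol = 1e-14)
    ),
    error = function(err) {
      stop("exponential power-curve fit failed to converge: ",
        conditionMessage(err),
        call. = FALSE
      )
    }
  )
  cf <- coef(fit)
  structure(list(
    a = unname(cf["a"]), b = unname(cf["b"]), c = unname(cf["c"]),
    rss = sum(stats::resid(fit)^2),
    fitted = function(effect) cf["a"] * exp(-cf["b"] * effect) + cf["c"],
    points = points
  ), class = "power_curve_fit")
}

#' @export
print.power_curve_fit <- function(x, ...) {
  cat(sprintf(
    "n_min(effect) = %.4g * exp(-%.4g * effect) + %.4g   (rss %.4g, %d points)\n",
    x$a, x$b, x$c, x$rss, nrow(x$points)
  ))
  invisible(x)
}

#' Smallest detectable effect at a plant budget
#'
#' Inverts the fitted exponential decay: for a plant budget `n` (with
#' `c < n <= a + c`), the smallest effect size whose minimum plant
#' requirement is `n` is `-log((n - c) / a) / b`.
#'
#' @param fit A `power_curve_fit`.
#' @param n Plant budget.
#' @return Effect size in percent.
#' @export
min_detectable_effect <- function(fit, n) {
  stopifnot(inherits(fit, "power_curve_fit"))
  if (any(n <= fit$c)) {
    stop("plant budget must exceed the fitted asymptote c = ", signif(fit$c, 4),
      call. = FALSE
    )
  }
  -log((n - fit$c) / fit$a) / fit$b
}

#' Simulate per-plant CVs from a batch-CV distribution
#'
#' Drives the sampling engine alone (no fluorescence generation): per batch a
#' batch CV is drawn, then plant CVs around it. Used to validate the
#' simulator against the empirical plant-CV distribution it was trained on.
#'
#' @param dist A `cv_distribution`.
#' @param n_batches Number of simulated batches.
#' @param plants_per_batch Plants per simulated batch.
#' @param seed Optional seed.
#' @return Numeric vector of simulated plant CVs.
#' @export
simulate_plant_cvs <- function(dist, n_batches, plants_per_batch, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bcv <- sample_batch_cv(dist, n_batches)
  as.vector(vapply(
    bcv, sample_plant_cvs,
    numeric(plants_per_batch),
    n_plants = plants_per_batch, dispersion = dist$plant_dispersion
  ))
}

#' Compare simulated and empirical plant-CV distributions
#'
#' Reports the exact 1-D Wasserstein distance and the mean absolute ECDF gap
#' between the two samples of plant CVs.
#'
#' @param simulated_plant_cvs,empirical_plant_cvs Non-empty numeric vectors.
#' @return A list: `wasserstein`, `mean_ecdf_difference`.
#' @export
validate_simulator <- function(simulated_plant_cvs, empirical_plant_cvs) {
  list(
    wasserstein = wasserstein_1d(simulated_plant_cvs, empirical_plant_cvs),
    mean_ecdf_difference = mean_ecdf_difference(
      simulated_plant_cvs,
      empirical_plant_cvs
    )
  )
}

#' Write / read a CV distribution as delimited text
#'
#' One batch CV per row in a `batch_cv` column; the plant dispersion and
#' source fields ride in `#`-prefixed header records.
#'
#' @param dist A `cv_distribution`.
#' @param path File path.
#' @return `write_cv_distribution()` returns `path` invisibly;
#'   `read_cv_distribution()` returns a `cv_distribution`.
#' @export
write_cv_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "cv_distribution"))
  header <- sprintf("# plant_dispersion: %.17g", dist$plant_dispersion)
  writeLines(
    c(header, "batch_cv", sprintf("%.17g", dist$batch_cv_values)),
    path
  )
  invisible(path)
}

#' @rdname write_cv_distribution
#' @export
read_cv_distribution <- function(path) {
  lines <- readLines(path)
  disp_line <- grep("^# plant_dispersion:", lines, value = TRUE)
  disp <- if (length(disp_line)) as.numeric(sub("^# plant_dispersion:", "", disp_line[1])) else 0
  body <- lines[!startsWith(lines, "#")]
  vals <- suppressWarnings(as.numeric(body))
  cv_distribution(vals[!is.na(vals)], disp, source = list(path = path))
}
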