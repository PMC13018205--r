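test_that("per-plant CVs pool both leaves' disks", {
  tab <- as_assay_table(make_plants_df(list(c(1, 3), c(2, 6), c(5, 5))))
  cvs <- per_plant_cvs(tab)
  expect_equal(cvs$cv, c(sqrt(2) / 2, sqrt(2) / 2, 0), tolerance = 1e-6)
})

test_that("batch-CV distribution is built from qualifying batches only", {
  # plants with two disks at mean m and spread chosen for an exact CV
  plant_pair <- function(m, cv) c(m * (1 - cv / sqrt(2)), m * (1 + cv / sqrt(2)))
  batch_of <- function(n, cv, batch_id) {
    make_plants_df(replicate(n, plant_pair(1000, cv), simplify = FALSE),
      batch_id = batch_id
    )
  }
  df <- dplyr::bind_rows(
    batch_of(30, 0.1, "2022.01.03"),
    batch_of(30, 0.3, "2022.01.10"),
    batch_of(29, 0.8, "2022.01.17") # below the plant threshold
  )
  dist <- build_cv_distribution(as_assay_table(df), min_plants = 30)
  expect_equal(dist$batch_cv_values, c(0.1, 0.3), tolerance = 1e-9)
  expect_equal(dist$plant_dispersion, 0, tolerance = 1e-9)

  expect_error(
    build_cv_distribution(as_assay_table(df), min_plants = 31),
    "at least 31"
  )
})

test_that("batch-CV sampling follows the empirical quantile function", {
  single <- cv_distribution(0.25)
  expect_equal(sample_batch_cv(single, 5), rep(0.25, 5))

  vals <- c(0.1, 0.2, 0.35, 0.5)
  dist <- cv_distribution(vals)
  set.seed(61)
  draws4 <- sample_batch_cv(dist, 1e4)
  # quantile bounds: u = 0 / u = 1 map to the extremes, never beyond
  expect_true(all(draws4 >= 0.1 & draws4 <= 0.5))

  # with a rich support the interpolation is negligible and 1e5 draws land
  # within Kolmogorov distance 0.01 of the source ECDF
  set.seed(610)
  src <- sort(runif(2000, 0.05, 0.6))
  big <- cv_distribution(src)
  draws <- sample_batch_cv(big, 1e5)
  expect_lt(ks_one_sample(draws, ecdf_step(src))$d_statistic, 0.01)
})

test_that("plant-CV draws are truncated, centred, and exact at zero dispersion", {
  expect_equal(sample_plant_cvs(0.2, 6, 0), rep(0.2, 6))
  set.seed(62)
  x <- sample_plant_cvs(0.2, 1e4, 0.05)
  expect_true(all(x >= 0))
  expect_lt(abs(mean(x) - 0.2), 0.005)
  # truncation bites when the batch CV is near zero, but never below zero
  y <- sample_plant_cvs(0.01, 1e3, 0.05)
  expect_true(all(y >= 0))
})

test_that("simulate_experiment matches a by-hand replica with Student's t-test", {
  dist <- cv_distribution(c(0.15, 0.25, 0.4), plant_dispersion = 0.04)
  n <- 6
  mA <- 10000
  for (effect in c(0, 30)) {
    set.seed(63)
    p_pkg <- simulate_experiment(n, effect, dist, mean_expression = mA)

    set.seed(63)
    u <- runif(1)
    bcv <- quantile(dist$batch_cv_values, u, type = 7, names = FALSE)
    cvA <- rnorm(n, bcv, dist$plant_dispersion)
    cvB <- rnorm(n, bcv, dist$plant_dispersion)
    stopifnot(all(c(cvA, cvB) >= 0)) # replica assumes no truncation resample
    mB <- mA * (1 + effect / 100)
    epsA <- matrix(rnorm(n * 8), ncol = 8)
    epsB <- matrix(rnorm(n * 8), ncol = 8)
    xA <- rowMeans(mA + cvA * mA * epsA)
    xB <- rowMeans(mB + cvB * mB * epsB)
    p_ref <- t.test(xA, xB, var.equal = TRUE)$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-12)
  }
})

test_that("power estimation is seeded, bounded, and monotone in effect and n", {
  dist <- cv_distribution(c(0.2, 0.3), plant_dispersion = 0.05)
  p1 <- estimate_power(6, 25, dist, n_reps = 300, seed = 64)
  p2 <- estimate_power(6, 25, dist, n_reps = 300, seed = 64)
  expect_identical(p1$power, p2$power)

  single <- estimate_power(4, 50, dist, n_reps = 1, seed = 65)
  expect_true(single$power %in% c(0, 1))

  # nondecreasing in effect at fixed n (shared seed, 1 MC SE slack)
  pows_e <- vapply(
    c(10, 25, 50, 100),
    function(e) estimate_power(6, e, dist, n_reps = 800, seed = 66)$power,
    numeric(1)
  )
  se <- sqrt(0.25 / 800)
  expect_true(all(diff(pows_e) > -se))

  # nondecreasing in n at fixed effect
  pows_n <- vapply(
    c(3, 6, 12, 24),
    function(n) estimate_power(n, 25, dist, n_reps = 800, seed = 67)$power,
    numeric(1)
  )
  expect_true(all(diff(pows_n) > -se))
})

test_that("null rejections and easy separations behave as expected", {
  dist <- cv_distribution(c(0.2, 0.35), plant_dispersion = 0.05)
  null <- estimate_power(6, 0, dist, n_reps = 600, seed = 68)
  expect_gt(null$power, 0.02)
  expect_lt(null$power, 0.09)

  sep <- estimate_power(4, 200, cv_distribution(0.05), n_reps = 1000, seed = 69)
  expect_gt(sep$power, 0.99)
})

test_that("find_min_n returns the bracketing minimum under its seed schedule", {
  dist <- cv_distribution(0.3)
  res <- find_min_n(60, dist, n_reps = 400, seed = 70)
  expect_false(res$capped)
  expect_gte(res$power, 0.95)

  # re-evaluating with the same per-n seed schedule reproduces the bracket
  set.seed(70)
  seeds <- sample.int(.Machine$integer.max - 1L, 50)
  at <- function(n) estimate_power(n, 60, dist, n_reps = 400, seed = seeds[n])$power
  expect_gte(at(res$n_min), 0.95)
  if (res$n_min > 2) expect_lt(at(res$n_min - 1), 0.95)

  # a huge effect needs only the minimum testable group size
  expect_equal(find_min_n(500, cv_distribution(0.2), n_reps = 200, seed = 71)$n_min, 2)

  # a tiny effect under a tight cap reports the cap was exceeded
  capped <- find_min_n(2, cv_distribution(0.4), n_cap = 4, n_reps = 100, seed = 72)
  expect_true(capped$capped)
  expect_true(is.na(capped$n_min))
})

test_that("exponential power curves invert exactly on noiseless points", {
  eff <- c(10, 20, 30, 50, 80, 120)
  pts <- tibble::tibble(effect_pct = eff, n_min = 100 * exp(-0.1 * eff) + 2)
  fit <- fit_power_curve(pts)
  expect_equal(fit$a, 100, tolerance = 1e-6)
  expect_equal(fit$b, 0.1, tolerance = 1e-6)
  expect_equal(fit$c, 2, tolerance = 1e-6)

  for (n in c(50, 10, 4)) {
    e <- min_detectable_effect(fit, n)
    expect_equal(fit$fitted(e), n, tolerance = 1e-6, ignore_attr = TRUE)
  }
  expect_error(min_detectable_effect(fit, 1.5), "asymptote")

  # jittered points still give a nonincreasing fitted curve
  set.seed(73)
  pts2 <- pts
  pts2$n_min <- pmax(2, round(pts2$n_min + rnorm(6, 0, 1)))
  fit2 <- fit_power_curve(pts2)
  grid <- seq(min(eff), max(eff), length.out = 50)
  expect_true(all(diff(fit2$fitted(grid)) <= 1e-9))

  expect_error(fit_power_curve(pts[1:3, ]), "at least 4")
})

test_that("simulated plant CVs track the distribution they came from", {
  dist <- cv_distribution(seq(0.12, 0.45, length.out = 12), plant_dispersion = 0.06)
  sim <- simulate_plant_cvs(dist, n_batches = 300, plants_per_batch = 20, seed = 74)
  expect_length(sim, 6000)
  expect_true(all(sim >= 0))

  same <- validate_simulator(sim, sim)
  expect_equal(same$wasserstein, 0)
  expect_equal(same$mean_ecdf_difference, 0)
})

test_that("CV distributions round-trip through their text form", {
  dist <- cv_distribution(c(0.12, 0.2, 0.31), plant_dispersion = 0.071,
    source = list(strain = "GV3101")
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_cv_distribution(dist, path)
  back <- read_cv_distribution(path)
  expect_equal(back$batch_cv_values, dist$batch_cv_values)
  expect_equal(back$plant_dispersion, dist$plant_dispersion)
})

test_that("direct plant-CV sampling is available behind a flag", {
  tab <- generate_hierarchical(generator_config(
    n_batches = 4, plants_per_batch = 30, seed = 75
  ))
  dist <- build_cv_distribution(tab, min_plants = 30)
  expect_false(is.null(dist$plant_cv_values))

  p1 <- estimate_power(5, 40, dist, n_reps = 300, seed = 76,
                       plant_sampling = "direct")
  p2 <- estimate_power(5, 40, dist, n_reps = 300, seed = 76,
                       plant_sampling = "direct")
  expect_identical(p1$power, p2$power)
  expect_true(p1$power >= 0 && p1$power <= 1)

  bare <- cv_distribution(c(0.2, 0.3))
  expect_error(
    estimate_power(4, 40, bare, n_reps = 10, seed = 77,
                   plant_sampling = "direct"),
    "plant_cv_values"
  )
})
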