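test_that("coefficient of variation: closed forms and scale invariance", {
  expect_equal(coefficient_of_variation(c(2, 2, 2)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), sqrt(2) / 2, tolerance = 1e-5)
  set.seed(41)
  x <- runif(20, 1, 5)
  for (k in c(0.01, 3, 1e4)) {
    expect_equal(coefficient_of_variation(k * x), coefficient_of_variation(x))
  }
  expect_error(coefficient_of_variation(5), "at least 2")
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
})

test_that("disk ratios are per disk, logged, and reciprocal-consistent", {
  df <- make_disk_df(c(100, 300, 500), red = c(50, NA, 0))
  tab <- as_assay_table(df)
  r <- disk_ratio(tab, "green", "red")
  expect_equal(r$ratio, 2)
  log <- assay_provenance(r)$filter_log
  expect_equal(log$n_removed[nrow(log)], 2L)

  full <- as_assay_table(make_disk_df(c(100, 300), red = c(50, 60)))
  ab <- disk_ratio(full, "green", "red")$ratio
  ba <- disk_ratio(full, "red", "green")$ratio
  expect_equal(ab * ba, rep(1, 2))
})

test_that("scheme summaries compute per-plant and pooled CVs", {
  tab <- as_assay_table(make_plants_df(list(c(1, 3), c(2, 6))))
  sm <- summarize_scheme(tab, "A", "green")
  expect_equal(sm$plant_cvs, rep(sqrt(2) / 2, 2), tolerance = 1e-5)
  expect_equal(sm$n_plants, 2)
  expect_equal(sm$n_disks, 4)

  const <- as_assay_table(make_plants_df(list(rep(7, 4), rep(7, 4))))
  expect_equal(summarize_scheme(const, "A", "green")$pooled_cv, 0)

  expect_error(summarize_scheme(tab, "missing", "green"), "not present")
})

test_that("correlated dual channels reduce the ratio plant CV", {
  cfg <- generator_config(
    rho_channels = 0.95, n_batches = 4, plants_per_batch = 12,
    seed = 42
  )
  tab <- generate_dual_channel(cfg)
  g <- summarize_scheme(tab, "A", "green")
  r <- summarize_scheme(tab, "A", "green_over_red")
  expect_lt(mean(r$plant_cvs), mean(g$plant_cvs))
})

test_that("Welch one-tailed p-values: null symmetry, separation, complement", {
  x <- c(0.1, 0.12, 0.11, 0.13)
  expect_equal(welch_one_tailed_less(x, x), 0.5)

  p_sep <- welch_one_tailed_less(
    c(0.1, 0.1, 0.1, 0.12),
    c(0.3, 0.31, 0.29, 0.3)
  )
  expect_lt(p_sep, 0.001)
  expect_equal(
    p_sep,
    welch_less_oracle(c(0.1, 0.1, 0.1, 0.12), c(0.3, 0.31, 0.29, 0.3)),
    tolerance = 1e-12
  )

  set.seed(43)
  a <- rnorm(6, 0.2, 0.05)
  b <- rnorm(9, 0.3, 0.08)
  expect_equal(
    welch_one_tailed_less(a, b) + welch_one_tailed_less(b, a), 1,
    tolerance = 1e-12
  )

  # degenerate constant groups follow the documented sign convention
  expect_equal(welch_one_tailed_less(c(1, 1), c(2, 2)), 0)
  expect_equal(welch_one_tailed_less(c(2, 2), c(1, 1)), 1)
  expect_equal(welch_one_tailed_less(c(1, 1), c(1, 1)), 0.5)
})

test_that("Welch p-values match the reference formula on random small samples", {
  set.seed(44)
  for (i in 1:100) {
    nx <- sample(2:12, 1)
    ny <- sample(2:12, 1)
    x <- rnorm(nx, runif(1, -1, 1), runif(1, 0.2, 2))
    y <- rnorm(ny, runif(1, -1, 1), runif(1, 0.2, 2))
    expect_equal(welch_one_tailed_less(x, y), welch_less_oracle(x, y),
      tolerance = 1e-6
    )
  }
})

test_that("Bonferroni adjustment is the capped product and monotone", {
  expect_equal(bonferroni(0.01, m = 17), 0.17)
  expect_equal(bonferroni(0.5, m = 3), 1.0)
  expect_equal(bonferroni(c(0.02, 0.4), m = 1), c(0.02, 0.4) * 2)
  expect_equal(bonferroni(0.3), 0.3)
  set.seed(45)
  p <- runif(10)
  expect_true(all(bonferroni(p, m = 7) >= p))
})

test_that("scheme-vs-control comparison table is coherent", {
  cfg <- generator_config(rho_channels = 0.95, n_batches = 2,
                          plants_per_batch = 6, seed = 46)
  tab <- generate_dual_channel(cfg)
  df <- tibble::as_tibble(as.data.frame(tab))
  df2 <- df
  df2$condition_id <- "scheme3"
  ctrl <- df
  ctrl$red <- NA_real_
  both <- as_assay_table(dplyr::bind_rows(ctrl, df2))

  res <- compare_scheme_cvs(both, "scheme3", "A", m = 17)
  expect_equal(res$p_adjusted, pmin(1, 17 * res$p_raw))
  expect_equal(res$m_tests, 17)
  expect_lt(res$percent_cv_change, 0)
})

test_that("CV matrices summarize factor grids", {
  df <- make_disk_df(c(100, 140), red = c(50, 60))
  df$od_a <- "0.1"
  df$od_b <- "0.5"
  m <- cv_matrix(as_assay_table(df), "od_a", "od_b", "green")
  expect_equal(dim(m), c(1, 1))
  expect_equal(m[1, 1], sd(c(100, 140)) / 120)

  # symmetric input yields a symmetric matrix
  set.seed(47)
  grid <- expand.grid(a = c("L", "H"), b = c("L", "H"), stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    pair <- sort(c(grid$a[i], grid$b[i]))
    set.seed(100 + match(paste(pair, collapse = ""), c("HH", "HL", "LL")))
    d <- make_disk_df(rnorm(8, 1000, 150), condition_id = paste0(grid$a[i], grid$b[i]),
                      plant_id = sprintf("p%02d", i))
    d$fa <- grid$a[i]
    d$fb <- grid$b[i]
    d
  })
  ms <- cv_matrix(as_assay_table(dplyr::bind_rows(rows)), "fa", "fb", "green")
  expect_equal(ms, t(ms))
  expect_error(cv_matrix(as_assay_table(df), "nope", "od_b"), "not present")
})

test_that("identical-promoter cells show the lowest ratio CV on a synthetic grid", {
  # 3x3 promoter grid: identical-promoter pairs generated with high channel
  # correlation, mismatched pairs with low correlation
  proms <- c("PCL2", "PCM2", "PCH5")
  cells <- list()
  k <- 0
  for (i in 1:3) {
    for (j in 1:3) {
      k <- k + 1
      rho <- if (i == j) 0.95 else 0.2
      cfg <- generator_config(
        rho_channels = rho, n_batches = 2, plants_per_batch = 8,
        seed = 500 + k
      )
      d <- tibble::as_tibble(as.data.frame(generate_dual_channel(cfg)))
      d$condition_id <- sprintf("c%d%d", i, j)
      d$prom_g <- proms[i]
      d$prom_r <- proms[j]
      cells[[k]] <- d
    }
  }
  tab <- as_assay_table(dplyr::bind_rows(cells))
  m <- cv_matrix(tab, "prom_g", "prom_r", "green_over_red")
  for (p in proms) {
    off_diag <- m[p, setdiff(proms, p)]
    expect_lt(m[p, p], min(off_diag))
  }
})
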