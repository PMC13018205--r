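# Shared fixture builders and independent oracles for the test suite.
# Oracles are deliberately implemented from first principles (formulas,
# brute-force grids, direct model simulation) so they never share code with
# the implementation paths they check.

# Strip class and provenance for value-only comparisons of assay tables.
plain_df <- function(x) {
  df <- tibble::as_tibble(as.data.frame(x))
  attr(df, "provenance") <- NULL
  df
}

# Small tidy disk table: one row per disk, defaults fill a single plant.
make_disk_df <- function(green, red = NA_real_,
                         batch_id = "2022.01.03", condition_id = "A",
                         plant_id = "p01", strain = "GV3101") {
  n <- length(green)
  leaves <- rep(c("T4", "T5"), each = 4)[seq_len(n)]
  disks <- rep(1:4, times = 2)[seq_len(n)]
  tibble::tibble(
    batch_id = batch_id, condition_id = condition_id, plant_id = plant_id,
    leaf = leaves, disk_index = disks, strain = strain,
    green = green, red = red
  )
}

# Multi-plant table: `values` is a list of per-plant disk vectors.
make_plants_df <- function(values, batch_id = "2022.01.03",
                           condition_id = "A", red = NULL) {
  dplyr::bind_rows(lapply(seq_along(values), function(i) {
    make_disk_df(values[[i]],
      red = if (is.null(red)) NA_real_ else red[[i]],
      batch_id = batch_id, condition_id = condition_id,
      plant_id = sprintf("p%02d", i)
    )
  }))
}

# Welch one-tailed (less) p-value from the raw formulas, as the reference
# implementation oracle.
welch_less_oracle <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  vx <- var(x)
  vy <- var(y)
  se2 <- vx / nx + vy / ny
  tstat <- (mean(x) - mean(y)) / sqrt(se2)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  pt(tstat, df)
}

# Closed-form noncentral-t power of the two-sample pooled t-test for the
# simulated design: per-plant means with SD cv * mean / sqrt(disks).
noncentral_t_power_oracle <- function(effect_pct, n, cv, disks = 8, alpha = 0.05) {
  mA <- 1
  mB <- 1 + effect_pct / 100
  sd_pooled <- sqrt((cv * mA)^2 / disks / 2 + (cv * mB)^2 / disks / 2)
  ncp <- (mB - mA) / (sd_pooled * sqrt(2 / n))
  df <- 2 * n - 2
  tc <- qt(1 - alpha / 2, df)
  pt(tc, df, ncp, lower.tail = FALSE) + pt(-tc, df, ncp)
}

# Sequential-ablation Monte Carlo attribution of the five variance shares:
# simulate the (untruncated) location-scale model, switch components off in
# the nesting order with common random numbers, and attribute the variance
# drops. Component draws are standardized to exact zero mean / unit variance
# (a variance-reduction device: the attribution differences then carry only
# higher-moment Monte Carlo noise). Independent of compute_shares' closed
# forms.
ablation_shares_oracle <- function(tau_b, tau_p, lambda, omega_b, omega_p,
                                   n_batches = 20000, plants = 10, disks = 5) {
  np <- n_batches * plants
  nd <- np * disks
  bi <- rep(seq_len(n_batches), each = plants * disks)
  pi <- rep(seq_len(np), each = disks)
  std <- function(z) (z - mean(z)) / sd(z)
  za <- std(rnorm(n_batches))
  zb <- std(rnorm(np))
  zu <- std(rnorm(n_batches))
  zv <- std(rnorm(np))
  ze <- std(rnorm(nd))
  v_of <- function(tb, tp, wb, wp) {
    sigma <- exp(lambda + wb * zu[bi] + wp * zv[pi])
    y <- tb * za[bi] + tp * zb[pi] + sigma * ze
    var(y)
  }
  v_full <- v_of(tau_b, tau_p, omega_b, omega_p)
  v1 <- v_of(0, tau_p, omega_b, omega_p) # - batch mean
  v2 <- v_of(0, 0, omega_b, omega_p) # - plant mean
  v3 <- v_of(0, 0, omega_b, 0) # - plant sd
  v4 <- v_of(0, 0, 0, 0) # - batch sd
  c(
    batch_mean_pct = 100 * (v_full - v1) / v_full,
    batch_sd_pct = 100 * (v3 - v4) / v_full,
    plant_mean_pct = 100 * (v1 - v2) / v_full,
    plant_sd_pct = 100 * (v2 - v3) / v_full,
    disk_sd_pct = 100 * v4 / v_full
  )
}

# Dense-grid brute-force one-sample KS D: max |ECDF_sample - F_ref| over a
# grid fine enough to land in every constant interval of both step functions.
ks_grid_oracle <- function(sample, reference_values) {
  pts <- sort(unique(c(sample, reference_values)))
  lo <- min(pts) - 1
  hi <- max(pts) + 1
  gap <- min(diff(c(lo, pts, hi)))
  grid <- seq(lo, hi, by = gap / 3)
  fs <- stats::ecdf(sample)
  fr <- stats::ecdf(reference_values)
  max(abs(fs(grid) - fr(grid)))
}

# Riemann-sum brute-force 1-D Wasserstein at fixed resolution.
wasserstein_grid_oracle <- function(a, b, resolution = 1e-5) {
  lo <- min(a, b)
  hi <- max(a, b)
  grid <- seq(lo, hi, by = (hi - lo) * resolution)
  fa <- stats::ecdf(a)
  fb <- stats::ecdf(b)
  sum(abs(fa(grid) - fb(grid))[-length(grid)] * diff(grid))
}
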