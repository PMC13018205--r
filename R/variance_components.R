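# Hierarchical location-scale model
#
#   y_bpd = mu + alpha_b + beta_bp + sigma_bp * eps_bpd
#   log sigma_bp = lambda + u_b + v_bp
#
# with alpha_b ~ N(0, tau_b^2), beta_bp ~ N(0, tau_p^2), u_b ~ N(0, omega_b^2),
# v_bp ~ N(0, omega_p^2), eps ~ N(0,1).
#
# Marginal likelihood: beta_bp integrates analytically (Gaussian); the
# plant-level scale effect v_bp is integrated by adaptively centred
# Gauss-Hermite quadrature; the batch-level pair (alpha_b, u_b) by a 2-D
# adaptively centred Gauss-Hermite product rule. Centres and scales come from
# closed-form conjugate-style posterior approximations, so the likelihood is
# a smooth deterministic function of the parameters (no inner optimization).

.gh_cache <- new.env(parent = emptyenv())

# Gauss-Hermite nodes/weights rescaled for expectations under N(0,1):
# E[h(Z)] ~ sum w_i h(z_i).
.gh_normal <- function(k) {
  key <- as.character(k)
  if (is.null(.gh_cache[[key]])) {
    gh <- pracma::gaussHermite(k)
    .gh_cache[[key]] <- list(z = gh$x * sqrt(2), w = gh$w / sqrt(pi))
  }
  .gh_cache[[key]]
}

# Importance-corrected adaptive nodes for integrals of the form
#   int f(x) dnorm(x, 0, prior_sd) dx
# evaluated with nodes centred at `center` with scale `sdev`.
# Returns X and log-weights LW, both n x K. Collapses to a single zero node
# when prior_sd is (numerically) zero.
.adapt_nodes <- function(center, sdev, prior_sd, k) {
  n <- length(center)
  if (prior_sd < 1e-10) {
    return(list(X = matrix(0, n, 1), LW = matrix(0, n, 1)))
  }
  gh <- .gh_normal(k)
  X <- outer(center, rep(1, k)) + outer(sdev, gh$z)
  LW <- matrix(log(gh$w), n, k, byrow = TRUE) +
    dnorm(X, 0, prior_sd, log = TRUE) +
    matrix(log(sdev), n, k) -
    matrix(dnorm(gh$z, log = TRUE), n, k, byrow = TRUE)
  list(X = X, LW = LW)
}

# log-sum-exp over the last dimension of an array laid out as (rows, K)
.lse_cols <- function(m) {
  amax <- do.call(pmax, c(lapply(seq_len(ncol(m)), function(j) m[, j]), na.rm = FALSE))
  amax + log(rowSums(exp(m - amax)))
}

# Per-plant sufficient statistics for one channel.
.plant_stats <- function(table, channel) {
  df <- tibble::as_tibble(as.data.frame(table))
  if (!channel %in% c("green", "red")) {
    stop("channel must be 'green' or 'red'", call. = FALSE)
  }
  df <- df[!is.na(df[[channel]]), , drop = FALSE]
  g <- per_plant_groups(.assay_rewrap(df, table))
  vals <- lapply(g[[channel]], function(x) x[!is.na(x)])
  keep <- vapply(vals, length, integer(1)) >= 2
  g <- g[keep, , drop = FALSE]
  vals <- vals[keep]
  tibble::tibble(
    batch_id = g$batch_id,
    n = vapply(vals, length, integer(1)),
    ybar = vapply(vals, mean, numeric(1)),
    ss = vapply(vals, function(x) sum((x - mean(x))^2), numeric(1))
  )
}

# Negative marginal log-likelihood on the standardized scale.
# theta = (mu, tau_b, tau_p, lambda, omega_b, omega_p)
.ls_negloglik <- function(theta, st, quad = c(7L, 9L)) {
  mu <- theta[1]
  tb <- theta[2]
  tp <- theta[3]
  lam <- theta[4]
  wb <- theta[5]
  wp <- theta[6]
  Ko <- quad[1]
  Ki <- quad[2]

  n <- st$n
  ybar <- st$ybar
  ss <- st$ss
  bi <- st$batch_i
  B <- st$B
  N <- length(n)

  # moment-style centres for the adaptive rules
  var_ls <- st$var_ls # sampling variance of log within-plant SD
  resid <- st$ls_adj - lam # estimates u_b + v_bp per plant

  prec_u_contrib <- 1 / (wp^2 + var_ls)
  prec_u <- 1 / max(wb^2, 1e-12) + st$sum_by_batch(prec_u_contrib)
  cu <- st$sum_by_batch(resid * prec_u_contrib) / prec_u
  su <- 1.3 / sqrt(prec_u)

  Unodes <- .adapt_nodes(cu, su, wb, Ko)
  U <- Unodes$X
  LWu <- Unodes$LW
  Ku <- ncol(U)

  sig2_hat <- exp(2 * (lam + cu) + 2 * wp^2) # E[sigma^2 | u = cu]
  s2p <- tp^2 + sig2_hat[bi] / n
  prec_a <- 1 / max(tb^2, 1e-12) + st$sum_by_batch(1 / s2p)
  ca <- st$sum_by_batch((ybar - mu) / s2p) / prec_a
  sa <- 1.3 / sqrt(prec_a)

  Anodes <- .adapt_nodes(ca, sa, tb, Ko)
  A <- Anodes$X
  LWa <- Anodes$LW
  Ka <- ncol(A)

  # plant-level scale effect v: centre depends on the u node
  shrink_v <- wp^2 / (wp^2 + var_ls)
  sv <- 1.3 / sqrt(1 / max(wp^2, 1e-12) + 1 / var_ls)
  wp_zero <- wp < 1e-10
  Kv <- if (wp_zero) 1L else Ki
  if (!wp_zero) {
    gh <- .gh_normal(Ki)
  }

  # accumulate log g_p(j, k) = log int f_p(alpha_j, sigma(u_k, v)) dN(v)
  # laid out as array (N, Ka, Ku)
  LG <- array(0, c(N, Ka, Ku))
  ln2pi <- log(2 * pi)
  for (k in seq_len(Ku)) {
    uk <- U[bi, k]
    if (wp_zero) {
      V <- matrix(0, N, 1)
      LWv <- matrix(0, N, 1)
    } else {
      mv <- shrink_v * (st$ls_adj - lam - uk)
      V <- outer(mv, rep(1, Kv)) + outer(sv, gh$z)
      LWv <- matrix(log(gh$w), N, Kv, byrow = TRUE) +
        dnorm(V, 0, wp, log = TRUE) +
        matrix(log(sv), N, Kv) -
        matrix(dnorm(gh$z, log = TRUE), N, Kv, byrow = TRUE)
    }
    S2 <- exp(2 * (lam + uk + V)) # N x Kv
    Q <- S2 / n + tp^2
    T1 <- LWv - 0.5 * ((n - 1) * (ln2pi + log(S2)) + ss / S2 + ln2pi + log(Q))
    for (j in seq_len(Ka)) {
      d2 <- (ybar - mu - A[bi, j])^2
      M <- T1 - 0.5 * d2 / Q
      LG[, j, k] <- if (Kv == 1L) M[, 1] else .lse_cols(M)
    }
  }

  # sum over plants within batch, add outer weights, integrate (alpha, u)
  ll <- 0
  Sb <- matrix(0, B, Ka * Ku)
  dim(LG) <- c(N, Ka * Ku)
  Sb <- rowsum(LG, bi, reorder = TRUE)
  for (k in seq_len(Ku)) {
    idx <- ((k - 1) * Ka + 1):(k * Ka)
    Sb[, idx] <- Sb[, idx] + LWa + LWu[, k]
  }
  ll <- sum(.lse_cols(Sb))
  if (!is.finite(ll)) {
    return(1e10)
  }
  -ll
}

.prep_stats <- function(ps) {
  bfac <- factor(ps$batch_id, levels = unique(ps$batch_id))
  bi <- as.integer(bfac)
  B <- nlevels(bfac)
  n <- ps$n
  ss_floor <- pmax(ps$ss, 1e-12)
  ls <- 0.5 * log(ss_floor / (n - 1))
  bias <- 0.5 * (digamma((n - 1) / 2) + log(2) - log(n - 1))
  list(
    n = n, ybar = ps$ybar, ss = ps$ss, batch_i = bi, B = B,
    ls_adj = ls - bias,
    var_ls = 0.25 * trigamma((n - 1) / 2),
    sum_by_batch = function(x) as.numeric(rowsum(x, bi, reorder = TRUE))
  )
}

# method-of-moments starting values on the standardized scale
.mom_start <- function(st) {
  n <- st$n
  Pbar <- length(n) / st$B
  sw2 <- sum(st$ss) / sum(n - 1)
  lam0 <- mean(st$ls_adj)
  bm_ls <- st$sum_by_batch(st$ls_adj) / st$sum_by_batch(rep(1, length(n)))
  vw_ls <- sum((st$ls_adj - bm_ls[st$batch_i])^2) / max(1, length(n) - st$B)
  vb_ls <- if (st$B > 1) var(bm_ls) else 0
  wp0 <- sqrt(max(vw_ls - mean(st$var_ls), 1e-4))
  wb0 <- sqrt(max(vb_ls - vw_ls / Pbar, 1e-4))

  bm_y <- st$sum_by_batch(st$ybar) / st$sum_by_batch(rep(1, length(n)))
  vw_y <- sum((st$ybar - bm_y[st$batch_i])^2) / max(1, length(n) - st$B)
  vb_y <- if (st$B > 1) var(bm_y) else 0
  tp0 <- sqrt(max(vw_y - sw2 / mean(n), 1e-4))
  tb0 <- sqrt(max(vb_y - vw_y / Pbar, 1e-4))
  mu0 <- mean(bm_y)
  c(mu0, tb0, tp0, lam0, wb0, wp0)
}

#' Fit the hierarchical location-scale model
#'
#' Maximum-likelihood fit of the batch/plant location-scale hierarchy (random
#' effects on level means *and* level log standard deviations; see
#' [generator_config()] for the generative form). Plant-level mean effects
#' are integrated analytically; plant-level scale effects and the batch-level
#' effect pair are integrated by adaptively centred Gauss-Hermite quadrature.
#' Optimization runs `nlminb` from a fixed multi-start schedule anchored at
#' method-of-moments values, so the fit is deterministic given the data.
#' Variance parameters may sit on the zero boundary; estimates below 1e-6 of
#' the response SD are reported as exact zeros.
#'
#' @param table An `assay_table` with at least 2 batches, 2 plants per batch
#'   and 2 disks per plant in the chosen channel (plants with fewer than two
#'   non-missing disks are dropped before this check).
#' @param channel `"green"` or `"red"`.
#' @param quad Quadrature sizes `c(outer, inner)`: nodes per batch-level
#'   dimension and nodes for the plant-level scale effect.
#' @param control Passed to [stats::nlminb()]; the default uses a relative
#'   tolerance of 1e-8.
#' @return A `location_scale_fit` with elements `mu`, `tau_batch`,
#'   `tau_plant`, `lambda_log_sigma`, `omega_batch`, `omega_plant`, `loglik`,
#'   counts, and convergence diagnostics.
#' @seealso [compute_shares()], [decompose()]
#' @export
fit_location_scale <- function(table, channel = c("green", "red"),
                               quad = c(7L, 9L),
                               control = list(rel.tol = 1e-8, iter.max = 300, eval.max = 600)) {
  channel <- match.arg(channel)
  ps <- .plant_stats(table, channel)
  if (nrow(ps) == 0) stop("no plants with >= 2 disks in channel ", channel, call. = FALSE)
  bt <- table(ps$batch_id)
  if (length(bt) < 2 || any(bt < 2)) {
    stop("insufficient nesting depth: need >= 2 batches with >= 2 plants each",
      call. = FALSE
    )
  }
  n_disks <- sum(ps$n)

  # fully degenerate data (no within-plant variation anywhere): the scale
  # model is vacuous; report boundary estimates from the plant/batch means
  if (all(ps$ss < 1e-12)) {
    bm <- tapply(ps$ybar, ps$batch_id, mean)
    within <- ps$ybar - bm[ps$batch_id]
    fit <- structure(list(
      mu = mean(bm), tau_batch = sqrt(max(0, var(as.numeric(bm)) * (length(bm) - 1) / length(bm))),
      tau_plant = sqrt(mean(within^2)),
      lambda_log_sigma = -Inf, omega_batch = 0, omega_plant = 0,
      loglik = NA_real_, n_batches = length(bt), n_plants = nrow(ps),
      n_disks = n_disks, channel = channel, convergence = "degenerate",
      message = "no within-plant variation; scale parameters at boundary"
    ), class = "location_scale_fit")
    if (fit$tau_batch < 1e-9) fit$tau_batch <- 0
    if (fit$tau_plant < 1e-9) fit$tau_plant <- 0
    return(fit)
  }

  # standardize the response for well-scaled optimization
  m0 <- sum(ps$ybar * ps$n) / n_disks
  s0 <- sqrt((sum(ps$ss) + sum(ps$n * (ps$ybar - m0)^2)) / (n_disks - 1))
  ps_std <- ps
  ps_std$ybar <- (ps$ybar - m0) / s0
  ps_std$ss <- ps$ss / s0^2
  st <- .prep_stats(ps_std)

  quad <- as.integer(quad)
  obj <- function(theta) .ls_negloglik(theta, st, quad)
  s1 <- .mom_start(st)
  starts <- list(
    s1,
    c(s1[1], s1[2:3] * 1.5, s1[4], 0.15, 0.15),
    c(s1[1], s1[2:3] * 0.5, s1[4], pmin(1, s1[5:6] * 1.75))
  )
  lower <- c(-Inf, 0, 0, -Inf, 0, 0)
  fits <- lapply(starts, function(s) {
    tryCatch(
      stats::nlminb(s, obj, lower = lower, control = control),
      error = function(e) list(objective = Inf, convergence = -1L, message = conditionMessage(e))
    )
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
  if (!is.finite(best$objective)) {
    stop(
      "location-scale fit failed to converge from every start; last message: ",
      best$message,
      call. = FALSE
    )
  }
  th <- best$par
  zero_snap <- function(x) ifelse(x < 1e-6, 0, x)
  structure(list(
    mu = m0 + th[1] * s0,
    tau_batch = zero_snap(th[2]) * s0,
    tau_plant = zero_snap(th[3]) * s0,
    lambda_log_sigma = th[4] + log(s0),
    omega_batch = zero_snap(th[5]),
    omega_plant = zero_snap(th[6]),
    loglik = -best$objective - n_disks * log(s0),
    n_batches = length(bt),
    n_plants = nrow(ps),
    n_disks = n_disks,
    channel = channel,
    convergence = best$convergence,
    message = best$message
  ), class = "location_scale_fit")
}

#' @export
print.location_scale_fit <- function(x, ...) {
  cat("Hierarchical location-scale fit (", x$channel, " channel)\n", sep = "")
  cat(sprintf(
    "  %d batches, %d plants, %d disks | loglik %.3f\n",
    x$n_batches, x$n_plants, x$n_disks, x$loglik
  ))
  cat(sprintf("  mu       = %.4g\n", x$mu))
  cat(sprintf("  tau_b    = %.4g   tau_p   = %.4g\n", x$tau_batch, x$tau_plant))
  cat(sprintf(
    "  exp(lam) = %.4g   omega_b = %.4g   omega_p = %.4g\n",
    exp(x$lambda_log_sigma), x$omega_batch, x$omega_plant
  ))
  invisible(x)
}

#' Five-way percent attribution of observed variance
#'
#' Under the location-scale hierarchy the marginal disk variance is
#' \deqn{V = \tau_b^2 + \tau_p^2 + E[\sigma^2], \qquad
#'       E[\sigma^2] = e^{2\lambda + 2\omega_b^2 + 2\omega_p^2}}
#' (lognormal moment identity). The scale contribution is split along the
#' nesting order, batch before plant: the disk-SD share is the baseline
#' \eqn{e^{2\lambda}}, the batch-SD share is what turning on \eqn{\omega_b}
#' adds at baseline, and the plant-SD share is what turning on
#' \eqn{\omega_p} adds on top of the batch-level scale effect. The five
#' shares are nonnegative and sum to 100 by construction.
#'
#' @param params A `location_scale_fit` or a named list with `tau_batch`,
#'   `tau_plant`, `lambda_log_sigma`, `omega_batch`, `omega_plant`.
#' @return A `variance_shares` list: `batch_mean_pct`, `batch_sd_pct`,
#'   `plant_mean_pct`, `plant_sd_pct`, `disk_sd_pct`.
#' @export
compute_shares <- function(params) {
  p <- params
  stopifnot(
    p$tau_batch >= 0, p$tau_plant >= 0,
    p$omega_batch >= 0, p$omega_plant >= 0
  )
  e_disk <- exp(2 * p$lambda_log_sigma)
  e_batch <- e_disk * (exp(2 * p$omega_batch^2) - 1)
  e_plant <- e_disk * exp(2 * p$omega_batch^2) * (exp(2 * p$omega_plant^2) - 1)
  v <- p$tau_batch^2 + p$tau_plant^2 + e_disk + e_batch + e_plant
  if (v <= 0) stop("total variance is zero; shares undefined", call. = FALSE)
  structure(list(
    batch_mean_pct = 100 * p$tau_batch^2 / v,
    batch_sd_pct = 100 * e_batch / v,
    plant_mean_pct = 100 * p$tau_plant^2 / v,
    plant_sd_pct = 100 * e_plant / v,
    disk_sd_pct = 100 * e_disk / v
  ), class = "variance_shares")
}

#' @export
print.variance_shares <- function(x, ...) {
  cat("Percent contributions to observed variance:\n")
  cat(sprintf("  batch mean %5.1f%%   batch SD %5.1f%%\n", x$batch_mean_pct, x$batch_sd_pct))
  cat(sprintf("  plant mean %5.1f%%   plant SD %5.1f%%\n", x$plant_mean_pct, x$plant_sd_pct))
  cat(sprintf("  disk  SD   %5.1f%%\n", x$disk_sd_pct))
  invisible(x)
}

#' Decompose an assay table's variance into five components
#'
#' Convenience composition of [fit_location_scale()] and [compute_shares()].
#'
#' @inheritParams fit_location_scale
#' @return A `variance_shares` object; the underlying fit is attached as the
#'   `"fit"` attribute.
#' @export
decompose <- function(table, channel = c("green", "red"), quad = c(7L, 9L)) {
  fit <- fit_location_scale(table, channel, quad = quad)
  shares <- compute_shares(fit)
  attr(shares, "fit") <- fit
  shares
}
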