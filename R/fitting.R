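# Grid-scan RMSE fitting of target-gene dynamics to scaled expression
# profiles: mRNA decay rate (alpha_m), promoter affinity (K) and
# transcriptional delay (tau) estimation, plus per-cluster half-life
# prediction and model comparison.
#
# Because the target gene feeds back on nothing, the upstream six species
# are solved once per stimulus and the scalar target equation
# dx/dt = f(pJun(t)) - alpha * x is re-integrated per grid point against
# the stored pJun(t) (compiled exact-propagator kernel).

#' Min-max scale a series to the unit interval
#'
#' Computes (x - min) / (max - min); a constant series maps to all zeros.
#'
#' @param x numeric vector.
#' @return Scaled vector in \[0, 1\].
#' @examples
#' minmax_scale(c(1, 3, 5))
#' @export
minmax_scale <- function(x) {
  x <- as.numeric(x)
  rng <- max(x) - min(x)
  if (rng == 0) return(rep(0, length(x)))
  (x - min(x)) / rng
}

#' Scaled experimental expression profile
#'
#' A per-gene or cluster-mean expression time course, min-max scaled to
#' \[0, 1\], under one of the three stimulus programs.
#'
#' @param condition `"sustained"`, `"transient"` or `"pulsed"` (selects the
#'   stimulus program used when fitting).
#' @param values scaled expression values in \[0, 1\].
#' @param timepoints measurement times (h), strictly increasing, >= 3.
#' @param sd optional per-timepoint standard deviations.
#' @param id optional gene or cluster identifier.
#' @return Object of class `expression_profile`.
#' @export
expression_profile <- function(condition, values,
                               timepoints = c(0, 2, 4, 6, 8),
                               sd = NULL, id = NULL) {
  condition <- match.arg(condition, c("sustained", "transient", "pulsed"))
  values <- as.numeric(values)
  timepoints <- as.numeric(timepoints)
  if (length(timepoints) < 3) stop("at least 3 timepoints are required")
  if (is.unsorted(timepoints, strictly = TRUE)) {
    stop("timepoints must be strictly increasing")
  }
  if (length(values) != length(timepoints)) {
    stop("values and timepoints must have equal length")
  }
  if (any(values < -1e-9) || any(values > 1 + 1e-9)) {
    stop("profile values must lie in [0, 1] (min-max scaled)")
  }
  structure(list(condition = condition, timepoints = timepoints,
                 values = pmin(pmax(values, 0), 1), sd = sd, id = id),
            class = "expression_profile")
}

#' RMSE between a model trajectory and an expression profile
#'
#' The sparse experimental profile is linearly interpolated onto the dense
#' comparison grid (splines are deliberately avoided) and the root mean
#' square difference is taken over grid points within the profile's time
#' span. Both sides are expected min-max scaled.
#'
#' @param model_times,model_values model target-gene series on (or
#'   covering) the comparison grid.
#' @param profile an [expression_profile()].
#' @param grid dense comparison grid (h), default 0-8 h at 0.1-h steps.
#' @return RMSE (dimensionless, on scaled values).
#' @export
profile_rmse <- function(model_times, model_values, profile,
                         grid = seq(0, 8, by = 0.1)) {
  span <- range(profile$timepoints)
  if (min(grid) > span[1] + 1e-9 || max(grid) < span[2] - 1e-9) {
    stop("comparison grid does not cover the profile's time span")
  }
  g <- grid[grid >= span[1] - 1e-9 & grid <= span[2] + 1e-9]
  if (min(model_times) > min(g) + 1e-9 || max(model_times) < max(g) - 1e-9) {
    stop("model series does not cover the comparison grid")
  }
  pv <- stats::approx(profile$timepoints, profile$values, xout = g)$y
  mv <- stats::approx(model_times, model_values, xout = g)$y
  sqrt(mean((mv - pv)^2))
}

#' Convert between first-order decay rate and half-life
#'
#' `half_life_h = ln(2) / rate` and inversely.
#'
#' @param value positive rate (h^-1) or half-life (h).
#' @param direction `"rate_to_halflife"` or `"halflife_to_rate"`.
#' @return Converted value.
#' @examples
#' decay_halflife_convert(0.693, "rate_to_halflife") # ~1 h
#' @export
decay_halflife_convert <- function(value,
                                   direction = c("rate_to_halflife",
                                                 "halflife_to_rate")) {
  direction <- match.arg(direction)
  if (any(!is.finite(value)) || any(value <= 0)) {
    stop("value must be strictly positive")
  }
  log(2) / value
}

# --- internal scan machinery ---------------------------------------------

# upstream pJun(t) on the fine integration grid, solved once per stimulus
upstream_pjun <- function(params, stimulus, t_end, dt_fine) {
  traj <- simulate_jnk(params, stimulus, t_end = t_end, dt_out = dt_fine,
                       variant = "mass_action")
  list(times = traj$times, pJun = traj$states[, "pJun"])
}

# forcing term f(t) = beta_t + beta_tj * g(pJun(t - tau)) on the fine grid
scan_forcing <- function(pjun, params, hill = FALSE, K = NULL,
                         n_target = NULL, tau = 0) {
  pj <- pjun$pJun
  if (tau > 0) {
    pj <- stats::approx(pjun$times, pj, xout = pjun$times - tau,
                        yleft = pj[1])$y
  }
  if (!hill) {
    matrix(params$beta_t + params$beta_tj * pj, ncol = 1)
  } else {
    pn <- ifelse(pj <= 0, 0, pj^n_target)
    vapply(K, function(k) params$beta_t + params$beta_tj * pn / (pn + k^n_target),
           numeric(length(pj)))
  }
}

# batch target integration: returns nout x nalpha x nk array
target_scan_batch <- function(f, dt_fine, alpha, x0, outidx) {
  .Call("jnk_target_scan", as.numeric(f), as.numeric(dt_fine),
        as.numeric(alpha), as.numeric(x0), as.integer(outidx),
        as.integer(nrow(f)), PACKAGE = "jnkdyn")
}

# column-wise min-max scaling of an nout x m matrix
scale_columns <- function(M) {
  mn <- M[1, ]; mx <- M[1, ]
  for (i in 2:nrow(M)) {
    mn <- pmin(mn, M[i, ])
    mx <- pmax(mx, M[i, ])
  }
  rng <- mx - mn
  rng[rng == 0] <- 1
  (M - rep(mn, each = nrow(M))) / rep(rng, each = nrow(M))
}

# RMSE of every scaled model column against the interpolated profile.
# With model sampling at the profile timepoints (the default), the model
# columns hold the profile-timepoint samples and both sides are pushed
# through the same linear-interpolation operator W onto the dense grid,
# so the objective vanishes exactly at the generating parameters. In
# "dense" mode the model columns are already on the comparison grid.
scan_rmse <- function(out, g, profile) {
  d <- dim(out)
  M <- matrix(out, nrow = d[1])
  S <- scale_columns(M)
  if (!is.null(g$W)) S <- g$W %*% S
  pv <- stats::approx(profile$timepoints, profile$values,
                      xout = g$cmp_keep)$y
  r <- sqrt(colMeans((S - pv)^2))
  if (length(d) == 3 && d[3] > 1) matrix(r, d[2], d[3]) else r
}

# linear interpolation operator from node times onto a dense grid
interp_operator <- function(nodes, grid) {
  W <- matrix(0, length(grid), length(nodes))
  seg <- findInterval(grid, nodes, rightmost.closed = TRUE)
  seg <- pmin(pmax(seg, 1), length(nodes) - 1)
  w <- (grid - nodes[seg]) / (nodes[seg + 1] - nodes[seg])
  for (i in seq_along(grid)) {
    W[i, seg[i]] <- 1 - w[i]
    W[i, seg[i] + 1] <- w[i]
  }
  W
}

scan_grids <- function(profile, params, t_end, dt_fine, grid_step, lag,
                       model_sampling = "profile_timepoints") {
  stim <- make_stimulus(profile$condition)
  fine <- seq(0, t_end, by = dt_fine)
  cmp_grid <- seq(0, t_end, by = grid_step)
  span <- range(profile$timepoints)
  cmp_keep <- cmp_grid[cmp_grid >= span[1] - 1e-9 & cmp_grid <= span[2] + 1e-9]
  if (model_sampling == "profile_timepoints") {
    outidx <- match(round(profile$timepoints, 9), round(fine, 9))
    if (anyNA(outidx)) stop("profile timepoints must be multiples of dt_fine")
    W <- interp_operator(profile$timepoints, cmp_keep)
  } else {
    outidx <- match(round(cmp_keep, 9), round(fine, 9))
    if (anyNA(outidx)) stop("grid_step must be a multiple of dt_fine")
    W <- NULL
  }
  pjun <- upstream_pjun(params, stim, t_end, dt_fine)
  if (lag != 0) {
    pjun$pJun <- stats::approx(pjun$times, pjun$pJun,
                               xout = pjun$times - lag,
                               yleft = pjun$pJun[1], rule = 2)$y
  }
  list(stim = stim, fine = fine, cmp_grid = cmp_grid, cmp_keep = cmp_keep,
       outidx = outidx, W = W, pjun = pjun)
}

new_fit_surface <- function(alpha_grid, K_grid, delay_grid, rmse, variant,
                            profile, settings) {
  # global argmin with deterministic tie-breaking: smallest alpha_m,
  # then smallest K, then smallest delay
  rm_min <- min(rmse)
  idx <- which(rmse <= rm_min, arr.ind = is.array(rmse) || is.matrix(rmse))
  if (is.matrix(idx)) {
    idx <- idx[order(idx[, 1], idx[, 2],
                     if (ncol(idx) > 2) idx[, 3] else idx[, 1])[1], ]
  } else {
    idx <- min(idx)
    idx <- c(idx)
  }
  a_hat <- alpha_grid[idx[1]]
  K_hat <- if (!is.null(K_grid)) K_grid[idx[2]] else NULL
  d_hat <- if (!is.null(delay_grid)) delay_grid[idx[length(idx)]] else NULL
  structure(list(
    alpha_grid = alpha_grid, K_grid = K_grid, delay_grid = delay_grid,
    rmse = rmse, rmse_min = rm_min,
    argmin = list(alpha_m = a_hat, K = K_hat, delay = d_hat),
    half_life_h = log(2) / a_hat,
    variant = variant, condition = profile$condition, profile_id = profile$id,
    settings = settings
  ), class = "fit_surface")
}

#' @export
print.fit_surface <- function(x, ...) {
  cat(sprintf("fit surface (%s, '%s' condition): rmse_min = %.4g\n",
              x$variant, x$condition, x$rmse_min))
  cat(sprintf("  alpha_m_hat = %.4g h^-1 (half-life %.3g h)",
              x$argmin$alpha_m, x$half_life_h))
  if (!is.null(x$argmin$K)) cat(sprintf(", K_hat = %.4g C_s", x$argmin$K))
  if (!is.null(x$argmin$delay)) cat(sprintf(", delay_hat = %.4g h", x$argmin$delay))
  cat("\n")
  invisible(x)
}

#' Scan mRNA decay rates against an expression profile
#'
#' Solves the upstream kinase/transcription-factor species once for the
#' profile's stimulus program, then integrates the target-gene equation
#' for each decay rate on the grid against the stored pJun(t), min-max
#' scales each model curve and reports the RMSE to the (linearly
#' interpolated) profile. The decay rate minimizing RMSE is the estimate;
#' its half-life is `ln 2 / alpha_m`.
#'
#' @param profile an [expression_profile()].
#' @param params model parameters ([jnk_params()]); `alpha_m` is ignored
#'   (it is the scanned axis).
#' @param variant `"mass_action"` (default) or `"hill"` (uses `params$K`
#'   and `params$n_target` in the promoter term).
#' @param n_grid number of decay-rate grid points.
#' @param alpha_range decay-rate grid bounds (h^-1), endpoints inclusive,
#'   uniform spacing; the default spans half-lives of 36 h to 30 min.
#' @param dt_fine internal integration step (h) for the target equation.
#' @param grid_step dense comparison grid step (h).
#' @param model_sampling `"profile_timepoints"` (default): the model
#'   curve is sampled at the profile's timepoints and both sides are
#'   linearly interpolated onto the dense grid by the same operator, so
#'   the objective is zero at the generating parameters of a noiseless
#'   profile. `"dense"`: the model curve enters at full resolution while
#'   only the sparse side is interpolated; the sparse side's
#'   interpolation error then biases the estimate.
#' @param lag optional shift (h) of the model curve relative to the
#'   profile clock.
#' @param t_end simulation horizon (h).
#' @return A `fit_surface` with the RMSE vector over the decay grid,
#'   argmin estimate and derived half-life.
#' @export
scan_decay <- function(profile, params = jnk_params(), variant = "mass_action",
                       n_grid = 200, alpha_range = c(0.02, 1.4),
                       dt_fine = 0.001, grid_step = 0.1, lag = 0, t_end = 8,
                       model_sampling = c("profile_timepoints", "dense")) {
  variant <- match.arg(variant, c("mass_action", "hill"))
  model_sampling <- match.arg(model_sampling)
  g <- scan_grids(profile, params, t_end, dt_fine, grid_step, lag,
                  model_sampling)
  alpha <- seq(alpha_range[1], alpha_range[2], length.out = n_grid)
  f <- scan_forcing(g$pjun, params, hill = variant == "hill",
                    K = params$K, n_target = params$n_target)
  out <- target_scan_batch(f, dt_fine, alpha, params$beta_t / alpha, g$outidx)
  rmse <- scan_rmse(out, g, profile)
  new_fit_surface(alpha, NULL, NULL, rmse, variant, profile,
                  list(n_grid = n_grid, alpha_range = alpha_range,
                       dt_fine = dt_fine, grid_step = grid_step, lag = lag,
                       t_end = t_end))
}

#' Joint scan of decay rate and promoter affinity (Hill variant)
#'
#' Two-dimensional grid scan of the Hill-promoter target model: decay
#' rates `alpha_m` crossed with half-maximal pJun concentrations `K`
#' (low K = high-affinity promoter). The global RMSE minimum gives the
#' joint estimate.
#'
#' @inheritParams scan_decay
#' @param n_target Hill coefficient of the promoter (1.8 for modest
#'   cooperativity, 4 for strong).
#' @param n_grid length-2 vector: grid sizes for `alpha_m` and `K`.
#' @param K_range affinity grid bounds (C_s).
#' @return A `fit_surface` with an `n_grid[1]` x `n_grid[2]` RMSE matrix
#'   (rows = decay rates, columns = K).
#' @export
scan_decay_affinity <- function(profile, n_target = 1.8,
                                params = jnk_params(),
                                n_grid = c(200, 200),
                                alpha_range = c(0.02, 1.4),
                                K_range = c(0.01, 3),
                                dt_fine = 0.002, grid_step = 0.1,
                                lag = 0, t_end = 8,
                                model_sampling = c("profile_timepoints",
                                                   "dense")) {
  model_sampling <- match.arg(model_sampling)
  g <- scan_grids(profile, params, t_end, dt_fine, grid_step, lag,
                  model_sampling)
  alpha <- seq(alpha_range[1], alpha_range[2], length.out = n_grid[1])
  K <- seq(K_range[1], K_range[2], length.out = n_grid[2])
  f <- scan_forcing(g$pjun, params, hill = TRUE, K = K, n_target = n_target)
  out <- target_scan_batch(f, dt_fine, alpha, params$beta_t / alpha, g$outidx)
  rmse <- scan_rmse(out, g, profile)
  fs <- new_fit_surface(alpha, K, NULL, rmse, "hill", profile,
                        list(n_target = n_target, n_grid = n_grid,
                             alpha_range = alpha_range, K_range = K_range,
                             dt_fine = dt_fine, grid_step = grid_step,
                             lag = lag, t_end = t_end))
  fs$n_target <- n_target
  fs
}

#' Scan transcriptional delays jointly with decay rate (and affinity)
#'
#' Adds a delay axis to the decay (and, for Hill variants, affinity)
#' scans: the target-gene production term reads pJun(t - tau) with
#' constant pre-simulation history. The optimum is the global RMSE
#' minimum over (alpha_m\[, K\], tau).
#'
#' @inheritParams scan_decay_affinity
#' @param variant `"mass_action_delay"` or `"hill_delay"`.
#' @param n_delay number of delay grid points.
#' @param delay_range delay bounds (h), endpoints inclusive, uniform.
#' @param n_grid decay grid size (scalar, mass-action) or length-2
#'   (decay, K) for the Hill variant.
#' @return A `fit_surface` whose `rmse` has a trailing delay dimension.
#' @export
scan_delay <- function(profile, variant = "mass_action_delay",
                       params = jnk_params(), n_delay = 25,
                       delay_range = c(0.01, 1), n_target = 1.8,
                       n_grid = NULL, alpha_range = c(0.02, 1.4),
                       K_range = c(0.01, 3), dt_fine = 0.002,
                       grid_step = 0.1, lag = 0, t_end = 8,
                       model_sampling = c("profile_timepoints", "dense")) {
  variant <- match.arg(variant, c("mass_action_delay", "hill_delay"))
  model_sampling <- match.arg(model_sampling)
  hill <- variant == "hill_delay"
  if (is.null(n_grid)) n_grid <- if (hill) c(100, 100) else 200
  g <- scan_grids(profile, params, t_end, dt_fine, grid_step, lag,
                  model_sampling)
  alpha <- seq(alpha_range[1], alpha_range[2], length.out = n_grid[1])
  K <- if (hill) seq(K_range[1], K_range[2], length.out = n_grid[2]) else NULL
  delays <- seq(delay_range[1], delay_range[2], length.out = n_delay)
  dims <- c(n_grid[1], if (hill) n_grid[2] else 1, n_delay)
  rmse <- array(NA_real_, dims)
  for (d in seq_along(delays)) {
    f <- scan_forcing(g$pjun, params, hill = hill, K = K,
                      n_target = n_target, tau = delays[d])
    out <- target_scan_batch(f, dt_fine, alpha, params$beta_t / alpha,
                             g$outidx)
    rmse[, , d] <- scan_rmse(out, g, profile)
  }
  if (!hill) rmse <- array(rmse, c(dims[1], dims[3]))
  fs_K <- if (hill) K else NULL
  settings <- list(n_delay = n_delay, delay_range = delay_range,
                   n_grid = n_grid, alpha_range = alpha_range,
                   dt_fine = dt_fine, grid_step = grid_step, lag = lag,
                   t_end = t_end)
  if (hill) settings$K_range <- K_range
  if (hill) settings$n_target <- n_target
  # argmin with tie-break alpha, then K, then delay
  fs <- new_fit_surface_delay(alpha, fs_K, delays, rmse, variant, profile,
                              settings)
  fs
}

new_fit_surface_delay <- function(alpha, K, delays, rmse, variant, profile,
                                  settings) {
  rm_min <- min(rmse)
  idx <- which(rmse <= rm_min, arr.ind = TRUE)
  if (is.null(K)) {
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]
    a_hat <- alpha[idx[1]]; K_hat <- NULL; d_hat <- delays[idx[2]]
  } else {
    idx <- idx[order(idx[, 1], idx[, 2], idx[, 3]), , drop = FALSE][1, ]
    a_hat <- alpha[idx[1]]; K_hat <- K[idx[2]]; d_hat <- delays[idx[3]]
  }
  structure(list(
    alpha_grid = alpha, K_grid = K, delay_grid = delays, rmse = rmse,
    rmse_min = rm_min,
    argmin = list(alpha_m = a_hat, K = K_hat, delay = d_hat),
    half_life_h = log(2) / a_hat, variant = variant,
    condition = profile$condition, profile_id = profile$id,
    settings = settings
  ), class = "fit_surface")
}

#' Predict the mean mRNA half-life of a gene cluster
#'
#' Runs [scan_decay()] for every per-gene profile in a cluster, converts
#' each estimated decay rate to a half-life and reports the mean with its
#' standard error (SD / sqrt(n)).
#'
#' @param profiles list of [expression_profile()] objects (one per gene,
#'   same condition).
#' @inheritParams scan_decay
#' @param ... further arguments passed to [scan_decay()].
#' @return List with `mean_half_life_h`, `sem_h` (0, flagged, for a
#'   single-gene cluster), `n_genes`, `single_gene` and `per_gene`
#'   (data.frame of per-gene estimates).
#' @export
predict_cluster_halflife <- function(profiles, params = jnk_params(),
                                     variant = "mass_action", ...) {
  if (length(profiles) < 1) stop("cluster must contain at least one gene profile")
  fits <- lapply(profiles, scan_decay, params = params, variant = variant, ...)
  hl <- vapply(fits, function(f) f$half_life_h, numeric(1))
  per_gene <- data.frame(
    id = vapply(seq_along(profiles), function(i) {
      if (is.null(profiles[[i]]$id)) paste0("gene_", i) else profiles[[i]]$id
    }, character(1)),
    alpha_m_hat = vapply(fits, function(f) f$argmin$alpha_m, numeric(1)),
    half_life_h = hl,
    rmse_min = vapply(fits, function(f) f$rmse_min, numeric(1)),
    stringsAsFactors = FALSE
  )
  n <- length(hl)
  list(mean_half_life_h = mean(hl),
       sem_h = if (n > 1) stats::sd(hl) / sqrt(n) else 0,
       n_genes = n, single_gene = n == 1, per_gene = per_gene)
}

#' Compare target-gene model variants on one profile
#'
#' Fits each candidate promoter model (mass action; Hill with modest or
#' strong cooperativity; optionally each with a transcriptional delay) by
#' its own grid scan and tabulates the minimal RMSE and optimal
#' parameters, sorted by fit quality.
#'
#' @inheritParams scan_decay
#' @param models candidate set, subset of `c("mass_action", "hill_1.8",
#'   "hill_4")`.
#' @param delay if `TRUE`, each model is also scanned over delays.
#' @param n_grid_2d grid sizes for the Hill scans.
#' @param ... further arguments passed to the scan functions.
#' @return data.frame with one row per model: `model`, `rmse_min`,
#'   `alpha_m_hat`, `half_life_h`, `K_hat`, `delay_hat`.
#' @export
compare_models <- function(profile, models = c("mass_action", "hill_1.8",
                                               "hill_4"),
                           delay = FALSE, params = jnk_params(),
                           n_grid = 200, n_grid_2d = c(100, 100), ...) {
  models <- match.arg(models, several.ok = TRUE)
  fit_one <- function(m) {
    if (m == "mass_action") {
      if (delay) scan_delay(profile, "mass_action_delay", params,
                            n_grid = n_grid, ...)
      else scan_decay(profile, params, "mass_action", n_grid = n_grid, ...)
    } else {
      nt <- if (m == "hill_1.8") 1.8 else 4
      if (delay) scan_delay(profile, "hill_delay", params, n_target = nt,
                            n_grid = n_grid_2d, ...)
      else scan_decay_affinity(profile, n_target = nt, params = params,
                               n_grid = n_grid_2d, ...)
    }
  }
  fits <- lapply(models, fit_one)
  tab <- data.frame(
    model = models,
    rmse_min = vapply(fits, function(f) f$rmse_min, numeric(1)),
    alpha_m_hat = vapply(fits, function(f) f$argmin$alpha_m, numeric(1)),
    half_life_h = vapply(fits, function(f) f$half_life_h, numeric(1)),
    K_hat = vapply(fits, function(f) {
      if (is.null(f$argmin$K)) NA_real_ else f$argmin$K
    }, numeric(1)),
    delay_hat = vapply(fits, function(f) {
      if (is.null(f$argmin$delay)) NA_real_ else f$argmin$delay
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  tab[order(tab$rmse_min), ]
}
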