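# Core seven-species ODE model of JNK -> pJun -> target-gene signaling.

.jnk_species <- c("inactive_cJun", "pJun", "cJun_mRNA", "target_gene",
                  "active_JNK", "DUSP1_mRNA", "DUSP1")

.jnk_variants <- c("mass_action", "hill", "mass_action_delay", "hill_delay")

# Hill activation term with the continuity convention 0^n/(0 + K^n) = 0.
hill_term <- function(x, K, n) {
  ifelse(x <= 0, 0, x^n / (x^n + K^n))
}

#' Right-hand side of the JNK signaling model
#'
#' Pure-R reference implementation of the seven coupled rate equations:
#' inactive c-Jun (translation, degradation, JNK-driven phosphorylation via
#' a Hill term), pJun (phosphorylation in, first-order loss), c-Jun mRNA
#' (basal + pJun autoregulation, turnover), target-gene mRNA (basal +
#' pJun-driven production -- linear in the mass-action variant, a Hill
#' function of pJun in the `hill` variant -- and first-order decay), active
#' JNK (stimulus-driven production, turnover, DUSP1-mediated saturating
#' dephosphorylation), DUSP1 mRNA and DUSP1 protein (pJun-driven negative
#' feedback loop). A compiled translation of the same equations is used for
#' bulk integration; this function is the reference the oracle integrator
#' uses.
#'
#' @param state named numeric vector with the seven species (see
#'   [steady_state()] for the order).
#' @param t time (h); the autonomous equations ignore it, it is accepted
#'   for solver compatibility.
#' @param params a [jnk_params()] object.
#' @param c_value stimulus value, 0 or 1.
#' @param variant `"mass_action"` or `"hill"` (the delay variants share
#'   these right-hand sides with a lagged pJun input).
#' @param pJun_lagged value of pJun(t - tau) to use in the target-gene
#'   production term instead of the instantaneous pJun (delay variants).
#' @return Named numeric vector of time derivatives (C_s h^-1).
#' @export
jnk_rhs <- function(state, t = 0, params = jnk_params(), c_value = 0,
                    variant = "mass_action", pJun_lagged = NULL) {
  variant <- match.arg(variant, c("mass_action", "hill"))
  if (any(!is.finite(state))) stop("state components must be finite")
  if (any(state < -1e-6)) {
    stop("negative state components beyond tolerance: integration fault")
  }
  s <- pmax(as.numeric(state), 0)
  names(s) <- .jnk_species
  p <- params
  hJ <- hill_term(s["active_JNK"], p$T, p$n_phos)
  hD <- hill_term(s["DUSP1"], p$Td, p$n_phos)
  phos <- p$beta_jp * s["inactive_cJun"] * hJ
  pj_drive <- if (is.null(pJun_lagged)) s["pJun"] else max(pJun_lagged, 0)
  prod_target <- if (variant == "hill") {
    p$beta_t + p$beta_tj * hill_term(pj_drive, p$K, p$n_target)
  } else {
    p$beta_t + p$beta_tj * pj_drive
  }
  d <- c(
    inactive_cJun = p$beta_j * s["cJun_mRNA"] - p$alpha_j * s["inactive_cJun"] - phos,
    pJun = phos - p$alpha_junp * s["pJun"],
    cJun_mRNA = p$beta_jmi + p$beta_mj * s["pJun"] - p$alpha_jm * s["cJun_mRNA"],
    target_gene = prod_target - p$alpha_m * s["target_gene"],
    active_JNK = p$beta_jnkp * c_value - p$alpha_jnkp * s["active_JNK"] -
      p$alpha_djnkp * s["active_JNK"] * hD,
    DUSP1_mRNA = p$beta_md * s["pJun"] - p$alpha_dusp * s["DUSP1_mRNA"],
    DUSP1 = p$beta_dusp * s["DUSP1_mRNA"] - p$alpha_dp * s["DUSP1"]
  )
  names(d) <- .jnk_species
  d
}

#' Resting (stimulus-off) steady state of the model
#'
#' With c = 0 the kinase arm is off (active JNK, pJun, DUSP1 mRNA and
#' DUSP1 all zero) and the remaining species settle at their basal
#' balance: cJun mRNA = beta_jmi / alpha_jm, inactive c-Jun =
#' beta_j * cJun mRNA / alpha_j, target gene = beta_t / alpha_m (the Hill
#' variant has the same fixed point because the promoter term vanishes at
#' pJun = 0). Used as the pre-treatment initial condition.
#'
#' @inheritParams jnk_rhs
#' @return Named numeric vector of the seven species at rest.
#' @export
steady_state <- function(params = jnk_params(), variant = "mass_action") {
  p <- params
  cjm <- p$beta_jmi / p$alpha_jm
  s <- c(
    inactive_cJun = p$beta_j * cjm / p$alpha_j,
    pJun = 0,
    cJun_mRNA = cjm,
    target_gene = p$beta_t / p$alpha_m,
    active_JNK = 0,
    DUSP1_mRNA = 0,
    DUSP1 = 0
  )
  rhs_variant <- if (grepl("hill", variant)) "hill" else "mass_action"
  d <- jnk_rhs(s, 0, params, c_value = 0, variant = rhs_variant)
  if (max(abs(d)) >= 1e-8) {
    stop("steady-state residual exceeds 1e-8; check parameters")
  }
  s
}

# parameter vector in the order the compiled right-hand side expects
compiled_parms <- function(params, c_value, variant) {
  c(params$beta_j, params$alpha_j, params$beta_jp, params$n_phos,
    params$T, params$alpha_junp, params$beta_jmi, params$beta_mj,
    params$alpha_jm, params$beta_t, params$beta_tj, params$alpha_m,
    params$beta_jnkp, params$alpha_jnkp, params$alpha_djnkp, params$Td,
    params$beta_md, params$alpha_dusp, params$beta_dusp, params$alpha_dp,
    params$n_target, params$K, c_value,
    as.numeric(grepl("hill", variant)))
}

#' Simulate the JNK signaling model
#'
#' Integrates the seven-species model under a piecewise-constant stimulus.
#' Integration is restarted at every stimulus switch time so the step
#' discontinuities are exact; within segments the adaptive `lsoda` solver
#' runs on a compiled right-hand side (rtol 1e-8, atol 1e-10). The delay
#' variants (`mass_action_delay`, `hill_delay`) use pJun(t - tau) in the
#' target-gene production term, integrated with [deSolve::dede()] and a
#' constant pre-simulation history equal to the initial state.
#'
#' @param params a [jnk_params()] object.
#' @param stimulus a [stimulus_program()].
#' @param t_end simulation horizon (h).
#' @param dt_out output grid step (h).
#' @param variant one of `"mass_action"`, `"hill"`, `"mass_action_delay"`,
#'   `"hill_delay"`.
#' @param init optional initial state; defaults to [steady_state()].
#' @param rtol,atol solver tolerances.
#' @return Object of class `jnk_trajectory`: list with `times`, `states`
#'   (matrix, one row per time, columns the seven species), `params`,
#'   `stimulus`, `variant`.
#' @examples
#' traj <- simulate_jnk(jnk_params(), make_stimulus("transient"), t_end = 2)
#' max(traj$states[, "pJun"])
#' @export
simulate_jnk <- function(params = jnk_params(), stimulus = make_stimulus("sustained"),
                         t_end = 8, dt_out = 0.05, variant = "mass_action",
                         init = NULL, rtol = 1e-8, atol = 1e-10) {
  variant <- match.arg(variant, .jnk_variants)
  if (t_end <= 0) stop("t_end must be > 0")
  if (dt_out <= 0) stop("dt_out must be > 0")
  delayed <- grepl("delay", variant)
  if (!delayed && params$tau > 0) {
    stop("tau > 0 requires a delay variant (mass_action_delay or hill_delay)")
  }
  if (is.null(init)) init <- steady_state(params, variant)
  grid <- seq(0, t_end, by = dt_out)
  if (grid[length(grid)] < t_end) grid <- c(grid, t_end)

  states <- if (delayed) {
    simulate_dede(params, stimulus, grid, variant, init, rtol, atol)
  } else {
    simulate_piecewise(params, stimulus, grid, t_end, variant, init, rtol, atol)
  }
  colnames(states) <- .jnk_species
  if (min(states) < -1e-9) {
    stop(sprintf("solver produced negative concentrations (min %.3g) at t = %.3g h",
                 min(states), grid[which(states == min(states), arr.ind = TRUE)[1, 1]]))
  }
  structure(list(times = grid, states = states, params = params,
                 stimulus = stimulus, variant = variant,
                 solver = list(rtol = rtol, atol = atol, dt_out = dt_out)),
            class = "jnk_trajectory")
}

simulate_piecewise <- function(params, stimulus, grid, t_end, variant, init,
                               rtol, atol) {
  sw <- stimulus_switch_times(stimulus, t_end)
  bounds <- unique(c(0, sw, t_end))
  states <- matrix(NA_real_, length(grid), 7)
  states[1, ] <- init
  y <- as.numeric(init)
  for (i in seq_len(length(bounds) - 1)) {
    a <- bounds[i]; b <- bounds[i + 1]
    cv <- stimulus_value(stimulus, a)
    inner <- grid[grid > a + 1e-12 & grid <= b + 1e-12]
    tt <- unique(c(a, inner, b))
    sol <- deSolve::lsoda(y, tt, func = "jnk_derivs",
                          parms = compiled_parms(params, cv, variant),
                          dllname = "jnkdyn", initfunc = "jnk_initmod",
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) {
      stop(sprintf("solver failure in segment starting at t = %.3g h", a))
    }
    idx <- match(round(inner, 10), round(sol[, 1], 10))
    states[match(round(inner, 10), round(grid, 10)), ] <- sol[idx, -1]
    y <- sol[nrow(sol), -1]
  }
  states
}

simulate_dede <- function(params, stimulus, grid, variant, init, rtol, atol) {
  tau <- params$tau
  rhs_variant <- if (grepl("hill", variant)) "hill" else "mass_action"
  init_pjun <- as.numeric(init["pJun"])
  func <- function(t, y, parms) {
    names(y) <- .jnk_species
    lag <- if (tau <= 0 || t - tau <= grid[1]) {
      init_pjun
    } else {
      deSolve::lagvalue(t - tau, 2)
    }
    list(jnk_rhs(y, t, params, c_value = stimulus_value(stimulus, t),
                 variant = rhs_variant, pJun_lagged = lag))
  }
  sol <- deSolve::dede(as.numeric(init), grid, func, parms = NULL,
                       rtol = rtol, atol = atol)
  if (nrow(sol) < length(grid)) stop("delay solver failed before t_end")
  unname(sol[, -1, drop = FALSE])
}

#' Sample the target-gene trajectory at requested times
#'
#' Linear interpolation on the stored output grid; exact at grid points.
#'
#' @param traj a `jnk_trajectory`.
#' @param times times (h) within the simulated range.
#' @return Numeric vector of target-gene values (C_s).
#' @export
sample_target <- function(traj, times) {
  rng <- range(traj$times)
  if (any(times < rng[1] - 1e-12) || any(times > rng[2] + 1e-12)) {
    stop("requested times outside the simulated range [",
         rng[1], ", ", rng[2], "] h; extrapolation is not supported")
  }
  stats::approx(traj$times, traj$states[, "target_gene"], xout = times,
                rule = 1)$y
}

#' @export
print.jnk_trajectory <- function(x, ...) {
  cat(sprintf("JNK model trajectory: variant '%s', stimulus '%s', %d times on [%g, %g] h\n",
              x$variant, x$stimulus$label, length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Count pulses in a simulated time course
#'
#' Identifies strict local maxima of a series (plateaus of equal values
#' collapse to their leftmost point; endpoints are never peaks) on the
#' min-max scaled curve and keeps those that qualify as distinct pulses:
#' scaled height at least `min_height` and topographic prominence at
#' least `min_prominence` of the dynamic range. Prominence is the rise
#' above the higher of the two saddle minima found by scanning each side
#' until the signal exceeds the peak; the signal's dominant peak (no
#' higher terrain on either side) is measured from the global minimum, so
#' it always counts once `min_height` is met.
#'
#' @param x numeric series (e.g. a species trajectory).
#' @param times optional time grid, used to report peak times.
#' @param min_height minimum scaled peak height in \[0, 1\].
#' @param min_prominence minimum scaled prominence in \[0, 1\]; 0 keeps
#'   every strict local maximum above `min_height`.
#' @return List with `n_peaks`, `peak_index`, `peak_times` (NULL if no
#'   `times`), `heights` (scaled), `prominence` (scaled).
#' @export
count_peaks <- function(x, times = NULL, min_height = 0, min_prominence = 0) {
  x <- as.numeric(x)
  rng <- diff(range(x))
  s <- if (rng > 0) (x - min(x)) / rng else rep(0, length(x))
  r <- rle(s)
  v <- r$values
  n <- length(v)
  first_idx <- cumsum(c(1, r$lengths[-n]))
  if (n < 3) {
    return(list(n_peaks = 0L, peak_index = integer(0),
                peak_times = if (is.null(times)) NULL else numeric(0),
                heights = numeric(0), prominence = numeric(0)))
  }
  is_peak <- c(FALSE, v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n], FALSE)
  pk <- which(is_peak)
  # topographic prominence: drop to the higher of the two saddle minima,
  # scanning each side until the signal rises above the peak (or ends)
  prom <- vapply(pk, function(i) {
    left <- v[i]; left_higher <- FALSE
    for (j in rev(seq_len(i - 1))) {
      if (v[j] > v[i]) { left_higher <- TRUE; break }
      left <- min(left, v[j])
    }
    right <- v[i]; right_higher <- FALSE
    for (j in seq(i + 1, n)) {
      if (v[j] > v[i]) { right_higher <- TRUE; break }
      right <- min(right, v[j])
    }
    if (!left_higher && !right_higher) return(v[i] - min(v))
    v[i] - max(left, right)
  }, numeric(1))
  keep <- v[pk] >= min_height & prom >= min_prominence
  pk <- pk[keep]; prom <- prom[keep]
  idx <- as.integer(first_idx[pk])
  list(n_peaks = length(idx), peak_index = idx,
       peak_times = if (is.null(times)) NULL else times[idx],
       heights = v[pk], prominence = prom)
}
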