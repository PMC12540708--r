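# Fixed-step explicit Euler integration of the model.
#
# Deliberately naive and independent of the compiled solver path: it uses
# the pure-R right-hand side and no adaptivity, so it serves as a
# cross-check oracle for the adaptive compiled integration.

#' Fixed-step Euler simulation (validation integrator)
#'
#' Explicit Euler at a user-chosen step, built on the pure-R [jnk_rhs()].
#' Far slower and less accurate than [simulate_jnk()]; intended to
#' validate the adaptive compiled solver, not for production use.
#'
#' @inheritParams simulate_jnk
#' @param dt Euler step (h); also the output grid step.
#' @return A `jnk_trajectory` (states on the Euler grid).
#' @export
euler_simulate <- function(params = jnk_params(),
                           stimulus = make_stimulus("sustained"),
                           t_end = 8, dt = 1e-4, variant = "mass_action",
                           init = NULL) {
  variant <- match.arg(variant, c("mass_action", "hill"))
  if (is.null(init)) init <- steady_state(params, variant)
  times <- seq(0, t_end, by = dt)
  n <- length(times)
  states <- matrix(NA_real_, n, 7, dimnames = list(NULL, .jnk_species))
  y <- as.numeric(init)
  names(y) <- .jnk_species
  cvals <- stimulus_value(stimulus, times)
  for (i in seq_len(n - 1)) {
    states[i, ] <- y
    y <- y + dt * jnk_rhs(y, times[i], params, cvals[i], variant)
  }
  states[n, ] <- y
  structure(list(times = times, states = states, params = params,
                 stimulus = stimulus, variant = variant,
                 solver = list(method = "euler", dt = dt)),
            class = "jnk_trajectory")
}
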