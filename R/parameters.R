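# Model parameters and global sensitivity ranges.

# canonical symbol order; also the order of the compiled parameter vector
.jnk_param_names <- c(
  "beta_j", "alpha_j", "beta_jp", "n_phos", "T", "alpha_junp",
  "beta_jmi", "beta_mj", "alpha_jm", "beta_t", "beta_tj", "alpha_m",
  "beta_jnkp", "alpha_jnkp", "alpha_djnkp", "Td", "beta_md",
  "alpha_dusp", "beta_dusp", "alpha_dp", "n_target", "K", "tau"
)

#' Model parameters for the JNK signaling model
#'
#' Construct the full parameter set of the seven-species JNK -> pJun ->
#' target-gene model. Defaults are the literature-anchored values used for
#' all base simulations; rates are in h^-1, concentrations in simulated
#' concentration units (C_s).
#'
#' @param beta_j c-Jun protein production rate (h^-1).
#' @param alpha_j c-Jun protein degradation rate (h^-1).
#' @param beta_jp saturating production rate of pJun (h^-1).
#' @param n_phos Hill coefficient shared by the c-Jun phosphorylation and
#'   DUSP1-mediated JNK dephosphorylation terms (dimensionless).
#' @param T active JNK concentration for half-maximal c-Jun phosphorylation
#'   (C_s).
#' @param alpha_junp pJun degradation rate (h^-1).
#' @param beta_jmi basal c-Jun mRNA production rate (C_s h^-1).
#' @param beta_mj pJun-dependent c-Jun mRNA production rate (h^-1),
#'   the autoregulatory feedback.
#' @param alpha_jm c-Jun mRNA turnover rate (h^-1).
#' @param beta_t basal target-gene mRNA production rate (C_s h^-1).
#' @param beta_tj pJun-dependent target-gene mRNA production rate (h^-1).
#' @param alpha_m target-gene mRNA degradation rate (h^-1). The central
#'   tunable of the fitting module; the default corresponds to a 1-h
#'   half-life.
#' @param beta_jnkp active JNK production rate per unit stimulus (C_s h^-1).
#' @param alpha_jnkp active JNK degradation rate (h^-1).
#' @param alpha_djnkp saturating DUSP1-mediated JNK dephosphorylation rate
#'   (h^-1).
#' @param Td DUSP1 concentration for half-maximal JNK dephosphorylation
#'   (C_s).
#' @param beta_md pJun-dependent DUSP1 mRNA production rate (h^-1).
#' @param alpha_dusp DUSP1 mRNA degradation rate (h^-1).
#' @param beta_dusp DUSP1 protein production rate (h^-1).
#' @param alpha_dp DUSP1 protein degradation rate (h^-1).
#' @param n_target Hill coefficient for target-gene transcription
#'   (Hill variant only).
#' @param K pJun concentration for half-maximal target transcription
#'   (C_s; Hill variant only).
#' @param tau transcription delay (h; delay variants only).
#' @return An object of class `jnk_params`: a named list of the 23
#'   parameters above.
#' @examples
#' p <- jnk_params(alpha_m = log(2) / 0.5) # 30-min mRNA half-life
#' p$alpha_m
#' @export
jnk_params <- function(beta_j = 3, alpha_j = 0.5, beta_jp = 3, n_phos = 4,
                       T = 1, alpha_junp = 2.1, beta_jmi = 1, beta_mj = 1.5,
                       alpha_jm = 2.1, beta_t = 1, beta_tj = 3,
                       alpha_m = 0.693, beta_jnkp = 10, alpha_jnkp = 7.5,
                       alpha_djnkp = 50, Td = 0.2, beta_md = 0.25,
                       alpha_dusp = 2.1, beta_dusp = 1, alpha_dp = 0.693,
                       n_target = 1.8, K = 1, tau = 0) {
  p <- list(
    beta_j = beta_j, alpha_j = alpha_j, beta_jp = beta_jp, n_phos = n_phos,
    T = T, alpha_junp = alpha_junp, beta_jmi = beta_jmi, beta_mj = beta_mj,
    alpha_jm = alpha_jm, beta_t = beta_t, beta_tj = beta_tj,
    alpha_m = alpha_m, beta_jnkp = beta_jnkp, alpha_jnkp = alpha_jnkp,
    alpha_djnkp = alpha_djnkp, Td = Td, beta_md = beta_md,
    alpha_dusp = alpha_dusp, beta_dusp = beta_dusp, alpha_dp = alpha_dp,
    n_target = n_target, K = K, tau = tau
  )
  validate_jnk_params(p)
  structure(p, class = "jnk_params")
}

validate_jnk_params <- function(p) {
  vals <- unlist(p[.jnk_param_names])
  if (anyNA(vals) || any(!is.finite(vals))) {
    stop("all model parameters must be finite numbers", call. = FALSE)
  }
  pos <- setdiff(.jnk_param_names, "tau")
  bad <- pos[unlist(p[pos]) <= 0]
  if (length(bad)) {
    stop("parameters must be strictly positive: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (p$tau < 0) stop("tau must be >= 0", call. = FALSE)
  invisible(p)
}

#' Update model parameters by symbol name
#'
#' @param params a [jnk_params()] object.
#' @param overrides named list or vector of parameter values; unknown
#'   symbols are rejected.
#' @return The updated `jnk_params` object.
#' @export
update_params <- function(params, overrides) {
  if (length(overrides) == 0) return(params)
  nm <- names(overrides)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("parameter overrides must be named", call. = FALSE)
  }
  unknown <- setdiff(nm, .jnk_param_names)
  if (length(unknown)) {
    stop("unknown parameter symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  for (s in nm) params[[s]] <- as.numeric(overrides[[s]])
  validate_jnk_params(params)
  structure(params, class = "jnk_params")
}

#' @export
print.jnk_params <- function(x, ...) {
  cat("JNK model parameters (rates h^-1, concentrations C_s):\n")
  print(unlist(x))
  invisible(x)
}

#' Parameter ranges for global sensitivity analysis
#'
#' The uniform sampling ranges for the 20 scanned parameters of the model
#' (Hill coefficients and concentration scales included; the promoter
#' parameters `n_target`/`K` of the Hill variant and the delay `tau` are
#' not part of the base-model scan).
#'
#' @return A data.frame with columns `symbol`, `low`, `high`.
#' @examples
#' r <- sensitivity_ranges()
#' nrow(r) # 20 parameters
#' @export
sensitivity_ranges <- function() {
  data.frame(
    symbol = c("beta_j", "alpha_j", "beta_jp", "n_phos", "T", "alpha_junp",
               "beta_jmi", "beta_mj", "alpha_jm", "beta_t", "beta_tj",
               "alpha_m", "beta_jnkp", "alpha_jnkp", "alpha_djnkp", "Td",
               "beta_md", "alpha_dusp", "beta_dusp", "alpha_dp"),
    low  = c(2, 0.3, 2, 1, 0.1, 0.5, 0.1, 1, 0.3, 0.1, 2,
             0.02, 5, 3, 30, 0.01, 0.1, 0.3, 0.1, 0.3),
    high = c(4, 1, 4, 10, 2, 3, 2, 3, 3, 2, 4,
             1.4, 15, 10, 70, 1, 2, 3, 2, 2.1),
    stringsAsFactors = FALSE
  )
}

# run code with a locally-seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
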