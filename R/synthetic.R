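# Synthetic-data generators with known ground truth for every pipeline
# input: scaled expression time courses from the model, single-cell KTR
# traces, and DEG tables for the filtering stage. Each generator returns
# its generating parameters (the truth) alongside the data, sufficient to
# regenerate bit-identically.

#' Generate scaled expression profiles from the model
#'
#' Simulates the target gene for each supplied decay rate under one
#' stimulus program, samples the trajectory at the expression timepoints,
#' min-max scales per gene and adds clipped Gaussian noise. The noiseless
#' cores are exactly what the fitting module's scans reproduce, so
#' parameter-recovery tests have known truth.
#'
#' @param condition `"sustained"`, `"transient"` or `"pulsed"`.
#' @param alpha_m vector of per-gene decay rates (h^-1), in (0, 2].
#' @param variant `"mass_action"` (default) or `"hill"`.
#' @param K per-gene promoter affinities (C_s), recycled; Hill variant
#'   only.
#' @param n_target promoter Hill coefficient (Hill variant only).
#' @param noise_sd additive Gaussian noise SD on the scaled values
#'   (clipped back to \[0, 1\]).
#' @param seed RNG seed for the noise.
#' @param params base model parameters.
#' @param timepoints sampling times (h).
#' @return List of class `synthetic_profiles`: `profiles` (genes x
#'   timepoints matrix in \[0, 1\]), `noiseless` (same without noise),
#'   `truth` (data.frame of generating parameters per gene), `condition`,
#'   `timepoints`.
#' @export
gen_expression_profiles <- function(condition, alpha_m,
                                    variant = "mass_action", K = NULL,
                                    n_target = 1.8, noise_sd = 0, seed = 1,
                                    params = jnk_params(),
                                    timepoints = c(0, 2, 4, 6, 8)) {
  variant <- match.arg(variant, c("mass_action", "hill"))
  if (any(alpha_m <= 0) || any(alpha_m > 2)) {
    stop("alpha_m values must lie in (0, 2]")
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  n_genes <- length(alpha_m)
  if (is.null(K)) K <- params$K
  K <- rep_len(K, n_genes)
  dt_fine <- 0.002
  t_end <- max(timepoints)
  stim <- make_stimulus(condition)
  fine <- seq(0, t_end, by = dt_fine)
  outidx <- match(round(timepoints, 9), round(fine, 9))
  if (anyNA(outidx)) stop("timepoints must be multiples of 0.002 h")
  pjun <- upstream_pjun(params, stim, t_end, dt_fine)
  M <- matrix(NA_real_, n_genes, length(timepoints))
  if (variant == "mass_action") {
    f <- scan_forcing(pjun, params, hill = FALSE)
    out <- target_scan_batch(f, dt_fine, alpha_m, params$beta_t / alpha_m,
                             outidx)
    M <- t(matrix(out, nrow = length(timepoints)))
  } else {
    for (i in seq_len(n_genes)) {
      f <- scan_forcing(pjun, params, hill = TRUE, K = K[i],
                        n_target = n_target)
      out <- target_scan_batch(f, dt_fine, alpha_m[i],
                               params$beta_t / alpha_m[i], outidx)
      M[i, ] <- as.numeric(out)
    }
  }
  noiseless <- t(apply(M, 1, minmax_scale))
  profiles <- if (noise_sd > 0) {
    noise <- with_local_seed(seed,
                             matrix(stats::rnorm(length(noiseless), 0, noise_sd),
                                    nrow = n_genes))
    pmin(pmax(noiseless + noise, 0), 1)
  } else {
    noiseless
  }
  gene_ids <- sprintf("g%03d", seq_len(n_genes))
  rownames(profiles) <- rownames(noiseless) <- gene_ids
  colnames(profiles) <- colnames(noiseless) <- paste0("t_", timepoints, "h")
  truth <- data.frame(gene_id = gene_ids, alpha_m = alpha_m,
                      K = if (variant == "hill") K else NA_real_,
                      variant = variant, condition = condition,
                      noise_sd = noise_sd, seed = seed,
                      stringsAsFactors = FALSE)
  structure(list(profiles = profiles, noiseless = noiseless, truth = truth,
                 condition = condition, timepoints = timepoints),
            class = "synthetic_profiles")
}

#' Expression profile view of one synthetic gene
#'
#' @param sp a [gen_expression_profiles()] result.
#' @param i gene index or id.
#' @return An [expression_profile()].
#' @export
synthetic_profile <- function(sp, i) {
  expression_profile(sp$condition, sp$profiles[i, ], sp$timepoints,
                     id = if (is.character(i)) i else rownames(sp$profiles)[i])
}

#' Generate single-cell KTR traces
#'
#' Responder cells receive the model's own active-JNK trajectory under the
#' requested stimulus pattern, rescaled to C/N units (baseline 1, peak
#' `peak_height_mult`), so the synthetic traces inherit realistic rise and
#' washout decay shapes; a double-sigmoid bump alternative is available
#' for speed. Non-responders stay at baseline. Multiplicative Gaussian
#' noise is applied per frame.
#'
#' @param pattern `"sustained"`, `"transient"`, `"pulsed"` or `"none"`.
#' @param n_cells number of cells.
#' @param responder_fraction fraction of cells that respond.
#' @param peak_height_mult peak C/N ratio as a multiple of baseline (> 1).
#' @param noise_sd multiplicative noise SD.
#' @param frame_interval frame spacing (h), default 10 min.
#' @param pre_frames number of pre-treatment baseline frames.
#' @param t_end last frame time (h).
#' @param seed RNG seed.
#' @param params model parameters for the JNK trajectory shape.
#' @param shape `"model"` (active-JNK trajectory) or `"sigmoid"`.
#' @return List of class `synthetic_traces`: `traces` (list of
#'   [cell_trace()]), `truth` (data.frame: cell_id, responder,
#'   programmed_pulses), plus the generator settings.
#' @export
gen_cell_traces <- function(pattern, n_cells, responder_fraction = 1,
                            peak_height_mult = 2, noise_sd = 0,
                            frame_interval = 1 / 6, pre_frames = 4,
                            t_end = 8.5, seed = 1, params = jnk_params(),
                            shape = c("model", "sigmoid")) {
  shape <- match.arg(shape)
  if (responder_fraction < 0 || responder_fraction > 1) {
    stop("responder_fraction must lie in [0, 1]")
  }
  if (peak_height_mult <= 1) stop("peak_height_mult must be > 1")
  stim <- make_stimulus(pattern)
  times <- seq(-pre_frames * frame_interval, t_end, by = frame_interval)
  post <- times[times >= 0]
  bump <- if (pattern == "none") {
    rep(0, length(post))
  } else if (shape == "model") {
    traj <- simulate_jnk(params, stim, t_end = t_end, dt_out = frame_interval)
    j <- stats::approx(traj$times, traj$states[, "active_JNK"],
                       xout = post, rule = 2)$y
    j / max(j)
  } else {
    iv <- stim$on_intervals
    b <- rep(0, length(post))
    for (i in seq_len(nrow(iv))) {
      s <- iv[i, 1]; e <- min(iv[i, 2], t_end)
      rise <- stats::plogis((post - s) / 0.08)
      fall <- ifelse(post <= e, 1, exp(-(post - e) / 0.3))
      b <- pmax(b, rise * fall)
    }
    b / max(b)
  }
  programmed <- switch(pattern, none = 0L, sustained = 1L,
                       transient = 1L, pulsed = nrow(stim$on_intervals))
  dat <- with_local_seed(seed, {
    responder <- stats::runif(n_cells) < responder_fraction
    noise <- matrix(if (noise_sd > 0)
      stats::rnorm(n_cells * length(times), 0, noise_sd) else 0,
      nrow = n_cells)
    list(responder = responder, noise = noise)
  })
  traces <- lapply(seq_len(n_cells), function(i) {
    v <- rep(1, length(times))
    if (dat$responder[i]) {
      v[times >= 0] <- 1 + (peak_height_mult - 1) * bump
    }
    v <- pmax(v * (1 + dat$noise[i, ]), 0.05)
    cell_trace(sprintf("cell_%03d", i), times, v,
               n_baseline_frames = pre_frames, treatment_time = 0)
  })
  truth <- data.frame(
    cell_id = sprintf("cell_%03d", seq_len(n_cells)),
    responder = dat$responder,
    programmed_pulses = ifelse(dat$responder, programmed, 0L),
    stringsAsFactors = FALSE
  )
  structure(list(traces = traces, truth = truth, pattern = pattern,
                 peak_height_mult = peak_height_mult, noise_sd = noise_sd,
                 frame_interval = frame_interval, pre_frames = pre_frames,
                 t_end = t_end, seed = seed, shape = shape),
            class = "synthetic_traces")
}

#' Generate a DEG table with factorial pass/fail structure
#'
#' Each gene passes or fails each of the four filter criteria (FDR, fold
#' change, expression level, biotype) independently with the given
#' probabilities; the expected filtered set is the genes passing all
#' four.
#'
#' @param n_genes number of genes.
#' @param pass_fraction named numeric vector with entries `fdr`,
#'   `log2fc`, `max_group_mean`, `biotype`, each in \[0, 1\].
#' @param condition condition label written to the table.
#' @param timepoints fold-change timepoints (h).
#' @param seed RNG seed.
#' @return List: `table` (DEG data.frame), `expected` (gene ids passing
#'   all criteria), `truth` (per-gene pass/fail matrix).
#' @export
gen_deg_table <- function(n_genes,
                          pass_fraction = c(fdr = 1, log2fc = 1,
                                            max_group_mean = 1, biotype = 1),
                          condition = "sustained",
                          timepoints = c(2, 4, 6, 8), seed = 1) {
  need <- c("fdr", "log2fc", "max_group_mean", "biotype")
  if (!all(need %in% names(pass_fraction))) {
    stop("pass_fraction needs entries: ", paste(need, collapse = ", "))
  }
  with_local_seed(seed, {
    pass <- vapply(need, function(cr) {
      stats::runif(n_genes) < pass_fraction[[cr]]
    }, logical(n_genes))
    pass <- matrix(pass, nrow = n_genes,
                   dimnames = list(NULL, need))
    nt <- length(timepoints)
    fc <- matrix(stats::runif(n_genes * nt, -0.9, 0.9), n_genes)
    for (i in which(pass[, "log2fc"])) {
      j <- sample(nt, 1)
      fc[i, j] <- sample(c(-1, 1), 1) * stats::runif(1, 1.2, 3)
    }
    table <- data.frame(
      gene_id = sprintf("g%04d", seq_len(n_genes)),
      condition = condition,
      biotype = ifelse(pass[, "biotype"], "protein_coding",
                       sample(c("lincRNA", "pseudogene", "miRNA"),
                              n_genes, replace = TRUE)),
      fdr = ifelse(pass[, "fdr"], stats::runif(n_genes, 1e-6, 0.049),
                   stats::runif(n_genes, 0.051, 1)),
      max_group_mean = ifelse(pass[, "max_group_mean"],
                              stats::runif(n_genes, 1.5, 100),
                              stats::runif(n_genes, 0.05, 0.95)),
      stringsAsFactors = FALSE
    )
    fc_df <- as.data.frame(fc)
    names(fc_df) <- paste0("log2fc_", timepoints, "h")
    table <- cbind(table, fc_df)
    expected <- table$gene_id[rowSums(pass) == 4]
    list(table = table, expected = expected,
         truth = cbind(data.frame(gene_id = table$gene_id), pass))
  })
}

#' Generate a DEG table of three dynamic archetypes
#'
#' Builds a filter-ready DEG table whose passing genes follow three
#' well-separated time-course archetypes -- gradual induction
#' ("sustained-like"), early peak with decline ("transient-like") and
#' immediate constant induction ("flat-high") -- plus decoy genes that
#' fail the biotype filter. Used to validate the
#' filter -> scale -> cluster pipeline against known membership.
#'
#' @param n_per_archetype genes per archetype.
#' @param noise_sd Gaussian noise SD on the fold-change shapes.
#' @param n_decoys non-protein-coding decoy genes.
#' @param condition condition label.
#' @param seed RNG seed.
#' @return List: `table` (DEG data.frame), `truth` (data.frame gene_id,
#'   archetype), `archetypes` (shape matrix at 2/4/6/8 h).
#' @export
gen_archetype_deg_table <- function(n_per_archetype = 50, noise_sd = 0.05,
                                    n_decoys = 10, condition = "sustained",
                                    seed = 1) {
  # log2 fold-change shapes at 2/4/6/8 h, all clearing the |fc| > 1 filter
  shapes <- rbind(
    sustained_like = c(0.8, 1.6, 2.4, 3.2),
    transient_like = c(3.0, 1.6, 0.6, 0.2),
    flat_high = c(2.4, 2.5, 2.4, 2.5)
  )
  n_arch <- nrow(shapes)
  n <- n_per_archetype * n_arch
  with_local_seed(seed, {
    arch <- rep(rownames(shapes), each = n_per_archetype)
    fc <- shapes[arch, , drop = FALSE] +
      matrix(stats::rnorm(n * 4, 0, noise_sd), n)
    ids <- sprintf("arch_%03d", seq_len(n))
    table <- data.frame(
      gene_id = c(ids, sprintf("decoy_%02d", seq_len(n_decoys))),
      condition = condition,
      biotype = c(rep("protein_coding", n), rep("lincRNA", n_decoys)),
      fdr = c(stats::runif(n, 1e-6, 0.04), stats::runif(n_decoys, 1e-6, 0.04)),
      max_group_mean = stats::runif(n + n_decoys, 2, 50),
      stringsAsFactors = FALSE
    )
    fc_all <- rbind(fc, shapes[sample(n_arch, n_decoys, replace = TRUE), ])
    fc_df <- as.data.frame(fc_all)
    names(fc_df) <- paste0("log2fc_", c(2, 4, 6, 8), "h")
    rownames(fc_df) <- NULL
    table <- cbind(table, fc_df)
    list(table = table,
         truth = data.frame(gene_id = ids, archetype = arch,
                            stringsAsFactors = FALSE),
         archetypes = shapes)
  })
}
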