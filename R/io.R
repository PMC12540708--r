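# Readers and writers for the pipeline's tabular formats, plus run
# configuration handling. Gene tables are tab-separated, trace tables
# comma-separated (matching common exports); all files carry headers.

#' Read single-cell traces from CSV
#'
#' Long format with columns `cell_id`, `time_h`, `cn_ratio`; rows may be
#' in any order.
#'
#' @param path CSV file.
#' @param n_baseline_frames,treatment_time passed to [cell_trace()].
#' @return List of [cell_trace()] objects (one per cell, ordered by id).
#' @export
read_traces <- function(path, n_baseline_frames = 4, treatment_time = 0) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "time_h", "cn_ratio")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("trace file is missing columns: ", paste(missing, collapse = ", "))
  }
  lapply(split(df, df$cell_id), function(d) {
    d <- d[order(d$time_h), ]
    cell_trace(d$cell_id[1], d$time_h, d$cn_ratio,
               n_baseline_frames = n_baseline_frames,
               treatment_time = treatment_time)
  })
}

#' Write single-cell traces to CSV
#'
#' @param traces list of [cell_trace()] objects.
#' @param path output CSV file.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  df <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(cell_id = as.character(tr$cell_id),
               time_h = tr$frame_times, cn_ratio = tr$cn_ratio,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a differential-expression table from TSV
#'
#' @param path TSV file with columns `gene_id`, `biotype`, `fdr`,
#'   `max_group_mean`, `log2fc_*h` and optionally `condition`.
#' @return data.frame validated against the DEG schema.
#' @export
read_deg_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_deg_table(df)
  df
}

#' Write a differential-expression table to TSV
#'
#' @param table DEG data.frame.
#' @param path output TSV file.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(table, path) {
  check_deg_table(table)
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write cluster assignments to TSV
#'
#' @param cluster_set a [cluster_genes()] result.
#' @param path output TSV file (columns gene_id, condition, cluster).
#' @return `path`, invisibly.
#' @export
write_cluster_set <- function(cluster_set, path) {
  df <- data.frame(
    gene_id = names(cluster_set$labels),
    condition = if (is.null(cluster_set$condition)) NA_character_
                else cluster_set$condition,
    cluster = as.integer(cluster_set$labels),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read cluster assignments from TSV
#'
#' Rebuilds a minimal cluster set (labels, sizes, condition) from a file
#' written by [write_cluster_set()]; mean profiles are not stored.
#'
#' @param path TSV file.
#' @return A `cluster_set` (without centers).
#' @export
read_cluster_set <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "condition", "cluster")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("cluster file is missing columns: ", paste(missing, collapse = ", "))
  }
  labels <- as.integer(df$cluster)
  names(labels) <- df$gene_id
  k <- max(labels)
  structure(list(condition = df$condition[1], k = k, labels = labels,
                 sizes = as.integer(table(factor(labels, levels = seq_len(k)))),
                 centers = NULL, center_sd = NULL, timepoints = NULL,
                 seed = NA_integer_),
            class = "cluster_set")
}

#' Write a fit surface to CSV (+ JSON summary)
#'
#' The grid and RMSE values go to a long-format CSV (columns `alpha_m`,
#' optionally `K` and `delay`, and `rmse`); the argmin estimates,
#' half-life and settings go to a JSON sidecar.
#'
#' @param fs a `fit_surface`.
#' @param path output CSV file.
#' @param json_path JSON summary path; default replaces the extension.
#' @return `path`, invisibly.
#' @export
write_fit_surface <- function(fs, path, json_path = NULL) {
  if (is.null(json_path)) json_path <- sub("\\.[^.]*$", ".json", path)
  g <- expand.grid(
    alpha_m = fs$alpha_grid,
    K = if (is.null(fs$K_grid)) NA_real_ else fs$K_grid,
    delay = if (is.null(fs$delay_grid)) NA_real_ else fs$delay_grid,
    KEEP.OUT.ATTRS = FALSE
  )
  g$rmse <- as.numeric(fs$rmse)
  utils::write.csv(g, path, row.names = FALSE, quote = FALSE)
  meta <- list(variant = fs$variant, condition = fs$condition,
               profile_id = fs$profile_id, argmin = fs$argmin,
               rmse_min = fs$rmse_min, half_life_h = fs$half_life_h,
               settings = fs$settings)
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a fit surface written by [write_fit_surface()]
#'
#' @param path CSV file.
#' @param json_path JSON summary path; default replaces the extension.
#' @return A `fit_surface`.
#' @export
read_fit_surface <- function(path, json_path = NULL) {
  if (is.null(json_path)) json_path <- sub("\\.[^.]*$", ".json", path)
  g <- utils::read.csv(path)
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  alpha <- sort(unique(g$alpha_m))
  K <- if (all(is.na(g$K))) NULL else sort(unique(g$K))
  delay <- if (all(is.na(g$delay))) NULL else sort(unique(g$delay))
  dims <- c(length(alpha), if (!is.null(K)) length(K),
            if (!is.null(delay)) length(delay))
  rmse <- if (length(dims) == 1) g$rmse else array(g$rmse, dims)
  structure(list(alpha_grid = alpha, K_grid = K, delay_grid = delay,
                 rmse = rmse, rmse_min = meta$rmse_min,
                 argmin = meta$argmin, half_life_h = meta$half_life_h,
                 variant = meta$variant, condition = meta$condition,
                 profile_id = meta$profile_id, settings = meta$settings),
            class = "fit_surface")
}

#' Write a trajectory to tidy CSV with a JSON metadata sidecar
#'
#' @param traj a `jnk_trajectory`.
#' @param path output CSV (columns time_h, species, value_Cs).
#' @param json_path metadata sidecar path; default replaces the extension.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, json_path = NULL) {
  if (is.null(json_path)) json_path <- sub("\\.[^.]*$", ".json", path)
  df <- data.frame(
    time_h = rep(traj$times, times = ncol(traj$states)),
    species = rep(colnames(traj$states), each = length(traj$times)),
    value_Cs = as.numeric(traj$states),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  meta <- list(variant = traj$variant,
               stimulus = list(label = traj$stimulus$label,
                               on_intervals = traj$stimulus$on_intervals),
               parameters = unclass(traj$params), solver = traj$solver)
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML (or JSON) document with optional keys `parameters` (overrides by
#' symbol name), `stimulus` (label or explicit on-intervals), `variant`,
#' `t_end`, `dt_out`, `seed`. Unknown parameter symbols are rejected.
#'
#' @param path configuration file.
#' @return List with `params` ([jnk_params()]), `stimulus`
#'   ([stimulus_program()]), `variant`, `t_end`, `dt_out`, `seed`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  }
  params <- jnk_params()
  if (!is.null(cfg$parameters)) params <- update_params(params, cfg$parameters)
  stim <- if (is.null(cfg$stimulus)) {
    make_stimulus("sustained")
  } else if (is.character(cfg$stimulus)) {
    make_stimulus(cfg$stimulus)
  } else {
    stimulus_program(do.call(rbind, lapply(cfg$stimulus, as.numeric)))
  }
  list(params = params, stimulus = stim,
       variant = if (is.null(cfg$variant)) "mass_action" else cfg$variant,
       t_end = if (is.null(cfg$t_end)) 8 else cfg$t_end,
       dt_out = if (is.null(cfg$dt_out)) 0.05 else cfg$dt_out,
       seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed))
}
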