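# Quantification of single-cell kinase-translocation-reporter (KTR)
# traces: baseline, pulse counting and activity durations from
# cytoplasmic-to-nuclear (C/N) ratio time series.

#' Single-cell C/N-ratio trace
#'
#' @param cell_id cell identifier.
#' @param frame_times frame times (h), uniformly spaced (default 10-min
#'   frames); frames strictly before `treatment_time` are the
#'   pre-treatment baseline window.
#' @param cn_ratio positive C/N ratio values, one per frame.
#' @param n_baseline_frames number of pre-treatment frames averaged for
#'   the baseline (default 4, i.e. 30-40 min of pre-imaging).
#' @param treatment_time time (h) at which treatment is added.
#' @return Object of class `cell_trace`.
#' @export
cell_trace <- function(cell_id, frame_times, cn_ratio,
                       n_baseline_frames = 4, treatment_time = 0) {
  frame_times <- as.numeric(frame_times)
  cn_ratio <- as.numeric(cn_ratio)
  if (length(frame_times) != length(cn_ratio)) {
    stop("frame_times and cn_ratio must have equal length")
  }
  if (any(cn_ratio <= 0)) stop("cn_ratio values must be > 0")
  d <- diff(frame_times)
  if (length(d) && (any(d <= 0) || max(d) - min(d) > 1e-6)) {
    stop("frame times must be uniformly spaced (within 1e-6 h)")
  }
  n_pre <- sum(frame_times < treatment_time)
  if (n_pre < n_baseline_frames) {
    stop(sprintf("%d pre-treatment frames required for the baseline, found %d",
                 n_baseline_frames, n_pre))
  }
  structure(list(cell_id = cell_id, frame_times = frame_times,
                 cn_ratio = cn_ratio,
                 n_baseline_frames = n_baseline_frames,
                 treatment_time = treatment_time,
                 frame_interval = if (length(d)) stats::median(d) else NA_real_),
            class = "cell_trace")
}

#' @export
print.cell_trace <- function(x, ...) {
  cat(sprintf("cell trace '%s': %d frames every %.3g h, treatment at %g h\n",
              as.character(x$cell_id), length(x$frame_times),
              x$frame_interval, x$treatment_time))
  invisible(x)
}

#' Baseline C/N ratio of a trace
#'
#' Arithmetic mean of the last `n_baseline_frames` C/N values before
#' treatment addition.
#'
#' @param trace a [cell_trace()].
#' @return Baseline C/N value.
#' @export
compute_baseline <- function(trace) {
  pre <- which(trace$frame_times < trace$treatment_time)
  if (length(pre) < trace$n_baseline_frames) {
    stop(sprintf("%d pre-treatment frames required, found %d",
                 trace$n_baseline_frames, length(pre)))
  }
  mean(trace$cn_ratio[utils::tail(pre, trace$n_baseline_frames)])
}

#' Detect kinase activity pulses in a trace
#'
#' Counts strict local maxima of the post-treatment C/N series whose value
#' reaches the detection threshold `(1 + threshold_frac) * baseline`
#' (default 50% above baseline, guarding against spurious noise peaks).
#' Plateaus of equal values count once at their leftmost frame; series
#' endpoints are never peaks.
#'
#' @param trace a [cell_trace()].
#' @param baseline baseline C/N value; computed via [compute_baseline()]
#'   if `NULL`.
#' @param threshold_frac fractional rise above baseline required.
#' @param min_peak_distance optional minimal spacing (h) between reported
#'   peaks; 0 (default) disables the extra rule. When active, peaks are
#'   kept greedily in decreasing height order.
#' @return Object of class `pulse_summary`: list with `cell_id`,
#'   `baseline`, `threshold`, `n_pulses`, `peak_times`.
#' @export
detect_pulses <- function(trace, baseline = NULL, threshold_frac = 0.5,
                          min_peak_distance = 0) {
  if (is.null(baseline)) baseline <- compute_baseline(trace)
  if (baseline <= 0) stop("baseline must be > 0")
  threshold <- (1 + threshold_frac) * baseline
  post <- trace$frame_times >= trace$treatment_time
  tt <- trace$frame_times[post]
  vv <- trace$cn_ratio[post]
  r <- rle(vv)
  v <- r$values
  n <- length(v)
  first_idx <- cumsum(c(1, r$lengths[-n]))
  peaks <- integer(0)
  if (n >= 3) {
    is_pk <- v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] > v[3:n]
    pk <- which(is_pk) + 1
    pk <- pk[v[pk] >= threshold]
    peaks <- first_idx[pk]
  }
  if (min_peak_distance > 0 && length(peaks) > 1) {
    keep <- integer(0)
    for (i in order(-vv[peaks])) {
      if (!length(keep) ||
          all(abs(tt[peaks[i]] - tt[peaks[keep]]) >= min_peak_distance)) {
        keep <- c(keep, i)
      }
    }
    peaks <- sort(peaks[keep])
  }
  structure(list(cell_id = trace$cell_id, baseline = baseline,
                 threshold = threshold, n_pulses = length(peaks),
                 peak_times = tt[peaks]),
            class = "pulse_summary")
}

#' @export
print.pulse_summary <- function(x, ...) {
  cat(sprintf("cell '%s': %d pulse(s) above %.3g (baseline %.3g)\n",
              as.character(x$cell_id), x$n_pulses, x$threshold, x$baseline))
  if (x$n_pulses) cat("  peak times (h):", paste(signif(x$peak_times, 4),
                                                 collapse = ", "), "\n")
  invisible(x)
}

#' Duration of kinase activity above threshold
#'
#' Number of post-treatment frames (within an optional time window) whose
#' C/N value reaches `(1 + threshold_frac) * baseline`, multiplied by the
#' frame spacing.
#'
#' @inheritParams detect_pulses
#' @param window optional `c(start, end)` window in hours (half-open,
#'   `start <= t < end`); default is the full post-treatment trace.
#' @return Duration (h).
#' @export
activity_duration <- function(trace, baseline = NULL, threshold_frac = 0.5,
                              window = NULL) {
  if (is.null(baseline)) baseline <- compute_baseline(trace)
  threshold <- (1 + threshold_frac) * baseline
  keep <- trace$frame_times >= trace$treatment_time
  if (!is.null(window)) {
    if (window[1] < min(trace$frame_times) - 1e-9 ||
        window[1] > max(trace$frame_times) + 1e-9) {
      stop("window lies outside the trace's time span")
    }
    keep <- keep & trace$frame_times >= window[1] &
      trace$frame_times < window[2]
  }
  sum(trace$cn_ratio[keep] >= threshold) * trace$frame_interval
}

#' Area under the curve above the activity threshold
#'
#' Secondary activity metric: `sum((value - threshold)+) * frame spacing`
#' over the post-treatment frames (optionally windowed).
#'
#' @inheritParams activity_duration
#' @return AUC (C/N x h).
#' @export
activity_auc <- function(trace, baseline = NULL, threshold_frac = 0.5,
                         window = NULL) {
  if (is.null(baseline)) baseline <- compute_baseline(trace)
  threshold <- (1 + threshold_frac) * baseline
  keep <- trace$frame_times >= trace$treatment_time
  if (!is.null(window)) {
    keep <- keep & trace$frame_times >= window[1] &
      trace$frame_times < window[2]
  }
  sum(pmax(trace$cn_ratio[keep] - threshold, 0)) * trace$frame_interval
}

#' Population summary of a set of traces
#'
#' Frame-aligned mean and standard deviation of the C/N ratio across
#' cells, plus a per-cell metrics table (baseline, pulse count, total and
#' windowed activity durations, AUC).
#'
#' @param traces list of [cell_trace()] objects sharing one frame grid.
#' @param threshold_frac fractional rise above baseline for the activity
#'   threshold.
#' @param window window (h) for the windowed duration, default `c(0, 3)`.
#' @param shared_baseline if `TRUE`, one population baseline (mean of the
#'   per-cell baselines) is applied to every cell; default is per-cell
#'   baselines.
#' @return List with `frame_summary` (data.frame: time_h, mean, sd) and
#'   `cell_summary` (data.frame of per-cell metrics).
#' @export
summarize_population <- function(traces, threshold_frac = 0.5,
                                 window = c(0, 3), shared_baseline = FALSE) {
  if (!length(traces)) stop("at least one trace is required")
  grid <- traces[[1]]$frame_times
  same <- vapply(traces, function(tr) {
    length(tr$frame_times) == length(grid) &&
      max(abs(tr$frame_times - grid)) <= 1e-9
  }, logical(1))
  if (!all(same)) stop("all traces must share the same frame grid")
  M <- vapply(traces, function(tr) tr$cn_ratio, numeric(length(grid)))
  M <- matrix(M, nrow = length(grid))
  frame_summary <- data.frame(
    time_h = grid,
    mean = rowMeans(M),
    sd = apply(M, 1, stats::sd)
  )
  frame_summary$sd[is.na(frame_summary$sd)] <- 0
  baselines <- vapply(traces, compute_baseline, numeric(1))
  if (shared_baseline) baselines <- rep(mean(baselines), length(traces))
  cell_summary <- do.call(rbind, lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]
    ps <- detect_pulses(tr, baselines[i], threshold_frac)
    data.frame(
      cell_id = as.character(tr$cell_id),
      baseline = baselines[i],
      threshold = ps$threshold,
      n_pulses = ps$n_pulses,
      total_duration_h = activity_duration(tr, baselines[i], threshold_frac),
      windowed_duration_h = activity_duration(tr, baselines[i],
                                              threshold_frac, window),
      auc = activity_auc(tr, baselines[i], threshold_frac),
      stringsAsFactors = FALSE
    )
  }))
  rownames(cell_summary) <- NULL
  list(frame_summary = frame_summary, cell_summary = cell_summary)
}
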