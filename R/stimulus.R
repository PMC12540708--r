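# Piecewise-constant stimulus programs c(t) in {0, 1}.

#' Build a stimulus program
#'
#' The stimulus is a step function c(t) in \{0, 1\} defined by half-open
#' on-intervals \[start, end). The canonical treatment programs are:
#' `sustained` (agonist never removed), `transient` (1-h treatment then
#' washout), `pulsed` (1-h treatment, washout, second 1-h treatment at
#' 4 h) and `none` (no stimulus).
#'
#' @param label one of `"sustained"`, `"transient"`, `"pulsed"`, `"none"`.
#' @param first_on_duration duration (h) of the first treatment for the
#'   transient and pulsed programs.
#' @param second_on_start start time (h) of the second treatment of the
#'   pulsed program.
#' @param second_on_duration duration (h) of the second treatment.
#' @return An object of class `stimulus_program`: list with `on_intervals`
#'   (two-column matrix of start/end times, possibly zero rows; end may be
#'   `Inf`) and `label`.
#' @examples
#' make_stimulus("pulsed")$on_intervals
#' @export
make_stimulus <- function(label, first_on_duration = 1,
                          second_on_start = 4, second_on_duration = 1) {
  valid <- c("sustained", "transient", "pulsed", "none")
  if (!is.character(label) || length(label) != 1 || !label %in% valid) {
    stop("unknown stimulus label; valid labels are: ",
         paste(valid, collapse = ", "), call. = FALSE)
  }
  iv <- switch(label,
    sustained = matrix(c(0, Inf), ncol = 2),
    transient = matrix(c(0, first_on_duration), ncol = 2),
    pulsed = matrix(c(0, second_on_start,
                      first_on_duration,
                      second_on_start + second_on_duration),
                    ncol = 2),
    none = matrix(numeric(0), ncol = 2)
  )
  stimulus_program(iv, label)
}

#' Construct a stimulus program from explicit on-intervals
#'
#' @param on_intervals two-column matrix (start, end) of half-open
#'   intervals in hours; must be sorted and non-overlapping with
#'   start < end (end may be `Inf`).
#' @param label program label.
#' @return A `stimulus_program` object.
#' @export
stimulus_program <- function(on_intervals, label = "custom") {
  iv <- matrix(as.numeric(on_intervals), ncol = 2)
  colnames(iv) <- c("start", "end")
  if (nrow(iv) > 0) {
    if (any(iv[, 1] >= iv[, 2])) {
      stop("stimulus intervals must satisfy start < end", call. = FALSE)
    }
    if (is.unsorted(iv[, 1], strictly = TRUE) && nrow(iv) > 1) {
      stop("stimulus intervals must be sorted by start time", call. = FALSE)
    }
    if (nrow(iv) > 1 && any(iv[-nrow(iv), 2] > iv[-1, 1])) {
      stop("stimulus intervals must not overlap", call. = FALSE)
    }
  }
  structure(list(on_intervals = iv, label = label),
            class = "stimulus_program")
}

#' Evaluate a stimulus program
#'
#' @param stimulus a `stimulus_program`.
#' @param t time(s) in hours.
#' @return 0/1 stimulus value(s) at `t`.
#' @export
stimulus_value <- function(stimulus, t) {
  iv <- stimulus$on_intervals
  out <- numeric(length(t))
  for (i in seq_len(nrow(iv))) {
    out[t >= iv[i, 1] & t < iv[i, 2]] <- 1
  }
  out
}

# switch times strictly inside (0, t_end), for piecewise integration
stimulus_switch_times <- function(stimulus, t_end) {
  sw <- as.numeric(t(stimulus$on_intervals))
  sort(unique(sw[sw > 0 & sw < t_end & is.finite(sw)]))
}

#' @export
print.stimulus_program <- function(x, ...) {
  cat("stimulus program '", x$label, "'\n", sep = "")
  if (nrow(x$on_intervals) == 0) {
    cat("  c(t) = 0 everywhere\n")
  } else {
    apply(x$on_intervals, 1, function(r) {
      cat(sprintf("  on [%g, %g) h\n", r[1], r[2]))
    })
  }
  invisible(x)
}
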