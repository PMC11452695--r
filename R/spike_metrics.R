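# Windowed spike metrics: the inverse interspike interval (iISI), aligned
# window grids, spike counts, min-max activity normalization, and kernel
# spike-density estimates.

.ALIGN_COLS <- c(fix_acquired = "t_fix_acquired", cue_on = "t_cue_on",
                 targets_on = "t_targets_on", saccade_on = "t_saccade_on")

#' Define a sliding-window grid aligned to a task event
#'
#' @param align_event One of `"fix_acquired"`, `"cue_on"`, `"targets_on"`,
#'   `"saccade_on"`.
#' @param start_s,stop_s Offsets of the analyzed span relative to the event,
#'   in seconds.
#' @param width_s Window duration (s), e.g. 0.01 for the classifier grid or
#'   0.1 for ROC/regression grids.
#' @param step_s Stride between window onsets (s).
#' @return An object of class `sef_window_grid` with the window start offsets
#'   in `$starts`; the number of windows is
#'   `floor((stop - start - width)/step) + 1`.
#' @export
window_grid <- function(align_event, start_s, stop_s, width_s, step_s) {
  align_event <- match.arg(align_event, names(.ALIGN_COLS))
  stopifnot(width_s > 0, step_s > 0, start_s < stop_s)
  n <- floor((stop_s - start_s - width_s) / step_s + 1e-9) + 1
  if (n < 1) stop("span too short for a single window")
  structure(list(align_event = align_event, start_s = start_s, stop_s = stop_s,
                 width_s = width_s, step_s = step_s,
                 starts = start_s + step_s * (seq_len(n) - 1)),
            class = "sef_window_grid")
}

#' @export
print.sef_window_grid <- function(x, ...) {
  cat(sprintf("<sef_window_grid> %s [%g, %g] s, width %g s, step %g s, %d windows\n",
              x$align_event, x$start_s, x$stop_s, x$width_s, x$step_s,
              length(x$starts)))
  invisible(x)
}

# centers of the windows, relative to the align event
grid_centers <- function(grid) grid$starts + grid$width_s / 2

same_grid <- function(a, b) {
  isTRUE(all.equal(a$starts, b$starts)) && isTRUE(all.equal(a$width_s, b$width_s)) &&
    identical(a$align_event, b$align_event)
}

#' Inverse interspike interval as a function of time
#'
#' For `s_i < t < s_(i+1)` the iISI is `1/(s_(i+1) - s_i)`; before the first
#' and after the last spike it is 0. Trains with fewer than two spikes give
#' the zero function.
#'
#' @param spike_times_s Sorted spike times (s).
#' @return A vectorized function `t -> iISI(t)` in 1/s.
#' @export
iisi_function <- function(spike_times_s) {
  if (is.unsorted(spike_times_s, strictly = TRUE)) stop("spike times must be sorted")
  k <- length(spike_times_s)
  if (k < 2) return(function(t) numeric(length(t)))
  v <- 1 / diff(spike_times_s)
  function(t) {
    i <- findInterval(t, spike_times_s)
    out <- numeric(length(t))
    inside <- i >= 1 & i < k
    out[inside] <- v[i[inside]]
    out
  }
}

# Cumulative integral of the iISI step function, evaluated at arbitrary times.
# Each interspike interval contributes exactly 1 to the integral, so
# C(t) = (i - 1) + (t - s_i)/(s_(i+1) - s_i) inside interval i.
iisi_cumulative <- function(spike_times_s) {
  k <- length(spike_times_s)
  if (k < 2) return(function(t) numeric(length(t)))
  d <- diff(spike_times_s)
  function(t) {
    i <- findInterval(t, spike_times_s)
    out <- numeric(length(t))
    inside <- i >= 1 & i < k
    out[inside] <- (i[inside] - 1) + (t[inside] - spike_times_s[i[inside]]) / d[i[inside]]
    out[i >= k] <- k - 1
    out
  }
}

#' Trial-by-window matrix of mean iISI
#'
#' Each entry is the exact time average of the iISI step function over one
#' aligned window of one trial. Trials whose align event is missing are
#' dropped with a warning.
#'
#' @param spike_times_s Sorted spike times for one neuron, session clock (s).
#' @param trials Trial table rows to use (see [select_trials()]).
#' @param grid A [window_grid()].
#' @param neuron_id Optional identifier carried in the result.
#' @return An object of class `sef_iisi` with fields `values`
#'   (trials x windows matrix, 1/s), `trial_ids`, `grid`, `neuron_id`.
#' @export
windowed_iisi <- function(spike_times_s, trials, grid, neuron_id = NA_character_) {
  ev <- trials[[.ALIGN_COLS[[grid$align_event]]]]
  drop <- is.na(ev)
  if (any(drop)) {
    warning(sum(drop), " trial(s) lack event '", grid$align_event, "' and were dropped")
    trials <- trials[!drop, , drop = FALSE]
    ev <- ev[!drop]
  }
  C <- iisi_cumulative(spike_times_s)
  w <- grid$width_s
  vals <- vapply(seq_along(ev), function(i) {
    a <- ev[i] + grid$starts
    (C(a + w) - C(a)) / w
  }, numeric(length(grid$starts)))
  vals <- t(matrix(vals, nrow = length(grid$starts)))
  structure(list(neuron_id = neuron_id, grid = grid, values = vals,
                 trial_ids = trials$trial_id),
            class = "sef_iisi")
}

#' Spike count in an event-aligned window
#'
#' Half-open convention: a spike exactly at the right edge is excluded, so
#' counts over a partition of `[a, b)` add up to the count over `[a, b)`.
#'
#' @param spike_times_s Sorted spike times (s).
#' @param event_time_s Alignment event time (s); may be a vector (one count
#'   per event).
#' @param window Length-2 numeric `c(a, b)`, offsets relative to the event.
#' @return Integer vector of counts.
#' @export
spike_count <- function(spike_times_s, event_time_s, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  vapply(event_time_s, function(ev) {
    if (is.na(ev)) return(NA_integer_)
    sum(spike_times_s >= ev + window[1] & spike_times_s < ev + window[2])
  }, integer(1))
}

# trials x windows count matrix on a grid
spike_count_matrix <- function(spike_times_s, event_times_s, grid) {
  w <- grid$width_s
  out <- matrix(NA_integer_, length(event_times_s), length(grid$starts))
  for (i in seq_along(event_times_s)) {
    ev <- event_times_s[i]
    if (is.na(ev)) next
    a <- ev + grid$starts
    out[i, ] <- findInterval(a + w, spike_times_s, left.open = TRUE) -
      findInterval(a, spike_times_s, left.open = TRUE)
  }
  out
}

#' Min-max normalization of condition-wise activity
#'
#' Applies the affine map `(FR_t - FR_min)/(FR_max - FR_min)` with the
#' extremes taken jointly across all conditions inside `within` (the task
#' range), so minimum activity becomes 0 and maximum activity becomes 1 and
#' the same map is applied to every condition.
#'
#' @param series Named list of numeric vectors (one mean activity series per
#'   condition, on a common time base) or a conditions-by-time matrix.
#' @param within Optional logical/integer index of the time base defining the
#'   range over which the extremes are taken (default: everything).
#' @return List with `series` (normalized, same shape), and `record` holding
#'   `fr_min`, `fr_max`, `normalizable`. A flat neuron
#'   (`fr_max == fr_min`) is flagged `normalizable = FALSE` and its series
#'   returned as `NA`.
#' @export
normalize_activity <- function(series, within = NULL) {
  if (is.matrix(series)) series <- lapply(seq_len(nrow(series)), function(i) series[i, ])
  stopifnot(is.list(series), length(series) > 0)
  idx <- within %||% seq_along(series[[1]])
  rng <- range(unlist(lapply(series, `[`, idx)), na.rm = TRUE)
  if (!(rng[2] > rng[1])) {
    return(list(series = lapply(series, function(s) rep(NA_real_, length(s))),
                record = list(fr_min = rng[1], fr_max = rng[2], normalizable = FALSE)))
  }
  list(series = lapply(series, function(s) (s - rng[1]) / (rng[2] - rng[1])),
       record = list(fr_min = rng[1], fr_max = rng[2], normalizable = TRUE))
}

#' Gaussian-kernel spike density function
#'
#' Visualization aid only; never feeds the statistics. The integral of the
#' returned function equals the spike count.
#'
#' @param spike_times_s Sorted spike times (s).
#' @param kernel_sigma_s Kernel standard deviation (s), default 20 ms.
#' @return A vectorized function `t -> rate` (1/s).
#' @export
spike_density <- function(spike_times_s, kernel_sigma_s = 0.02) {
  stopifnot(kernel_sigma_s > 0)
  function(t) {
    vapply(t, function(tt) sum(stats::dnorm(tt, mean = spike_times_s,
                                            sd = kernel_sigma_s)), numeric(1))
  }
}
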