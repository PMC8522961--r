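#' Spike trains
#'
#' One electrode's spike times within one recording.
#'
#' @param times Numeric vector of spike times in seconds, strictly
#'   increasing, within `[0, duration_s]`.
#' @param duration_s Recording length in seconds (> 0).
#' @param well,electrode Identifiers.
#' @return Object of class `spike_train`.
#' @export
spike_train <- function(times, duration_s, well = "well", electrode = 1L) {
  stopifnot(is.numeric(times), is.numeric(duration_s), duration_s > 0)
  if (length(times)) {
    if (any(times < 0) || any(times > duration_s)) {
      stop("spike times must lie in [0, duration_s]")
    }
    if (is.unsorted(times, strictly = TRUE)) {
      stop("spike times must be strictly increasing")
    }
  }
  structure(list(times = as.numeric(times), duration_s = duration_s,
                 well = well, electrode = electrode),
            class = "spike_train")
}

#' Spike rate
#'
#' Number of spikes per second over the whole recording.
#'
#' @param train A [spike_train()].
#' @return Spikes/s.
#' @export
spike_rate <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  if (train$duration_s <= 0) stop("zero-length recording")
  length(train$times) / train$duration_s
}

#' Detect bursts (at least 5 spikes within 100 ms)
#'
#' A burst is a maximal run of consecutive spikes of length at least
#' `min_spikes` in which every window of `min_spikes` consecutive spikes
#' spans at most `max_span_s` seconds. The detector scans left to right:
#' a burst opens at the earliest spike starting a qualifying window and
#' extends while each newly appended spike keeps its trailing
#' `min_spikes`-spike window within the span; bursts are therefore
#' non-overlapping and ordered.
#'
#' @param train A [spike_train()] (times already sorted; unsorted input
#'   is rejected by the constructor).
#' @param max_span_s Maximum span of a qualifying window (default 0.100).
#' @param min_spikes Minimum spikes per window and per burst (default 5).
#' @return Data.frame with one row per burst: `start_s`, `end_s`,
#'   `n_spikes`, `i_start`, `i_end` (spike indices).
#' @export
detect_bursts <- function(train, max_span_s = 0.1, min_spikes = 5L) {
  stopifnot(inherits(train, "spike_train"), max_span_s > 0,
            min_spikes >= 2)
  t <- train$times
  n <- length(t)
  m <- as.integer(min_spikes)
  empty <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      n_spikes = integer(0), i_start = integer(0),
                      i_end = integer(0))
  if (n < m) return(empty)
  bursts <- list()
  j <- 1L  # earliest spike allowed to open the next burst
  while (j + m - 1L <= n) {
    # first qualifying m-spike window starting at or after spike j
    i <- j + m - 1L
    while (i <= n && t[i] - t[i - m + 1L] > max_span_s) i <- i + 1L
    if (i > n) break
    a <- i - m + 1L
    b <- i
    while (b + 1L <= n && t[b + 1L] - t[b - m + 2L] <= max_span_s) {
      b <- b + 1L
    }
    bursts[[length(bursts) + 1L]] <- data.frame(
      start_s = t[a], end_s = t[b], n_spikes = b - a + 1L,
      i_start = a, i_end = b)
    j <- b + 1L
  }
  if (length(bursts) == 0L) return(empty)
  do.call(rbind, bursts)
}

#' Count network bursts across a well's electrodes
#'
#' Computes each electrode's burst intervals, then counts the maximal
#' time intervals during which the number of electrodes simultaneously
#' inside a burst reaches `min_fraction` of the electrode count. The
#' default (`min_fraction = 1`) requires synchronised bursting on all
#' electrodes, the strict reading of "synchronized bursts among all 12
#' electrodes"; lower fractions accommodate wells with silent
#' electrodes. Burst intervals are treated as closed, so intervals
#' touching at a point still count as overlapping.
#'
#' @param trains A list of [spike_train()] objects sharing one duration,
#'   or a [spike_train_set()].
#' @param min_fraction Fraction of electrodes that must burst
#'   simultaneously, in (0, 1].
#' @param ... Passed to [detect_bursts()].
#' @return Integer count of network bursts.
#' @export
network_bursts <- function(trains, min_fraction = 1, ...) {
  if (inherits(trains, "spike_train_set")) trains <- as_spike_trains(trains)
  stopifnot(length(trains) >= 1, min_fraction > 0, min_fraction <= 1)
  durs <- vapply(trains, function(tr) tr$duration_s, numeric(1))
  if (length(unique(durs)) != 1L) {
    stop("all electrodes must share one recording duration")
  }
  n_el <- length(trains)
  need <- ceiling(min_fraction * n_el - 1e-9)
  events <- list()
  for (tr in trains) {
    b <- detect_bursts(tr, ...)
    if (nrow(b)) {
      events[[length(events) + 1L]] <- data.frame(
        time = c(b$start_s, b$end_s),
        delta = rep(c(1L, -1L), each = nrow(b)))
    }
  }
  if (length(events) == 0L) return(0L)
  ev <- do.call(rbind, events)
  # closed intervals: starts first at equal timestamps
  ev <- ev[order(ev$time, -ev$delta), ]
  active <- cumsum(ev$delta)
  above <- active >= need
  sum(above & !c(FALSE, above[-length(above)]))
}

#' Summarise one well's activity
#'
#' The three reported MEA metrics for one well at one timepoint: spike
#' rate (total spikes across electrodes per second), burst count (summed
#' over electrodes) and network-burst count.
#'
#' @param trains List of [spike_train()] or a [spike_train_set()].
#' @param timepoint Treatment day recorded alongside the metrics.
#' @param min_fraction Passed to [network_bursts()].
#' @param ... Passed to [detect_bursts()].
#' @return One-row data.frame: `well`, `timepoint`, `spike_rate`,
#'   `burst_count`, `network_burst_count`.
#' @export
summarize_well <- function(trains, timepoint = 0, min_fraction = 1, ...) {
  if (inherits(trains, "spike_train_set")) trains <- as_spike_trains(trains)
  dur <- trains[[1]]$duration_s
  total_spikes <- sum(vapply(trains, function(tr) length(tr$times),
                             numeric(1)))
  bursts <- sum(vapply(trains, function(tr) nrow(detect_bursts(tr, ...)),
                       numeric(1)))
  data.frame(
    well = trains[[1]]$well, timepoint = timepoint,
    spike_rate = total_spikes / dur, burst_count = bursts,
    network_burst_count = network_bursts(trains,
                                         min_fraction = min_fraction, ...))
}

#' Normalise a longitudinal activity series to day 0
#'
#' Divides each metric at each treatment day by its pre-treatment
#' (day 0) value, per well. A zero day-0 metric cannot be used as a
#' denominator: the normalised value is flagged missing (`NA`) with a
#' warning rather than divided.
#'
#' @param series Data.frame of [summarize_well()] rows over treatment
#'   days, containing a `timepoint == 0` row per well.
#' @return `series` with `spike_rate`, `burst_count`,
#'   `network_burst_count` replaced by their day-0 ratios.
#' @export
normalize_to_day0 <- function(series) {
  metrics <- c("spike_rate", "burst_count", "network_burst_count")
  stopifnot(all(c("well", "timepoint", metrics) %in% names(series)))
  out <- split(series, series$well)
  out <- lapply(out, function(d) {
    d0 <- d[d$timepoint == 0, , drop = FALSE]
    if (nrow(d0) != 1L) stop("each well needs exactly one day-0 summary")
    for (m in metrics) {
      base <- d0[[m]]
      if (base == 0) {
        warning(sprintf("day-0 %s is zero for well %s: flagged missing",
                        m, d$well[1]))
        d[[m]] <- NA_real_
      } else {
        d[[m]] <- d[[m]] / base
      }
    }
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
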