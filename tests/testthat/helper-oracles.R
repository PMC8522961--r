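# Independent oracles used to cross-check the package implementations.
# These are deliberately written as naive brute-force formulations, not
# as copies of the production algorithms.

# Burst oracle: enumerate every m-spike window, keep the qualifying ones
# (span <= max_span), chain consecutive qualifying window indices, and
# consume windows left to right so bursts never overlap.
oracle_bursts <- function(times, max_span = 0.1, m = 5L) {
  n <- length(times)
  out <- list()
  if (n < m) return(out)
  q <- which(vapply(m:n, function(i) times[i] - times[i - m + 1] <= max_span,
                    logical(1))) + m - 1L  # window end indices
  while (length(q)) {
    first <- q[1]
    run_end <- first
    while ((run_end + 1L) %in% q) run_end <- run_end + 1L
    out[[length(out) + 1L]] <- c(i_start = first - m + 1L, i_end = run_end)
    q <- q[q - m + 1L > run_end]  # next burst must start after this one
  }
  out
}

# Network-burst oracle: sample time on a 1 ms grid, mark each electrode
# "in burst" wherever the grid point falls inside one of its burst
# intervals, and count maximal grid runs with enough active electrodes.
oracle_network_count <- function(trains, min_fraction = 1,
                                 max_span = 0.1, m = 5L) {
  dur <- trains[[1]]$duration_s
  grid <- seq(0, dur, by = 0.001)
  n_el <- length(trains)
  active <- matrix(FALSE, nrow = length(grid), ncol = n_el)
  for (j in seq_len(n_el)) {
    b <- oracle_bursts(trains[[j]]$times, max_span, m)
    for (iv in b) {
      lo <- trains[[j]]$times[iv["i_start"]]
      hi <- trains[[j]]$times[iv["i_end"]]
      active[grid >= lo & grid <= hi, j] <- TRUE
    }
  }
  need <- ceiling(min_fraction * n_el - 1e-9)
  hot <- rowSums(active) >= need
  sum(hot & !c(FALSE, hot[-length(hot)]))
}

# Truth-table oracle for the two-criterion mixture rule.
oracle_classify <- function(tu, dev, max_bmr, tu_thr = 1, bmr_thr = 5,
                            fold = 2) {
  crit_i <- (tu <= tu_thr) && (dev > bmr_thr)
  crit_ii <- dev >= fold * max_bmr
  if (crit_i && crit_ii) "synergistic" else
    if (crit_ii) "interactive" else "none"
}

# ICx oracle: numeric root-finding on the curve equation, independent of
# the closed-form inversion.
oracle_icx <- function(curve, level, upper = 1e6) {
  dir_sign <- if (curve$direction == "decreasing") -1 else 1
  target <- curve$top + dir_sign * level
  stats::uniroot(function(d) predict(curve, d) - target,
                 lower = 1e-12, upper = upper, tol = 1e-12)$root
}

# Random spike train generator for oracle comparisons: mixes sparse
# background with dense clusters so qualifying windows actually occur.
random_train <- function(seed, duration = 60) {
  set.seed(seed)
  t_bg <- sort(runif(rpois(1, 40), 0, duration))
  n_cl <- rpois(1, 6)
  t_cl <- unlist(lapply(seq_len(n_cl), function(i) {
    centre <- runif(1, 0, duration)
    centre + sort(runif(3 + rpois(1, 8), 0, runif(1, 0.05, 0.4)))
  }))
  times <- sort(unique(pmin(c(t_bg, t_cl), duration)))
  spike_train(times, duration_s = duration)
}
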