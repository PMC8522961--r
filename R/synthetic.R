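#' Simulate replicate dose-response data for a single chemical
#'
#' Draws replicate endpoint responses around a known four-parameter
#' logistic truth, emulating a normalised plate-based screen (solvent
#' control = 100%). Replicate noise is Gaussian on the % of control scale,
#' truncated at zero. Identical seeds give identical tables; the global
#' RNG state is not disturbed.
#'
#' @param curve A [curve_spec()] ground truth.
#' @param doses Strictly positive dose vector, sorted ascending.
#' @param noise A [noise_spec()].
#' @param chemical,endpoint,unit Identifier columns for the output table.
#' @return A [response_table()] with one row per (dose, replicate).
#' @examples
#' cs <- curve_spec(100, 0, ec50 = 10, hill = 1)
#' tab <- simulate_single_chemical(cs, doses = 10,
#'                                 noise = noise_spec(0, 4, seed = 1))
#' all(tab$value == 50) # response at the EC50 is the midpoint
#' @export
simulate_single_chemical <- function(curve, doses, noise = noise_spec(),
                                     chemical = "chem", endpoint = "viability",
                                     unit = "uM") {
  stopifnot(inherits(curve, "curve_spec"), inherits(noise, "noise_spec"))
  if (length(doses) == 0L) stop("empty dose list")
  if (any(!is.finite(doses)) || any(doses <= 0)) {
    stop("doses must be strictly positive")
  }
  if (is.unsorted(doses, strictly = TRUE)) {
    stop("doses must be sorted strictly ascending")
  }
  mu <- predict(curve, doses)
  n <- noise$n_replicates
  values <- withr::with_seed(noise$seed, {
    pmax(0, rep(mu, each = n) +
           stats::rnorm(length(doses) * n, 0, noise$replicate_sd))
  })
  response_table(data.frame(
    chemical = chemical, endpoint = endpoint,
    concentration = rep(doses, each = n), unit = unit,
    replicate = rep(seq_len(n), times = length(doses)),
    value = values))
}

#' Simulate a mixture response under concentration addition
#'
#' Implements exact dose addition: each component concentration is
#' converted into an equivalent dose of the reference curve (the first
#' component) by EC50-ratio scaling, the equivalents are summed, and the
#' reference curve is evaluated at the summed equivalent dose. This is the
#' simplest Loewe-consistent prediction for components sharing a common
#' curve shape. An [interaction_spec()] can then inject a known deviation:
#' synergism adds, antagonism removes, percentage points of deviation from
#' the 100% control level (antagonism never overshoots past 100%).
#'
#' @param components List of components; each is a `list(curve =, conc =)`
#'   with a [curve_spec()] and a non-negative nominal concentration.
#' @param interaction An [interaction_spec()].
#' @param noise A [noise_spec()].
#' @param mixture_id,endpoint,unit Identifier columns for the output.
#' @param dilution_level Dilution level recorded alongside the rows
#'   (1, 1/2, 1/4, 1/8 in a LOAEC-anchored design).
#' @return A [response_table()] with attributes `ca_prediction` (the
#'   noise-free concentration-addition response), `true_mean` (after any
#'   injected interaction) and `equivalent_dose`.
#' @export
simulate_mixture <- function(components,
                             interaction = interaction_spec("additive"),
                             noise = noise_spec(),
                             mixture_id = "mixture", endpoint = "viability",
                             unit = "uM", dilution_level = 1) {
  stopifnot(inherits(interaction, "interaction_spec"),
            inherits(noise, "noise_spec"))
  if (length(components) == 0L) stop("empty component list")
  for (cmp in components) {
    if (!inherits(cmp$curve, "curve_spec")) {
      stop("each component needs a `curve` of class curve_spec")
    }
    if (!is.numeric(cmp$conc) || cmp$conc < 0) {
      stop("component concentrations must be >= 0")
    }
  }
  ref <- components[[1L]]$curve
  eq_dose <- sum(vapply(
    components, function(cmp) cmp$conc * ref$ec50 / cmp$curve$ec50,
    numeric(1)))
  predicted <- predict(ref, eq_dose)
  dev <- predicted - 100
  if (interaction$mode == "synergistic") {
    dir_sign <- if (dev != 0) sign(dev) else {
      if (ref$direction == "decreasing") -1 else 1
    }
    dev <- dev + dir_sign * interaction$deviation_pct
  } else if (interaction$mode == "antagonistic") {
    dev <- sign(dev) * max(0, abs(dev) - interaction$deviation_pct)
  }
  mu <- 100 + dev
  n <- noise$n_replicates
  values <- withr::with_seed(noise$seed, {
    pmax(0, mu + stats::rnorm(n, 0, noise$replicate_sd))
  })
  out <- response_table(data.frame(
    chemical = mixture_id, endpoint = endpoint,
    concentration = dilution_level, unit = unit,
    replicate = seq_len(n), value = values))
  attr(out, "ca_prediction") <- predicted
  attr(out, "true_mean") <- mu
  attr(out, "equivalent_dose") <- eq_dose
  out
}

#' Spike-train sets
#'
#' Container for one well's multi-electrode spike times: a data.frame
#' with columns `well`, `electrode`, `time_s` plus the recording duration
#' as an attribute.
#'
#' @param x Data.frame with columns `well`, `electrode`, `time_s`.
#' @param duration_s Recording length in seconds.
#' @return An object of class `spike_train_set`.
#' @export
spike_train_set <- function(x, duration_s) {
  stopifnot(all(c("well", "electrode", "time_s") %in% names(x)),
            is.numeric(duration_s), duration_s > 0)
  if (nrow(x) && (any(x$time_s < 0) || any(x$time_s > duration_s))) {
    stop("spike times must lie in [0, duration_s]")
  }
  structure(x, duration_s = duration_s,
            class = unique(c("spike_train_set", class(x))))
}

#' @rdname spike_train_set
#' @param set A `spike_train_set`.
#' @param electrodes Optional electrode ids to keep (defaults to all
#'   present in the set).
#' @return `as_spike_trains()`: a named list of [spike_train()] objects,
#'   one per electrode.
#' @export
as_spike_trains <- function(set, electrodes = NULL) {
  stopifnot(inherits(set, "spike_train_set"))
  dur <- attr(set, "duration_s")
  ids <- electrodes %||% sort(unique(set$electrode))
  out <- lapply(ids, function(e) {
    spike_train(sort(set$time_s[set$electrode == e]), duration_s = dur,
                well = if (nrow(set)) set$well[1] else "well",
                electrode = e)
  })
  names(out) <- as.character(ids)
  out
}

#' Simulate a multi-electrode array well
#'
#' Generates per-electrode spike trains as homogeneous Poisson background
#' activity with embedded high-rate burst epochs, emulating a 5-minute
#' recording of a 12-electrode well. With `sync = 1` the burst epochs are
#' placed identically on all electrodes (perfect network synchrony); with
#' `sync < 1` each electrode's copy of each epoch is jittered uniformly by
#' up to `(1 - sync)` times the epoch length.
#'
#' @param rate_hz Background firing rate, spikes/s (>= 0).
#' @param burst_epochs `NULL` or a data.frame with columns `start_s`,
#'   `end_s`, `rate_hz` (the in-burst rate); epochs must not overlap.
#' @param duration_s Recording length, seconds (> 0). Default 300 s.
#' @param n_electrodes Number of electrodes (default 12).
#' @param sync Fraction in \[0, 1\]: 1 = identical epoch placement.
#' @param seed Integer seed (all randomness flows through it).
#' @param well Well identifier.
#' @return A [spike_train_set()].
#' @export
simulate_mea_well <- function(rate_hz, burst_epochs = NULL,
                              duration_s = 300, n_electrodes = 12,
                              sync = 1, seed = 1L, well = "A1") {
  stopifnot(is.numeric(rate_hz), rate_hz >= 0, duration_s > 0,
            n_electrodes >= 1, sync >= 0, sync <= 1)
  if (!is.null(burst_epochs) && nrow(burst_epochs)) {
    be <- burst_epochs[order(burst_epochs$start_s), , drop = FALSE]
    stopifnot(all(c("start_s", "end_s", "rate_hz") %in% names(be)),
              all(be$rate_hz >= 0), all(be$end_s > be$start_s),
              all(be$start_s >= 0), all(be$end_s <= duration_s))
    if (nrow(be) > 1L && any(be$start_s[-1L] < be$end_s[-nrow(be)])) {
      stop("overlapping burst epochs")
    }
  } else {
    be <- NULL
  }
  sim <- withr::with_seed(as.integer(seed), {
    rows <- lapply(seq_len(n_electrodes), function(e) {
      n_bg <- stats::rpois(1, rate_hz * duration_s)
      times <- stats::runif(n_bg, 0, duration_s)
      if (!is.null(be)) {
        for (k in seq_len(nrow(be))) {
          len <- be$end_s[k] - be$start_s[k]
          jitter <- if (sync < 1) {
            stats::runif(1, -(1 - sync) * len, (1 - sync) * len)
          } else 0
          s0 <- min(max(be$start_s[k] + jitter, 0), duration_s - len)
          n_b <- stats::rpois(1, be$rate_hz[k] * len)
          times <- c(times, stats::runif(n_b, s0, s0 + len))
        }
      }
      times <- sort(times)
      if (length(times)) {
        data.frame(well = well, electrode = e, time_s = times)
      } else {
        data.frame(well = character(0), electrode = integer(0),
                   time_s = numeric(0))
      }
    })
    do.call(rbind, rows)
  })
  spike_train_set(sim, duration_s = duration_s)
}

#' Write simulated data with its ground-truth sidecar
#'
#' Writes a [response_table()] or [spike_train_set()] as CSV together with
#' a JSON sidecar recording the generating parameters, so downstream
#' estimates can always be compared with truth.
#'
#' @param x The simulated object.
#' @param path Output CSV path; the sidecar goes to `<path>.truth.json`.
#' @param truth A list of ground-truth parameters to record.
#' @return `path`, invisibly.
#' @export
write_simulated <- function(x, path, truth = list()) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  jsonlite::write_json(truth, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
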