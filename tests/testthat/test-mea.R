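test_that("spike rate is spikes per second", {
  expect_equal(spike_rate(spike_train(seq(0.5, 300, 0.5), 300)), 2)
  expect_equal(spike_rate(spike_train(numeric(0), 300)), 0)
  expect_equal(spike_rate(spike_train(5, 300)), 1 / 300)
  expect_error(spike_train(c(2, 1), 300), "strictly increasing")
  expect_error(spike_train(c(1, 301), 300), "lie in")
})

test_that("burst detection applies the 5-in-100-ms rule", {
  b <- detect_bursts(spike_train(c(0, 0.01, 0.02, 0.03, 0.04), 10))
  expect_equal(nrow(b), 1)
  expect_equal(b$n_spikes, 5)
  # four spikes in 10 ms are not a burst
  expect_equal(nrow(detect_bursts(spike_train(c(0, 1e-3, 2e-3, 3e-3), 10))),
               0)
  # five spikes spread over more than 100 ms are not a burst
  expect_equal(nrow(detect_bursts(spike_train(seq(0, 0.2, 0.05), 10))), 0)
  # a long dense run is one maximal burst, not several
  run <- spike_train(seq(0, 0.24, 0.02), 10)
  b2 <- detect_bursts(run)
  expect_equal(nrow(b2), 1)
  expect_equal(b2$n_spikes, 13)
})

test_that("burst detection equals the exhaustive window-scan oracle", {
  for (seed in 1:300) {
    tr <- random_train(seed)
    got <- detect_bursts(tr)
    want <- oracle_bursts(tr$times)
    expect_equal(nrow(got), length(want), info = paste("seed", seed))
    if (length(want)) {
      expect_equal(got$i_start,
                   vapply(want, `[[`, integer(1), "i_start"),
                   info = paste("seed", seed))
      expect_equal(got$i_end,
                   vapply(want, `[[`, integer(1), "i_end"),
                   info = paste("seed", seed))
    }
  }
})

test_that("burst detection is invariant under time translation", {
  for (seed in 1:20) {
    tr <- random_train(seed, duration = 50)
    shifted <- spike_train(tr$times + 5, duration_s = 60)
    a <- detect_bursts(tr); b <- detect_bursts(shifted)
    expect_equal(nrow(a), nrow(b))
    if (nrow(a)) expect_equal(b$start_s - a$start_s, rep(5, nrow(a)))
  }
})

test_that("network bursts require synchronised bursting electrodes", {
  burst_times <- c(10, 10.01, 10.02, 10.03, 10.04)
  full_well <- lapply(1:12, function(e) {
    spike_train(burst_times, 300, electrode = e)
  })
  expect_equal(network_bursts(full_well), 1)   # all 12 in perfect synchrony
  # one silent electrode breaks the strict all-electrode rule
  eleven <- full_well
  eleven[[12]] <- spike_train(numeric(0), 300, electrode = 12)
  expect_equal(network_bursts(eleven), 0)
  expect_equal(network_bursts(eleven, min_fraction = 11 / 12), 1)
  # a single electrode at the loosest fraction counts its own bursts
  tr <- random_train(3)
  expect_equal(network_bursts(list(tr), min_fraction = 1e-6),
               nrow(detect_bursts(tr)))
  expect_error(network_bursts(list(spike_train(1, 10),
                                   spike_train(1, 20))),
               "share one recording duration")
})

test_that("network-burst counts match the 1-ms time-grid oracle", {
  for (seed in 1:30) {
    set.seed(seed)
    n_el <- sample(3:6, 1)
    trains <- lapply(seq_len(n_el), function(e) {
      # staggered dense clusters so burst intervals partially overlap
      starts <- sort(runif(sample(2:5, 1), 0, 50)) + runif(1, 0, 0.05)
      times <- sort(unlist(lapply(starts, function(s) {
        s + seq(0, 0.08, length.out = 8)
      })))
      spike_train(unique(times), 60, electrode = e)
    })
    frac <- sample(c(0.5, 1), 1)
    expect_equal(network_bursts(trains, min_fraction = frac),
                 oracle_network_count(trains, min_fraction = frac),
                 info = paste("seed", seed))
  }
})

test_that("day-0 normalisation divides by the pre-treatment baseline", {
  series <- data.frame(
    well = "w1", timepoint = c(0, 3, 7),
    spike_rate = c(2, 3, 1), burst_count = c(10, 20, 5),
    network_burst_count = c(4, 4, 2))
  out <- normalize_to_day0(series)
  expect_equal(out$spike_rate, c(1, 1.5, 0.5))
  expect_equal(out$burst_count, c(1, 2, 0.5))
  expect_equal(out$network_burst_count, c(1, 1, 0.5))

  zero <- series
  zero$burst_count[zero$timepoint == 0] <- 0
  expect_warning(out0 <- normalize_to_day0(zero), "flagged missing")
  expect_true(all(is.na(out0$burst_count)))
  expect_equal(out0$spike_rate, c(1, 1.5, 0.5))
})
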