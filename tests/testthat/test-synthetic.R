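test_that("zero-noise single-chemical tables reproduce the curve exactly", {
  cs <- curve_spec(100, 0, ec50 = 10, hill = 1)
  at_ec50 <- simulate_single_chemical(cs, 10, noise_spec(0, 4, 1))
  expect_equal(at_ec50$value, rep(50, 4))  # midpoint at the EC50

  for (seed in 1:5) {
    set.seed(seed)
    cs2 <- curve_spec(top = runif(1, 90, 110), bottom = runif(1, 0, 40),
                      ec50 = runif(1, 0.5, 50), hill = runif(1, 0.3, 4))
    doses <- sort(runif(7, 0.01, 100))
    tab <- simulate_single_chemical(cs2, doses, noise_spec(0, 3, seed))
    expect_equal(tab$value, rep(predict(cs2, doses), each = 3),
                 tolerance = 0)
  }
})

test_that("generators are deterministic under a fixed seed and validate input", {
  cs <- curve_spec(100, 0, 10, 1)
  a <- simulate_single_chemical(cs, c(1, 10), noise_spec(5, 6, 7))
  b <- simulate_single_chemical(cs, c(1, 10), noise_spec(5, 6, 7))
  expect_identical(a, b)
  c <- simulate_single_chemical(cs, c(1, 10), noise_spec(5, 6, 8))
  expect_false(identical(a$value, c$value))

  expect_error(simulate_single_chemical(cs, numeric(0)), "empty")
  expect_error(simulate_single_chemical(cs, c(-1, 2)), "positive")
  expect_error(simulate_single_chemical(cs, c(10, 1)), "ascending")

  # the generator must not disturb the caller's RNG stream
  set.seed(99); before <- runif(1)
  set.seed(99); invisible(simulate_single_chemical(cs, 1, noise_spec(5, 3, 1)))
  expect_identical(runif(1), before)
})

test_that("additive mixtures follow exact dose addition", {
  cs <- curve_spec(100, 0, ec50 = 10, hill = 1.5)
  # single component reduces to the single-chemical simulation
  mix1 <- simulate_mixture(list(list(curve = cs, conc = 7)),
                           noise = noise_spec(0, 3, 1))
  expect_equal(unique(mix1$value), predict(cs, 7))

  # two identical curves at c equal the single curve at 2c
  mix2 <- simulate_mixture(list(list(curve = cs, conc = 4),
                                list(curve = cs, conc = 4)),
                           noise = noise_spec(0, 3, 1))
  expect_equal(unique(mix2$value), predict(cs, 8))

  # components at the 5%-benchmark-equivalent dose / k predict a 5% deviation
  bmd5_equiv <- inverse_curve(cs, 95)
  for (k in c(2, 5)) {
    comps <- replicate(k, list(curve = cs, conc = bmd5_equiv / k),
                       simplify = FALSE)
    mixk <- simulate_mixture(comps, noise = noise_spec(0, 2, 1))
    expect_equal(attr(mixk, "ca_prediction"), 95, tolerance = 1e-10)
  }

  # EC50-ratio scaling: a twice-as-potent second component counts double
  cs_potent <- curve_spec(100, 0, ec50 = 5, hill = 1.5)
  mix3 <- simulate_mixture(list(list(curve = cs, conc = 2),
                                list(curve = cs_potent, conc = 3)),
                           noise = noise_spec(0, 2, 1))
  expect_equal(attr(mix3, "equivalent_dose"), 2 + 3 * 10 / 5)

  expect_error(simulate_mixture(list()), "empty")
})

test_that("injected interactions shift the deviation by the stated amount", {
  cs <- curve_spec(100, 0, ec50 = 10, hill = 1.5)
  comps <- list(list(curve = cs, conc = 5))
  base <- predict(cs, 5)
  syn <- simulate_mixture(comps, interaction_spec("synergistic", 10),
                          noise_spec(0, 2, 1))
  expect_equal(attr(syn, "true_mean"), base - 10)
  ant <- simulate_mixture(comps, interaction_spec("antagonistic", 10),
                          noise_spec(0, 2, 1))
  expect_equal(attr(ant, "true_mean"), base + 10)
  # antagonism cannot overshoot past the control level
  weak <- simulate_mixture(list(list(curve = cs, conc = 0.01)),
                           interaction_spec("antagonistic", 50),
                           noise_spec(0, 2, 1))
  expect_equal(attr(weak, "true_mean"), 100)
  expect_error(interaction_spec("additive", 5), "deviation_pct")
})

test_that("simulated MEA wells respect rate, sync and determinism contracts", {
  empty <- simulate_mea_well(0, NULL, duration_s = 60, n_electrodes = 3,
                             seed = 1)
  expect_equal(nrow(empty), 0)

  a <- simulate_mea_well(2, NULL, duration_s = 60, n_electrodes = 3,
                         seed = 5)
  b <- simulate_mea_well(2, NULL, duration_s = 60, n_electrodes = 3,
                         seed = 5)
  expect_identical(as.data.frame(a), as.data.frame(b))

  epochs <- data.frame(start_s = c(10, 40), end_s = c(10.4, 40.4),
                       rate_hz = 150)
  bad <- data.frame(start_s = c(10, 10.2), end_s = c(10.4, 10.6),
                    rate_hz = 150)
  expect_error(simulate_mea_well(1, bad, duration_s = 60, seed = 1),
               "overlapping")

  # dense epochs are detected as bursts in essentially every seeded run
  hits <- vapply(1:100, function(s) {
    w <- simulate_mea_well(0.5, epochs, duration_s = 60, n_electrodes = 1,
                           seed = s)
    tr <- as_spike_trains(w)[[1]]
    bursts <- detect_bursts(tr)
    all(vapply(seq_len(nrow(epochs)), function(k) {
      any(bursts$start_s <= epochs$end_s[k] &
            bursts$end_s >= epochs$start_s[k])
    }, logical(1)))
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})
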