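make_plate <- function(samples_au, blank = 50, ctrl = 1050, n_ctrl = 4) {
  data.frame(
    chemical = c(rep("blank", 2), rep("DMSO", n_ctrl),
                 paste0("s", seq_along(samples_au))),
    role = c(rep("blank", 2), rep("control", n_ctrl),
             rep("treated", length(samples_au))),
    concentration = c(rep(0, 2 + n_ctrl), seq_along(samples_au)),
    unit = "uM", replicate = 1,
    au = c(rep(blank, 2), rep(ctrl, n_ctrl), samples_au))
}

test_that("normalisation applies the blank-subtracted control formula", {
  out <- normalize_to_control(make_plate(c(850, 1050, 50)))
  treated <- out[out$role == "treated", ]
  expect_equal(treated$value, c(80, 100, 0))      # formula, identity, zero
  expect_equal(mean(out$value[out$role == "control"]), 100)

  # unusable plate: control does not rise above blank
  expect_error(normalize_to_control(make_plate(900, blank = 500, ctrl = 400)),
               class = "dntmix_unusable_plate")

  # normalising an already-normalised table (blank 0, control 100) is identity
  renorm <- normalize_to_control(make_plate(treated$value, blank = 0,
                                            ctrl = 100))
  expect_equal(renorm$value[renorm$role == "treated"], treated$value)
})

test_that("4PL fitting recovers generating parameters from clean data", {
  truth <- curve_spec(100, 0, ec50 = 10, hill = 1.5)
  fit <- fit_4pl(viab_tab(truth, sd = 0, n = 2, seed = 1))
  expect_true(fit$converged)
  expect_equal(fit$curve$top, 100, tolerance = 1e-6)
  expect_equal(fit$curve$ec50, 10, tolerance = 1e-6)
  expect_equal(fit$curve$hill, 1.5, tolerance = 1e-6)
  expect_lt(abs(fit$curve$bottom), 1e-4)

  # increasing curves are recovered too
  up <- curve_spec(100, 150, ec50 = 5, hill = 2)
  fit_up <- fit_4pl(viab_tab(up, sd = 0, n = 2, seed = 1,
                             doses = 5 * 4^(-3:3)))
  expect_true(fit_up$converged)
  expect_equal(fit_up$curve$ec50, 5, tolerance = 1e-5)
  expect_equal(fit_up$curve$direction, "increasing")
})

test_that("degenerate and noisy inputs are handled honestly", {
  flat <- data.frame(concentration = rep(std_doses(), each = 2), value = 100)
  expect_false(fit_4pl(flat)$converged)
  expect_error(fit_4pl(data.frame(concentration = rep(1:4, 2),
                                  value = rnorm(8, 100))),
               "5 distinct")

  # noisy recovery: ec50 lands near truth (seeded)
  truth <- curve_spec(100, 0, 10, 1.5)
  fit <- fit_4pl(viab_tab(truth, sd = 5, n = 6, seed = 42))
  expect_true(fit$converged)
  expect_lt(abs(log(fit$curve$ec50 / 10)), log(1.5))
})

test_that("ICx inversion matches the root-finding oracle and round-trips", {
  truth <- curve_spec(100, 0, 10, 1.5)
  fit <- fit_4pl(viab_tab(truth, sd = 0, n = 2, seed = 1))

  expect_equal(invert_icx(fit, 50)$concentration, 10, tolerance = 1e-6)
  expect_equal(invert_icx(fit, 20)$concentration, 3.9685, tolerance = 1e-4)
  expect_equal(invert_icx(fit, 20)$concentration,
               oracle_icx(fit$curve, 20), tolerance = 1e-8)
  # IC20/100 is the IC20 divided by 100
  expect_equal(invert_icx(fit, 20, derived_divisor = 100)$concentration,
               invert_icx(fit, 20)$concentration / 100)

  # round trip and ordering over random decreasing curves
  for (seed in 1:10) {
    set.seed(seed)
    cs <- curve_spec(top = runif(1, 95, 105), bottom = runif(1, 0, 20),
                     ec50 = runif(1, 1, 20), hill = runif(1, 0.5, 3))
    f <- fit_4pl(viab_tab(cs, 0, 2, seed, doses = cs$ec50 * 4^(-3:3)))
    lv <- runif(1, 1, 0.8 * (cs$top - cs$bottom))
    conc <- invert_icx(f, lv)$concentration
    expect_equal(predict(f$curve, conc), f$curve$top - lv,
                 tolerance = 1e-8)
    expect_lt(invert_icx(f, 5)$concentration,
              invert_icx(f, 20)$concentration)
  }

  expect_error(invert_icx(fit, 120), class = "dntmix_level_unattainable")
})

test_that("truncated curves refuse extrapolation but allow substitution", {
  # highest tested dose only reaches ~6% inhibition (solubility-limited)
  truth <- curve_spec(100, 0, ec50 = 830, hill = 1.3)
  doses <- rev(serial_dilution(83, 4, 7, 4))
  fit <- fit_4pl(simulate_single_chemical(truth, doses, noise_spec(0, 2, 1)))
  expect_error(invert_icx(fit, 20), class = "dntmix_icx_out_of_range")
  ics <- ic_levels(fit, substitute_highest = TRUE)
  expect_true(ics$truncated[ics$anchor == "IC20"])
  expect_equal(ics$concentration[ics$anchor == "IC20"], 83)
})
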