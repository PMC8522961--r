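test_that("Dunnett comparisons flag planted effects and honest nulls", {
  # a 10-SD shift in the top group is essentially always ***
  hits <- vapply(1:20, function(s) {
    tab <- feature_tab(s, shift = 50, shift_at = 8)
    rec <- dunnett_vs_control(response_table(tab), seed = s)
    rec$p_adj[rec$concentration == 8] < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.99)

  rec <- dunnett_vs_control(response_table(feature_tab(1)), seed = 1)
  expect_equal(nrow(rec), 4)             # one record per treated conc
  expect_true(all(rec$p_adj >= 0 & rec$p_adj <= 1))
  expect_true(all(rec$tier %in% c("ns", "*", "**", "***")))

  const <- feature_tab(1, sd = 0)
  expect_error(dunnett_vs_control(response_table(const)),
               class = "dntmix_degenerate_variance")
  no_ctrl <- feature_tab(1)
  no_ctrl <- no_ctrl[no_ctrl$role != "control", ]
  expect_error(dunnett_vs_control(response_table(no_ctrl)), "control")
})

test_that("LOAEC is the lowest concentration significant on any feature", {
  rec <- function(feature, concentration, tier) {
    data.frame(chemical = "x", endpoint = "ep", feature = feature,
               concentration = concentration, estimate = 0, p_adj = 0.5,
               tier = tier, significant = tier != "ns")
  }
  # significance only at the highest tested concentration
  r1 <- rbind(rec("f1", 1, "ns"), rec("f1", 2, "ns"),
              rec("f1", 4, "ns"), rec("f1", 8, "*"))
  expect_equal(derive_loaec(r1)$loaec, 8)
  # nothing significant: undefined, a valid outcome
  r2 <- rbind(rec("f1", 1, "ns"), rec("f1", 2, "ns"))
  out <- derive_loaec(r2)
  expect_false(out$defined)
  expect_true(is.na(out$loaec))
  # "at least one feature": feature A at 2 beats feature B at 4
  r3 <- rbind(rec("fA", 2, "*"), rec("fA", 4, "ns"),
              rec("fB", 2, "ns"), rec("fB", 4, "**"))
  d3 <- derive_loaec(r3)
  expect_equal(d3$loaec, 2)
  expect_equal(d3$basis_feature, "fA")

  # monotone: adding significance records can only lower (or keep) the LOAEC
  for (seed in 1:10) {
    set.seed(seed)
    concs <- c(1, 2, 4, 8)
    tiers <- sample(c("ns", "*"), 4, replace = TRUE)
    base <- do.call(rbind, Map(rec, "f1", concs, tiers))
    extra <- rec("f2", sample(concs, 1), "*")
    l_base <- derive_loaec(base)$loaec
    l_more <- derive_loaec(rbind(base, extra))$loaec
    if (!is.na(l_base)) expect_lte(l_more, l_base)
  }
})

test_that("serial dilutions reproduce the printed concentration series", {
  expect_equal(serial_dilution(100, 4, 7, 2),
               c(100, 25, 6.25, 1.56, 0.39, 0.10, 0.02))
  etoh <- serial_dilution(200, 4, 7, 2)
  expect_equal(etoh, c(200, 50, 12.50, 3.13, 0.78, 0.20, 0.05))
  expect_equal(etoh[4], 3.13)
  expect_equal(serial_dilution(830, 4, 7, 2),
               c(830, 207.5, 51.88, 12.97, 3.24, 0.81, 0.20))
  expect_equal(serial_dilution(1000, 4, 6, 1),
               c(1000, 250, 62.5, 15.6, 3.9, 1.0))
  expect_error(serial_dilution(100, 1, 5), "factor")
  # unrounded series are exactly geometric
  v <- serial_dilution(137.7, 3, 9, 12)
  expect_equal(v[-length(v)] / v[-1], rep(3, 8), tolerance = 1e-9)
})

test_that("mixture design tables halve unrounded anchors per chemical", {
  lo <- data.frame(chemical = c("BPA", "CPF"),
                   endpoint = c("bdnf", "syn"),
                   loaec = c(12.74, 21.01))
  d <- build_mixture_design(lo[1, ], list(mix = "BPA"),
                            decimals = c(BPA = 2))
  expect_equal(d$concentration, c(12.74, 6.37, 3.19, 1.59))
  d2 <- build_mixture_design(lo[2, ], list(mix = "CPF"),
                             decimals = c(CPF = 2))
  expect_equal(d2$concentration[d2$dilution_level == 0.5], 10.51)
  # dilution factor 1 reproduces the LOAEC table
  d3 <- build_mixture_design(lo[1, ], list(m1 = "BPA"), levels = 1)
  expect_equal(d3$concentration, 12.74)
  # undefined LOAEC for a member is an error
  lo_na <- data.frame(chemical = "Z", endpoint = "bdnf", loaec = NA_real_)
  expect_error(build_mixture_design(lo_na, list(m = "Z")),
               class = "dntmix_undefined_loaec")
})
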