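lin_tab <- function(slope = 1, n = 3, sd = 0, seed = 1,
                    concs = c(0, 1, 2, 4, 8, 16)) {
  set.seed(seed)
  data.frame(chemical = "lin", endpoint = "ep",
             concentration = rep(concs, each = n), unit = "uM",
             replicate = rep(seq_len(n), length(concs)),
             value = 100 - slope * rep(concs, each = n) +
               rnorm(length(concs) * n, 0, sd))
}

test_that("the generating family achieves the lowest AIC", {
  mods <- fit_model_family(lin_tab())
  aics <- vapply(mods, function(m) m$aic, numeric(1))
  expect_equal(names(which.min(aics)), "linear")
  expect_equal(select_best(mods)$family, "linear")

  hill_dat <- viab_tab(curve_spec(100, 0, 10, 1.5), sd = 0, n = 2, seed = 1)
  mods_h <- fit_model_family(hill_dat)
  aics_h <- vapply(mods_h, function(m) m$aic, numeric(1))
  expect_equal(names(which.min(aics_h)), "hill")

  # AIC bookkeeping: aic = 2k - 2 loglik
  for (m in mods) {
    if (m$converged) expect_equal(m$aic, 2 * m$k - 2 * m$loglik)
  }
})

test_that("model selection applies the tie-break rules", {
  mk <- function(family, aic, k) {
    structure(list(family = family, aic = aic, k = k, converged = TRUE),
              class = "parametric_model")
  }
  expect_equal(select_best(list(mk("hill", 3, 5)))$family, "hill")
  expect_equal(select_best(list(mk("linear", 10, 3),
                                mk("hill", 12, 5)))$family, "linear")
  expect_equal(select_best(list(mk("hill", 10, 5),
                                mk("linear", 10, 3)))$family, "linear")
  # equal AIC and k: fixed family order decides
  expect_equal(select_best(list(mk("power", 10, 4),
                                mk("poly2", 10, 4)))$family, "poly2")
  expect_error(select_best(list()), "empty")
})

test_that("benchmark doses solve the 5% deviation equation", {
  m <- select_best(fit_model_family(lin_tab()))
  b <- compute_bmd(m, n_boot = 50, seed = 1)
  expect_equal(b$bmd5, 5, tolerance = 1e-9)        # 100 - c: closed form
  expect_equal(b$direction, "decrease")
  expect_equal(predict_bmr(b, 7)$bmr_pct, 7, tolerance = 1e-9)
  expect_equal(predict_bmr(b, 0)$bmr_pct, 0)

  # hill truth: compare against the numeric oracle on the true curve
  truth <- curve_spec(100, 0, 10, 1.5)
  hb <- compute_bmd(select_best(fit_model_family(
    viab_tab(truth, sd = 0, n = 2, seed = 1))), n_boot = 50, seed = 1)
  oracle <- uniroot(function(c) (100 - predict(truth, c)) - 5,
                    c(1e-9, 10), tol = 1e-12)$root
  expect_equal(hb$bmd5, oracle, tolerance = 1e-4)
  expect_equal(oracle, 1.40442, tolerance = 1e-4)

  # self-consistency: the BMR at the BMD is the benchmark response
  expect_equal(predict_bmr(hb, hb$bmd5)$bmr_pct, 5, tolerance = 1e-6)
})

test_that("BMD errors when the benchmark response is never reached", {
  const <- lin_tab(slope = 0, sd = 0.5, seed = 3)
  m <- select_best(fit_model_family(const, families = c("linear", "poly2")))
  expect_error(compute_bmd(m, n_boot = 10, seed = 1),
               class = "dntmix_bmr_not_reached")
})

test_that("bootstrap bounds bracket the point estimate", {
  for (seed in 1:25) {
    m <- select_best(fit_model_family(lin_tab(sd = 4, seed = seed),
                                      families = c("linear", "poly2")))
    b <- compute_bmd(m, n_boot = 100, seed = seed)
    expect_lte(b$bmdl, b$bmd5)
    expect_gte(b$bmdu, b$bmd5)
  }
  # repeated calls with one seed agree exactly
  m <- select_best(fit_model_family(lin_tab(sd = 4, seed = 7)))
  b1 <- compute_bmd(m, n_boot = 100, seed = 11)
  b2 <- compute_bmd(m, n_boot = 100, seed = 11)
  expect_identical(c(b1$bmdl, b1$bmd5, b1$bmdu),
                   c(b2$bmdl, b2$bmd5, b2$bmdu))
})

test_that("extrapolated BMR predictions are flagged", {
  m <- select_best(fit_model_family(lin_tab()))
  b <- compute_bmd(m, n_boot = 20, seed = 1)
  expect_warning(p <- predict_bmr(b, 100), "extrapolated")
  expect_true(p$extrapolated)
})
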