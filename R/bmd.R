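#' Fit the continuous benchmark-dose model family
#'
#' Fits each member of a fixed family of continuous dose-response models
#' by maximum likelihood with Gaussian error (equivalently least squares):
#' linear, second-order polynomial, power, hill (four-parameter logistic)
#' and three-parameter exponential. Individual family failures are
#' recorded, not fatal; only if every family fails is an error raised.
#' The AIC is `2k - 2 loglik` with `k` counting the mean parameters plus
#' the error variance.
#'
#' @param responses A [response_table()] (or data.frame with
#'   `concentration` and `value`) for one chemical/endpoint; zero-dose
#'   control rows are used to anchor the modelled control response.
#' @param families Character vector of families to fit.
#' @return A list of class `model_family_fits` of `parametric_model`
#'   objects, one per requested family (failed fits have
#'   `converged = FALSE`).
#' @export
fit_model_family <- function(responses,
                             families = c("linear", "poly2", "power",
                                          "hill", "exp3")) {
  dat <- as.data.frame(responses)
  doses <- dat$concentration
  values <- dat$value
  if (length(unique(doses[doses > 0])) < 4L) {
    stop("need >= 4 distinct positive concentrations for BMD analysis")
  }
  families <- match.arg(families, several.ok = TRUE)
  meta <- list(chemical = if ("chemical" %in% names(dat))
    as.character(dat$chemical[1]) else "chem",
    endpoint = if ("endpoint" %in% names(dat))
      as.character(dat$endpoint[1]) else "endpoint")
  fits <- lapply(families, function(fam) {
    .fit_one_family(fam, doses, values, meta)
  })
  names(fits) <- families
  if (!any(vapply(fits, function(f) f$converged, logical(1)))) {
    stop_dntmix("all model families failed to fit (degenerate data)",
                "dntmix_all_families_failed")
  }
  structure(fits, class = "model_family_fits")
}

# Gaussian log-likelihood at the least-squares optimum; sigma^2 floored so
# interpolating fits of exact data share one finite likelihood and model
# comparison falls through to the parameter-count tie-break.
.gauss_ll <- function(rss, n) {
  sigma2 <- max(rss / n, 1e-12)
  -n / 2 * (log(2 * pi * sigma2) + 1)
}

.make_model <- function(family, coefs, fn, rss, n_mean_par, doses, values,
                        meta, converged = TRUE, reason = "ok") {
  n <- length(values)
  ll <- .gauss_ll(rss, n)
  k <- n_mean_par + 1L  # + error variance
  structure(list(family = family, coefs = coefs, fn = fn, rss = rss,
                 loglik = ll, aic = 2 * k - 2 * ll, k = k,
                 n_mean_par = n_mean_par, converged = converged,
                 reason = reason, doses = doses, values = values,
                 dose_range = range(doses),
                 chemical = meta$chemical, endpoint = meta$endpoint),
            class = "parametric_model")
}

.fail_model <- function(family, doses, values, meta, reason) {
  m <- .make_model(family, NULL, NULL, Inf, 0L, doses, values, meta,
                   converged = FALSE, reason = reason)
  m$aic <- Inf
  m
}

.fit_one_family <- function(family, doses, values, meta) {
  try_fit <- function(expr) tryCatch(expr, error = function(e) {
    .fail_model(family, doses, values, meta, conditionMessage(e))
  })
  switch(family,
    linear = try_fit({
      X <- cbind(1, doses)
      cf <- stats::lm.fit(X, values)$coefficients
      fn <- function(c) cf[1] + cf[2] * c
      .make_model("linear", c(a = unname(cf[1]), b = unname(cf[2])), fn,
                  sum((values - fn(doses))^2), 2L, doses, values, meta)
    }),
    poly2 = try_fit({
      X <- cbind(1, doses, doses^2)
      cf <- stats::lm.fit(X, values)$coefficients
      fn <- function(c) cf[1] + cf[2] * c + cf[3] * c^2
      .make_model("poly2",
                  c(a = unname(cf[1]), b = unname(cf[2]),
                    d = unname(cf[3])),
                  fn, sum((values - fn(doses))^2), 3L, doses, values, meta)
    }),
    power = try_fit(.fit_power(doses, values, meta)),
    hill = try_fit(.fit_hill(doses, values, meta)),
    exp3 = try_fit(.fit_exp3(doses, values, meta)),
    stop("unknown family: ", family))
}

# power model f(c) = a + b * c^p: profile the exponent on a deterministic
# grid (linear subfit for a, b), then refine around the best grid value.
.fit_power <- function(doses, values, meta) {
  p_grid <- exp(seq(log(0.25), log(6), length.out = 25))
  rss_at <- function(p) {
    X <- cbind(1, doses^p)
    sum(stats::lm.fit(X, values)$residuals^2)
  }
  rss_grid <- vapply(p_grid, rss_at, numeric(1))
  i <- which.min(rss_grid)
  lo <- p_grid[max(1, i - 1)]; hi <- p_grid[min(length(p_grid), i + 1)]
  opt <- stats::optimize(rss_at, c(lo, hi), tol = 1e-10)
  p <- opt$minimum
  cf <- stats::lm.fit(cbind(1, doses^p), values)$coefficients
  fn <- function(c) cf[1] + cf[2] * c^p
  .make_model("power",
              c(a = unname(cf[1]), b = unname(cf[2]), p = p), fn,
              sum((values - fn(doses))^2), 3L, doses, values, meta)
}

# hill model: the 4PL evaluated on the raw dose scale (zero dose allowed),
# deterministic multi-start nonlinear least squares.
.fit_hill <- function(doses, values, meta) {
  mu4 <- function(c, top, bottom, lec50, lhill) {
    x <- ifelse(c > 0, exp(exp(lhill) * (log(c) - lec50)), 0)
    bottom + (top - bottom) / (1 + x)
  }
  pos <- sort(unique(doses[doses > 0]))
  dose_means <- tapply(values, doses, mean)
  top0 <- as.numeric(dose_means[1])
  bot0 <- as.numeric(dose_means[length(dose_means)])
  if (abs(top0 - bot0) < 1e-10) bot0 <- top0 - 1
  starts <- expand.grid(
    lec50 = log(stats::quantile(pos, c(1 / 3, 2 / 3), names = FALSE)),
    hill = c(0.5, 1, 2, 4))
  best <- NULL
  for (j in seq_len(nrow(starts))) {
    fit <- tryCatch(suppressWarnings(
      minpack.lm::nlsLM(
        values ~ mu4(doses, top, bottom, lec50, lhill),
        start = list(top = top0, bottom = bot0,
                     lec50 = starts$lec50[j],
                     lhill = log(starts$hill[j])),
        control = minpack.lm::nls.lm.control(maxiter = 500))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12) {
        best <- list(fit = fit, rss = rss)
      }
    }
  }
  if (is.null(best)) stop("hill: no start converged")
  cf <- stats::coef(best$fit)
  fn <- function(c) mu4(c, cf[["top"]], cf[["bottom"]], cf[["lec50"]],
                        cf[["lhill"]])
  .make_model("hill",
              c(top = unname(cf[["top"]]), bottom = unname(cf[["bottom"]]),
                ec50 = exp(unname(cf[["lec50"]])),
                hill = exp(unname(cf[["lhill"]]))),
              fn, best$rss, 4L, doses, values, meta)
}

# exponential model f(c) = a * exp(b * c^d): log-linear profile of d for
# the start, then full nonlinear refinement.
.fit_exp3 <- function(doses, values, meta) {
  if (any(values <= 0)) values_pos <- pmax(values, 1e-6) else
    values_pos <- values
  d_grid <- exp(seq(log(0.25), log(4), length.out = 13))
  rss_log <- vapply(d_grid, function(d) {
    X <- cbind(1, doses^d)
    sum(stats::lm.fit(X, log(values_pos))$residuals^2)
  }, numeric(1))
  d0 <- d_grid[which.min(rss_log)]
  cf0 <- stats::lm.fit(cbind(1, doses^d0), log(values_pos))$coefficients
  fit <- tryCatch(suppressWarnings(
    minpack.lm::nlsLM(
      values ~ a * exp(b * doses^exp(ld)),
      start = list(a = exp(cf0[1]), b = cf0[2], ld = log(d0)),
      control = minpack.lm::nls.lm.control(maxiter = 500))),
    error = function(e) NULL)
  if (is.null(fit)) stop("exp3: fit failed")
  cf <- stats::coef(fit)
  fn <- function(c) cf[["a"]] * exp(cf[["b"]] * c^exp(cf[["ld"]]))
  .make_model("exp3",
              c(a = unname(cf[["a"]]), b = unname(cf[["b"]]),
                d = exp(unname(cf[["ld"]]))),
              fn, sum(stats::resid(fit)^2), 3L, doses, values, meta)
}

#' @export
print.parametric_model <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("%s model: AIC = %.3f, loglik = %.3f, k = %d\n",
                x$family, x$aic, x$loglik, x$k))
    print(signif(x$coefs, 6))
  } else {
    cat(sprintf("%s model: failed (%s)\n", x$family, x$reason))
  }
  invisible(x)
}

#' Select the best-fitting parametric model
#'
#' Lowest AIC among converged fits; ties are broken by fewer parameters,
#' then by a fixed family order (linear, poly2, power, hill, exp3), so
#' selection is fully deterministic.
#'
#' @param models A `model_family_fits` list (or list of
#'   `parametric_model`).
#' @return The selected `parametric_model`.
#' @export
select_best <- function(models) {
  if (length(models) == 0L) stop("empty model list")
  models <- Filter(function(m) isTRUE(m$converged), models)
  if (length(models) == 0L) stop("no converged model to select from")
  fam_order <- c("linear", "poly2", "power", "hill", "exp3")
  ord <- order(vapply(models, function(m) m$aic, numeric(1)),
               vapply(models, function(m) m$k, numeric(1)),
               match(vapply(models, function(m) m$family, character(1)),
                     fam_order))
  models[[ord[1]]]
}

# Solve |f(c) - f(0)| = (bmr_level/100) * |f(0)| on [0, cmax].
# Returns NA when the deviation never reaches the benchmark response.
.solve_bmd <- function(fn, cmax, bmr_level, check_unique = FALSE) {
  f0 <- fn(0)
  target <- bmr_level / 100 * abs(f0)
  g <- function(c) abs(fn(c) - f0) - target
  grid <- seq(0, cmax, length.out = 401L)
  gv <- vapply(grid, g, numeric(1))
  crossings <- which(gv[-1] >= 0 & gv[-length(gv)] < 0)
  if (length(crossings) == 0L) return(list(bmd = NA_real_, unique = TRUE))
  root <- stats::uniroot(g, c(grid[crossings[1]], grid[crossings[1] + 1]),
                         tol = 1e-12)$root
  n_cross <- if (check_unique) {
    sum(abs(diff(sign(gv[gv != 0] + 1e-300))) > 0)
  } else 1L
  list(bmd = root, unique = length(crossings) == 1L)
}

#' Compute the benchmark dose with bootstrap bounds
#'
#' Solves for the dose at which the best-fit model's predicted response
#' deviates from the modelled control response `f(0)` by `bmr_level`% of
#' `f(0)` (on the normalised scale where `f(0)` is close to 100%,
#' relative and absolute 5% changes coincide). Uncertainty bounds BMDL
#' and BMDU come from a seeded nonparametric bootstrap: replicates are
#' resampled within each dose level, the same model family is refitted,
#' and the 2.5/97.5 percentiles of the re-derived BMDs are taken,
#' clamped to bracket the point estimate.
#'
#' @param model A converged `parametric_model` (it carries its data).
#' @param bmr_level Benchmark response, % change of the control response
#'   (default 5).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap resampling.
#' @param ci Bootstrap interval coverage (default 0.95).
#' @return An object of class `bmd_result`: `chemical`, `endpoint`,
#'   `bmd5` (named after the requested level), `bmdl`, `bmdu`,
#'   `best_model`, `direction`, `bmr_level`, `n_boot_ok`, `unique_root`.
#' @examples
#' tab <- data.frame(concentration = rep(c(0, 1, 2, 4, 8), each = 3),
#'                   value = 100 - rep(c(0, 1, 2, 4, 8), each = 3))
#' m <- select_best(fit_model_family(tab, families = "linear"))
#' compute_bmd(m, n_boot = 50, seed = 1)$bmd5 # 5 for f = 100 - c
#' @export
compute_bmd <- function(model, bmr_level = 5, n_boot = 1000, seed = 1L,
                        ci = 0.95) {
  stopifnot(inherits(model, "parametric_model"))
  if (!model$converged) stop("cannot compute a BMD from a failed fit")
  stopifnot(bmr_level > 0, ci > 0, ci < 1)
  cmax <- max(model$dose_range)
  sol <- .solve_bmd(model$fn, cmax, bmr_level, check_unique = TRUE)
  if (is.na(sol$bmd)) {
    stop_dntmix(
      sprintf("predicted deviation never reaches %g%% within the tested range",
              bmr_level),
      "dntmix_bmr_not_reached")
  }
  if (!sol$unique) {
    warning("deviation function crosses the benchmark response more than once; ",
            "reporting the lowest crossing")
  }
  f0 <- model$fn(0)
  direction <- if (model$fn(sol$bmd) >= f0) "increase" else "decrease"

  doses <- model$doses
  values <- model$values
  groups <- split(seq_along(doses), doses)
  boot_bmds <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(b) {
      idx <- unlist(lapply(groups, function(g) {
        g[sample.int(length(g), length(g), replace = TRUE)]
      }), use.names = FALSE)
      m <- tryCatch(
        .fit_one_family(model$family, doses[idx], values[idx],
                        list(chemical = model$chemical,
                             endpoint = model$endpoint)),
        error = function(e) NULL)
      if (is.null(m) || !m$converged) return(NA_real_)
      .solve_bmd(m$fn, cmax, bmr_level)$bmd
    }, numeric(1))
  })
  ok <- boot_bmds[is.finite(boot_bmds)]
  alpha <- (1 - ci) / 2
  if (length(ok) >= 20L) {
    qs <- stats::quantile(ok, c(alpha, 1 - alpha), names = FALSE, type = 7)
    bmdl <- min(qs[1], sol$bmd)
    bmdu <- max(qs[2], sol$bmd)
  } else {
    bmdl <- bmdu <- sol$bmd
    warning("fewer than 20 usable bootstrap replicates; bounds collapsed ",
            "to the point estimate")
  }
  structure(list(chemical = model$chemical, endpoint = model$endpoint,
                 bmd5 = sol$bmd, bmdl = bmdl, bmdu = bmdu,
                 best_model = model, direction = direction,
                 bmr_level = bmr_level, n_boot_ok = length(ok),
                 unique_root = sol$unique),
            class = "bmd_result")
}

#' @export
print.bmd_result <- function(x, ...) {
  cat(sprintf(
    "BMD%g [%s, %s]: %.4g [%.4g, %.4g] (%s, %s model)\n",
    x$bmr_level, x$chemical, x$endpoint, x$bmd5, x$bmdl, x$bmdu,
    x$direction, x$best_model$family))
  invisible(x)
}

#' Predict the benchmark response at a nominal concentration
#'
#' The absolute benchmark response of a single chemical at an arbitrary
#' concentration (typically its nominal concentration inside a mixture),
#' under the best-fit model from its own dose-response analysis:
#' `bmr_pct = |f(c) - f(0)| / f(0) * 100`.
#'
#' @param result A [compute_bmd()] result.
#' @param concentration Non-negative concentration(s).
#' @return Data.frame with `chemical`, `endpoint`, `concentration`,
#'   `bmr_pct`, `extrapolated` (flagged beyond twice the maximum tested
#'   dose, with a warning).
#' @export
predict_bmr <- function(result, concentration) {
  stopifnot(inherits(result, "bmd_result"),
            is.numeric(concentration), all(concentration >= 0))
  fn <- result$best_model$fn
  f0 <- fn(0)
  bmr <- abs(vapply(concentration, fn, numeric(1)) - f0) / f0 * 100
  extrap <- concentration > 2 * max(result$best_model$dose_range)
  if (any(extrap)) {
    warning("concentration(s) beyond twice the tested range; BMR flagged ",
            "as extrapolated")
  }
  data.frame(chemical = result$chemical, endpoint = result$endpoint,
             concentration = concentration, bmr_pct = bmr,
             extrapolated = extrap)
}

#' Export BMD results as a flat table
#'
#' @param results List of `bmd_result` objects.
#' @param path Optional CSV path; when given the table is also written.
#' @return Data.frame with one row per (chemical, endpoint).
#' @export
bmd_table <- function(results, path = NULL) {
  rows <- lapply(results, function(r) {
    data.frame(chemical = r$chemical, endpoint = r$endpoint,
               bmd5 = r$bmd5, bmdl = r$bmdl, bmdu = r$bmdu,
               best_model = r$best_model$family, direction = r$direction)
  })
  out <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
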