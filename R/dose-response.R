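#' Normalise raw plate fluorescence to the solvent control
#'
#' Blank-subtracts raw arbitrary-unit readings and expresses them as % of
#' the solvent-control mean:
#' `value = 100 * (AU - mean(blank)) / (mean(control) - mean(blank))`.
#' Control rows are retained (they average 100% by construction); blank
#' rows are consumed.
#'
#' @param raw Data.frame with columns `chemical`, `role` (one of
#'   `"blank"`, `"control"`, `"treated"`), `concentration`, `unit`,
#'   `replicate`, `au` (raw fluorescence, >= 0).
#' @param endpoint Endpoint label for the output table.
#' @return A [response_table()] with the `role` column preserved.
#' @examples
#' raw <- data.frame(
#'   chemical = c("blank", "DMSO", "chemA"),
#'   role = c("blank", "control", "treated"),
#'   concentration = c(0, 0, 10), unit = "uM", replicate = 1,
#'   au = c(50, 1050, 850))
#' normalize_to_control(raw)$value[2] # 80% of control
#' @export
normalize_to_control <- function(raw, endpoint = "viability") {
  stopifnot(all(c("chemical", "role", "concentration", "unit", "replicate",
                  "au") %in% names(raw)))
  if (any(raw$au < 0)) stop("raw fluorescence must be >= 0")
  if (!any(raw$role == "blank")) stop("no blank wells on plate")
  if (!any(raw$role == "control")) stop("no solvent-control wells on plate")
  blank <- mean(raw$au[raw$role == "blank"])
  ctrl <- mean(raw$au[raw$role == "control"])
  if (ctrl <= blank) {
    stop_dntmix(
      sprintf("mean control signal (%g) does not exceed mean blank (%g): unusable plate",
              ctrl, blank),
      "dntmix_unusable_plate")
  }
  keep <- raw$role != "blank"
  out <- data.frame(
    chemical = raw$chemical[keep], endpoint = endpoint,
    concentration = raw$concentration[keep], unit = raw$unit[keep],
    replicate = raw$replicate[keep],
    value = pmax(0, 100 * (raw$au[keep] - blank) / (ctrl - blank)),
    role = raw$role[keep])
  response_table(out)
}

# Internal 4PL mean function on (top, bottom, log ec50, log hill).
.fourpl_mu <- function(doses, top, bottom, lec50, lhill) {
  x <- exp(exp(lhill) * (log(doses) - lec50))
  bottom + (top - bottom) / (1 + x)
}

#' Fit a variable-slope four-parameter logistic curve
#'
#' Unweighted least-squares fit of the 4PL model to normalised responses
#' for one chemical and endpoint, with concentrations log-transformed
#' internally. Initialisation uses eight deterministic starts built from
#' data quantiles (two EC50 candidates crossed with four Hill-slope
#' candidates); there are no stochastic restarts, so refits are
#' bit-reproducible. Zero-dose (solvent-control) rows never enter the
#' log-dose fit; the normalised scale anchors the top plateau instead.
#'
#' @param responses A [response_table()] for a single chemical/endpoint,
#'   or a data.frame with `concentration` and `value` columns.
#' @return An object of class `fit_4pl` with elements `curve`
#'   (a [curve_spec()], `NULL` when no fit succeeded), `rss`, `converged`,
#'   `n_points`, `dose_range` and the fitted data.
#' @export
fit_4pl <- function(responses) {
  dat <- as.data.frame(responses)
  dat <- dat[dat$concentration > 0, , drop = FALSE]
  doses <- dat$concentration
  values <- dat$value
  if (length(unique(doses)) < 5L) {
    stop("need >= 5 distinct positive concentrations for a 4-parameter fit")
  }
  failed <- function(reason) {
    structure(list(curve = NULL, rss = Inf, converged = FALSE,
                   reason = reason, n_points = length(values),
                   dose_range = range(doses), doses = doses,
                   values = values),
              class = "fit_4pl")
  }
  dose_means <- tapply(values, doses, mean)
  if (diff(range(dose_means)) < 1e-8) return(failed("flat response"))

  top0 <- as.numeric(dose_means[1])        # lowest dose anchors top
  bot0 <- as.numeric(dose_means[length(dose_means)])
  ld <- log(doses)
  starts <- expand.grid(
    lec50 = as.numeric(stats::quantile(ld, c(1 / 3, 2 / 3))),
    hill = c(0.5, 1, 2, 4))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- list(top = top0, bottom = bot0,
               lec50 = starts$lec50[i], lhill = log(starts$hill[i]))
    fit <- tryCatch(suppressWarnings(
      minpack.lm::nlsLM(
        values ~ .fourpl_mu(doses, top, bottom, lec50, lhill),
        start = st,
        control = minpack.lm::nls.lm.control(maxiter = 500))),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-12) {
        best <- list(fit = fit, rss = rss)
      }
    }
  }
  if (is.null(best)) return(failed("no start converged"))
  cf <- stats::coef(best$fit)
  if (abs(cf[["top"]] - cf[["bottom"]]) < 1e-6) {
    return(failed("non-identifiable: top ~ bottom"))
  }
  curve <- curve_spec(top = cf[["top"]], bottom = cf[["bottom"]],
                      ec50 = exp(cf[["lec50"]]), hill = exp(cf[["lhill"]]))
  structure(list(curve = curve, rss = best$rss, converged = TRUE,
                 reason = "ok", n_points = length(values),
                 dose_range = range(doses), doses = doses, values = values),
            class = "fit_4pl")
}

#' @export
print.fit_4pl <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("4PL fit (n = %d, rss = %.4g)\n", x$n_points, x$rss))
    print(x$curve)
  } else {
    cat(sprintf("4PL fit failed: %s (n = %d)\n", x$reason, x$n_points))
  }
  invisible(x)
}

#' Invert a fitted curve at an inhibition level (ICx)
#'
#' Returns the concentration at which the fitted curve deviates from its
#' zero-dose plateau by `level` percentage points (for a decreasing
#' viability curve, the concentration causing a `level`% decrease, i.e.
#' the ICx). The sub-cytotoxic anchor IC20/100 is the IC20 concentration
#' divided by 100 (not an IC0.2 inversion); request it with
#' `derived_divisor = 100`.
#'
#' When the highest tested concentration does not reach `level`%
#' deviation, the inversion refuses to extrapolate and signals a condition
#' of class `dntmix_icx_out_of_range`; callers studying
#' solubility-truncated curves may catch it and substitute the highest
#' tested concentration.
#'
#' @param fit A converged [fit_4pl()].
#' @param level Target deviation from the zero-dose plateau, in
#'   percentage points; must satisfy `0 < level < |top - bottom|`.
#' @param derived_divisor Divisor applied to the inverted concentration
#'   (default 1; use 100 for the IC20/100 anchor).
#' @return A list of class `ic_estimate`: `level`, `concentration`,
#'   `derived_divisor`, `source_fit`.
#' @examples
#' cs <- curve_spec(100, 0, 10, 1.5)
#' tab <- simulate_single_chemical(cs, 10 * 4^(-3:3),
#'                                 noise = noise_spec(0, 2, 1))
#' fit <- fit_4pl(tab)
#' invert_icx(fit, 20)$concentration # ~= 3.969
#' @export
invert_icx <- function(fit, level, derived_divisor = 1) {
  stopifnot(inherits(fit, "fit_4pl"))
  if (!fit$converged) stop("cannot invert a non-converged fit")
  stopifnot(is.numeric(level), length(level) == 1L, derived_divisor > 0)
  cs <- fit$curve
  span <- abs(cs$top - cs$bottom)
  if (level <= 0 || level >= span) {
    stop_dntmix(
      sprintf("level %g%% outside attainable range (0, %g)", level, span),
      "dntmix_level_unattainable")
  }
  dir_sign <- if (cs$direction == "decreasing") -1 else 1
  target <- cs$top + dir_sign * level
  max_dev <- abs(predict(cs, max(fit$dose_range)) - cs$top)
  if (level > max_dev + 1e-9) {
    stop_dntmix(
      sprintf(paste0("level %g%% is not reached within the tested range ",
                     "(max deviation %.3g%% at %g); refusing to extrapolate"),
              level, max_dev, max(fit$dose_range)),
      "dntmix_icx_out_of_range")
  }
  conc <- inverse_curve(cs, target) / derived_divisor
  structure(list(level = level, concentration = conc,
                 derived_divisor = derived_divisor, source_fit = fit),
            class = "ic_estimate")
}

#' Standard IC anchor concentrations for one fitted chemical
#'
#' Convenience wrapper returning the three anchors used to pick exposure
#' concentrations for endpoint screens: non-cytotoxic IC20/100, very low
#' cytotoxic IC5, and moderately cytotoxic IC20.
#'
#' @param fit A converged [fit_4pl()].
#' @param substitute_highest If `TRUE`, levels not reached within the
#'   tested range (e.g. a solubility-truncated curve) are replaced by the
#'   highest tested concentration, flagged in the `truncated` column.
#' @return Data.frame with columns `anchor`, `level`, `concentration`,
#'   `truncated`.
#' @export
ic_levels <- function(fit, substitute_highest = FALSE) {
  specs <- list(
    list(anchor = "IC20/100", level = 20, div = 100),
    list(anchor = "IC5", level = 5, div = 1),
    list(anchor = "IC20", level = 20, div = 1))
  rows <- lapply(specs, function(s) {
    est <- tryCatch(invert_icx(fit, s$level, s$div),
                    dntmix_icx_out_of_range = function(e) e)
    if (inherits(est, "condition")) {
      if (!substitute_highest) stop(est)
      data.frame(anchor = s$anchor, level = s$level,
                 concentration = max(fit$dose_range) / s$div,
                 truncated = TRUE)
    } else {
      data.frame(anchor = s$anchor, level = s$level,
                 concentration = est$concentration, truncated = FALSE)
    }
  })
  do.call(rbind, rows)
}
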