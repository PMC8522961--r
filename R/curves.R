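#' Four-parameter logistic curve specification
#'
#' The variable-slope sigmoidal dose-response shape used both to generate
#' synthetic endpoint data and as the parametric form recovered by
#' [fit_4pl()]. On the normalised scale the response at dose `d` is
#'
#' \deqn{f(d) = bottom + \frac{top - bottom}{1 + (d / ec50)^{hill}}}
#'
#' so `top` is the plateau at zero dose and `bottom` the plateau at
#' infinite dose; a decreasing curve has `top > bottom`, an increasing one
#' `top < bottom`. `hill` is the unitless slope and is always positive.
#'
#' @param top Plateau at zero dose, in % of solvent control.
#' @param bottom Plateau at infinite dose, in % of solvent control.
#' @param ec50 Dose at the midpoint of the transition; same units as the
#'   dose axis; must be positive.
#' @param hill Hill slope, must be positive.
#' @param direction `"decreasing"` or `"increasing"`; inferred from
#'   `top`/`bottom` when omitted, validated against them when given.
#' @return An object of class `curve_spec`.
#' @seealso [predict.curve_spec()], [inverse_curve()]
#' @examples
#' cs <- curve_spec(top = 100, bottom = 0, ec50 = 10, hill = 1)
#' predict(cs, doses = c(0, 10, 1e6)) # 100, 50, ~0
#' @export
curve_spec <- function(top, bottom, ec50, hill, direction = NULL) {
  stopifnot(is.numeric(top), is.numeric(bottom), is.numeric(ec50),
            is.numeric(hill), length(top) == 1L, length(bottom) == 1L,
            length(ec50) == 1L, length(hill) == 1L)
  if (!is.finite(ec50) || ec50 <= 0) stop("`ec50` must be positive")
  if (!is.finite(hill) || hill <= 0) stop("`hill` must be positive")
  if (top == bottom) stop("`top` and `bottom` must differ")
  inferred <- if (top > bottom) "decreasing" else "increasing"
  if (is.null(direction)) {
    direction <- inferred
  } else {
    direction <- match.arg(direction, c("decreasing", "increasing"))
    if (direction != inferred) {
      stop(sprintf(
        "direction '%s' inconsistent with top = %g, bottom = %g",
        direction, top, bottom))
    }
  }
  structure(list(top = top, bottom = bottom, ec50 = ec50, hill = hill,
                 direction = direction),
            class = "curve_spec")
}

#' Evaluate a four-parameter logistic curve
#'
#' @param object A [curve_spec()].
#' @param doses Non-negative dose vector (zero allowed: returns `top`).
#' @param ... Unused.
#' @return Numeric vector of responses in % of control.
#' @export
predict.curve_spec <- function(object, doses, ...) {
  stopifnot(is.numeric(doses), all(doses >= 0))
  x <- (doses / object$ec50)^object$hill
  object$bottom + (object$top - object$bottom) / (1 + x)
}

#' Invert a four-parameter logistic curve
#'
#' Closed-form dose at which the curve attains a given response. Only
#' responses strictly between the two plateaus are attainable.
#'
#' @param spec A [curve_spec()].
#' @param response Target response, % of control.
#' @return The dose `d` with `predict(spec, d) == response`.
#' @export
inverse_curve <- function(spec, response) {
  stopifnot(inherits(spec, "curve_spec"), is.numeric(response))
  lo <- min(spec$top, spec$bottom)
  hi <- max(spec$top, spec$bottom)
  if (any(response <= lo | response >= hi)) {
    stop_dntmix(
      sprintf("response %s outside the open range (%g, %g) of the curve",
              paste(signif(response, 6), collapse = ", "), lo, hi),
      "dntmix_response_unattainable")
  }
  ratio <- (spec$top - response) / (response - spec$bottom)
  spec$ec50 * ratio^(1 / spec$hill)
}

#' @export
print.curve_spec <- function(x, ...) {
  cat(sprintf(
    "4PL curve (%s): top = %g, bottom = %g, ec50 = %g, hill = %g\n",
    x$direction, x$top, x$bottom, x$ec50, x$hill))
  invisible(x)
}

#' Replicate-noise specification for synthetic data
#'
#' Gaussian replicate noise on the normalised (% of control) scale,
#' truncated at zero. Defaults mirror typical plate-based DNT screens:
#' six internal replicates with a replicate standard deviation of 5% of
#' control.
#'
#' @param replicate_sd Standard deviation of replicate noise, % of control.
#' @param n_replicates Number of replicates per condition (>= 1).
#' @param seed Integer seed; every source of randomness in the generators
#'   flows through this seed, and the global RNG state is left untouched.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(replicate_sd = 5, n_replicates = 6, seed = 1L) {
  stopifnot(is.numeric(replicate_sd), length(replicate_sd) == 1L,
            replicate_sd >= 0,
            is.numeric(n_replicates), length(n_replicates) == 1L,
            n_replicates >= 1, n_replicates == as.integer(n_replicates),
            is.numeric(seed), length(seed) == 1L)
  structure(list(replicate_sd = replicate_sd,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Mixture-interaction specification for synthetic data
#'
#' Ground-truth deviation from exact concentration addition injected into
#' simulated mixtures, used to validate the synergy classifier. In
#' `"additive"` mode the mixture follows concentration addition exactly
#' (`deviation_pct` must be 0); `"synergistic"` adds and `"antagonistic"`
#' removes `deviation_pct` percentage points from the predicted deviation
#' from the 100% control level.
#'
#' @param mode One of `"additive"`, `"synergistic"`, `"antagonistic"`.
#' @param deviation_pct Non-negative extra deviation, percentage points.
#' @return An object of class `interaction_spec`.
#' @export
interaction_spec <- function(mode = c("additive", "synergistic",
                                      "antagonistic"),
                             deviation_pct = 0) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(deviation_pct), length(deviation_pct) == 1L,
            deviation_pct >= 0)
  if (mode == "additive" && deviation_pct != 0) {
    stop("additive mode requires deviation_pct = 0")
  }
  structure(list(mode = mode, deviation_pct = deviation_pct),
            class = "interaction_spec")
}
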