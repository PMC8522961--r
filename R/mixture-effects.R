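#' Toxic Units under concentration addition
#'
#' The concentration-addition score of a mixture condition: the sum over
#' member chemicals of nominal concentration divided by that chemical's
#' BMD5 for the same endpoint,
#' `TU = sum_i [chem_i] / BMD5(chem_i)`.
#' Per-chemical terms are retained for attribution. Concentrations and
#' BMDs must share one unit.
#'
#' @param conc Named numeric vector of nominal concentrations (>= 0), one
#'   per member chemical.
#' @param bmd5 Named numeric vector of BMD5 values (> 0) covering every
#'   name in `conc`, or a list of [compute_bmd()] results (names taken
#'   from their `chemical` fields).
#' @param mixture_id,endpoint,dilution_level Identifiers carried through
#'   to the score.
#' @return Object of class `toxic_unit_score`: `tu`, `per_chemical`,
#'   identifiers.
#' @examples
#' toxic_units(c(a = 1, b = 2, d = 3), c(a = 10, b = 10, d = 10))$tu # 0.6
#' @export
toxic_units <- function(conc, bmd5, mixture_id = "mixture",
                        endpoint = "endpoint", dilution_level = 1) {
  stopifnot(is.numeric(conc), length(conc) >= 1, !is.null(names(conc)))
  if (is.list(bmd5) && all(vapply(bmd5, inherits, logical(1),
                                  "bmd_result"))) {
    bmd5 <- stats::setNames(
      vapply(bmd5, function(r) r$bmd5, numeric(1)),
      vapply(bmd5, function(r) r$chemical, character(1)))
  }
  missing_bmd <- setdiff(names(conc), names(bmd5))
  if (length(missing_bmd)) {
    stop("missing BMD5 for chemical(s): ",
         paste(missing_bmd, collapse = ", "))
  }
  b <- bmd5[names(conc)]
  if (any(!is.finite(b)) || any(b <= 0)) stop("BMD5 values must be positive")
  if (any(conc < 0)) stop("concentrations must be >= 0")
  per <- conc / b
  structure(list(mixture_id = mixture_id, endpoint = endpoint,
                 dilution_level = dilution_level,
                 tu = sum(per), per_chemical = per),
            class = "toxic_unit_score")
}

#' @export
print.toxic_unit_score <- function(x, ...) {
  cat(sprintf("TU [%s, %s, level %s] = %.4g\n", x$mixture_id, x$endpoint,
              format(x$dilution_level), x$tu))
  print(signif(x$per_chemical, 4))
  invisible(x)
}

#' Classify a mixture condition as synergistic, interactive or none
#'
#' The two-criterion rule applied to each (mixture, endpoint, dilution
#' level):
#' \itemize{
#'   \item criterion i: the Toxic Unit sum is at most `tu_threshold`
#'     (default 1) *and* the observed mixture deviation from the 100%
#'     control level exceeds the benchmark response (`bmr_threshold`,
#'     default 5 percentage points);
#'   \item criterion ii: the observed mixture deviation is at least
#'     `fold_threshold` (default 2) times the benchmark response of the
#'     most potent member chemical at its nominal concentration.
#' }
#' Both criteria met: `"synergistic"`. Only criterion ii: `"interactive"`.
#' Otherwise `"none"`. Deviations and BMRs are compared as absolute
#' magnitudes; when signed single-chemical BMRs are supplied and the most
#' potent chemical pushes the endpoint in the opposite direction to the
#' mixture, a `direction_mismatch` flag is raised (classification is not
#' blocked). Antagonism is deliberately not classified: with endpoints
#' responding in both directions it cannot be separated from additivity
#' here, so the raw quantities are exposed instead.
#'
#' @param tu A [toxic_units()] score (or a single number).
#' @param single_bmrs Named numeric vector: per-chemical benchmark
#'   responses (%) at the nominal concentrations of this condition; may
#'   be signed (sign = effect direction).
#' @param observed Replicate mixture responses (% of control): a numeric
#'   vector or [response_table()] rows for the condition.
#' @param mixture_direction Optional sign (+1/-1) of the observed mixture
#'   effect; derived from the replicate mean when omitted.
#' @param bmr_threshold,fold_threshold,tu_threshold Rule thresholds.
#' @return Object of class `synergy_assessment` with the classification
#'   and all inputs to it.
#' @examples
#' classify_mixture(0.8, c(a = 4, b = 1), observed = c(112, 111, 113))
#' @export
classify_mixture <- function(tu, single_bmrs, observed,
                             mixture_direction = NULL,
                             bmr_threshold = 5, fold_threshold = 2,
                             tu_threshold = 1) {
  tu_val <- if (inherits(tu, "toxic_unit_score")) tu$tu else {
    stopifnot(is.numeric(tu), length(tu) == 1L, tu >= 0)
    tu
  }
  vals <- if (inherits(observed, "data.frame")) observed$value else observed
  if (length(vals) == 0L) stop("empty observation set")
  stopifnot(is.numeric(single_bmrs), length(single_bmrs) >= 1)
  mean_resp <- mean(vals)
  observed_deviation <- abs(mean_resp - 100)
  sem <- if (length(vals) > 1L) {
    stats::sd(vals) / sqrt(length(vals))
  } else NA_real_
  max_single_bmr <- max(abs(single_bmrs))
  crit_i <- tu_val <= tu_threshold && observed_deviation > bmr_threshold
  crit_ii <- observed_deviation >= fold_threshold * max_single_bmr
  classification <- if (crit_i && crit_ii) "synergistic" else
    if (crit_ii) "interactive" else "none"
  mix_dir <- mixture_direction %||% sign(mean_resp - 100)
  top_chem <- names(single_bmrs)[which.max(abs(single_bmrs))]
  top_bmr <- single_bmrs[which.max(abs(single_bmrs))]
  direction_mismatch <- !is.null(names(single_bmrs)) &&
    any(single_bmrs < 0) && sign(top_bmr) != 0 && mix_dir != 0 &&
    sign(top_bmr) != mix_dir
  if (isTRUE(direction_mismatch)) {
    warning("most potent single chemical acts in the opposite direction ",
            "to the mixture effect")
  }
  structure(list(
    mixture_id = if (inherits(tu, "toxic_unit_score")) tu$mixture_id else
      "mixture",
    endpoint = if (inherits(tu, "toxic_unit_score")) tu$endpoint else
      "endpoint",
    dilution_level = if (inherits(tu, "toxic_unit_score"))
      tu$dilution_level else NA,
    tu = tu_val, single_bmrs = single_bmrs,
    max_single_bmr = max_single_bmr, most_potent = top_chem,
    observed_mean = mean_resp, observed_deviation = observed_deviation,
    sem = sem, criterion_i = crit_i, criterion_ii = crit_ii,
    direction_mismatch = isTRUE(direction_mismatch),
    classification = classification),
    class = "synergy_assessment")
}

#' @export
print.synergy_assessment <- function(x, ...) {
  cat(sprintf(
    "%s [%s, %s, level %s]: TU = %.3g, deviation = %.3g%%, max single BMR = %.3g%%\n",
    x$classification, x$mixture_id, x$endpoint, format(x$dilution_level),
    x$tu, x$observed_deviation, x$max_single_bmr))
  invisible(x)
}

#' Flatten synergy assessments to a table
#'
#' @param assessments List of `synergy_assessment` objects.
#' @param path Optional CSV path.
#' @return Data.frame, one row per assessment.
#' @export
assessment_table <- function(assessments, path = NULL) {
  out <- do.call(rbind, lapply(assessments, function(a) {
    data.frame(mixture_id = a$mixture_id, endpoint = a$endpoint,
               dilution_level = a$dilution_level, tu = a$tu,
               max_single_bmr = a$max_single_bmr,
               observed_deviation = a$observed_deviation,
               classification = a$classification,
               direction_mismatch = a$direction_mismatch)
  }))
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}

#' Delta summary: % difference versus solvent control
#'
#' One signed delta per (condition, endpoint): the replicate mean of the
#' normalised response minus 100, with the significance tier joined from
#' Dunnett records when available — the quantity displayed in
#' cross-mixture summary heatmaps.
#'
#' @param responses A [response_table()] (several conditions/endpoints
#'   allowed; control rows with `role == "control"` are dropped).
#' @param significance Optional records from [dunnett_vs_control()];
#'   matched on (chemical, endpoint, concentration).
#' @return Data.frame: `condition`, `endpoint`, `concentration`,
#'   `delta_pct`, `sem`, `tier`.
#' @export
delta_summary <- function(responses, significance = NULL) {
  dat <- as.data.frame(responses)
  if ("role" %in% names(dat)) dat <- dat[dat$role != "control", ]
  key <- interaction(dat$chemical, dat$endpoint, dat$concentration,
                     drop = TRUE)
  rows <- lapply(split(dat, key), function(d) {
    data.frame(condition = as.character(d$chemical[1]),
               endpoint = as.character(d$endpoint[1]),
               concentration = d$concentration[1],
               delta_pct = mean(d$value) - 100,
               sem = if (nrow(d) > 1)
                 stats::sd(d$value) / sqrt(nrow(d)) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$tier <- "ns"
  if (!is.null(significance)) {
    m <- match(paste(out$condition, out$endpoint, out$concentration),
               paste(significance$chemical, significance$endpoint,
                     significance$concentration))
    out$tier[!is.na(m)] <- as.character(significance$tier[m[!is.na(m)]])
  }
  out
}
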