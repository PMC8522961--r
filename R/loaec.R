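#' Dunnett many-to-one comparisons against the solvent control
#'
#' One-way ANOVA on normalised replicate values followed by Dunnett's
#' multiple-comparison test of every treated concentration against the
#' solvent control, with family-wise adjustment over the many-to-one
#' comparisons within one measured feature. Critical values come from the
#' many-to-one multivariate-t structure (via the multcomp machinery); the
#' quasi-Monte-Carlo evaluation of the multivariate-t probabilities is
#' seeded so repeated calls agree.
#'
#' @param responses A [response_table()] for one chemical and feature;
#'   control rows are those with `role == "control"` or, failing that,
#'   `concentration == 0`.
#' @param feature Feature identifier recorded in the output (defaults to
#'   a `feature` column when present, else the endpoint).
#' @param alpha Significance level used only for the `significant`
#'   convenience column (tiers use the fixed 0.05/0.01/0.001 thresholds).
#' @param seed Seed for the multivariate-t evaluation.
#' @return Data.frame of significance records: `chemical`, `endpoint`,
#'   `feature`, `concentration`, `estimate`, `p_adj`, `tier`,
#'   `significant`.
#' @export
dunnett_vs_control <- function(responses, feature = NULL, alpha = 0.05,
                               seed = 1L) {
  dat <- as.data.frame(responses)
  is_ctrl <- if ("role" %in% names(dat)) dat$role == "control" else
    dat$concentration == 0
  if (!any(is_ctrl)) stop("no control group present")
  if (!any(!is_ctrl)) stop("no treated groups present")
  feature <- feature %||%
    (if ("feature" %in% names(dat)) as.character(dat$feature[1]) else
      as.character(dat$endpoint[1]))
  concs <- sort(unique(dat$concentration[!is_ctrl]))
  grp <- factor(ifelse(is_ctrl, "ctrl", as.character(dat$concentration)),
                levels = c("ctrl", as.character(concs)))
  counts <- table(grp)
  if (any(counts < 2L)) {
    stop("need >= 2 replicates in every group (incl. control)")
  }
  vars <- tapply(dat$value, grp, stats::var)
  if (all(vars < 1e-24)) {
    stop_dntmix("zero within-group variance in every group: degenerate data",
                "dntmix_degenerate_variance")
  }
  fit <- stats::aov(value ~ grp, data = data.frame(value = dat$value,
                                                   grp = grp))
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(grp = "Dunnett"))
  smry <- withr::with_seed(as.integer(seed), summary(gl))
  p <- as.numeric(smry$test$pvalues)
  est <- as.numeric(smry$test$coefficients)
  data.frame(
    chemical = as.character(dat$chemical[!is_ctrl][1]),
    endpoint = as.character(dat$endpoint[1]),
    feature = feature, concentration = concs, estimate = est,
    p_adj = p, tier = as.character(significance_tier(p)),
    significant = p < alpha)
}

#' Derive the LOAEC from significance records
#'
#' The lowest observed adverse effect concentration: the minimum tested
#' concentration showing a statistically significant change (tier other
#' than `"ns"`) on at least one measured feature of the endpoint. When
#' nothing is significant the LOAEC is undefined (`NA`), a valid outcome.
#'
#' @param records Significance records from [dunnett_vs_control()]
#'   (rows may cover several features).
#' @param endpoint Endpoint to restrict to (default: all rows).
#' @return One-row data.frame: `chemical`, `endpoint`, `loaec`,
#'   `basis_feature` (a feature significant at the LOAEC), `defined`.
#' @export
derive_loaec <- function(records, endpoint = NULL) {
  stopifnot(all(c("concentration", "tier", "feature") %in% names(records)))
  if (!is.null(endpoint)) records <- records[records$endpoint == endpoint, ]
  if (nrow(records) == 0L) stop("no records for the requested endpoint")
  sig <- records[records$tier != "ns", , drop = FALSE]
  if (nrow(sig) == 0L) {
    return(data.frame(
      chemical = as.character(records$chemical[1]),
      endpoint = as.character(records$endpoint[1]),
      loaec = NA_real_, basis_feature = NA_character_, defined = FALSE))
  }
  loaec <- min(sig$concentration)
  data.frame(
    chemical = as.character(records$chemical[1]),
    endpoint = as.character(records$endpoint[1]),
    loaec = loaec,
    basis_feature = as.character(
      sig$feature[sig$concentration == loaec][1]),
    defined = TRUE)
}

#' Serial dilution series
#'
#' `v[i] = top / factor^(i-1)`, rounded half away from zero to the stated
#' number of decimals — the arithmetic behind the in vitro concentration
#' ranges (e.g. a 4-fold series from 100 uM: 100, 25, 6.25, 1.56, 0.39,
#' 0.10, 0.02).
#'
#' @param top Highest concentration (> 0).
#' @param factor Dilution factor (> 1).
#' @param n_points Number of concentrations (>= 1).
#' @param decimals Decimal places for [round_half_away()].
#' @return Numeric vector of length `n_points`, descending.
#' @export
serial_dilution <- function(top, factor, n_points, decimals = 2) {
  stopifnot(is.numeric(top), length(top) == 1L, top > 0,
            is.numeric(n_points), n_points >= 1,
            n_points == as.integer(n_points))
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 1) {
    stop("`factor` must be > 1")
  }
  round_half_away(top / factor^(seq_len(n_points) - 1), decimals)
}

#' Build endpoint-anchored mixture design tables
#'
#' For every mixture and endpoint, assigns each member chemical its
#' endpoint-specific LOAEC at dilution level 1, then halves the
#' *unrounded* anchor for each further 2-fold level, rounding half away
#' from zero to the chemical's stated precision (so 21.01 / 2 prints as
#' 10.51, not 10.50).
#'
#' @param loaecs Data.frame with `chemical`, `endpoint`, `loaec`
#'   (rows from [derive_loaec()] may be rbind-ed directly).
#' @param membership Named list: mixture id -> character vector of member
#'   chemicals.
#' @param levels Dilution levels as fractions of the LOAEC (default
#'   `c(1, 1/2, 1/4, 1/8)`).
#' @param decimals Named numeric vector of decimal places per chemical
#'   (unnamed scalar recycles to all); chemicals absent from the vector
#'   default to 2.
#' @param unit Concentration unit recorded in the table.
#' @return Long-format data.frame of class `mixture_design`:
#'   `mixture_id`, `endpoint`, `dilution_level`, `chemical`,
#'   `concentration`, `unit`.
#' @examples
#' lo <- data.frame(chemical = c("BPA", "CPF"), endpoint = "bdnf",
#'                  loaec = c(12.74, 37.10))
#' d <- build_mixture_design(lo, list(`2-Sim` = c("BPA", "CPF")))
#' subset(d, chemical == "BPA" & dilution_level == 0.125)$concentration # 1.59
#' @export
build_mixture_design <- function(loaecs, membership,
                                 levels = c(1, 1 / 2, 1 / 4, 1 / 8),
                                 decimals = 2, unit = "uM") {
  stopifnot(all(c("chemical", "endpoint", "loaec") %in% names(loaecs)),
            is.list(membership), length(membership) >= 1,
            all(levels > 0), all(levels <= 1))
  dec_for <- function(chem) {
    if (!is.null(names(decimals)) && chem %in% names(decimals)) {
      decimals[[chem]]
    } else if (is.null(names(decimals))) decimals[1] else 2
  }
  rows <- list()
  for (mix in names(membership)) {
    members <- membership[[mix]]
    for (ep in unique(loaecs$endpoint)) {
      for (chem in members) {
        hit <- loaecs$chemical == chem & loaecs$endpoint == ep
        if (!any(hit) || is.na(loaecs$loaec[hit][1])) {
          stop_dntmix(
            sprintf("chemical '%s' has no defined LOAEC for endpoint '%s'",
                    chem, ep),
            "dntmix_undefined_loaec")
        }
        anchor <- loaecs$loaec[hit][1]
        rows[[length(rows) + 1L]] <- data.frame(
          mixture_id = mix, endpoint = ep, dilution_level = levels,
          chemical = chem,
          concentration = round_half_away(anchor * levels, dec_for(chem)),
          unit = unit)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- unique(c("mixture_design", class(out)))
  out
}
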