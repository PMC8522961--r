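#' Study configuration
#'
#' Loads and validates the single configuration object that drives
#' [run_pipeline()]: the chemical roster (units, rounding precision,
#' tested dose range, synthetic ground-truth potency), mixture
#' membership, dilution scheme, endpoints with their measured features,
#' decision thresholds and simulation settings.
#'
#' @param x A YAML file path or an already-built list.
#' @return The validated configuration, class `study_config`.
#' @seealso [default_config()], [validate_config()]
#' @export
study_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  stopifnot(is.list(cfg))
  issues <- validate_config(cfg)
  if (length(issues)) {
    stop("invalid study configuration:\n  - ",
         paste(issues, collapse = "\n  - "))
  }
  class(cfg) <- unique(c("study_config", class(cfg)))
  cfg
}

#' Validate a study configuration
#'
#' @param cfg A configuration list (see [default_config()] for the
#'   shape).
#' @return Character vector of issues; empty when the configuration is
#'   usable. Each issue names the offending field and rule.
#' @export
validate_config <- function(cfg) {
  issues <- character(0)
  push <- function(msg) issues <<- c(issues, msg)
  if (!is.list(cfg$chemicals) || !length(cfg$chemicals)) {
    push("chemicals: at least one chemical must be defined")
    return(issues)
  }
  chems <- names(cfg$chemicals)
  for (nm in chems) {
    ch <- cfg$chemicals[[nm]]
    if (is.null(ch$top_dose) || ch$top_dose <= 0) {
      push(sprintf("chemicals.%s.top_dose: must be positive", nm))
    }
  }
  th <- cfg$thresholds
  for (f in c("bmr_level", "tu_threshold", "fold_threshold", "alpha")) {
    if (is.null(th[[f]]) || !is.numeric(th[[f]]) || th[[f]] <= 0) {
      push(sprintf("thresholds.%s: must be a positive number", f))
    }
  }
  if (!is.null(th$alpha) && is.numeric(th$alpha) && th$alpha >= 1) {
    push("thresholds.alpha: must be below 1")
  }
  if (!is.list(cfg$mixtures) || length(cfg$mixtures) < 1) {
    push("mixtures: at least one mixture must be defined")
  } else {
    for (mx in names(cfg$mixtures)) {
      unknown <- setdiff(cfg$mixtures[[mx]], chems)
      if (length(unknown)) {
        push(sprintf("mixtures.%s: unknown chemical(s) %s", mx,
                     paste(unknown, collapse = ", ")))
      }
    }
    am <- cfg$all_mixture
    if (!is.null(am)) {
      if (!am %in% names(cfg$mixtures)) {
        push(sprintf("all_mixture: '%s' is not a defined mixture", am))
      } else {
        others <- setdiff(names(cfg$mixtures), am)
        union_members <- sort(unique(unlist(cfg$mixtures[others])))
        if (!setequal(union_members, cfg$mixtures[[am]])) {
          push(sprintf(
            "all_mixture: '%s' must equal the union of the other mixtures",
            am))
        }
      }
    }
  }
  if (is.null(cfg$levels) || any(cfg$levels <= 0) || any(cfg$levels > 1)) {
    push("levels: dilution levels must lie in (0, 1]")
  }
  if (!is.null(cfg$interactions)) {
    for (ia in cfg$interactions) {
      if (!ia$mixture %in% names(cfg$mixtures %||% list())) {
        push(sprintf("interactions: unknown mixture '%s'", ia$mixture))
      }
    }
  }
  issues
}

#' Built-in demo configuration
#'
#' A fully synthetic ten-chemical study emulating the structure of an
#' endpoint-anchored mixture DNT screen: five similar-MoA chemicals
#' (BDNF-level perturbers), five dissimilar-MoA chemicals, the three
#' mixtures 5-Sim, 5-Diss and 10-All, two-fold LOAEC dilutions, and
#' synergistic interaction injected into the synaptogenesis endpoint of
#' the BDE47-containing mixtures. All potencies are synthetic ground
#' truth, not measured values.
#'
#' @param n_boot Bootstrap replicates for the BMD stage.
#' @return A `study_config`.
#' @export
default_config <- function(n_boot = 100) {
  path <- system.file("extdata", "demo_config.yaml", package = "dntmix")
  cfg <- yaml::read_yaml(path)
  cfg$bmd$n_boot <- n_boot
  study_config(cfg)
}

# Ground-truth curves implied by a chemical's config entry.
.truth_curves <- function(ch) {
  viab_ec50 <- ch$viab_ec50 %||% (ch$top_dose / 8)
  viab <- curve_spec(100, 0, viab_ec50, ch$viab_hill %||% 1.5)
  effects <- list()
  for (ep in names(ch$effects %||% list())) {
    ef <- ch$effects[[ep]]
    mag <- ef$magnitude %||% 30
    bottom <- if ((ef$direction %||% "decrease") == "decrease") {
      100 - mag
    } else 100 + mag
    effects[[ep]] <- curve_spec(
      top = 100, bottom = bottom,
      ec50 = viab_ec50 * (ef$ec50_frac %||% 1),
      hill = ef$hill %||% 2)
  }
  list(viability = viab, effects = effects)
}

#' Run the full analysis pipeline
#'
#' Orchestrates the whole study on synthetic data generated from the
#' configuration's ground truth: viability simulation and 4PL/IC
#' fitting, endpoint feature simulation with Dunnett-based LOAECs, the
#' LOAEC-anchored mixture design, benchmark-dose analysis, mixture
#' simulation with Toxic-Unit scoring and synergy classification,
#' correlation attribution, and MEA spike-train analytics. Every stage
#' writes its tables under `outdir` and is recorded, with MD5 hashes of
#' its outputs, in the returned manifest; a rerun with the same
#' configuration and seed reproduces the hashes bit for bit.
#'
#' @param config A [study_config()] (or list/path coercible to one).
#' @param seed Integer master seed; all stage seeds derive from it.
#' @param outdir Output directory (created if needed).
#' @return The run manifest (list, class `run_manifest`), invisibly
#'   written to `manifest.json` as well.
#' @export
run_pipeline <- function(config = default_config(), seed = 1L,
                         outdir = tempfile("dntmix_run_")) {
  cfg <- if (inherits(config, "study_config")) config else
    study_config(config)
  seed <- as.integer(seed)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  warnings_log <- character(0)
  note <- function(...) {
    warnings_log <<- c(warnings_log, sprintf(...))
  }
  stages <- list()
  record <- function(name, files, n_records) {
    stages[[length(stages) + 1L]] <<- list(
      stage = name, files = basename(files),
      md5 = unname(tools::md5sum(files)), n_records = n_records)
  }
  chems <- names(cfg$chemicals)
  truth <- lapply(cfg$chemicals, .truth_curves)
  noise <- noise_spec(cfg$noise$replicate_sd %||% 5,
                      cfg$noise$n_replicates %||% 6, seed)
  dil <- cfg$dilution %||% list(factor = 4, n_points = 7)

  ## stage 1: viability simulation + 4PL/IC anchors -----------------------
  doses_of <- function(nm) {
    rev(serial_dilution(cfg$chemicals[[nm]]$top_dose, dil$factor,
                        dil$n_points,
                        cfg$chemicals[[nm]]$decimals %||% 2))
  }
  viability <- list()
  fits <- list()
  ic_rows <- list()
  for (k in seq_along(chems)) {
    nm <- chems[k]
    tab <- simulate_single_chemical(
      truth[[nm]]$viability, doses_of(nm),
      noise_spec(noise$replicate_sd, noise$n_replicates, seed + k),
      chemical = nm, endpoint = "viability",
      unit = cfg$chemicals[[nm]]$unit %||% "uM")
    viability[[nm]] <- tab
    fits[[nm]] <- fit_4pl(tab)
    if (!fits[[nm]]$converged) {
      stop(sprintf("stage fit: 4PL fit failed for chemical '%s' (%s)",
                   nm, fits[[nm]]$reason))
    }
    ic <- ic_levels(fits[[nm]], substitute_highest = TRUE)
    if (any(ic$truncated)) {
      note("truncated dose-response for %s: highest tested dose substituted",
           nm)
    }
    ic$chemical <- nm
    ic_rows[[nm]] <- ic
  }
  viab_path <- file.path(outdir, "viability.csv")
  write_response_table(do.call(rbind, viability), viab_path)
  ic_path <- file.path(outdir, "ic_anchors.csv")
  utils::write.csv(do.call(rbind, ic_rows), ic_path, row.names = FALSE)
  record("simulate_fit", c(viab_path, ic_path),
         sum(vapply(viability, nrow, numeric(1))))

  ## stage 2: endpoint features, Dunnett, LOAEC ---------------------------
  endpoints <- names(cfg$endpoints)
  feature_tabs <- list()
  sig_rows <- list()
  loaec_rows <- list()
  for (k in seq_along(chems)) {
    nm <- chems[k]
    for (ep in endpoints) {
      feats <- cfg$endpoints[[ep]]
      eff <- truth[[nm]]$effects[[ep]]
      if (is.null(eff)) next
      sens <- cfg$feature_sensitivity[[ep]] %||% rep(1, length(feats))
      for (fi in seq_along(feats)) {
        # secondary features may respond at lower doses than the primary
        # (modelled) feature: scale the truth EC50 by the sensitivity factor
        eff_f <- curve_spec(eff$top, eff$bottom,
                            eff$ec50 * sens[[fi]], eff$hill)
        fseed <- seed + 1000L + k * 37L + match(ep, endpoints) * 7L + fi
        tab <- simulate_single_chemical(
          eff_f, doses_of(nm),
          noise_spec(noise$replicate_sd, noise$n_replicates, fseed),
          chemical = nm, endpoint = ep,
          unit = cfg$chemicals[[nm]]$unit %||% "uM")
        tab$feature <- feats[fi]
        ctrl <- data.frame(
          chemical = nm, endpoint = ep, concentration = 0,
          unit = tab$unit[1],
          replicate = seq_len(noise$n_replicates),
          value = withr::with_seed(fseed + 500000L, pmax(0, 100 +
            stats::rnorm(noise$n_replicates, 0, noise$replicate_sd))),
          feature = feats[fi])
        tab <- response_table(rbind(as.data.frame(tab), ctrl))
        feature_tabs[[paste(nm, ep, feats[fi], sep = ".")]] <- tab
        sig_rows[[paste(nm, ep, feats[fi], sep = ".")]] <-
          dunnett_vs_control(tab, feature = feats[fi],
                             alpha = cfg$thresholds$alpha, seed = fseed)
      }
      recs <- do.call(rbind, sig_rows[paste(nm, ep, feats, sep = ".")])
      loaec_rows[[paste(nm, ep, sep = ".")]] <- derive_loaec(recs, ep)
    }
  }
  sig <- do.call(rbind, sig_rows); rownames(sig) <- NULL
  loaecs <- do.call(rbind, loaec_rows); rownames(loaecs) <- NULL
  sig_path <- file.path(outdir, "dunnett_significance.csv")
  loaec_path <- file.path(outdir, "loaec.csv")
  utils::write.csv(sig, sig_path, row.names = FALSE)
  utils::write.csv(loaecs, loaec_path, row.names = FALSE)
  record("loaec", c(sig_path, loaec_path), nrow(sig))
  if (any(!loaecs$defined)) {
    note("undefined LOAEC for %d chemical-endpoint pair(s)",
         sum(!loaecs$defined))
  }

  ## stage 3: mixture design ----------------------------------------------
  decs <- vapply(cfg$chemicals, function(ch) ch$decimals %||% 2, numeric(1))
  design_parts <- list()
  for (mix in names(cfg$mixtures)) {
    for (ep in endpoints) {
      part <- tryCatch(
        build_mixture_design(
          loaecs[loaecs$defined & loaecs$endpoint == ep, ],
          cfg$mixtures[mix], levels = unlist(cfg$levels), decimals = decs),
        dntmix_undefined_loaec = function(e) {
          note("design skipped for %s/%s: %s", mix, ep,
               conditionMessage(e))
          NULL
        })
      if (!is.null(part)) design_parts[[paste(mix, ep)]] <- part
    }
  }
  if (!length(design_parts)) stop("stage design: no mixture could be built")
  design <- do.call(rbind, design_parts)
  rownames(design) <- NULL
  design_path <- file.path(outdir, "mixture_design.csv")
  utils::write.csv(as.data.frame(design), design_path, row.names = FALSE)
  record("design", design_path, nrow(design))

  ## stage 4: benchmark-dose analysis -------------------------------------
  bmd_results <- list()
  for (nm in chems) {
    for (ep in endpoints) {
      primary <- cfg$endpoints[[ep]][1]
      tab <- feature_tabs[[paste(nm, ep, primary, sep = ".")]]
      if (is.null(tab)) next
      models <- fit_model_family(tab)
      best <- select_best(models)
      res <- tryCatch(
        compute_bmd(best, bmr_level = cfg$thresholds$bmr_level,
                    n_boot = cfg$bmd$n_boot %||% 100,
                    seed = seed + 2000L + match(nm, chems)),
        dntmix_bmr_not_reached = function(e) NULL)
      if (is.null(res)) {
        note("no BMD in tested range for %s/%s", nm, ep)
      } else {
        bmd_results[[paste(nm, ep, sep = ".")]] <- res
      }
    }
  }
  bmd_path <- file.path(outdir, "bmd.csv")
  bmd_tab <- bmd_table(bmd_results, bmd_path)
  record("bmd", bmd_path, nrow(bmd_tab))

  ## stage 5: mixtures, Toxic Units, classification -----------------------
  interaction_for <- function(mix, ep) {
    for (ia in cfg$interactions %||% list()) {
      if (ia$mixture == mix && ia$endpoint == ep) {
        return(interaction_spec(ia$mode, ia$deviation_pct %||% 0))
      }
    }
    interaction_spec("additive")
  }
  assessments <- list()
  mix_obs <- list()
  for (mix in names(cfg$mixtures)) {
    for (ep in endpoints) {
      for (lv in unlist(cfg$levels)) {
        sub <- design[design$mixture_id == mix & design$endpoint == ep &
                        abs(design$dilution_level - lv) < 1e-12, ]
        if (!nrow(sub)) next
        comp <- lapply(seq_len(nrow(sub)), function(i) {
          list(curve = truth[[sub$chemical[i]]]$effects[[ep]],
               conc = sub$concentration[i])
        })
        obs <- simulate_mixture(
          comp, interaction_for(mix, ep),
          noise_spec(noise$replicate_sd, noise$n_replicates,
                     seed + 3000L + match(mix, names(cfg$mixtures)) * 101L +
                       match(ep, endpoints) * 11L + round(1000 * lv)),
          mixture_id = mix, endpoint = ep, dilution_level = lv)
        mix_obs[[paste(mix, ep, lv, sep = ".")]] <- obs
        keys <- paste(sub$chemical, ep, sep = ".")
        have <- keys %in% names(bmd_results)
        if (!all(have)) {
          note("skipping TU for %s/%s level %s: missing BMD for %s",
               mix, ep, format(lv),
               paste(sub$chemical[!have], collapse = ", "))
          next
        }
        bmds <- stats::setNames(
          vapply(keys, function(k) bmd_results[[k]]$bmd5, numeric(1)),
          sub$chemical)
        tu <- toxic_units(
          stats::setNames(sub$concentration, sub$chemical), bmds,
          mixture_id = mix, endpoint = ep, dilution_level = lv)
        bmrs <- vapply(seq_len(nrow(sub)), function(i) {
          suppressWarnings(predict_bmr(
            bmd_results[[keys[i]]], sub$concentration[i])$bmr_pct)
        }, numeric(1))
        names(bmrs) <- sub$chemical
        assessments[[paste(mix, ep, lv, sep = ".")]] <-
          classify_mixture(tu, bmrs, obs,
                           bmr_threshold = cfg$thresholds$bmr_level,
                           fold_threshold = cfg$thresholds$fold_threshold,
                           tu_threshold = cfg$thresholds$tu_threshold)
      }
    }
  }
  assess_path <- file.path(outdir, "synergy_assessments.csv")
  assess_tab <- assessment_table(assessments, assess_path)
  record("mixture_effects", assess_path, nrow(assess_tab))

  ## stage 6: correlation attribution -------------------------------------
  sub_levels <- setdiff(unlist(cfg$levels), 1)
  single_profile <- function(nm, ep) {
    anchor <- loaecs$loaec[loaecs$chemical == nm & loaecs$endpoint == ep]
    vapply(sub_levels, function(lv) {
      predict(truth[[nm]]$effects[[ep]], anchor * lv) - 100
    }, numeric(1))
  }
  corr_files <- character(0)
  mix_deltas <- list()
  for (ep in endpoints) {
    for (mix in names(cfg$mixtures)) {
      members <- cfg$mixtures[[mix]]
      singles <- lapply(members, single_profile, ep = ep)
      names(singles) <- members
      mixture_vec <- vapply(sub_levels, function(lv) {
        obs <- mix_obs[[paste(mix, ep, lv, sep = ".")]]
        if (is.null(obs)) NA_real_ else mean(obs$value) - 100
      }, numeric(1))
      mix_deltas[[mix]] <- c(mix_deltas[[mix]], mixture_vec)
      hm <- contribution_heatmap(singles, stats::setNames(
        list(mixture_vec), mix))
      f <- file.path(outdir, sprintf("contribution_%s_%s.csv", ep, mix))
      utils::write.csv(hm, f)
      corr_files <- c(corr_files, f)
    }
  }
  sim_mat <- mixture_similarity(mix_deltas)
  sim_path <- file.path(outdir, "mixture_similarity.csv")
  utils::write.csv(sim_mat, sim_path)
  corr_files <- c(corr_files, sim_path)
  record("correlation", corr_files, length(corr_files))

  ## stage 7: MEA ----------------------------------------------------------
  mea_cfg <- cfg$mea %||% list()
  days <- mea_cfg$days %||% c(0, 3, 7, 10, 14)
  conditions <- list(
    control = mea_cfg$control_rates %||% c(0.5, 0.8, 1.2, 1.6, 2.0),
    treated = mea_cfg$treated_rates %||% c(0.5, 0.6, 0.5, 0.3, 0.2))
  mea_rows <- list()
  for (cond in names(conditions)) {
    for (di in seq_along(days)) {
      rate <- conditions[[cond]][di]
      dur <- mea_cfg$duration_s %||% 300
      epochs <- if (rate > 0) {
        data.frame(start_s = dur * c(0.1, 0.4, 0.7),
                   end_s = dur * c(0.1, 0.4, 0.7) + 0.4,
                   rate_hz = 150 * rate / max(unlist(conditions)))
      } else NULL
      well <- simulate_mea_well(
        rate, epochs,
        duration_s = mea_cfg$duration_s %||% 300,
        n_electrodes = mea_cfg$n_electrodes %||% 12,
        sync = mea_cfg$sync %||% 1,
        seed = seed + 4000L + match(cond, names(conditions)) * 31L + di,
        well = cond)
      mea_rows[[paste(cond, di)]] <- summarize_well(well, timepoint = days[di])
    }
  }
  mea_summary <- do.call(rbind, mea_rows)
  rownames(mea_summary) <- NULL
  mea_norm <- withCallingHandlers(
    normalize_to_day0(mea_summary),
    warning = function(w) {
      note("%s", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  mea_path <- file.path(outdir, "mea_summary.csv")
  mea_norm_path <- file.path(outdir, "mea_normalized.csv")
  utils::write.csv(mea_summary, mea_path, row.names = FALSE)
  utils::write.csv(mea_norm, mea_norm_path, row.names = FALSE)
  record("mea", c(mea_path, mea_norm_path), nrow(mea_summary))

  ## manifest ---------------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("dntmix")),
    seed = seed, outdir = outdir, stages = stages,
    warnings = warnings_log)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("dntmix run (seed %d) -> %s\n", x$seed, x$outdir))
  for (s in x$stages) {
    cat(sprintf("  %-16s %d record(s), %d file(s)\n", s$stage,
                s$n_records, length(s$files)))
  }
  if (length(x$warnings)) {
    cat("warnings:\n")
    for (w in x$warnings) cat("  -", w, "\n")
  }
  invisible(x)
}
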