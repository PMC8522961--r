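# Shared fixture builders (everything generated in code at test time).

std_doses <- function(ec50 = 10) ec50 * 4^(-3:3)

# Replicate table around a known curve via the package generator.
viab_tab <- function(curve = curve_spec(100, 0, 10, 1.5), sd = 0,
                     n = 2, seed = 1, doses = std_doses(curve$ec50)) {
  simulate_single_chemical(curve, doses, noise_spec(sd, n, seed))
}

# One-feature normalised table with a shift planted at selected
# concentrations, built without the package generator.
feature_tab <- function(seed, concs = c(1, 2, 4, 8), shift = 0,
                        shift_at = numeric(0), n = 6, sd = 5,
                        feature = "f1", chemical = "chemX",
                        endpoint = "ep") {
  set.seed(seed)
  all_concs <- c(0, concs)
  mu <- 100 + ifelse(all_concs %in% shift_at, shift, 0)
  data.frame(
    chemical = chemical, endpoint = endpoint, feature = feature,
    concentration = rep(all_concs, each = n), unit = "uM",
    replicate = rep(seq_len(n), length(all_concs)),
    value = pmax(0, rep(mu, each = n) + rnorm(length(all_concs) * n, 0, sd)),
    role = rep(c("control", rep("treated", length(concs))), each = n))
}

# Small pipeline configuration for smoke/determinism tests: same noise
# and threshold conditions as the demo, fewer chemicals and replicates
# of the heavy stages.
small_config <- function() {
  study_config(list(
    chemicals = list(
      A = list(unit = "uM", decimals = 2, top_dose = 100,
               effects = list(bdnf = list(direction = "increase",
                                          magnitude = 30),
                              syn = list(direction = "decrease",
                                         magnitude = 40))),
      B = list(unit = "uM", decimals = 2, top_dose = 100,
               effects = list(bdnf = list(direction = "increase",
                                          magnitude = 20),
                              syn = list(direction = "decrease",
                                         magnitude = 25))),
      C = list(unit = "uM", decimals = 4, top_dose = 10,
               effects = list(bdnf = list(direction = "decrease",
                                          magnitude = 25),
                              syn = list(direction = "increase",
                                         magnitude = 30))),
      D = list(unit = "uM", decimals = 4, top_dose = 1,
               effects = list(bdnf = list(direction = "increase",
                                          magnitude = 25),
                              syn = list(direction = "increase",
                                         magnitude = 20)))),
    mixtures = list(`2-Sim` = c("A", "B"), `2-Diss` = c("C", "D"),
                    `4-All` = c("A", "B", "C", "D")),
    all_mixture = "4-All",
    endpoints = list(bdnf = c("bdnf_total"), syn = c("synapses")),
    levels = c(1, 0.5, 0.25, 0.125),
    dilution = list(factor = 4, n_points = 7),
    noise = list(replicate_sd = 5, n_replicates = 6),
    thresholds = list(bmr_level = 5, tu_threshold = 1,
                      fold_threshold = 2, alpha = 0.05),
    interactions = list(list(mixture = "2-Sim", endpoint = "syn",
                             mode = "synergistic", deviation_pct = 12)),
    bmd = list(n_boot = 40),
    mea = list(duration_s = 120, n_electrodes = 6, sync = 1,
               days = c(0, 7, 14),
               control_rates = c(0.8, 1.4, 2.0),
               treated_rates = c(0.8, 0.5, 0.2))))
}
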