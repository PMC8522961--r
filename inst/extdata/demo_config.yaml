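# Synthetic demo study: ten chemicals, three endpoint-anchored mixtures.
# All potencies below are synthetic ground truth for the generators, not
# measured values; units are uM throughout (EtOH's mM range expressed in uM).
chemicals:
  BPA:      {unit: uM, decimals: 2, top_dose: 100,    viab_hill: 1.5,
             effects: {bdnf: {direction: increase, magnitude: 30},
                       syn:  {direction: decrease, magnitude: 35, hill: 3}}}
  CPF:      {unit: uM, decimals: 2, top_dose: 100,    viab_hill: 1.5,
             effects: {bdnf: {direction: increase, magnitude: 25},
                       syn:  {direction: decrease, magnitude: 30, hill: 3}}}
  Lead:     {unit: uM, decimals: 4, top_dose: 10,     viab_hill: 1.5,
             effects: {bdnf: {direction: increase, magnitude: 20},
                       syn:  {direction: decrease, magnitude: 25, hill: 3}}}
  BDE47:    {unit: uM, decimals: 2, top_dose: 100,    viab_hill: 1.5,
             effects: {bdnf: {direction: increase, magnitude: 20},
                       syn:  {direction: decrease, magnitude: 50, hill: 3}}}
  EtOH:     {unit: uM, decimals: 2, top_dose: 200000, viab_hill: 1.5,
             effects: {bdnf: {direction: increase, magnitude: 25},
                       syn:  {direction: decrease, magnitude: 20, hill: 3}}}
  Methyl-Hg: {unit: uM, decimals: 4, top_dose: 1,     viab_hill: 1.5,
             effects: {bdnf: {direction: increase, magnitude: 30},
                       syn:  {direction: decrease, magnitude: 25, hill: 3}}}
  PCB138:   {unit: uM, decimals: 4, top_dose: 10,     viab_hill: 1.5,
             effects: {bdnf: {direction: increase, magnitude: 15},
                       syn:  {direction: increase, magnitude: 30, hill: 3}}}
  VA:       {unit: uM, decimals: 2, top_dose: 10000,  viab_hill: 1.5,
             effects: {bdnf: {direction: decrease, magnitude: 20},
                       syn:  {direction: increase, magnitude: 25, hill: 3}}}
  Vincl:    {unit: uM, decimals: 2, top_dose: 1000,   viab_hill: 1.5,
             effects: {bdnf: {direction: increase, magnitude: 20},
                       syn:  {direction: increase, magnitude: 15, hill: 3}}}
  TCDD:     {unit: uM, decimals: 4, top_dose: 0.83,   viab_hill: 1.5,
             effects: {bdnf: {direction: increase, magnitude: 25},
                       syn:  {direction: increase, magnitude: 20, hill: 3}}}
mixtures:
  5-Sim:  [BPA, CPF, Lead, BDE47, EtOH]
  5-Diss: [Methyl-Hg, PCB138, VA, Vincl, TCDD]
  10-All: [BPA, CPF, Lead, BDE47, EtOH, Methyl-Hg, PCB138, VA, Vincl, TCDD]
all_mixture: 10-All
endpoints:
  bdnf: [bdnf_total, bdnf_ratio]
  syn: [synapses, syp, psd95]
# EC50 multipliers per feature: the synapse count anchors the BMD models,
# while SYP and PSD95 respond at lower doses and usually set the LOAEC.
feature_sensitivity:
  bdnf: [1, 1]
  syn: [1, 0.25, 0.5]
levels: [1, 0.5, 0.25, 0.125]
dilution: {factor: 4, n_points: 7}
noise: {replicate_sd: 5, n_replicates: 6}
thresholds: {bmr_level: 5, tu_threshold: 1, fold_threshold: 2, alpha: 0.05}
interactions:
  - {mixture: 5-Sim,  endpoint: syn, mode: synergistic, deviation_pct: 12}
  - {mixture: 10-All, endpoint: syn, mode: synergistic, deviation_pct: 12}
bmd: {n_boot: 100}
mea:
  duration_s: 300
  n_electrodes: 12
  sync: 1
  days: [0, 3, 7, 10, 14]
  control_rates: [0.5, 0.8, 1.2, 1.6, 2.0]
  treated_rates: [0.5, 0.6, 0.5, 0.3, 0.2]
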