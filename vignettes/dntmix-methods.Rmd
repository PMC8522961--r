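---
title: "Models and methods behind dntmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dntmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dntmix)
```

## The problem

In vitro developmental neurotoxicity (DNT) screens expose differentiating
human neural cultures to single chemicals and to defined mixtures, and read
out endpoints anchored to key events of neurodevelopment: BDNF protein
levels, neurite outgrowth, synaptogenesis (SYP, PSD95, synapse counts), the
proportions of neurons and astrocytes, and spontaneous electrical activity
on multi-electrode arrays (MEAs). All plate endpoints are normalised to a
solvent control (0.1% DMSO) set to 100%.

`dntmix` implements the quantitative machinery such a study needs, end to
end: concentration-series design, curve fitting and benchmark-dose (BMD)
analysis of the single chemicals, LOAEC determination, construction of
endpoint-anchored mixtures, concentration-addition scoring with a
synergy/interaction classification, correlation-based attribution, and MEA
spike-train analytics. Because real screens of this kind rarely deposit
replicate-level data, the package pairs every analysis stage with a
synthetic-data generator whose ground truth is known, so each statistical
property of the pipeline can be verified rather than assumed.

## Dose-response model and ICx anchors

The response of one endpoint to one chemical is modelled by the
variable-slope four-parameter logistic (4PL),

$$f(d) = bottom + \frac{top - bottom}{1 + (d/EC_{50})^{h}},$$

with `top` the plateau at zero dose (about 100% on the normalised scale),
`bottom` the plateau at infinite dose, and Hill slope $h > 0$. Fitting
(`fit_4pl()`) is unweighted least squares with concentrations
log-transformed internally; zero-dose control rows never enter the log-dose
fit. Initialisation uses eight deterministic starts (two EC50 candidates
from log-dose quantiles crossed with Hill slopes 0.5, 1, 2, 4); there are no
stochastic restarts, so a refit is bit-reproducible. A fit is declared
non-converged when no start converges or when `top` and `bottom` collapse
onto each other (flat, non-identifiable data) — the `converged` flag is
honest rather than optimistic.

Inhibitory concentrations come from the closed-form inverse of the fitted
curve: `invert_icx(fit, 20)` returns the concentration producing a 20%
deviation from the zero-dose plateau. The sub-cytotoxic anchor IC20/100 is
*defined* as the IC20 concentration divided by 100, not as an IC0.2
inversion. When the highest tested concentration does not reach the
requested level — as happens when solubility truncates a curve — the
inversion refuses to extrapolate and signals a typed condition; callers may
substitute the highest tested concentration (`ic_levels(substitute_highest
= TRUE)`), which is the convention for solubility-limited chemicals.

## Benchmark-dose analysis

`fit_model_family()` fits five continuous mean models by Gaussian maximum
likelihood (least squares): linear, quadratic polynomial, power
($a + b\,c^p$), hill (the 4PL on the raw dose axis) and a three-parameter
exponential ($a\,e^{b c^d}$). This family approximates the continuous model
set of the standard BMD software for such endpoints; the exact internals of
any particular tool are not reproduced. AIC is $2k - 2\ell$ with $k$
counting mean parameters plus the error variance; `select_best()` takes the
lowest AIC, breaking ties by fewer parameters and then a fixed family
order, so selection is deterministic. The error variance is floored at
$10^{-12}$ so that several families interpolating the same exact data share
one finite likelihood and the tie-break decides.

The benchmark dose solves $|f(c) - f(0)| = \frac{BMR}{100}\,|f(0)|$ with
BMR = 5% by default — a *relative* deviation from the modelled control
response, which on the normalised scale (where $f(0) \approx 100$)
coincides with an absolute 5-point change. Uniqueness is verified by
sign-checking the deviation function on a 401-point dose grid; multiple
crossings trigger a warning and the lowest crossing is reported. Both
response directions are treated as adverse signals; the `direction` field
records which way the best model moves at the BMD.

BMDL/BMDU bounds come from a seeded nonparametric bootstrap: replicates are
resampled within each dose level, the selected family is refitted, the BMD
re-derived, and the 2.5/97.5 percentiles taken (default 1000 replicates).
The interval is clamped to bracket the point estimate, so
`bmdl <= bmd5 <= bmdu` holds unconditionally. Percentile intervals are
known to be anti-conservative when per-dose replicate groups are small: on
simulated linear data the measured coverage of the nominal 95% interval is
roughly 79% with 3 replicates per dose, 87% with 6 and 92% with 8. The
package's validation experiments therefore use 8 replicates per dose, the
upper end of the 6–8 internal replicates such plate designs use. Users with
3-replicate designs should read the bounds as descriptive, not as exact
95% intervals; profile-likelihood bounds were deliberately not implemented
(simplicity and distribution-freeness won), and this is the main known
limitation of the BMD stage.

`predict_bmr()` inverts the direction of use: given the fitted model, it
returns the absolute benchmark response (% deviation from $f(0)$) at an
arbitrary nominal concentration — the single-chemical contribution entering
the mixture assessment. Predictions beyond twice the tested range are
flagged as extrapolated.

## LOAEC and mixture design

Significance against the solvent control is assessed per measured feature
by one-way ANOVA followed by Dunnett's many-to-one comparison
(`dunnett_vs_control()`, via the multivariate-t machinery of multcomp, with
the quasi-Monte-Carlo evaluation seeded for reproducibility). Tiers use the
conventional 0.05/0.01/0.001 cuts. The LOAEC of a (chemical, endpoint) is
the lowest tested concentration significant on *at least one* of the
endpoint's features; no significance anywhere leaves it undefined, a valid
outcome. No correction is applied across features, endpoints or chemicals
beyond the within-family Dunnett adjustment. Tests run on normalised
(% of control) replicate values for cross-plate comparability.

Mixture design tables anchor each member chemical at its endpoint-specific
LOAEC and halve the *unrounded* anchor for each further 2-fold level,
rounding half away from zero to the chemical's stated precision — the
convention needed so that, e.g., 21.01/2 prints as 10.51. Serial dilution
series for single-chemical ranges follow the same rounding
(`serial_dilution()`).

## Toxic Units and the two-criterion classification

Under concentration addition the Toxic Unit score of a mixture condition is

$$TU = \sum_i \frac{[chem_i]}{BMD_5(chem_i)},$$

with per-chemical terms retained for attribution. A condition is classified
(`classify_mixture()`) by two criteria:

1. $TU \le 1$ **and** the observed mixture deviation from the 100% control
   level exceeds the 5% benchmark response;
2. the observed deviation is at least two-fold the benchmark response of
   the most potent member at its nominal concentration.

Both met: *synergistic*; only the second: *interactive*; otherwise *none*.
Deviations and BMRs are compared as absolute magnitudes, since endpoints
move in both directions; when signed BMRs are supplied and the strongest
single chemical opposes the mixture's direction, a warning flag is raised
without blocking classification. Antagonism is deliberately not
classified: with endpoints responding in both directions an effect weaker
than predicted cannot be separated from additivity here, so the raw
quantities are exposed for users who want their own rule.

Two structural properties of this rule are worth knowing. First, a mixture
of several comparably potent chemicals under *exact* additivity already
satisfies the fold criterion (the joint effect of $k$ similar components
exceeds twice any single contribution), so "interactive" must be read as
"beyond the strongest single chemical", not as proof of interaction; only
a dominant-driver composition can read "none". Second, when the strongest
single BMR is near zero, the fold criterion can fire on replicate noise
alone. The calibration experiments below therefore use a dominant-driver
composition, and the demo study shows both behaviours.

## Correlation attribution

Each chemical's contribution to a mixture is summarised by the Pearson
correlation between its response profile and the mixture's profile across
the shared dilution levels (LOAEC/2, /4, /8): positive r means the chemical
moves with the mixture (a plausible driver), negative r opposite
directionality. Mixtures are compared pairwise over concatenated delta
profiles across all endpoints. With only three dilution points r is noisy;
no p-values are attached, matching how such heatmaps are read
(qualitatively). Missing levels drop to pairwise-complete observations with
a two-point minimum. Aggregation per feature or per endpoint is the
caller's choice of input vectors.

## MEA analytics

A burst is a train of at least 5 spikes within 100 ms. Since that criterion
alone does not fix how a burst *extends*, the detector uses maximal-run
semantics: a burst opens at the earliest spike beginning a qualifying
5-spike window and grows while every trailing 5-spike window stays within
100 ms; bursts are non-overlapping and ordered. This choice is verified
against an exhaustive window-scan oracle in the test suite (exact
agreement on 1000 random trains). Fixed-ISI burst detectors are out of
scope.

A network burst is a maximal time interval during which the number of
electrodes simultaneously inside a burst reaches a threshold fraction of
the well's electrodes — all 12 by default (the strict reading of
synchronised bursting across the well), with `min_fraction` exposed
because real wells have silent electrodes. Burst intervals are treated as
closed, so intervals touching at a point count as overlapping; whether the
instrument's algorithm uses interval overlap or a fixed synchrony bin is
not decidable from published descriptions, so overlap was chosen and made
configurable. Longitudinal treatment series are normalised per well to the
pre-treatment (day 0) recording; a zero day-0 metric is flagged missing
rather than divided.

## The synthetic-data generator

`simulate_single_chemical()` draws replicate responses around a known 4PL
truth with Gaussian noise on the % of control scale, truncated at zero.
Published studies of this design report means ± SEM only, so the
replicate-level distribution is unconstrained by data; Gaussian was chosen
for transparency. Defaults emulate the plate design: 6 internal replicates,
replicate SD of 5% of control (a typical resazurin/HCI replicate spread),
7-point 4-fold dilution series, 300 s MEA recordings over 12 electrodes.
All randomness flows through one explicit seed per call and the caller's
RNG state is restored.

`simulate_mixture()` implements exact dose addition: component
concentrations are converted to equivalents of the first component's curve
by EC50-ratio scaling (the simplest Loewe-consistent choice; the
concentration-addition concept fixes no particular mixture curve form), the
equivalents are summed and the reference curve evaluated there. An
interaction specification can then inject ground-truth deviation:
synergism adds, antagonism removes, percentage points of deviation from
100% (never overshooting past the control level).

`simulate_mea_well()` generates Poisson background spiking with embedded
high-rate burst epochs; `sync = 1` places epochs identically on all
electrodes, lower values jitter each electrode's copy uniformly by up to
`(1 - sync)` epoch lengths.

What the generator does *not* emulate: non-Gaussian replicate tails,
plate-position and batch effects, correlated features within an endpoint,
biphasic (hormetic) dose-response shapes, and chemical-specific MEA
waveform changes. Passing tests therefore demonstrate that the pipeline's
arithmetic, fits and decision rules behave as specified under controlled
conditions — not that any particular laboratory dataset satisfies those
conditions.

## The demo study and pipeline

`run_pipeline(default_config())` executes the full flow on a synthetic
ten-chemical study shaped like the motivating design: five similar-MoA
chemicals (BDNF-level perturbers: BPA, CPF, Lead, BDE47, EtOH), five
dissimilar-MoA chemicals (Methyl-Hg, PCB138, VA, Vincl, TCDD), and the
mixtures 5-Sim, 5-Diss and 10-All at LOAEC, /2, /4, /8 for the BDNF and
synaptogenesis endpoints. All potencies in the configuration are synthetic
ground truth. Within the synaptogenesis endpoint the secondary features
(SYP, PSD95) are modelled as more dose-sensitive than the synapse count
that anchors the BMD models (EC50 multipliers 0.25 and 0.5); that
separation is what allows low dilutions to reach $TU \le 1$ — if the LOAEC
feature and the BMD feature coincide, the LOAEC (a ~7% detection
threshold) always sits above the 5% benchmark dose and criterion (i) can
never hold, which is itself an informative structural fact about the rule.
Synergistic interaction (+12 percentage points) is injected into the
synaptogenesis endpoint of the two BDE47-containing mixtures, and the
classifier recovers it at the lowest dilution where TU drops below 1.

Every stage writes plain CSV, and the manifest records MD5 hashes of all
outputs; reruns with the same configuration and seed are hash-identical.
The heavy stages are scaled for interactive use (100 bootstrap replicates
per BMD in the demo; 1000 is the analysis default).

## Numerical choices, in one place

- Rounding: half away from zero with a relative $10^{-8}$ guard against
  binary representation error (`round_half_away()`).
- 4PL and hill fits: Levenberg–Marquardt, at most 500 iterations,
  deterministic 8-start grids; degenerate fits flagged, never silently
  accepted.
- Power and exponential families: deterministic exponent grids
  (25 and 13 points) with local refinement, so no fit depends on RNG state.
- BMD root finding: 401-point bracketing grid, `uniroot` at $10^{-12}$;
  bootstrap percentile interval type 7, clamped to bracket the estimate.
- Dunnett p-values: multivariate-t via quasi-Monte-Carlo, seeded per call.
- Network-burst sweep: event ordering puts interval starts before ends at
  equal timestamps (closed-interval semantics).
- Validation problem sizes: 200 datasets x 200 bootstrap replicates for
  interval coverage, 1000 null simulations for the Dunnett type-I rate,
  1000 random trains for the burst oracle, 200 seeded runs per calibration
  scenario.
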