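---
title: "Models and methods behind fretscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fretscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretscreen)
```

# The assay and its readout

The package analyzes a family of FRET assays built around a protein (RAD52
is the motivating case) that wraps single-stranded DNA around its ring. A
30-mer oligonucleotide carries Cy3 at one end and Cy5 at the other; wrapping
brings the dyes close and raises FRET, and an inhibitor of the protein–DNA
interaction lowers it. Two instruments and hence two FRET formulas appear:

* **Plate reader (primary screen):** apparent FRET is the raw acceptor
  fraction `I_Cy5/(I_Cy5 + I_Cy3)` (`fret_app_raw()`). It is a proximity
  proxy, not a photophysically corrected efficiency, which is all a
  single-point screen needs.
* **Spectrofluorimeter (titrations, kinetics):** the calibrated form
  `4.2·I_Cy5/(4.2·I_Cy5 + 1.7·I_Cy3)` (`fret_app_calibrated()`). The
  factors 4.2 and 1.7 compensate the different channel detection
  efficiencies of the cuvette instrument; they are configurable because
  they are instrument properties, not constants of nature.

Reference FRET levels used as generator defaults: ~0.63 for the intact
stoichiometric complex, ~0.30 for the complex disrupted by excess unlabeled
ssDNA, ~0.48 for free labeled ssDNA.

## Control-label convention

In this assay the **negative control** is the *intact* high-FRET complex
and the **positive control** the *disrupted* low-FRET complex. Only under
this convention is the dynamic range `μ_n − μ_p` positive, so `Z′ ≤ 1` and
the "k SD below the negative control" hit rule are well defined; swapped
controls produce a negative dynamic range, which `plate_qc()` reports as an
explicit "inverted controls" diagnostic rather than silently returning a
meaningless Z′.

# Plate stage

`plate_qc()` computes `μ` and `SD` of the two control populations per
plate and from them `Z′ = 1 − 3(SD_n + SD_p)/(μ_n − μ_p)`,
`S/N = (μ_n − μ_p)/SD_n` and `S/B = μ_n/μ_p`.

`call_hits()` applies `FRET ≤ μ_n − k·SD_n`, with:

* `k = 5` by default, **boundary inclusive** ("at least 5 SD").
* Control statistics taken **per plate**, never pooled across the
  campaign. Controls sit on every plate precisely so that plate-to-plate
  drift cancels; pooling would re-import it. For single-point screens the
  negative-control SD is the only dispersion estimate available, so it is
  the SD in the criterion.
* A plate Z′ floor (default 0.5, standard screening practice for an
  excellent-to-acceptable assay); wells on failing plates are flagged
  `qc_failed` and excluded rather than dropped silently.

`confirm_hits()` mirrors cherry-pick rescreening: a compound is confirmed
only if it passes the criterion in *every* rescreen round; failures are
labeled "poor reproducibility" and absences "untested".

`flag_optical_artifacts()` targets the classic false-positive signature of
colored or fluorescent compounds: a signal that tracks compound
concentration roughly linearly instead of saturating. The decision rule —
straight-line fit (better of linear- and log-concentration regressors)
with R² ≥ 0.95 *and* no converged sigmoidal inhibition fit — flags the
linear signature only when the mechanistic model cannot claim the data,
so genuine steep inhibitors are not flagged. A separate `HIGH_BACKGROUND`
flag catches compounds whose compound-only wells exceed a configurable
FRET ceiling (default 0.8).

# Dose–response stage

## Artifact correction

Compounds that absorb or fluoresce distort both the protein-present and
protein-free signals in the same additive way. The paired correction
subtracts, per concentration, the change of the no-protein control
relative to its zero-compound baseline:
`corrected(c) = F_protein(c) − (F_no_protein(c) − F_no_protein(0))`. It is
exactly the identity when the control series is flat. Note the correction
propagates the control's noise into the corrected curve (variance roughly
triples for equal per-series noise), which is why the package fits
uncorrected protein series when a compound is known to be optically clean.

## The inhibition model and its parameterization

`fit_inhibition()` fits

`F(c) = f_sat + (f0 − f_sat)/(1 + (c/IC50)^h)`

The familiar log-logistic form
`FRET0 − FRETmin/(1 + 10^((logIC50 − log c)·h))` describes the same curve
for `c > 0` with `FRET0 = f0` and `FRETmin = f0 − f_sat`; the test suite
verifies pointwise equality to 1e−12. The plateau-anchored
parameterization is used because the saturation FRET `f_sat` is itself a
reported assay readout (it encodes how much of the complex survives at
full inhibition — partial disruption leaves `f_sat` well above the free-DNA
level), so it should be a primary parameter with a standard error, not a
derived difference.

Numerical choices:

* **Initialization:** coarse grid of 40 log-spaced IC50 candidates ×
  Hill slopes {0.5, 1, 2}; at each node the two plateaus solve a linear
  least-squares problem, making the scan cheap and exhaustive. The best
  node seeds Levenberg–Marquardt refinement (`minpack.lm::nlsLM`), plus
  two restarts from perturbed initials. If every LM start is rejected
  (rare, e.g. singular gradient at the seed), a Nelder–Mead refinement of
  the grid optimum is used so the single shared code path never aborts an
  analysis batch.
* **Bounds:** Hill slope in (0.1, 10]; plateaus in [−0.5, 1.5] (slightly
  outside the physical [0, 1] so boundary estimates do not bias).
* **Zero-concentration points** are valid inputs: the model evaluates to
  `f0` at `c = 0`, so baselines anchor `f0` without entering any
  log-domain computation. Fitting is least squares on linear FRET versus
  concentration (the concentrations themselves are log-spaced by design).
* **Status rules:** `NO_INHIBITION` when the fitted amplitude
  `f0 − f_sat` is below 0.02 FRET units or within 2 SE of zero (there is
  no published rule for "NI" calls; 0.02 is ~2–4× a typical point SD);
  `LOWER_BOUND_ONLY` with the maximum tested concentration as the bound
  when the fitted IC50 exceeds the tested range (the ">300 µM" style of
  report).
* Concentrations are carried in molar throughout; printing auto-scales to
  mM/µM/nM.

`classify_specificity()` condenses per-condition fits (ssDNA, RPA-coated
ssDNA, dsDNA, protein-free RPA control) into a profile string such as
`ssDNA+, ssDNA_RPA+, dsDNA-, RPA_only-`, the signature of an inhibitor
specific for the ssDNA-wrapping interaction.

# Annealing stage

`fit_biexp()` fits the asymptote-anchored biexponential
`F(t) = F_inf − A1·e^(−k1 t) − A2·e^(−k2 t)` with nonnegative amplitudes.
The asymptote `F_inf` *is* the final extent of annealing: it is the only
plateau measure that is stable under refitting and resampling, unlike the
last observed point (noise-limited) or a baseline-subtracted amplitude
(confounds baseline error into the extent). The rising-amplitude and
decaying-offset forms of a double exponential are algebraically
equivalent; the asymptote-anchored one makes the quantity of interest a
direct parameter.

* Initialization is separable: a log-spaced grid of rate pairs, a linear
  solve of `(F_inf, A1, A2)` at each pair, then LM refinement.
* Rates are bounded below by ~0.5/t_max: slower phases are not
  identifiable inside the observation window, and allowing them lets a
  near-flat trace extrapolate an arbitrarily high, unobservable
  asymptote. With the default 500 s window the slowest fittable rate is
  1e−3/s.
* The fast phase is labeled 1 (`k1 ≥ k2` by relabeling). When the two
  fitted rates differ by less than 1.5×, they are not distinguishable and
  the reduced single-exponential model is refitted and reported
  (`model = "single"`, `a2 = 0`).
* A trace with a clear trend that the (rise-only) model cannot fit better
  than a flat line fails with `FIT_FAILED` instead of returning a
  meaningless asymptote; a genuinely flat trace is fine and returns the
  baseline with near-zero amplitudes.

`annealing_ic50()` then fits extent versus concentration with **the same
`fit_inhibition()` code path** (tested for verbatim agreement), the
zero-compound reference anchoring the uninhibited extent.

# Virtual-screening stage

`build_roc()` constructs a pose-level ROC (each docked pose is an
instance; a compound-level best-pose analysis is available through
`select_candidates()`). Conventions, chosen where the usual descriptions
are ambiguous for lower-is-better scores:

* Scores are free energies: lower is better (`lower_is_better = FALSE`
  inverts).
* A cutoff `t` predicts a pose active iff its score is *strictly better*
  than `t`.
* Tied scores form a single ROC vertex (block ties), so the curve is
  independent of input order, and the trapezoidal AUC equals the
  Mann–Whitney pair-count probability with ties at 1/2 — an identity the
  suite checks to 1e−12 against an independent pair-counting oracle and
  against pROC.
* `pick_threshold()` maximizes Youden's J = TPR − FPR (no selection
  criterion is standard in the source workflows; Youden's J is the common
  default), breaking ties toward the more stringent cutoff.

`score_histogram()` summarizes active/decoy separation as
`|mean_a − mean_d|/pooled SD`, the natural scale on which "bimodal" score
distributions show separations well above 2.

# The synthetic-data generators

The generators are first-class, tested code: they define the study
conditions under which the pipeline's recovery claims are made.

* **Screen** (`gen_screen()`): 16 × 24 plates; intact-complex controls in
  columns 1/24, disrupted controls in 2/23, 320 test compounds in columns
  3–22; control means 0.63/0.30. Planted actives are depressed by
  `active_effect` (default the full dynamic range); a configurable
  fraction of inactives get a spurious FRET offset. Per-well FRET SD
  defaults to 0.005 — no control SD is published for this assay family,
  and 0.005 both is typical of well-behaved plate readers and reproduces
  the reported Z′ regime (≈0.9 for control wells). Noise is additive
  Gaussian on the two channel intensities (instruments read intensities),
  scaled by first-order propagation so the induced FRET SD equals the
  configured value; a pure FRET-level noise mode exists for closed-form
  checks. Total intensity is fixed at 1000 au — absolute intensities are
  never reported in this assay family and only the ratio matters.
* **Titration** (`gen_titration()`): the inhibition model plus an optical
  artifact linear in log concentration, added to *both* the protein and
  no-protein series — an artifact lives in the optics, so it must appear
  in both for the paired correction to remove it (the suite checks that
  correcting an artifact-bearing series recovers the artifact-free curve).
  Default grid: 12 log-spaced concentrations spanning 30-fold either side
  of the IC50, point noise SD 0.01 FRET, free-DNA baseline 0.48.
* **Annealing** (`gen_annealing()`): biexponential rises over 500 s
  (defaults k1 = 0.05/s, k2 = 0.005/s, 70% fast amplitude, baseline 0.2,
  uninhibited extent 0.6), with the per-concentration asymptote supplied
  by the caller — inhibition enters through the extents, so full
  inhibition pins the extent at the baseline.
* **Scores** (`gen_pose_scores()`): two Gaussians (defaults: actives
  −9 ± 0.8, decoys −5.5 ± 1.0 kcal/mol), the statistical skeleton of a
  bimodal active/decoy histogram. No chemistry is simulated.

All generators run inside `withr::with_seed()`: the same config and seed
reproduce outputs bit-for-bit, and different seeds share expectations —
both are tested.

What the generators deliberately do **not** emulate: photobleaching and
blinking, dispenser positional effects and edge artifacts, plate-to-plate
drift, non-Gaussian outliers, compound aggregation, or any docking
chemistry. Passing recovery tests therefore demonstrates correctness of
the *analysis* under the stated noise model, not robustness to every
pathology of real plates.

# Parameter-recovery study sizes

The recovery checks simulate 100 titrations (12 concentrations each) per
inhibitor parameter set, and 100 end-to-end annealing campaigns (9 time
courses × 251 points each), with medians compared against the generative
values; these sizes give sub-percent Monte-Carlo error on the medians
while keeping a full run in the tens of seconds. The campaign-scale
screen check uses 9 plates / 2880 test wells with 96 planted full-effect
actives at 0.005 FRET noise — an effect ≈ 66 SD, so exact recovery is the
correct expectation, and the normal tail bound (Φ(5) miss probability
under a 10-SD effect with a 5-SD cut) is tested explicitly.

# Known limitations

* IC50s are empirical potencies, not binding constants; no mechanistic
  (Kd, cooperativity, competition) model is fitted.
* Asymptotic (Wald) standard errors from the NLS fits are approximate at
  small n and near bounds; the coverage of the IC50 intervals is verified
  by simulation (≥85% nominal 95% coverage) under the default design, not
  guaranteed universally.
* The artifact flagger is a screening heuristic: a compound that is both
  a genuine inhibitor and strongly chromogenic can evade the linear
  signature; the paired titration correction, not the flag, is the
  definitive treatment.
* Extent estimates degrade when inhibition also slows annealing so much
  that the window captures < ~3 slow-phase half-lives; the rate floor
  keeps such fits bounded but cannot restore unobserved information.
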