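---
title: "Protection-factor footprinting and the enzyme assay panel: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Protection-factor footprinting and the enzyme assay panel: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrfassay)
```

This vignette documents the models the package fits, the defaults it chooses
where the underlying experimental conventions leave room, and what the
synthetic-data generators do and do not emulate.

## The footprinting model

Hydroxyl radical footprinting exposes a protein to X-ray-generated •OH for
millisecond doses; solvent-exposed side chains oxidise, buried ones do not.
Quantification starts from integrated MS peak areas. For one modification
site at one exposure/replicate, with `A_u` the unmodified-peptide area and
`A_m` the areas of its modified species,

$$F_u = 1 - \frac{A_m}{A_u + \sum A_m}$$

is the fraction unmodified (per species, or with $\sum A_m$ in the numerator
for the site-level aggregate). `fraction_unmodified()` implements both; the
default pipeline fits the **aggregate** per residue site, because protection
factors are interpreted per residue — per-species fits remain available by
passing a `species` label to `build_exposure_series()`.

The dose response is first-order,

$$F_u(t) = F_u(0)\, e^{-kt},$$

fitted by unweighted nonlinear least squares with every replicate entering
as an independent point (duplicate reactions at four exposure times give
eight independent observations per site, the design the generator defaults
to). Assumptions worth stating:

* modification is irreversible and pseudo-first-order over the dose range —
  no secondary-oxidation correction is attempted;
* replicate scatter is homoscedastic on the fraction scale (hence unweighted
  least squares);
* `F_u(0)` is a free parameter bounded in `(0, 1.2]` rather than pinned to 1,
  accommodating baseline oxidation of the unexposed control; `fix_f0 = TRUE`
  pins it for workflows that treat the control as definitionally unmodified.
  The upper bound 1.2 tolerates noise pushing the intercept slightly above 1
  without letting it absorb the decay.

The protection factor normalises the observed rate by the residue type's
intrinsic reactivity:

$$\mathrm{PF}_i = R_i / k_i, \qquad \ln \mathrm{PF}_i \text{ used throughout.}$$

The package ships **no literature $R_i$ values**: intrinsic reactivities are
a user-editable CSV (`read_reactivity_csv()`), because published scales vary
in units and coverage and the absolute PF scale inherits whatever table the
user supplies. A synthetic table with a plausible relative ordering
(aromatic/sulfur-containing fast, small polar slow) ships for testing and is
labelled synthetic in both filename and documentation. Relative and
differential quantities (ΔlnPF) are insensitive to the table's overall scale.

### Censoring and degenerate fits

A site whose series is flat at 1 has no detectable modification: its rate is
reported as exactly 0 with the flag `no_detectable_modification`, and its PF
is only bounded from below. `compute_protection_factor()` substitutes a
minimum resolvable rate (`min_rate`, default 0.5 s⁻¹) and flags the record
`censored` instead of reporting an infinite PF. The default is the slowest
rate whose decay (≈ 4% over a 75 ms window) is still distinguishable from
flat at the default 10% area noise; it is configurable and censored records
are excluded from numeric ΔlnPF (they appear in a qualitative side list
from `compare_states()`). Non-converged fits are reported with `rate = NA`
and `converged = FALSE` — never silently zero.

### Numerical engine

All nonlinear fits use bounded Levenberg–Marquardt (`minpack.lm::nls.lm`)
with standard errors from the Gauss–Newton approximation $J^\top J$ at the
solution. This matters for exactly reproducible synthetic data: wrappers
that re-derive an `nls` object after convergence can fail with singular
gradients when residuals reach machine zero, whereas the direct engine
handles zero-residual fits cleanly (their SEs are simply 0). Start values
come from closed forms: log-linear regression for the decay rate,
inverse interpolation at half-maximum for Km and IC50. The IC50 model is
parameterised internally on log(IC50) for conditioning, with the SE
back-transformed by the delta method.

## Differential protection

`compare_states()` joins protection records by site and computes
`ΔlnPF = lnPF_b − lnPF_a` (bound minus unbound; antisymmetric under swap).
The SE of each delta is propagated from the rate SEs via
$\mathrm{SE}(\ln\mathrm{PF}) = \mathrm{SE}(k)/k$.

There is no community-standard numeric cutoff for calling a residue "more
protected"; the package's rule is a documented choice: `ΔlnPF ≥ 1` (an
e-fold PF change, comfortably above replicate scatter at default noise)
**and** `|Δ| ≥ 2 × SE(Δ)`. Both knobs are arguments of
`classify_residues()`; when SEs are unavailable the rule degrades to the
threshold alone with a warning.

Structure mapping (`map_to_structure()`) matches residues by chain + author
residue number and treats a residue-type mismatch as an error rather than a
warning — numbering drift between the quantification table and the
coordinate file is a silent way to colour the wrong residues, and a hard
failure is the safer default. Scores go into the B-factor column of every
atom of the residue; unmatched residues keep a sentinel (default 0) and are
reported.

## The assay panel

**Thermal shift.** Tm is defined as the temperature of the extremum of
−d(RFU)/dT — the inflection of the melt curve, i.e. the two-state transition
midpoint. The curve is smoothed and differentiated with a Savitzky–Golay
filter (window 7 points, order 3), defaults suited to 0.5 °C sampling — the
read spacing of a 2 °C/min gradient sampled every 15 s; both are arguments.
The discrete extremum is refined by the vertex of a least-squares quadratic
over one filter window, giving sub-grid precision without trusting a single
noisy 3-point parabola. Extrema at the scan edge are flagged `boundary`;
secondary extrema within 50% of the main one flag `multimodal` (the largest
is returned); a flat curve returns `no_transition` with `tm = NA`.
`delta_tm()` does the ladder bookkeeping (apo → +cofactor → +cofactor+drug);
increments are exact successive differences, so they sum to the total Tm
change, and `stabilization_loss()` subtracts mutant from reference
increments.

**Kinetics.** Activity is the OLS slope of the first eight reads at 15 s
spacing (105 s), the window in which product accumulation is linear at the
simulated rates; both are arguments. The Hill model is fitted with the
exponent free by default (`fix_hill = 1` gives Michaelis–Menten); a fitted
Km outside 100× the titration range is flagged `extrapolated_km` rather than
trusted.

**Dose–response.** Percent inhibition relative to the uninhibited reference
is clamped to [−10, 110] with a warning (small negatives are replicate
noise at zero inhibition). The IC50 fit is the three-parameter logistic with
unit Hill slope — bottom, top and IC50 free — matching the common
plate-reader analysis convention; `pin_limits = TRUE` fixes bottom = 0,
top = 100. **No tight-binding (Morrison) correction is applied** even though
an enzyme concentration of a few nM can exceed the smallest IC50s in such
panels: the plain logistic is fitted deliberately, reproducing the
conventional reduction, and reported IC50s should be read as apparent
values under the stated assay conditions.

## What the generators emulate

Each generator draws from the model its analysis stage assumes and emits a
truth table, so recovery can be scored exactly.

* `gen_hrf_dataset()` — exposures 0/25/50/75 ms, duplicate reactions,
  expected fraction `exp(−kt)`, and **multiplicative log-normal noise**
  (CV-parameterised, default 0.1) applied independently to each peak area —
  an MS-intensity-like noise model; realistic CVs for footprinting peak
  areas are not well established, so 10% is a placeholder that the
  recovery tests quantify against. The default panel has ten probe sites
  with rates 2–80 s⁻¹ (so `k·t_max` spans 0.15–6, all measurable within the
  window), named after canonical probe positions from buried (F21, slow) to
  exposed (Y256, fast). Two-state mode divides the rates of a designated
  protected set — by default the mid-rate drug-contact probes F185, I190,
  Y217 — by a single protection multiplier (default e²), coupling the
  states the way a ligand-induced burial does. Protected defaults are
  mid-rate deliberately: an e²-protected rate must remain quantifiable
  within the dose window.
* `gen_melt_curve()` — linear pre/post baselines joined by a logistic
  transition (default midpoint 51.6 °C, width 1.2 °C) plus Gaussian noise
  (default SD 20 RFU on a ~3200 RFU amplitude, ~0.6%, typical of RT-PCR
  DSF optics). Default baseline slopes are zero so the noiseless derivative
  extremum sits exactly at the design midpoint.
* `gen_progress_curves()` — linear signal growth at the Hill-kinetics rate
  over the six-point twofold titration 1.25–40 µM, triplicate wells,
  Gaussian read noise (SD 5 RFU).
* `gen_dose_response()` — three-parameter logistic over a 13-point twofold
  ladder, 0.078–320 nM, plus Gaussian noise (SD 3 percentage points). The
  ladder is anchored at the low end of the conventional 0.078–500 nM range;
  no exact twofold series contains both endpoints (their ratio is
  ≈ 2^12.65), and anchoring at the bottom keeps the sub-nM IC50s this panel
  targets well bracketed.

They do **not** emulate raw spectra or chromatograms, peak integration,
retention-time drift, correlated replicate noise, secondary oxidation
chemistry, plate-position effects, or inner-filter/quench artefacts. Passing
recovery tests therefore demonstrates that the reduction pipeline is
correct and unbiased under its own model assumptions — not that those
assumptions hold for any particular instrument.

## Problem sizes used by the test suite

Chosen to keep the suite fast while estimating medians stably: rate-recovery
bias uses 200 simulated datasets of 5 sites each with rates log-uniform on
[1, 100] s⁻¹ at default noise; IC50 recovery uses 200 stochastic replicates;
Tm recovery uses 20 seeds at default noise; the planted-protection
end-to-end check uses 10 seeds of the default two-state design. Determinism
is tested as byte-identity of generator output under a fixed seed.

## Known limitations

* PF absolute scale depends entirely on the user's reactivity table; only
  differential quantities are table-scale-free.
* The decay fit assumes homoscedastic noise on the fraction scale; strongly
  intensity-dependent MS noise would call for weighted fits.
* The Tm estimator targets a single dominant two-state transition;
  multi-domain proteins with comparable transitions get a flag, not a
  deconvolution.
* The IC50 model fixes the Hill slope at 1; steep or shallow dose-response
  data will show it in the residuals, not in a fitted slope.
* mmCIF files are read for mapping, but output is always fixed-column PDB.
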