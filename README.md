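# hrfassay

Quantitative analysis of **hydroxyl radical protein footprinting (HRF)** and
the biophysical assay panel that typically accompanies it — thermal-shift
melting temperatures, Michaelis–Menten/Hill enzyme kinetics, and IC50
dose–response fits. The package is aimed at structural-MS and enzymology
groups who have integrated peak areas or plate-reader exports in hand and
want a reproducible, tested reduction pipeline rather than spreadsheet
arithmetic.

## The model

In an HRF (synchrotron X-ray) experiment, solvent-exposed side chains are
covalently oxidised; buried residues react slowly. For each modification site
the fraction of the peptide population left unmodified is computed from
integrated MS peak areas of the unmodified (`A_u`) and modified (`A_m`)
species:

    F_u = 1 − A_m / (A_u + ΣA_m)

`F_u` decays with X-ray exposure time as a first-order process,

    F_u(t) = F_u(0) · exp(−k t)

and the fitted rate `k` is normalised by the residue type's intrinsic
hydroxyl-radical reactivity `R_i` to give a **protection factor**

    PF_i = R_i / k_i ,

whose natural log (`lnPF`) measures how buried the residue is. Comparing
`lnPF` per residue between two states (e.g. cofactor-bound apo versus
inhibitor-bound) yields a differential-protection map: residues with
`ΔlnPF = lnPF_bound − lnPF_apo` above a threshold (default 1 natural-log
unit and 2 propagated SEs) are called *more protected*, and the scores can
be written into the B-factor column of a PDB file for structure colouring.

The assay panel implements: Tm extraction as the extremum of −d(RFU)/dT on a
Savitzky–Golay-smoothed melt curve, with ladder bookkeeping of Tm increments
(apo → +cofactor → +cofactor+drug) and cross-variant stabilization losses;
initial-rate slopes and the Hill fit `v = Vmax·S^n/(K^n + S^n)`; and the
three-parameter logistic `y = bottom + (top − bottom)/(1 + IC50/[I])` with
unit Hill slope.

A synthetic-data module (`gen_hrf_dataset()`, `gen_melt_curve()`,
`gen_progress_curves()`, `gen_dose_response()`) generates inputs with each
assay's statistical structure plus machine-readable truth tables, so every
stage is testable without instrument data.

## Worked example

```r
library(hrfassay)
library(dplyr)

# two-state synthetic footprinting dataset: drug-contact probes
# F185/I190/Y217 are protected e^2-fold in the bound state
hrf <- gen_hrf_dataset(hrf_design(seed = 42, two_state = TRUE))
tab <- as_peak_area_table(hrf$records)
R   <- read_reactivity_csv(system.file("extdata", "reactivity_synthetic.csv",
                                       package = "hrfassay"))
apo   <- summarize_rates(filter(tab, state == "apo"),   R, "apo")$records
bound <- summarize_rates(filter(tab, state == "bound"), R, "bound")$records
diffs <- classify_residues(compare_states(apo, bound)$diffs)
arrange(diffs, desc(delta_ln_pf))
#>   site_id ln_pf_a ln_pf_b delta_ln_pf protection_class
#> 1 A:I190   -0.985    1.04      2.03   more_protected
#> 2 A:Y217    1.40     3.38      1.98   more_protected
#> 3 A:F185    0.679    2.54      1.87   more_protected
#> 4 A:Y151    1.80     1.87      0.0751 unchanged
#> # ... 6 more rows, all unchanged
```

The three planted residues — and only those — are recovered: their ΔlnPF ≈ 2
matches the e² protection multiplier, and everything else sits on the
diagonal. A melt curve generated with midpoint 51.6 °C at 0.5 °C sampling:

```r
g <- gen_melt_curve(melt_design(seed = 42, tm = 51.6))
melt_tm(g$curve$temperature, g$curve$rfu)
#>      tm derivative_extremum sg_window sg_order flag
#> 1  51.5               -659.         7        3 <NA>
```

## The analysis workflow

The `analysis/` scripts run the whole study on synthetic data and write
tables under `results/`:

```sh
Rscript analysis/01_simulate.R       # datasets + truth + manifest
Rscript analysis/02_fit_footprint.R  # rates and protection factors
Rscript analysis/03_differential.R   # classification, scatter table, PDB map
Rscript analysis/04_assays.R         # Tm ladder, Km/Hill, IC50 panels
```

Stage 04 prints, for curves simulated at the reported parameter values:

```
DM loses 13.0 degC of drug-induced stabilization vs WT
Km: WT 2.20 uM (nH 1.00), Y217A 10.9 uM -> 5.0-fold increase
quinoxaline: IC50 WT 1.18 nM, Y217A 8.37 nM -> 7.1-fold increase
thienopyridine: IC50 WT 0.42 nM, Y217A 0.91 nM -> 2.1-fold increase
```

i.e. the double mutant loses 13.0 °C of drug-induced thermal stabilization,
the Y217A-like variant shows the fivefold Km increase, and the two inhibitor
scaffolds show the sevenfold and twofold IC50 shifts.

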