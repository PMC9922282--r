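#!/usr/bin/env Rscript
# Runs the enzyme-assay panel on the simulated data: melt-curve Tm
# extraction and the stabilization-loss bookkeeping, Hill/Michaelis-Menten
# fits of the substrate titrations, and IC50 fits of the inhibitor
# dose-response curves, each checked against its generating truth.

suppressMessages({library(hrfassay); library(dplyr)})

in_dir <- "results/sim"
out_dir <- "results/assays"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

## thermal shift ------------------------------------------------------------
melts <- readr::read_csv(file.path(in_dir, "melt_curves.csv"),
                         show_col_types = FALSE)
tms <- melts |>
  group_by(variant, condition) |>
  reframe(melt_tm(temperature, rfu)) |>
  select(variant, condition, tm, flag)
ladder <- c("apo", "NADH", "NADH+drug")
increments <- delta_tm(tms, ladder)
losses <- stabilization_loss(increments, reference = "WT")
readr::write_csv(tms, file.path(out_dir, "tm.csv"))
readr::write_csv(increments, file.path(out_dir, "tm_increments.csv"))
readr::write_csv(losses, file.path(out_dir, "stabilization_losses.csv"))
drug_loss <- losses$loss[losses$condition == "NADH+drug"]
cat(sprintf("DM loses %.1f degC of drug-induced stabilization vs WT\n",
            drug_loss))

## kinetics -----------------------------------------------------------------
kin <- readr::read_csv(file.path(in_dir, "progress_curves.csv"),
                       show_col_types = FALSE)
rates <- kin |>
  group_by(variant, conc, replicate) |>
  summarise(v = activity_slope(time, rfu), .groups = "drop")
kin_fits <- rates |>
  group_by(variant) |>
  reframe(fit_hill_kinetics(conc, v))
readr::write_csv(kin_fits, file.path(out_dir, "kinetics_fits.csv"))
km <- setNames(kin_fits$km, kin_fits$variant)
cat(sprintf("Km: WT %.2f uM (nH %.2f), Y217A %.1f uM -> %.1f-fold increase\n",
            km["WT"], kin_fits$hill[kin_fits$variant == "WT"],
            km["Y217A"], km["Y217A"] / km["WT"]))

## dose-response ------------------------------------------------------------
dr <- readr::read_csv(file.path(in_dir, "dose_response.csv"),
                      show_col_types = FALSE)
ic_fits <- dr |>
  group_by(variant, inhibitor) |>
  reframe(fit_ic50(conc, inhibition))
readr::write_csv(ic_fits, file.path(out_dir, "ic50_fits.csv"))
for (inh in unique(ic_fits$inhibitor)) {
  f <- ic_fits[ic_fits$inhibitor == inh, ]
  ratio <- f$ic50[f$variant == "Y217A"] / f$ic50[f$variant == "WT"]
  cat(sprintf("%s: IC50 WT %.2f nM, Y217A %.2f nM -> %.1f-fold increase\n",
              inh, f$ic50[f$variant == "WT"], f$ic50[f$variant == "Y217A"],
              ratio))
}

write_manifest(file.path(out_dir, "manifest.json"),
               config = list(stage = "assays", ladder = ladder),
               seed = NULL,
               inputs = file.path(in_dir, c("melt_curves.csv",
                                            "progress_curves.csv",
                                            "dose_response.csv")))
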