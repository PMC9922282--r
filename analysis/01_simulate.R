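#!/usr/bin/env Rscript
# Generates the synthetic datasets every later stage consumes:
#   - a two-state hydroxyl-radical footprinting peak-area table (apo vs
#     drug-bound, with the drug-contact probes F185/I190/Y217 protected
#     e^2-fold when bound), plus its truth table
#   - thermal melt curves for a WT/mutant x condition ladder
#   - progress-curve titrations for WT-like (Km 2.2 uM) and Y217A-like
#     (Km 11 uM) kinetics
#   - inhibitor dose-response curves at the four reported IC50 truths
# Outputs land under results/sim/ with a JSON run manifest.

suppressMessages(library(hrfassay))

seed <- 20260921L
out_dir <- "results/sim"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

## footprinting -------------------------------------------------------------
hrf <- gen_hrf_dataset(hrf_design(seed = seed, two_state = TRUE))
write_peak_area_csv(hrf$records, file.path(out_dir, "hrf_peak_areas.csv"))
readr::write_csv(hrf$truth, file.path(out_dir, "hrf_truth.csv"))
cat("HRF: ", nrow(hrf$records), " peak-area rows over ",
    length(unique(hrf$records$site_id)), " sites x 2 states\n", sep = "")

## thermal shift ------------------------------------------------------------
# Ladder midpoints chosen so WT gains ~5 degC from cofactor and ~21.5 degC
# from cofactor+drug while the lid double mutant gains only ~8.5 degC from
# the drug -- the stabilization geometry the delta-Tm stage quantifies.
melt_plan <- expand.grid(
  variant = c("WT", "DM"), condition = c("apo", "NADH", "NADH+drug"),
  stringsAsFactors = FALSE
)
melt_plan$tm <- c(48.0, 44.5, 53.0, 47.5, 74.5, 56.0)
melts <- do.call(rbind, lapply(seq_len(nrow(melt_plan)), function(i) {
  g <- gen_melt_curve(melt_design(seed = seed + i, tm = melt_plan$tm[i]))
  cbind(variant = melt_plan$variant[i], condition = melt_plan$condition[i],
        g$curve)
}))
readr::write_csv(melts, file.path(out_dir, "melt_curves.csv"))
readr::write_csv(melt_plan, file.path(out_dir, "melt_truth.csv"))
cat("Melt: ", nrow(melt_plan), " curves, ", nrow(melts), " readings\n", sep = "")

## kinetics -----------------------------------------------------------------
kin_plan <- data.frame(variant = c("WT", "Y217A"), km = c(2.2, 11))
kin <- do.call(rbind, lapply(seq_len(nrow(kin_plan)), function(i) {
  g <- gen_progress_curves(kinetics_design(seed = seed + 10L + i,
                                           km = kin_plan$km[i]))
  cbind(variant = kin_plan$variant[i], g$curves)
}))
readr::write_csv(kin, file.path(out_dir, "progress_curves.csv"))
readr::write_csv(kin_plan, file.path(out_dir, "kinetics_truth.csv"))
cat("Kinetics: ", nrow(kin), " fluorescence reads\n", sep = "")

## dose-response ------------------------------------------------------------
dr_plan <- data.frame(
  variant = c("WT", "Y217A", "WT", "Y217A"),
  inhibitor = c("thienopyridine", "thienopyridine", "quinoxaline", "quinoxaline"),
  ic50 = c(0.43, 0.86, 1.2, 8.5)
)
dr <- do.call(rbind, lapply(seq_len(nrow(dr_plan)), function(i) {
  g <- gen_dose_response(inhibition_design(seed = seed + 20L + i,
                                           ic50 = dr_plan$ic50[i],
                                           replicates = 3L))
  cbind(variant = dr_plan$variant[i], inhibitor = dr_plan$inhibitor[i],
        g$curve)
}))
readr::write_csv(dr, file.path(out_dir, "dose_response.csv"))
readr::write_csv(dr_plan, file.path(out_dir, "dose_response_truth.csv"))
cat("Dose-response: ", nrow(dr), " wells\n", sep = "")

write_manifest(file.path(out_dir, "manifest.json"),
               config = list(stage = "simulate", two_state = TRUE),
               seed = seed,
               inputs = character())
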