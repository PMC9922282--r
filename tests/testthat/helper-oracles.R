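# Independent oracle for the first-order decay fit: ordinary linear
# regression of log(F_u) on t; slope = -k, intercept = log F_u(0).
loglinear_decay <- function(t, fu) {
  fit <- stats::lm(log(fu) ~ t)
  c(k = -unname(coef(fit)[2L]), f0 = exp(unname(coef(fit)[1L])))
}

# Noiseless exposure series at given rate/intercept (times in seconds)
noiseless_series <- function(k, f0 = 1, times = c(0, 0.025, 0.050, 0.075),
                             site = "A:F185") {
  tibble::tibble(
    site_id = site,
    exposure_time = times,
    replicate_id = "rep1",
    fraction_unmodified = f0 * exp(-k * times)
  )
}

# Minimal long-format peak-area table with exact areas for given site truths
make_peak_table <- function(sites, times_s = c(0, 0.025, 0.050, 0.075),
                            replicates = 1L, total = 1e6) {
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    for (t in times_s) for (r in seq_len(replicates)) {
      fu <- exp(-sites$k[i] * t)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        site_id = sites$site_id[i], chain = sites$chain[i],
        resnum = sites$resnum[i], restype = sites$restype[i],
        exposure_time = t, time_unit = "s",
        replicate_id = paste0("rep", r),
        area_unmodified = total * fu,
        species_label = "ox", area_modified = total * (1 - fu)
      )
    }
  }
  dplyr::bind_rows(rows)
}
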