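test_that("fraction unmodified follows the peak-area ratio definition", {
  expect_equal(fraction_unmodified(90, c(10), species = 1), 0.90)
  expect_equal(fraction_unmodified(100, c(0)), 1.0)
  # two modified species: per-species and aggregate fractions
  expect_equal(fraction_unmodified(70, c(20, 10), species = 1), 0.80)
  expect_equal(fraction_unmodified(70, c(20, 10), species = 2), 0.90)
  expect_equal(fraction_unmodified(70, c(20, 10)), 0.70)
})

test_that("degenerate peak areas are rejected, not silently scored", {
  expect_error(fraction_unmodified(0, c(0, 0)), "unquantifiable")
  expect_error(fraction_unmodified(-5, c(10)), "negative")
  expect_error(fraction_unmodified(10, c(-1)), "negative")
  expect_error(fraction_unmodified(10, c(5), species = 3), "out of range")
})

test_that("fraction unmodified and rates are invariant to intensity scale", {
  for (scale in c(0.01, 1, 250)) {
    expect_equal(fraction_unmodified(90 * scale, c(10) * scale, species = 1), 0.9)
  }
  sites <- tibble::tibble(site_id = "A:Y116", chain = "A", resnum = 116L,
                          restype = "Y", k = 12)
  tab1 <- make_peak_table(sites, total = 1e6)
  tab2 <- tab1
  tab2$area_unmodified <- tab2$area_unmodified * 37.5
  tab2$area_modified <- tab2$area_modified * 37.5
  R <- synthetic_reactivity()
  r1 <- summarize_rates(tab1, R)$records
  r2 <- summarize_rates(tab2, R)$records
  expect_equal(r1$rate_constant, r2$rate_constant, tolerance = 1e-10)
  expect_equal(r1$pf, r2$pf, tolerance = 1e-10)
})

test_that("exposure series keeps replicates as independent points", {
  sites <- tibble::tibble(site_id = "A:F185", chain = "A", resnum = 185L,
                          restype = "F", k = 30)
  tab <- make_peak_table(sites, replicates = 2L)
  series <- build_exposure_series(tab, "A:F185")
  expect_identical(nrow(series), 8L)   # duplicate reactions x four time points
  expect_identical(length(unique(series$exposure_time)), 4L)

  tab3 <- make_peak_table(sites, times_s = c(0, 0.025, 0.05), replicates = 1L)
  expect_identical(nrow(build_exposure_series(tab3, "A:F185")), 3L)

  expect_error(build_exposure_series(tab, "A:W99"), "not present")
  tab2 <- make_peak_table(sites, times_s = c(0, 0.05), replicates = 3L)
  expect_error(build_exposure_series(tab2, "A:F185"), "underdetermined")
})

test_that("first-order decay fit matches the log-linear oracle on noiseless data", {
  for (k_true in c(0.5, 5, 20, 80)) {
    series <- noiseless_series(k_true)
    fit <- fit_first_order_decay(series)
    oracle <- loglinear_decay(series$exposure_time, series$fraction_unmodified)
    expect_true(fit$converged)
    expect_equal(fit$rate_constant, unname(oracle["k"]), tolerance = 1e-6)
    expect_equal(fit$rate_constant, k_true, tolerance = 1e-6)
  }
})

test_that("fitted intercept recovers baseline oxidation", {
  series <- noiseless_series(5, f0 = 0.95)
  fit <- fit_first_order_decay(series)
  oracle <- loglinear_decay(series$exposure_time, series$fraction_unmodified)
  expect_equal(fit$rate_constant, 5, tolerance = 1e-6)
  expect_equal(fit$f0, 0.95, tolerance = 1e-6)
  expect_equal(fit$f0, unname(oracle["f0"]), tolerance = 1e-6)

  pinned <- fit_first_order_decay(series, fix_f0 = TRUE)
  expect_identical(pinned$f0, 1)
})

test_that("unmodified-flat and underdetermined series are flagged, never silently zero", {
  flat <- noiseless_series(0)
  fit <- fit_first_order_decay(flat)
  expect_identical(fit$rate_constant, 0)
  expect_identical(fit$flag, "no_detectable_modification")

  short <- noiseless_series(5)[1:2, ]
  fit2 <- fit_first_order_decay(short)
  expect_false(fit2$converged)
  expect_true(is.na(fit2$rate_constant))
})

test_that("protection factor is intrinsic reactivity over observed rate", {
  R <- tibble::tibble(restype = c("F", "Y"), reactivity = c(50, 30))
  fits <- tibble::tibble(
    site_id = c("A:F10", "A:F11", "A:Y12"),
    restype = c("F", "F", "Y"),
    rate_constant = c(10, 50, 0.3),
    rate_se = c(0.1, 0.1, 0.01), converged = TRUE
  )
  pf <- compute_protection_factor(fits, R)$records
  expect_equal(pf$pf, c(5, 1, 100))
  expect_equal(pf$ln_pf, log(c(5, 1, 100)))
  expect_equal(pf$ln_pf[2], 0)
})

test_that("PF is strictly decreasing in the modification rate at fixed reactivity", {
  R <- tibble::tibble(restype = "F", reactivity = 60)
  ks <- sort(stats::runif(25, 0.1, 100))
  fits <- tibble::tibble(site_id = paste0("A:F", seq_along(ks)),
                         restype = "F", rate_constant = ks,
                         rate_se = 0.1, converged = TRUE)
  pf <- compute_protection_factor(fits, R)$records
  expect_true(all(diff(pf$pf) < 0))
})

test_that("zero-rate sites are right-censored with the minimum-rate bound", {
  R <- tibble::tibble(restype = "F", reactivity = 60)
  fits <- tibble::tibble(site_id = "A:F1", restype = "F", rate_constant = 0,
                         rate_se = 0, converged = TRUE)
  pf <- compute_protection_factor(fits, R, min_rate = 0.5)$records
  expect_true(pf$censored)
  expect_equal(pf$pf, 60 / 0.5)
})

test_that("batch summariser scores every quantifiable site and side-reports the rest", {
  d <- hrf_design(seed = 11)
  tab <- as_peak_area_table(gen_hrf_dataset(d)$records)
  res <- summarize_rates(tab, synthetic_reactivity(), state_label = "apo")
  expect_identical(nrow(res$records), 10L)
  expect_identical(nrow(res$unscorable), 0L)
  expect_true(all(res$records$state_label == "apo"))
  # deterministic ordering by chain/residue number
  expect_identical(res$records$site_id,
                   res$records$site_id[order(res$records$chain,
                                             res$records$resnum)])

  # drop one residue type from the reactivity table -> unscorable side report
  R_missing <- dplyr::filter(synthetic_reactivity(), restype != "S")
  res2 <- summarize_rates(tab, R_missing)
  expect_identical(nrow(res2$records), 9L)
  expect_identical(res2$unscorable$site_id, "A:S138")
  expect_identical(res2$unscorable$reason, "missing_intrinsic_reactivity")

  expect_warning(empty <- summarize_rates(tab[0, ], synthetic_reactivity()),
                 "empty")
  expect_identical(nrow(empty$records), 0L)
})
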